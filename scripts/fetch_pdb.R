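#!/usr/bin/env Rscript
# Optional helper: download the published binding-pocket structures so
# the real-structure angle checks can run. Requires network access; the
# rest of the package and test suite never does.
#
#   Rscript scripts/fetch_pdb.R [destdir]

args <- commandArgs(trailingOnly = TRUE)
dest <- if (length(args) >= 1) args[1] else file.path("scratch", "pdb")
dir.create(dest, recursive = TRUE, showWarnings = FALSE)
for (id in c("2l7p", "5ix2")) {
  out <- file.path(dest, paste0(id, ".pdb"))
  if (file.exists(out)) next
  url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(id))
  message("fetching ", url)
  tryCatch(utils::download.file(url, out, quiet = TRUE),
           error = function(e) message("failed: ", conditionMessage(e)))
}
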