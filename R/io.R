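# Shared table IO (TSV/CSV with '#' metadata headers), per-stage
# readers/writers, and the run_stage() pipeline entry point that binds
# the analysis stages into reproducible, manifest-logged runs.

#' Read a delimited table with schema validation
#'
#' The delimiter is sniffed from the extension (`.csv` comma, anything
#' else tab). Leading lines starting with `#` are treated as metadata:
#' `# key = value` pairs are parsed and returned in the `metadata`
#' attribute. Missing required columns and non-numeric cells are
#' reported by name and position.
#'
#' @param path file path.
#' @param schema optional list with `required` (column names) and
#'   `numeric` (columns that must parse as numbers; defaults to
#'   `required`).
#' @return data.frame with a `metadata` attribute (named list).
#' @export
read_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.+?)\\s*$", h))[[1]]
    if (length(m) == 3L) {
      val <- suppressWarnings(as.numeric(m[3]))
      meta[[m[2]]] <- if (is.na(val)) m[3] else val
    }
  }
  df <- utils::read.table(text = lines, sep = sep, header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    req <- schema$required
    missing_cols <- setdiff(req, names(df))
    if (length(missing_cols) > 0L)
      stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
    numcols <- if (is.null(schema$numeric)) req else schema$numeric
    for (cn in intersect(numcols, names(df))) {
      v <- df[[cn]]
      if (!is.numeric(v)) {
        parsed <- suppressWarnings(as.numeric(v))
        bad <- which(is.na(parsed) & !is.na(v))
        if (length(bad) > 0L)
          stop(sprintf("non-numeric cell in column '%s', row %d: '%s'",
                       cn, bad[1], v[bad[1]]))
        df[[cn]] <- parsed
      }
    }
  }
  attr(df, "metadata") <- meta
  df
}

#' Write a table as TSV with optional '#' metadata header
#'
#' Numeric columns are written at full precision (15 significant
#' digits), so re-reading an output table reproduces the values.
#'
#' @param df data.frame.
#' @param path output path.
#' @param metadata named list written as `# key = value` lines.
#' @export
write_table <- function(df, path, metadata = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(metadata))
    writeLines(sprintf("# %s = %s", k, format(metadata[[k]], digits = 15)), con)
  is_num <- vapply(df, is.numeric, logical(1))
  df[is_num] <- lapply(df[is_num], function(v) format(v, digits = 15,
                                                      trim = TRUE))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ITC heat table into an isotherm
#'
#' Expects columns `injection_index`, `volume_ul`, `heat_uJ` and
#' metadata (in `#` header lines or the `config` list): `V0_ul`,
#' `cell_conc_uM`, `syringe_conc_uM`, `temperature_C`.
#'
#' @param path TSV/CSV path.
#' @param config optional named list overriding/supplying metadata.
#' @return an [itc_isotherm()].
#' @export
read_itc <- function(path, config = NULL) {
  df <- read_table(path, schema = list(
    required = c("injection_index", "volume_ul", "heat_uJ")))
  meta <- attr(df, "metadata")
  meta[names(config)] <- config
  need <- c("V0_ul", "cell_conc_uM", "syringe_conc_uM", "temperature_C")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0L)
    stop("missing experiment metadata: ", paste(miss, collapse = ", "))
  df <- df[order(df$injection_index), ]
  design <- itc_design(V0 = meta$V0_ul * 1e-6,
                       M0 = meta$cell_conc_uM * 1e-6,
                       X0 = meta$syringe_conc_uM * 1e-6,
                       inj_volumes = df$volume_ul * 1e-6,
                       T = meta$temperature_C + 273.15)
  itc_isotherm(design, df$heat_uJ)
}

#' Write an ITC isotherm as a heat table
#' @param iso an [itc_isotherm()].
#' @param path output path.
#' @export
write_itc <- function(iso, path) {
  d <- iso$design
  write_table(
    data.frame(injection_index = seq_along(iso$heats),
               volume_ul = d$inj_volumes * 1e6,
               heat_uJ = iso$heats),
    path,
    metadata = list(V0_ul = d$V0 * 1e6, cell_conc_uM = d$M0 * 1e6,
                    syringe_conc_uM = d$X0 * 1e6,
                    temperature_C = d$T - 273.15))
}

#' Read a melting table (precomputed ratio or long-format spectra)
#'
#' A table with columns `temperature_C`, `ratio_328_352` yields a
#' [melt_curve()]; one with `temperature_C`, `wavelength_nm`,
#' `intensity` yields a [spectrum_series()].
#'
#' @param path TSV/CSV path.
#' @return a [melt_curve()] or [spectrum_series()].
#' @export
read_melt <- function(path) {
  df <- read_table(path)
  if (all(c("temperature_C", "ratio_328_352") %in% names(df)))
    return(melt_curve(df$temperature_C, df$ratio_328_352))
  if (all(c("temperature_C", "wavelength_nm", "intensity") %in% names(df))) {
    tt <- sort(unique(df$temperature_C))
    wl <- sort(unique(df$wavelength_nm))
    m <- matrix(NA_real_, length(tt), length(wl))
    m[cbind(match(df$temperature_C, tt), match(df$wavelength_nm, wl))] <-
      df$intensity
    if (anyNA(m)) stop("incomplete temperature x wavelength grid")
    return(spectrum_series(tt, wl, m))
  }
  stop("expected columns (temperature_C, ratio_328_352) or ",
       "(temperature_C, wavelength_nm, intensity)")
}

#' Read a peak list (id, dH_ppm, dN_ppm)
#' @param path TSV/CSV path.
#' @param assigned flag stored on the list.
#' @return a [peak_list()].
#' @export
read_peaks <- function(path, assigned = TRUE) {
  df <- read_table(path, schema = list(required = c("id", "dH_ppm", "dN_ppm"),
                                       numeric = c("dH_ppm", "dN_ppm")))
  peak_list(df$id, df$dH_ppm, df$dN_ppm, assigned = assigned)
}

#' Read hetNOE intensity pairs (id, I_sat, I_ref[, sigma_sat, sigma_ref])
#' @param path TSV/CSV path.
#' @return a `"hetnoe_table"` via [het_noe()].
#' @export
read_noe <- function(path) {
  df <- read_table(path, schema = list(required = c("id", "I_sat", "I_ref"),
                                       numeric = c("I_sat", "I_ref")))
  het_noe(df$I_sat, df$I_ref,
          sigma_sat = if ("sigma_sat" %in% names(df)) df$sigma_sat else 0,
          sigma_ref = if ("sigma_ref" %in% names(df)) df$sigma_ref else 0,
          id = df$id)
}

#' Read long-format relaxation decays (id, delay_s, intensity)
#' @param path TSV/CSV path.
#' @return named list of [decay_series()].
#' @export
read_decays <- function(path) {
  df <- read_table(path, schema = list(required = c("id", "delay_s",
                                                    "intensity"),
                                       numeric = c("delay_s", "intensity")))
  out <- lapply(split(df, df$id), function(g) {
    g <- g[order(g$delay_s), ]
    decay_series(g$delay_s, g$intensity, id = g$id[1])
  })
  out
}

.stage_names <- c("itc_fit", "melt_fit", "csp", "hetnoe", "relax_fit",
                  "pocket_angle", "simulate")

#' Run one analysis stage from a configuration
#'
#' The reproducible pipeline entry point: validates the configuration
#' (unknown keys are rejected), runs the stage, writes its output
#' table(s) into `out_dir` and a `manifest.yaml` echoing the resolved
#' configuration, package version, seed and input checksums. Rerunning
#' the same configuration gives byte-identical numeric outputs.
#'
#' @param config list with `stage` (one of itc_fit, melt_fit, csp,
#'   hetnoe, relax_fit, pocket_angle, simulate), `inputs` (named paths),
#'   `params` (stage parameters), `out_dir`, optional `seed`.
#' @return named list of output paths (invisibly also written to
#'   `out_dir`).
#' @export
run_stage <- function(config) {
  allowed <- c("stage", "inputs", "params", "out_dir", "seed")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  stage <- config$stage
  if (is.null(stage) || !stage %in% .stage_names)
    stop("config$stage must be one of: ", paste(.stage_names, collapse = ", "))
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- if (is.null(config$params)) list() else config$params
  inputs <- config$inputs
  seed <- if (is.null(config$seed)) 0L else config$seed

  handler <- switch(stage,
    itc_fit = .stage_itc_fit, melt_fit = .stage_melt_fit,
    csp = .stage_csp, hetnoe = .stage_hetnoe,
    relax_fit = .stage_relax_fit, pocket_angle = .stage_pocket_angle,
    simulate = .stage_simulate)
  outputs <- tryCatch(
    handler(inputs, params, out_dir, seed),
    error = function(e) stop(sprintf("stage '%s' failed on %s: %s", stage,
                                     paste(unlist(inputs), collapse = ", "),
                                     conditionMessage(e)), call. = FALSE))

  manifest <- list(
    stage = stage,
    package = "readerbind",
    version = as.character(utils::packageVersion("readerbind")),
    seed = seed,
    params = params,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = outputs)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(c(outputs, manifest = file.path(out_dir, "manifest.yaml")))
}

.stage_itc_fit <- function(inputs, params, out_dir, seed) {
  iso <- read_itc(inputs$heats, config = params$experiment)
  if (!is.null(inputs$blank)) {
    blank <- read_itc(inputs$blank, config = params$experiment)
    iso <- subtract_blank(iso, blank)
  }
  free_n <- !isTRUE(params$fix_n)
  fit <- itc_fit(iso, free_n = free_n,
                 discard_first = isTRUE(params$discard_first))
  p <- fit$params
  tab <- data.frame(
    Kd_uM = if (fit$converged) p$Kd * 1e6 else NA,
    se_Kd_uM = fit$se[["Kd"]] * 1e6,
    dH_kJ_mol = if (fit$converged) p$dH else NA,
    se_dH_kJ_mol = fit$se[["dH"]],
    n = if (fit$converged) p$n else NA,
    se_n = fit$se[["n"]],
    dG_kJ_mol = if (fit$converged) p$dG else NA,
    TdS_kJ_mol = if (fit$converged) p$TdS else NA,
    dS_J_mol_K = if (fit$converged) p$dS else NA,
    c_value = fit$c_value,
    residual_rms_uJ = fit$residual_rms,
    converged = fit$converged,
    message = fit$message)
  f1 <- file.path(out_dir, "fit.tsv")
  write_table(tab, f1)
  f2 <- file.path(out_dir, "residuals.tsv")
  write_table(data.frame(injection_index = seq_along(iso$heats),
                         molar_ratio = iso$molar_ratio,
                         heat_uJ = iso$heats,
                         fitted_uJ = fit$fitted,
                         residual_uJ = iso$heats - fit$fitted), f2)
  list(fit = f1, residuals = f2)
}

.stage_melt_fit <- function(inputs, params, out_dir, seed) {
  obj <- read_melt(inputs$curve)
  if (inherits(obj, "spectrum_series")) {
    blank <- if (!is.null(inputs$blank)) read_melt(inputs$blank) else NULL
    obj <- ratio_from_spectra(obj, blank = blank)
  }
  fit <- melt_fit(obj)
  tab <- data.frame(Tm_C = fit$Tm,
                    y0 = fit$coefficients[["y0"]],
                    a = fit$coefficients[["a"]],
                    b = fit$coefficients[["b"]],
                    se_Tm_C = fit$se[["x0"]],
                    r_squared = fit$r_squared,
                    sigmoidal = fit$sigmoidal,
                    reasons = paste(fit$reasons, collapse = "; "))
  f1 <- file.path(out_dir, "tm.tsv")
  write_table(tab, f1)
  list(tm = f1)
}

.stage_csp <- function(inputs, params, out_dir, seed) {
  alphaN <- if (is.null(params$alphaN)) 0.17 else params$alphaN
  threshold <- if (is.null(params$threshold)) 0.2 else params$threshold
  apo <- read_peaks(inputs$apo)
  holo <- read_peaks(inputs$holo)
  if (isTRUE(params$unassigned)) {
    pairing <- match_unassigned(apo, holo, alphaN = alphaN)
    fs <- fraction_shifted(pairing, threshold = threshold)
    tab <- data.frame(ref_id = pairing$ref_id, query_id = pairing$query_id,
                      d_scaled_ppm = pairing$d,
                      shifted = pairing$d > threshold)
  } else {
    rec <- csp(apo, holo, alphaN = alphaN)
    fs <- fraction_shifted(rec, threshold = threshold)
    tab <- data.frame(id = rec$id, delta_dHN_ppm = rec$delta_dHN,
                      delta_dN_ppm = rec$delta_dN,
                      delta_ppm = rec$delta_ppm,
                      shifted = rec$delta_ppm > threshold)
  }
  f1 <- file.path(out_dir, "csp.tsv")
  write_table(tab, f1, metadata = list(
    alphaN = alphaN, threshold_ppm = threshold,
    percent_shifted = fs$percent, n_matched = fs$n_matched,
    n_unmatched_ref = fs$n_unmatched_ref,
    n_unmatched_query = fs$n_unmatched_query))
  list(csp = f1)
}

.stage_hetnoe <- function(inputs, params, out_dir, seed) {
  threshold <- if (is.null(params$threshold)) 0.75 else params$threshold
  tab <- read_noe(inputs$pairs)
  tab$class <- classify_mobility(tab, flexible_below = threshold)
  f1 <- file.path(out_dir, "hetnoe.tsv")
  write_table(as.data.frame(tab), f1,
              metadata = list(flexible_below = threshold))
  list(hetnoe = f1)
}

.stage_relax_fit <- function(inputs, params, out_dir, seed) {
  series <- read_decays(inputs$decays)
  rows <- lapply(series, function(s) {
    fit <- fit_monoexponential(s)
    data.frame(id = s$id, T_relax_s = fit$T_relax,
               se_T_relax_s = fit$se[["T_relax"]], I0 = fit$I0,
               converged = fit$converged)
  })
  f1 <- file.path(out_dir, "relax.tsv")
  write_table(do.call(rbind, rows), f1)
  list(relax = f1)
}

.stage_pocket_angle <- function(inputs, params, out_dir, seed) {
  res_pair <- params$residues
  if (is.null(res_pair) || length(res_pair) != 2L)
    stop("params$residues must give the two tryptophan residue numbers")
  chain <- if (is.null(params$chain)) "A" else params$chain
  pa <- pocket_angle(inputs$pdb, chain = chain, res_pair = res_pair,
                     include_cb = isTRUE(params$include_cb))
  tab <- cbind(pdb = basename(inputs$pdb), chain = chain,
               res1 = res_pair[1], res2 = res_pair[2], pa$per_model)
  names(tab)[names(tab) == "angle_unsigned"] <- "angle_unsigned_deg"
  names(tab)[names(tab) == "angle_oriented"] <- "angle_oriented_deg"
  names(tab)[names(tab) == "rms1"] <- "rms1_A"
  names(tab)[names(tab) == "rms2"] <- "rms2_A"
  f1 <- file.path(out_dir, "angles.tsv")
  write_table(tab, f1)
  list(angles = f1)
}

.stage_simulate <- function(inputs, params, out_dir, seed) {
  kind <- params$kind
  if (is.null(kind)) stop("params$kind is required for simulate")
  out <- list()
  if (kind == "isotherm") {
    truth <- thermo_params(Kd = params[["Kd"]], dH = params[["dH"]],
                           n = if (is.null(params[["n"]])) 1
                               else params[["n"]])
    sim <- gen_isotherm(truth,
                        noise_sigma = if (is.null(params$noise_sigma)) 2
                                      else params$noise_sigma,
                        seed = seed)
    out$heats <- file.path(out_dir, "heats.tsv")
    out$blank <- file.path(out_dir, "blank.tsv")
    write_itc(sim$sample, out$heats)
    write_itc(sim$blank, out$blank)
  } else if (kind == "melt") {
    cu <- gen_melt(params$truth,
                   noise_sigma = if (is.null(params$noise_sigma)) 0
                                 else params$noise_sigma,
                   seed = seed)
    out$curve <- file.path(out_dir, "melt.tsv")
    write_table(data.frame(temperature_C = cu$temperatures,
                           ratio_328_352 = cu$ratio), out$curve)
  } else if (kind == "fingerprint") {
    fp <- gen_fingerprint(
      n_peaks = if (is.null(params$n_peaks)) 60 else params$n_peaks,
      shifted_fraction = params$shifted_fraction, seed = seed)
    out$reference <- file.path(out_dir, "reference.tsv")
    out$query <- file.path(out_dir, "query.tsv")
    for (nm in c("reference", "query"))
      write_table(data.frame(id = fp[[nm]]$id, dH_ppm = fp[[nm]]$dH,
                             dN_ppm = fp[[nm]]$dN), out[[nm]])
  } else if (kind == "ringpair") {
    model <- gen_ringpair(params$angle_deg)
    out$pdb <- file.path(out_dir, "ringpair.pdb")
    write_pdb(model, out$pdb)
  } else if (kind == "relaxation") {
    tab <- gen_relaxation(params$profile, kind = "noe",
                          noise = if (is.null(params$noise)) 0
                                  else params$noise, seed = seed)
    out$pairs <- file.path(out_dir, "noe_pairs.tsv")
    write_table(as.data.frame(tab)[, c("id", "I_sat", "I_ref")], out$pairs)
  } else {
    stop("unknown simulation kind: ", kind)
  }
  out
}
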