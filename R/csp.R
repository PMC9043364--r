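# Chemical-shift perturbation analysis of 1H-15N fingerprint spectra:
# combined amide shifts, peak-list matching for unassigned spectra, and
# the fraction of substantially shifted signals.

#' An amide fingerprint peak list
#'
#' @param id residue numbers or opaque peak labels (unique).
#' @param dH 1H chemical shifts, ppm.
#' @param dN 15N chemical shifts, ppm.
#' @param assigned logical flag (single value or per peak).
#' @return a data.frame of class `"peak_list"` with columns
#'   `id`, `dH`, `dN`, `assigned`. Shifts outside the amide fingerprint
#'   window (1H 5-13 ppm, 15N 100-140 ppm) trigger a warning, not an
#'   error, since folded side-chain signals can fall outside it.
#' @export
peak_list <- function(id, dH, dN, assigned = TRUE) {
  stopifnot(length(dH) == length(id), length(dN) == length(id))
  if (anyDuplicated(id)) stop("peak ids must be unique within a list")
  if (any(dH < 5 | dH > 13) || any(dN < 100 | dN > 140))
    warning("shifts outside the usual amide fingerprint window ",
            "(1H 5-13 ppm, 15N 100-140 ppm)")
  structure(data.frame(id = id, dH = as.numeric(dH), dN = as.numeric(dN),
                       assigned = assigned),
            class = c("peak_list", "data.frame"))
}

# scaled distance in the combined-shift metric
.csp_dist <- function(ddH, ddN, alphaN) sqrt(ddH^2 + (alphaN * ddN)^2)

#' Combined chemical-shift perturbation between two assigned peak lists
#'
#' For each residue id present in both lists, the combined shift
#' `delta_ppm = sqrt(ddHN^2 + (ddN * alphaN)^2)` with the nitrogen
#' scaling factor `alphaN` (default 0.17) that places 15N shift changes
#' on a 1H-equivalent ppm scale.
#'
#' @param apo,holo [peak_list()]s (e.g. unbound and peptide-bound forms),
#'   matched on `id`.
#' @param alphaN nitrogen scaling factor, default 0.17.
#' @return data.frame of class `"csp_table"`: `id`, `delta_dHN`,
#'   `delta_dN`, `delta_ppm`, sorted by id order of `apo`. Ids present
#'   in only one list (exchange-broadened or unassigned in the other
#'   state) are reported in attributes `only_apo` / `only_holo`.
#' @examples
#' a <- peak_list(1:2, c(8.0, 8.5), c(120, 125))
#' b <- peak_list(1:2, c(8.1, 8.5), c(121, 125))
#' csp(a, b)
#' @export
csp <- function(apo, holo, alphaN = 0.17) {
  stopifnot(inherits(apo, "peak_list"), inherits(holo, "peak_list"))
  common <- intersect(apo$id, holo$id)
  if (length(common) == 0L) stop("no ids shared between the two lists")
  ia <- match(common, apo$id)
  ih <- match(common, holo$id)
  ddH <- holo$dH[ih] - apo$dH[ia]
  ddN <- holo$dN[ih] - apo$dN[ia]
  out <- data.frame(id = common, delta_dHN = ddH, delta_dN = ddN,
                    delta_ppm = .csp_dist(ddH, ddN, alphaN))
  structure(out, class = c("csp_table", "data.frame"),
            only_apo = setdiff(apo$id, common),
            only_holo = setdiff(holo$id, common),
            alphaN = alphaN)
}

#' Match peaks between a reference and an unassigned query fingerprint
#'
#' Greedy mutual-nearest-neighbour matching in the alphaN-scaled metric
#' `d = sqrt(ddHN^2 + (alphaN * ddN)^2)`: candidate pairs are taken in
#' order of increasing d (ties broken by lowest reference id, then
#' lowest query position), each peak used at most once. Used to compare
#' mutant fingerprints, which lack assignments, against the wild type.
#'
#' @param reference,query [peak_list()]s.
#' @param alphaN nitrogen scaling factor, default 0.17.
#' @param max_distance optional cap on the pairing distance (ppm in the
#'   scaled metric); pairs farther apart are left unmatched. Default
#'   `Inf`.
#' @return data.frame of class `"peak_pairing"` with columns `ref_id`,
#'   `query_id`, `d` (scaled ppm), plus attributes `unmatched_ref` and
#'   `unmatched_query`.
#' @export
match_unassigned <- function(reference, query, alphaN = 0.17,
                             max_distance = Inf) {
  stopifnot(inherits(reference, "peak_list"), inherits(query, "peak_list"),
            nrow(reference) > 0L, nrow(query) > 0L)
  nr <- nrow(reference); nq <- nrow(query)
  dmat <- outer(reference$dH, query$dH, "-")^2 +
    alphaN^2 * outer(reference$dN, query$dN, "-")^2
  dmat <- sqrt(dmat)
  ord <- order(dmat, row(dmat), col(dmat))   # d, then ref index, then query
  ref_used <- logical(nr); qry_used <- logical(nq)
  ref_idx <- integer(0); qry_idx <- integer(0)
  for (k in ord) {
    if (dmat[k] > max_distance) break
    i <- row(dmat)[k]; j <- col(dmat)[k]
    if (ref_used[i] || qry_used[j]) next
    ref_used[i] <- TRUE; qry_used[j] <- TRUE
    ref_idx <- c(ref_idx, i); qry_idx <- c(qry_idx, j)
    if (all(ref_used) || all(qry_used)) break
  }
  o <- order(ref_idx)
  out <- data.frame(ref_id = reference$id[ref_idx[o]],
                    query_id = query$id[qry_idx[o]],
                    d = dmat[cbind(ref_idx[o], qry_idx[o])])
  structure(out, class = c("peak_pairing", "data.frame"),
            unmatched_ref = reference$id[!ref_used],
            unmatched_query = query$id[!qry_used],
            alphaN = alphaN)
}

#' Percentage of matched peaks shifted beyond a threshold
#'
#' The fingerprint-change summary used to compare mutants against the
#' wild type: the percentage of matched peak pairs whose scaled distance
#' exceeds `threshold` (default 0.2 ppm, the customary cutoff for a
#' "substantial" shift). Unmatched peaks are reported alongside but are
#' excluded from the denominator.
#'
#' @param pairing a `"peak_pairing"` from [match_unassigned()], or a
#'   `"csp_table"` from [csp()] (then `delta_ppm` is used as d).
#' @param threshold ppm in the scaled combined-shift metric, default 0.2.
#' @return list with `percent` (100 x shifted/matched), `n_shifted`,
#'   `n_matched`, `n_unmatched_ref`, `n_unmatched_query`.
#' @export
fraction_shifted <- function(pairing, threshold = 0.2) {
  if (inherits(pairing, "csp_table")) {
    d <- pairing$delta_ppm
    unref <- attr(pairing, "only_apo"); unqry <- attr(pairing, "only_holo")
  } else if (inherits(pairing, "peak_pairing")) {
    d <- pairing$d
    unref <- attr(pairing, "unmatched_ref")
    unqry <- attr(pairing, "unmatched_query")
  } else stop("pairing must be a peak_pairing or csp_table")
  if (length(d) == 0L) stop("empty pairing")
  n_shift <- sum(d > threshold)
  list(percent = 100 * n_shift / length(d),
       n_shifted = n_shift, n_matched = length(d),
       n_unmatched_ref = length(unref), n_unmatched_query = length(unqry))
}
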