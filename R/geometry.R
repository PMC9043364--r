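# Binding-pocket tryptophan geometry from PDB coordinates: total-least-
# squares plane fits through indole ring atoms and the angle between the
# two ring planes of the pocket tryptophan pair.

# canonical indole ring atoms; perimeter order used for oriented normals
TRP_RING_ATOMS <- c("CG", "CD1", "CD2", "NE1", "CE2", "CE3",
                    "CZ2", "CZ3", "CH2")
TRP_RING_PERIMETER <- c("CG", "CD1", "NE1", "CE2", "CZ2", "CH2",
                        "CZ3", "CE3", "CD2")

#' Read a PDB file into per-model atom tables
#'
#' Parses fixed-column PDB ATOM/HETATM records (via bio3d) into one atom
#' data.frame per MODEL block (a single implicit model when the file has
#' no MODEL records, as in crystal structures). Alternate locations are
#' filtered to blank or 'A'; hydrogens are retained here and ignored by
#' downstream ring extraction.
#'
#' @param path path to a PDB-format file, or a character vector of PDB
#'   lines (detected by the presence of newline-separated records).
#' @return list of class `"pdb_models"`; each element a data.frame with
#'   columns `serial`, `atom_name`, `alt_loc`, `res_name`, `chain_id`,
#'   `res_seq`, `insert`, `x`, `y`, `z`, `element`.
#' @export
read_pdb <- function(path) {
  if (length(path) > 1L || grepl("\n", path[1])) {
    tf <- tempfile(fileext = ".pdb")
    on.exit(unlink(tf))
    writeLines(if (length(path) > 1L) path else strsplit(path, "\n")[[1]], tf)
    path <- tf
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  at <- pdb$atom
  if (nrow(at) == 0L) stop("empty structure: no ATOM/HETATM records")
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  nmodels <- nrow(pdb$xyz)
  models <- vector("list", nmodels)
  for (m in seq_len(nmodels)) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    df <- data.frame(
      serial = at$eleno, atom_name = at$elety,
      alt_loc = ifelse(is.na(at$alt), "", at$alt),
      res_name = at$resid, chain_id = at$chain, res_seq = at$resno,
      insert = ifelse(is.na(at$insert), "", at$insert),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      element = ifelse(is.na(at$elesy), "", at$elesy),
      stringsAsFactors = FALSE)
    models[[m]] <- df[keep, , drop = FALSE]
  }
  structure(models, class = "pdb_models")
}

#' Serialize a single-model atom table to PDB text
#'
#' Fixed-width ATOM records (the subset of the PDB format needed to
#' round-trip generated structures through [read_pdb()]).
#'
#' @param model a data.frame as returned in [read_pdb()] elements.
#' @param path optional output file; when omitted the lines are
#'   returned.
#' @return character vector of PDB lines, invisibly when written.
#' @export
write_pdb <- function(model, path = NULL) {
  stopifnot(is.data.frame(model), nrow(model) > 0L)
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    model$serial,
    ifelse(nchar(model$atom_name) < 4L, paste0(" ", model$atom_name),
           model$atom_name),
    substr(paste0(model$alt_loc, " "), 1, 1),
    model$res_name, model$chain_id, model$res_seq,
    substr(paste0(model$insert, " "), 1, 1),
    model$x, model$y, model$z, 1, 0,
    ifelse(nchar(model$element) > 0, model$element,
           substr(gsub("[0-9]", "", model$atom_name), 1, 1)))
  lines <- c(lines, "END")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Extract the nine indole ring atoms of a tryptophan residue
#'
#' @param model one element of a [read_pdb()] result.
#' @param chain chain identifier.
#' @param res_seq residue sequence number.
#' @return 9 x 3 coordinate matrix (Angstroms) with rownames CG, CD1,
#'   CD2, NE1, CE2, CE3, CZ2, CZ3, CH2; errors if the residue is
#'   missing, is not a tryptophan, or lacks ring atoms.
#' @export
extract_trp_ring <- function(model, chain, res_seq) {
  sel <- model$chain_id == chain & model$res_seq == res_seq
  if (!any(sel)) stop(sprintf("residue %s/%d not found", chain, res_seq))
  res <- model[sel, , drop = FALSE]
  rn <- unique(res$res_name)
  if (!identical(rn, "TRP"))
    stop(sprintf("residue %s/%d is not a tryptophan (found %s)",
                 chain, res_seq, paste(rn, collapse = ",")))
  idx <- match(TRP_RING_ATOMS, res$atom_name)
  if (anyNA(idx))
    stop("incomplete indole ring; missing atoms: ",
         paste(TRP_RING_ATOMS[is.na(idx)], collapse = ", "))
  coords <- as.matrix(res[idx, c("x", "y", "z")])
  rownames(coords) <- TRP_RING_ATOMS
  d <- stats::dist(coords)
  if (any(d < 1.2) || any(d > 5.5))
    stop("ring atom distances outside [1.2, 5.5] Angstroms; ",
         "coordinates look corrupted")
  coords
}

#' Total-least-squares plane through a set of points
#'
#' The plane through the centroid whose unit normal is the eigenvector
#' of the 3x3 coordinate scatter matrix with the smallest eigenvalue
#' (the direction of least variance), which minimizes the sum of squared
#' out-of-plane distances over all planes. The normal's sign is fixed
#' deterministically (largest-magnitude component positive).
#'
#' @param coords n x 3 coordinate matrix, n >= 3, non-collinear.
#' @return object of class `"plane_fit"`: `centroid`, `normal` (unit),
#'   `rms_out_of_plane` (Angstroms), `eigenvalues`.
#' @export
fit_plane <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L, nrow(coords) >= 3L)
  centroid <- colMeans(coords)
  cc <- sweep(coords, 2, centroid)
  sc <- crossprod(cc)
  eg <- eigen(sc, symmetric = TRUE)
  if (eg$values[2] < 1e-12 * max(eg$values[1], 1))
    stop("degenerate (collinear) coordinates: no unique plane")
  normal <- eg$vectors[, 3]
  i <- which.max(abs(normal))
  if (normal[i] < 0) normal <- -normal
  structure(list(centroid = centroid, normal = normal,
                 rms_out_of_plane = sqrt(eg$values[3] / nrow(coords)),
                 eigenvalues = eg$values),
            class = "plane_fit")
}

# Newell-method normal over the canonical ring perimeter; orientation is
# therefore a deterministic function of the ring winding, not of the
# eigen decomposition's arbitrary sign.
newell_normal <- function(ring) {
  stopifnot(all(TRP_RING_PERIMETER %in% rownames(ring)))
  v <- ring[TRP_RING_PERIMETER, , drop = FALSE]
  nv <- nrow(v)
  nxt <- c(2:nv, 1)
  n <- c(sum((v[, 2] - v[nxt, 2]) * (v[, 3] + v[nxt, 3])),
         sum((v[, 3] - v[nxt, 3]) * (v[, 1] + v[nxt, 1])),
         sum((v[, 1] - v[nxt, 1]) * (v[, 2] + v[nxt, 2])))
  len <- sqrt(sum(n^2))
  if (len == 0) stop("zero-length Newell normal")
  n / len
}

#' Angle between two fitted planes
#'
#' The unsigned angle `acos(|n1 . n2|)` lies in \[0, 90\] degrees and is
#' free of any normal-orientation convention; the oriented angle
#' `acos(n1 . n2)` in \[0, 180\] uses the supplied oriented normals
#' (e.g. Newell normals over the canonical ring winding) and satisfies
#' `unsigned = min(oriented, 180 - oriented)`.
#'
#' @param p1,p2 `"plane_fit"` objects.
#' @param oriented_normals optional list of two unit normals with a
#'   deterministic orientation; defaults to the plane-fit normals.
#' @return list with `angle_unsigned` and `angle_oriented` (degrees).
#' @export
interplane_angle <- function(p1, p2, oriented_normals = NULL) {
  stopifnot(inherits(p1, "plane_fit"), inherits(p2, "plane_fit"))
  clamp <- function(x) pmin(1, pmax(-1, x))
  dotu <- clamp(abs(sum(p1$normal * p2$normal)))
  unsigned <- acos(dotu) * 180 / pi
  if (is.null(oriented_normals)) {
    doto <- clamp(sum(p1$normal * p2$normal))
  } else {
    n1 <- oriented_normals[[1]]; n2 <- oriented_normals[[2]]
    if (any(abs(c(sum(n1^2), sum(n2^2)) - 1) > 1e-6))
      stop("oriented normals must be unit vectors")
    doto <- clamp(sum(n1 * n2))
  }
  list(angle_unsigned = unsigned, angle_oriented = acos(doto) * 180 / pi)
}

#' Binding-pocket tryptophan pair angle of a structure
#'
#' Composition of ring extraction, plane fitting and the inter-plane
#' angle for the two pocket tryptophans. For multi-model (NMR ensemble)
#' entries every model is measured; model 1 is the headline value and
#' the per-model mean and range are reported alongside.
#'
#' @param structure a `"pdb_models"` list from [read_pdb()], or a path
#'   to a PDB file.
#' @param chain chain used for the calculation; `'A'` by convention when
#'   several chains are present.
#' @param res_pair integer vector of the two tryptophan residue numbers
#'   (numbering of the PDB entry).
#' @param include_cb also include the sp3 CB atom in each plane fit
#'   (sensitivity check; default `FALSE` keeps the nine planar ring
#'   atoms).
#' @return object of class `"pocket_angle"`: `per_model` data.frame
#'   (`model`, `angle_unsigned`, `angle_oriented`, `rms1`, `rms2`),
#'   headline `angle_unsigned`/`angle_oriented` (model 1), `mean`,
#'   `range`, `chain`, `res_pair`.
#' @examples
#' m <- gen_ringpair(65)
#' pocket_angle(list(m), res_pair = c(1, 2))
#' @export
pocket_angle <- function(structure, chain = "A", res_pair,
                         include_cb = FALSE) {
  if (is.character(structure)) structure <- read_pdb(structure)
  if (is.data.frame(structure)) structure <- list(structure)
  stopifnot(length(res_pair) == 2L)
  rows <- lapply(seq_along(structure), function(m) {
    model <- structure[[m]]
    r1 <- extract_trp_ring(model, chain, res_pair[1])
    r2 <- extract_trp_ring(model, chain, res_pair[2])
    f1 <- r1; f2 <- r2
    if (include_cb) {
      cb <- function(rs) {
        sel <- model$chain_id == chain & model$res_seq == rs &
          model$atom_name == "CB"
        as.matrix(model[sel, c("x", "y", "z")])
      }
      f1 <- rbind(r1, cb(res_pair[1]))
      f2 <- rbind(r2, cb(res_pair[2]))
    }
    p1 <- fit_plane(f1)
    p2 <- fit_plane(f2)
    ang <- interplane_angle(p1, p2,
                            list(newell_normal(r1), newell_normal(r2)))
    data.frame(model = m, angle_unsigned = ang$angle_unsigned,
               angle_oriented = ang$angle_oriented,
               rms1 = p1$rms_out_of_plane, rms2 = p2$rms_out_of_plane)
  })
  per_model <- do.call(rbind, rows)
  structure(list(per_model = per_model,
                 angle_unsigned = per_model$angle_unsigned[1],
                 angle_oriented = per_model$angle_oriented[1],
                 mean = mean(per_model$angle_unsigned),
                 range = range(per_model$angle_unsigned),
                 chain = chain, res_pair = res_pair),
            class = "pocket_angle")
}

#' @export
print.pocket_angle <- function(x, ...) {
  cat(sprintf("Pocket tryptophan pair %d/%d, chain %s\n",
              x$res_pair[1], x$res_pair[2], x$chain))
  cat(sprintf("  unsigned angle: %.1f deg (model 1)\n", x$angle_unsigned))
  cat(sprintf("  oriented angle: %.1f deg (canonical ring winding)\n",
              x$angle_oriented))
  if (nrow(x$per_model) > 1L)
    cat(sprintf("  %d models: mean %.1f, range [%.1f, %.1f] deg\n",
                nrow(x$per_model), x$mean, x$range[1], x$range[2]))
  invisible(x)
}
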