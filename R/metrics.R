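#' Construct a structure model
#'
#' Parallel arrays of atom names, 1-based residue ids and coordinates; the
#' minimal representation needed for selection and superposition.
#'
#' @param atom_names character vector.
#' @param residue_ids integer vector (1-based).
#' @param coordinates `n x 3` numeric matrix (Angstrom).
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atom_names, residue_ids, coordinates) {
  coordinates <- as.matrix(coordinates)
  n <- length(atom_names)
  if (length(residue_ids) != n || nrow(coordinates) != n ||
      ncol(coordinates) != 3)
    stop("atom_names, residue_ids and coordinates must be parallel (n x 3)")
  structure(list(atom_names = as.character(atom_names),
                 residue_ids = as.integer(residue_ids),
                 coordinates = unname(coordinates * 1.0)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d atoms, %d residues\n",
              length(x$atom_names), length(unique(x$residue_ids))))
  invisible(x)
}

#' Select alpha- and beta-carbon atoms
#'
#' Indices of atoms named `CA` plus atoms named `CB`, ordered by residue
#' (CA before CB within a residue).  Residues lacking a CB (glycine)
#' contribute only their CA.
#'
#' @param structure a `structure_model` (or anything with `atom_names` and
#'   `residue_ids`).
#' @return integer vector of atom indices.
#' @export
select_cab <- function(structure) {
  nm <- structure$atom_names
  rid <- structure$residue_ids
  if (!any(nm == "CA")) stop("selection error: no CA atoms present")
  idx <- integer(0)
  for (r in sort(unique(rid))) {
    idx <- c(idx, which(rid == r & nm == "CA"), which(rid == r & nm == "CB"))
  }
  idx
}

pair_cab <- function(mobile, reference) {
  im <- select_cab(mobile)
  ir <- select_cab(reference)
  key <- function(s, i) paste(s$residue_ids[i], s$atom_names[i], sep = ":")
  if (length(im) != length(ir) ||
      !identical(key(mobile, im), key(reference, ir)))
    stop("pairing error: mobile and reference CA/CB atoms do not match ",
         "by (residue_id, atom_name)")
  cbind(im, ir)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Optimal proper rotation and translation minimising the unweighted mean
#' squared distance between paired atoms; reflections are forbidden (the
#' rotation determinant is forced to +1).  No mass weighting.
#'
#' @param mobile a `structure_model` to be fitted.
#' @param reference a `structure_model` to fit onto.
#' @param selection two-column integer matrix of paired atom indices
#'   (mobile, reference); defaults to the matched CA/CB selection.
#' @return list of class `superposition` with elements `rotation` (3x3,
#'   det +1), `translation` (applied after rotation about the mobile
#'   centroid), `rmsd` (Angstrom) and `fitted` (transformed mobile
#'   selection coordinates).
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  if (is.null(selection)) selection <- pair_cab(mobile, reference)
  selection <- as.matrix(selection)
  if (ncol(selection) == 1) selection <- cbind(selection, selection)
  if (nrow(selection) < 3) stop("need at least 3 paired atoms")
  P <- mobile$coordinates[selection[, 1], , drop = FALSE]
  Q <- reference$coordinates[selection[, 2], , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  sv_p <- svd(P0)$d
  if (sv_p[2] < 1e-8 * max(sv_p[1], 1))
    stop("numerical degeneracy: selected atoms are collinear")
  H <- crossprod(P0, Q0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- P0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q0)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(cq),
                 centroid_mobile = as.numeric(cp),
                 rmsd = rmsd,
                 fitted = sweep(fitted, 2, cq, "+")),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' RMSD between two structures after optimal superposition
#' @inheritParams superpose
#' @return RMSD in Angstrom.
#' @export
rmsd_fit <- function(mobile, reference, selection = NULL) {
  superpose(mobile, reference, selection)$rmsd
}

#' Per-frame Calpha/Cbeta RMSD series for a trajectory
#'
#' Each saved frame is independently superposed (unweighted least squares)
#' onto the reference over the matched CA/CB selection and its RMSD
#' recorded.
#'
#' @param trajectory a `trajectory` whose frames match `topology`.
#' @param reference a `structure_model` (e.g. the first model of an NMR
#'   ensemble).
#' @param topology a `structure_model` supplying atom names and residue ids
#'   for the trajectory frames (coordinates ignored).
#' @param selection optional two-column index matrix (frame atom, reference
#'   atom); defaults to the matched CA/CB pairing.
#' @return numeric vector of RMSDs (Angstrom), one per frame.
#' @export
cab_rmsd_series <- function(trajectory, reference, topology,
                            selection = NULL) {
  if (n_frames(trajectory) == 0) return(numeric(0))
  natom <- nrow(trajectory$frames[[1]])
  if (natom != length(topology$atom_names))
    stop("format error: frame atom count does not match topology")
  if (is.null(selection)) selection <- pair_cab(topology, reference)
  vapply(trajectory$frames, function(fr) {
    mob <- structure_model(topology$atom_names, topology$residue_ids, fr)
    superpose(mob, reference, selection)$rmsd
  }, numeric(1))
}

#' Classify frames as native by an RMSD cutoff
#'
#' A conformation is native when its RMSD is less than or equal to the
#' cutoff (inclusive boundary).  The conventional cutoff for the CLN025 /
#' chignolin beta-hairpin systems is 1.96 Angstrom, chosen to admit
#' crystal-structure-like conformations (NMR/crystal gap 1.95 Angstrom)
#' while excluding native-like misfolds; it is a parameter here, never a
#' constant.
#'
#' @param series numeric RMSD series (Angstrom).
#' @param cutoff positive cutoff (Angstrom).
#' @return logical vector, `TRUE` for native frames.
#' @export
classify_native <- function(series, cutoff = 1.96) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  as.logical(series <= cutoff)
}
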