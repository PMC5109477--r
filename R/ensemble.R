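#' Coordinate ensembles and fluctuation series
#'
#' `coordinate_ensemble()` bundles a frames x sites x 3 Cartesian coordinate
#' array (Angstrom) with per-site labels and the time spacing between stored
#' frames. It is the common container produced by [read_ensemble()] and
#' consumed by the superposition, fluctuation and distance operations.
#'
#' @param coords numeric array, frames x sites x 3, in Angstrom.
#' @param site_labels data.frame with columns `resno` (source-file residue
#'   number, kept verbatim), `resname`, `atom`, `chain` and optionally
#'   `record` (`"ATOM"`/`"HETATM"`); one row per site, rows unique.
#' @param dt time between stored frames, ps (formats carry this unreliably,
#'   so it is always supplied by the caller).
#' @param source free-text provenance.
#' @return An object of class `"coordinate_ensemble"`.
#' @export
coordinate_ensemble <- function(coords, site_labels, dt, source = "") {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    abort_argument("coords must be a frames x sites x 3 array")
  if (dim(coords)[1] < 2)
    abort_insufficient("a coordinate ensemble needs at least 2 frames")
  if (any(!is.finite(coords)))
    abort_integrity("non-finite coordinates in ensemble")
  if (!is.data.frame(site_labels) || nrow(site_labels) != dim(coords)[2])
    abort_argument("site_labels must have one row per site")
  if (is.null(site_labels$record)) site_labels$record <- "ATOM"
  if (anyDuplicated(site_key(site_labels)))
    abort_integrity("site labels are not unique")
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    abort_argument("dt must be a single positive number (ps)")
  structure(list(coords = coords, site_labels = site_labels,
                 dt = as.numeric(dt), source = as.character(source)),
            class = "coordinate_ensemble")
}

#' @export
print.coordinate_ensemble <- function(x, ...) {
  cat(sprintf("<coordinate_ensemble> %d frames x %d sites, dt = %g ps\n",
              dim(x$coords)[1], dim(x$coords)[2], x$dt))
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

n_frames <- function(x) dim(if (inherits(x, "fluctuation_series")) x$deltas else x$coords)[1]
n_sites  <- function(x) dim(if (inherits(x, "fluctuation_series")) x$deltas else x$coords)[2]

# Kabsch optimal rotation R minimizing ||P0 R - Q0|| (both pre-centered).
kabsch_rotation <- function(P0, Q0) {
  H <- crossprod(P0, Q0)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Superpose every frame onto a reference frame
#'
#' Removes rigid-body motion by least-squares superposition (optimal rotation
#' plus translation, uniform weights over all selected sites) of each frame
#' onto the chosen reference frame. The reference frame itself is returned
#' unchanged; the operation is idempotent.
#'
#' @param ensemble a [coordinate_ensemble()].
#' @param reference_frame 1-based frame index to align onto (default 1,
#'   i.e. the initial structure).
#' @return A superposed `coordinate_ensemble` (provenance notes the fit).
#' @export
superpose_to_reference <- function(ensemble, reference_frame = 1L) {
  stopifnot(inherits(ensemble, "coordinate_ensemble"))
  nf <- n_frames(ensemble); ns <- n_sites(ensemble)
  if (reference_frame < 1 || reference_frame > nf)
    abort_argument(sprintf("reference_frame must be in [1, %d]", nf))
  if (ns < 3)
    abort_degenerate("superposition needs at least 3 sites for a unique rotation")
  ref <- ensemble$coords[reference_frame, , , drop = TRUE]
  ref_cen <- colMeans(ref)
  ref0 <- sweep(ref, 2, ref_cen)
  sv <- svd(ref0)$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    abort_degenerate("reference sites are collinear; rotation is not unique")
  out <- ensemble$coords
  for (f in seq_len(nf)) {
    P <- ensemble$coords[f, , , drop = TRUE]
    cen <- colMeans(P)
    P0 <- sweep(P, 2, cen)
    R <- kabsch_rotation(P0, ref0)
    out[f, , ] <- sweep(P0 %*% R, 2, ref_cen, "+")
  }
  out[reference_frame, , ] <- ref
  coordinate_ensemble(out, ensemble$site_labels, ensemble$dt,
                      source = paste0(ensemble$source,
                                      sprintf(" | superposed(ref=%d)", reference_frame)))
}

#' Mean-centered fluctuation series
#'
#' Subtracts the per-site time-mean position from every frame, yielding the
#' fluctuation vectors that all stiffness and correlation estimators
#' consume. The ensemble should already be superposed (caller
#' responsibility; provenance records whether it was).
#'
#' @param ensemble a [coordinate_ensemble()] with at least 2 frames.
#' @return An object of class `"fluctuation_series"` with elements `deltas`
#'   (frames x sites x 3, Angstrom), `means` (sites x 3), `dt` (ps) and
#'   `site_labels`.
#' @export
compute_fluctuations <- function(ensemble) {
  stopifnot(inherits(ensemble, "coordinate_ensemble"))
  if (n_frames(ensemble) < 2)
    abort_insufficient("fluctuations need at least 2 frames")
  means <- apply(ensemble$coords, c(2, 3), mean)
  deltas <- sweep(ensemble$coords, c(2, 3), means)
  fluctuation_series(deltas, means, ensemble$dt, ensemble$site_labels,
                     source = ensemble$source)
}

#' @rdname compute_fluctuations
#' @param deltas frames x sites x 3 mean-centered displacements (Angstrom).
#' @param means sites x 3 mean positions that were removed.
#' @param dt frame spacing, ps.
#' @param site_labels as in [coordinate_ensemble()].
#' @param source provenance string.
#' @export
fluctuation_series <- function(deltas, means, dt, site_labels, source = "") {
  if (length(dim(deltas)) != 3 || dim(deltas)[3] != 3)
    abort_argument("deltas must be a frames x sites x 3 array")
  if (is.null(site_labels$record)) site_labels$record <- "ATOM"
  m <- apply(deltas, c(2, 3), mean)
  if (max(abs(m)) > 1e-10)
    abort_integrity("fluctuation series is not mean-centered (per-site mean exceeds 1e-10 A)")
  if (!is.numeric(dt) || dt <= 0) abort_argument("dt must be positive (ps)")
  structure(list(deltas = deltas, means = means, dt = as.numeric(dt),
                 site_labels = site_labels, source = as.character(source)),
            class = "fluctuation_series")
}

#' @export
print.fluctuation_series <- function(x, ...) {
  cat(sprintf("<fluctuation_series> %d frames x %d sites, dt = %g ps\n",
              dim(x$deltas)[1], dim(x$deltas)[2], x$dt))
  invisible(x)
}

# frames x 3 slice of one site's fluctuations
site_series <- function(fluct, i) {
  matrix(fluct$deltas[, i, ], ncol = 3)
}

#' Per-site root mean square fluctuation
#'
#' RMSF_i = sqrt(mean over frames of |dR_i(t)|^2), in Angstrom.
#'
#' @param fluct a [fluctuation_series()].
#' @return Named numeric vector (one value per site, names are site keys).
#' @export
compute_rmsf <- function(fluct) {
  stopifnot(inherits(fluct, "fluctuation_series"))
  sq <- apply(fluct$deltas^2, c(1, 2), sum)   # frames x sites |dR|^2
  setNames(sqrt(colMeans(sq)), site_key(fluct$site_labels))
}
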