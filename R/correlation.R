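# Time-independent cross-correlation maps and residue-pair distance
# distributions.

#' Dynamic cross-correlation coefficient map
#'
#' C_ij = <dR_i . dR_j> / sqrt(<|dR_i|^2> <|dR_j|^2>), with 3-D dot-product
#' numerator and norm-product denominator. Values lie in \[-1, 1\]: 1 for
#' sites always moving in parallel in the same direction, -1 for parallel
#' opposite motion, 0 for independent motion. Zero-variance (frozen) sites
#' yield `NA` rows/columns with a warning rather than an error, so
#' full-molecule maps survive fixed atoms.
#'
#' @param fluct a [fluctuation_series()].
#' @return Object of class `"correlation_map"`: list with `C` (sites x
#'   sites) and `site_labels`.
#' @export
cross_correlation_map <- function(fluct) {
  stopifnot(inherits(fluct, "fluctuation_series"))
  G <- dot_covariance_matrix(fluct)
  msf <- diag(G)
  tol <- 1e-14 * max(msf, 1e-300)
  dead <- msf <= tol
  denom <- sqrt(outer(pmax(msf, tol), pmax(msf, tol)))
  C <- G / denom
  C[dead, ] <- NA_real_
  C[, dead] <- NA_real_
  if (any(dead))
    warning(sprintf("%d zero-variance site(s) flagged NA in correlation map", sum(dead)))
  C[C > 1] <- 1; C[C < -1] <- -1            # round-off clamping only
  diag(C)[!dead] <- 1
  C[lower.tri(C)] <- t(C)[lower.tri(C)]
  structure(list(C = C, site_labels = fluct$site_labels),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("<correlation_map> %d sites\n", nrow(x$C)))
  invisible(x)
}

#' Threshold a correlation map for display
#'
#' Classifies every entry as `positive` (C >= pos_min), `negative`
#' (C <= neg_max) or `none`. Defaults follow the common display convention
#' of highlighting C >= 0.6 and C <= -0.45; both boundaries are inclusive.
#'
#' @param C a `correlation_map`.
#' @param pos_min,neg_max thresholds with `-1 <= neg_max < pos_min <= 1`.
#' @return Character matrix (`positive`/`negative`/`none`, `NA` for flagged
#'   entries) with attributes `pos_min`, `neg_max`.
#' @export
threshold_map <- function(C, pos_min = 0.6, neg_max = -0.45) {
  stopifnot(inherits(C, "correlation_map"))
  if (!(neg_max >= -1 && neg_max < pos_min && pos_min <= 1))
    abort_argument("need -1 <= neg_max < pos_min <= 1")
  m <- matrix(NA_character_, nrow(C$C), ncol(C$C))
  ok <- !is.na(C$C)
  m[ok] <- "none"
  m[ok & C$C >= pos_min] <- "positive"
  m[ok & C$C <= neg_max] <- "negative"
  structure(m, pos_min = pos_min, neg_max = neg_max)
}

#' Per-frame distance between two sites
#'
#' @param ensemble a [coordinate_ensemble()].
#' @param i,j distinct 1-based site indices.
#' @return Numeric vector of Euclidean distances R_ij(t), Angstrom, one per
#'   frame.
#' @export
pair_distance_series <- function(ensemble, i, j) {
  stopifnot(inherits(ensemble, "coordinate_ensemble"))
  ns <- n_sites(ensemble)
  if (i == j) abort_argument("i and j must differ")
  if (i < 1 || j < 1 || i > ns || j > ns)
    abort_argument(sprintf("site indices must be in [1, %d]", ns))
  d <- matrix(ensemble$coords[, i, ], ncol = 3) - matrix(ensemble$coords[, j, ], ncol = 3)
  sqrt(rowSums(d^2))
}

#' Distance distribution of a residue pair
#'
#' Histograms a distance series over its observed \[min, max\] range and
#' normalizes to unit integral (density per Angstrom). A constant series
#' degenerates to a single narrow bin carrying all the mass.
#'
#' @param series numeric distance series (A), length >= 1.
#' @param bins number of bins (default 100); ignored when `width` is given.
#' @param width optional bin width in Angstrom.
#' @return Object of class `"distance_distribution"`: list with `bin_edges`,
#'   `density` (per A), `counts`, `n_samples`, `peak` (midpoint of the modal
#'   bin), `mean`, `sd`.
#' @export
distance_distribution <- function(series, bins = 100, width = NULL) {
  if (length(series) < 1) abort_argument("need at least one distance sample")
  if (any(!is.finite(series))) abort_argument("non-finite distances")
  rng <- range(series)
  if (diff(rng) <= 0) {
    w <- max(abs(rng[1]) * 1e-6, 1e-6)
    edges <- c(rng[1] - w / 2, rng[1] + w / 2)
    counts <- length(series)
  } else {
    if (!is.null(width)) {
      if (width <= 0) abort_argument("width must be positive")
      bins <- max(1L, ceiling(diff(rng) / width))
    }
    if (bins < 1) abort_argument("bins must be >= 1")
    edges <- seq(rng[1], rng[2], length.out = bins + 1)
    idx <- pmin(pmax(findInterval(series, edges, rightmost.closed = TRUE), 1L), bins)
    counts <- tabulate(idx, nbins = bins)
  }
  bw <- diff(edges)
  density <- counts / (length(series) * bw)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  structure(list(bin_edges = edges, density = density, counts = counts,
                 n_samples = length(series), peak = mid[which.max(density)],
                 mean = mean(series), sd = if (length(series) > 1) sd(series) else 0),
            class = "distance_distribution")
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("<distance_distribution> %d samples, %d bins, peak %.3f A, mean %.3f A\n",
              x$n_samples, length(x$density), x$peak, x$mean))
  invisible(x)
}
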