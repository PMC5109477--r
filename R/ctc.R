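# Time-delayed correlations and causality.
#
# The time-delayed correlation of an ordered site pair is
#
#   C_ij(tau) = < dR_i(t) . dR_j(t + tau) >
#
# estimated over all frame pairs whose endpoints fall inside the trajectory
# (truncated overlap, no padding; the denominator is the count of valid
# pairs).  By the law of total expectation this plain lagged average equals
# the conditional construction that averages dR_j(t + tau) given dR_i(t)
# (binned-conditional estimator, provided as a fidelity check).  At tau = 0
# the ordering is immaterial: C_ij(0) = C_ji(0) exactly.  Asymmetry between
# C_ij(tau) and C_ji(tau) at tau > 0 indicates directed influence: if
# C_ij(tau) > C_ji(tau), fluctuations of i drive those of j.

#' Connectivity-vector fluctuation series
#'
#' The connectivity vector of a site pair is the difference of their
#' fluctuation vectors, v(t) = dR_i(t) - dR_j(t); its autocorrelation
#' measures the persistence of the pair's relative motion (the sign
#' convention is irrelevant for autocorrelation).
#'
#' @param fluct a [fluctuation_series()].
#' @param i,j distinct 1-based site indices.
#' @return Object of class `"vector_series"`: frames x 3 matrix with
#'   attributes `dt` (ps) and `pair`.
#' @export
connectivity_fluctuation <- function(fluct, i, j) {
  stopifnot(inherits(fluct, "fluctuation_series"))
  if (i == j) abort_argument("i and j must differ")
  ns <- n_sites(fluct)
  if (i < 1 || j < 1 || i > ns || j > ns)
    abort_argument(sprintf("site indices must be in [1, %d]", ns))
  v <- site_series(fluct, i) - site_series(fluct, j)
  structure(v, dt = fluct$dt, pair = c(i, j), class = c("vector_series", "matrix", "array"))
}

#' Wrap a plain frames x 3 matrix as a vector series
#'
#' @param m frames x 3 numeric matrix.
#' @param dt frame spacing, ps.
#' @return A `"vector_series"`.
#' @export
as_vector_series <- function(m, dt) {
  m <- as.matrix(m)
  if (ncol(m) != 3) abort_argument("a vector series has 3 columns")
  if (dt <= 0) abort_argument("dt must be positive")
  structure(m, dt = dt, pair = NULL, class = c("vector_series", "matrix", "array"))
}

# raw lagged dot product between two frames x 3 matrices at a frame offset
lagged_dot <- function(Xi, Xj, lag_frames) {
  nf <- nrow(Xi)
  keep <- nf - lag_frames
  sum(Xi[seq_len(keep), , drop = FALSE] *
      Xj[seq_len(keep) + lag_frames, , drop = FALSE]) / keep
}

lag_grid_frames <- function(lags, dt, nf) {
  if (any(lags < 0)) abort_argument("lags must be non-negative")
  if (any(diff(lags) <= 0)) abort_argument("lags must be strictly increasing")
  lf <- lags / dt
  if (any(abs(lf - round(lf)) > 1e-6))
    abort_argument("every lag must be a multiple of dt")
  lf <- as.integer(round(lf))
  if (max(lf) >= nf)
    abort_argument(sprintf("max lag %g ps reaches past the series duration %g ps",
                           max(lags), (nf - 1) * dt))
  lf
}

new_delayed_curve <- function(lags, values, pair, normalized, estimator, c0,
                              normalization = if (normalized) "c0" else "none") {
  structure(list(lags = lags, values = values, pair = pair,
                 normalized = normalized, normalization = normalization,
                 estimator = estimator, c0 = c0),
            class = "delayed_correlation")
}

#' @export
print.delayed_correlation <- function(x, ...) {
  p <- if (is.null(x$pair)) "series" else paste(x$pair, collapse = "->")
  cat(sprintf("<delayed_correlation> %s, %d lags in [%g, %g] ps, %s, %s\n",
              p, length(x$lags), min(x$lags), max(x$lags),
              x$estimator, if (x$normalized) x$normalization else "raw"))
  invisible(x)
}

#' Time-delayed autocorrelation of a vector series
#'
#' C(tau) = < v(t) . v(t + tau) > over all frame pairs with both endpoints
#' in range, normalized by C(0) so the curve starts at exactly 1.
#'
#' @param series a `"vector_series"` (see [connectivity_fluctuation()]).
#' @param max_lag largest lag, ps; must be below the series duration.
#' @param lag_stride lag spacing, ps; must be a multiple of `dt` (default
#'   `dt`).
#' @param normalize divide by C(0) (default TRUE).
#' @return A `"delayed_correlation"` curve (lags start at 0).
#' @export
delayed_autocorrelation <- function(series, max_lag, lag_stride = NULL,
                                    normalize = TRUE) {
  if (!inherits(series, "vector_series"))
    abort_argument("series must be a vector_series")
  dt <- attr(series, "dt")
  lag_stride <- lag_stride %||% dt
  if (lag_stride <= 0) abort_argument("lag_stride must be positive")
  lags <- seq(0, max_lag, by = lag_stride)
  lf <- lag_grid_frames(lags, dt, nrow(series))
  vals <- vapply(lf, function(L) lagged_dot(series, series, L), numeric(1))
  c0 <- vals[1]
  if (normalize) {
    if (c0 <= 0) abort_degenerate("zero-variance series cannot be normalized")
    vals <- vals / c0
  }
  new_delayed_curve(lags, vals, attr(series, "pair"), normalize, "direct", c0)
}

#' 1/e decay time of a normalized correlation curve
#'
#' Returns the lag of the first downward crossing of `level`, linearly
#' interpolated between adjacent lag samples. Curves that never fall below
#' the level within their lag range return `NA` with attribute
#' `reached = FALSE` (the not-reached flag).
#'
#' @param curve a normalized `"delayed_correlation"`.
#' @param level crossing level (default `exp(-1)`).
#' @return Decay time in ps, or flagged `NA`.
#' @export
decay_time <- function(curve, level = exp(-1)) {
  stopifnot(inherits(curve, "delayed_correlation"))
  if (!isTRUE(curve$normalized))
    abort_argument("decay_time needs a normalized curve")
  v <- curve$values; l <- curve$lags
  for (k in seq_len(length(v) - 1)) {
    if (v[k] >= level && v[k + 1] < level) {
      frac <- (v[k] - level) / (v[k] - v[k + 1])
      return(structure(l[k] + frac * (l[k + 1] - l[k]), reached = TRUE))
    }
  }
  structure(NA_real_, reached = FALSE)
}

# binned-conditional estimator of <dR_i(t) . dR_j(t+tau)>: per spatial
# component, condition on equal-count bins of dR_i(t) and recombine the
# conditional means (empirical law of total expectation).
binned_lagged_dot <- function(Xi, Xj, lag_frames, n_bins) {
  nf <- nrow(Xi)
  keep <- nf - lag_frames
  if (keep %/% n_bins < 10)
    abort_binning(sprintf(
      "only %d samples for %d bins (< 10 per bin); reduce n_bins", keep, n_bins))
  total <- 0
  for (c in 1:3) {
    xi <- Xi[seq_len(keep), c]
    xj <- Xj[seq_len(keep) + lag_frames, c]
    rnk <- rank(xi, ties.method = "first")
    bin <- pmin(ceiling(rnk / (keep / n_bins)), n_bins)  # equal-count bins
    grp <- split(seq_len(keep), bin)
    for (g in grp) {
      total <- total + (length(g) / keep) * mean(xi[g]) * mean(xj[g])
    }
  }
  total
}

#' Conditional time-delayed cross-correlation of an ordered pair
#'
#' Estimates C_ij(tau) = < dR_i(t) . dR_j(t + tau) > on a lag grid. The
#' `direct` estimator averages the lagged dot products; the `binned`
#' estimator conditions dR_j(t + tau) on equal-count bins of each component
#' of dR_i(t) and recombines the conditional means -- the two estimate the
#' same expectation and are both exposed so the conditional reading can be
#' checked against the plain one.
#'
#' Normalization: `"c0"` (default) divides by C_ij(0), matching the
#' convention of normalized CTC curves; `"pearson"` divides by
#' sqrt(C_ii(0) C_jj(0)) giving values comparable across pairs;
#' `"none"` returns raw averages (A^2).
#'
#' @param fluct a [fluctuation_series()].
#' @param i,j 1-based site indices (ordered: i earlier, j later).
#' @param lags strictly increasing lag grid, ps (multiples of `dt`).
#' @param estimator `"direct"` or `"binned"`.
#' @param normalization `"c0"`, `"pearson"` or `"none"`.
#' @param n_bins bins per component for the binned estimator (default 20).
#' @return A `"delayed_correlation"` curve for the ordered pair (i, j).
#' @export
delayed_cross_correlation <- function(fluct, i, j, lags,
                                      estimator = c("direct", "binned"),
                                      normalization = c("c0", "pearson", "none"),
                                      n_bins = 20) {
  stopifnot(inherits(fluct, "fluctuation_series"))
  estimator <- match.arg(estimator)
  normalization <- match.arg(normalization)
  ns <- n_sites(fluct)
  if (i < 1 || j < 1 || i > ns || j > ns)
    abort_argument(sprintf("site indices must be in [1, %d]", ns))
  Xi <- site_series(fluct, i); Xj <- site_series(fluct, j)
  lf <- lag_grid_frames(lags, fluct$dt, n_frames(fluct))
  est_fun <- if (estimator == "direct") {
    function(L) lagged_dot(Xi, Xj, L)
  } else {
    function(L) binned_lagged_dot(Xi, Xj, L, n_bins)
  }
  vals <- vapply(lf, est_fun, numeric(1))
  c0 <- if (estimator == "direct") lagged_dot(Xi, Xj, 0L)
        else binned_lagged_dot(Xi, Xj, 0L, n_bins)
  denom <- switch(normalization,
    c0 = c0,
    pearson = sqrt(lagged_dot(Xi, Xi, 0L) * lagged_dot(Xj, Xj, 0L)),
    none = 1)
  if (normalization != "none" && abs(denom) <= 0)
    abort_degenerate("zero normalization denominator (zero-variance site?)")
  new_delayed_curve(lags, vals / denom, c(i, j),
                    normalized = normalization != "none",
                    estimator = estimator, c0 = c0,
                    normalization = normalization)
}

#' Scan all site pairs for causality edges
#'
#' For every (unordered) pair, the lagged correlations C_ij(tau) and
#' C_ji(tau) at the scan lag are Pearson-normalized (divided by
#' sqrt(C_ii(0) C_jj(0)), so values are comparable across pairs and
#' thresholds live on a fixed \[0, 1\]-like scale). The direction with the
#' larger value is the driver; an edge is emitted when
#' `max(|c_forward|, |c_backward|) >= min_strength` and
#' `c_forward - c_backward >= min_asymmetry`. Pairs below the asymmetry
#' threshold yield no edge (never an arbitrary direction). Edges are sorted
#' by asymmetry, descending; output is deterministic given the input.
#'
#' @param fluct a [fluctuation_series()].
#' @param lag scan lag, ps (> 0, a multiple of `dt`, below the duration).
#' @param min_strength minimum normalized correlation magnitude (default
#'   0.2).
#' @param min_asymmetry minimum forward-backward difference (default 0.1).
#' @param pairs optional 2-column matrix/data.frame of site index pairs to
#'   scan (default: all distinct pairs).
#' @param normalization `"pearson"` (default) or `"c0"` (divide both
#'   directions by their common C_ij(0); note this rescales weakly
#'   equal-time-correlated pairs aggressively).
#' @return data.frame of class `"causality_edges"` with columns `driver`,
#'   `follower` (site indices), `driver_site`, `follower_site` (labels),
#'   `lag`, `c_forward`, `c_backward`, `asymmetry`, `strength`.
#' @export
causality_scan <- function(fluct, lag, min_strength = 0.2, min_asymmetry = 0.1,
                           pairs = NULL, normalization = c("pearson", "c0")) {
  stopifnot(inherits(fluct, "fluctuation_series"))
  normalization <- match.arg(normalization)
  if (lag <= 0) abort_argument("scan lag must be positive")
  if (min_strength < 0 || min_strength > 1 || min_asymmetry < 0 || min_asymmetry > 1)
    abort_argument("thresholds must lie in [0, 1]")
  nf <- n_frames(fluct); ns <- n_sites(fluct)
  L <- lag_grid_frames(c(0, lag), fluct$dt, nf)[2]
  if (is.null(pairs)) {
    pairs <- t(utils::combn(ns, 2))
  } else {
    pairs <- as.matrix(pairs)[, 1:2, drop = FALSE]
    storage.mode(pairs) <- "integer"
  }
  X <- lapply(seq_len(ns), function(s) site_series(fluct, s))
  var0 <- vapply(X, function(x) lagged_dot(x, x, 0L), numeric(1))
  keys <- site_key(fluct$site_labels)
  rows <- vector("list", nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    if (i == j) abort_argument("pairs must have distinct sites")
    cij <- lagged_dot(X[[i]], X[[j]], L)
    cji <- lagged_dot(X[[j]], X[[i]], L)
    denom <- if (normalization == "pearson") sqrt(var0[i] * var0[j])
             else lagged_dot(X[[i]], X[[j]], 0L)
    if (!is.finite(denom) || denom == 0) next
    cij <- cij / denom; cji <- cji / denom
    if (cij >= cji) { drv <- i; fol <- j; cf <- cij; cb <- cji }
    else            { drv <- j; fol <- i; cf <- cji; cb <- cij }
    strength <- max(abs(cf), abs(cb))
    asym <- cf - cb
    if (strength >= min_strength && asym >= min_asymmetry) {
      rows[[p]] <- data.frame(driver = drv, follower = fol,
                              driver_site = keys[drv], follower_site = keys[fol],
                              lag = lag, c_forward = cf, c_backward = cb,
                              asymmetry = asym, strength = strength,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(driver = integer(0), follower = integer(0),
                      driver_site = character(0), follower_site = character(0),
                      lag = numeric(0), c_forward = numeric(0),
                      c_backward = numeric(0), asymmetry = numeric(0),
                      strength = numeric(0), stringsAsFactors = FALSE)
  out <- out[order(-out$asymmetry, out$driver, out$follower), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("causality_edges", "data.frame")
  attr(out, "normalization") <- normalization
  out
}

#' Export causality edges as GraphML
#'
#' @param edges a `"causality_edges"` data.frame from [causality_scan()].
#' @param path output file.
#' @param site_labels optional label data.frame used to name vertices.
#' @return `path`, invisibly.
#' @export
write_edges_graphml <- function(edges, path, site_labels = NULL) {
  vnames <- unique(c(edges$driver_site, edges$follower_site))
  if (length(vnames) == 0) {
    g <- igraph::make_empty_graph(directed = TRUE)
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges$driver_site, to = edges$follower_site,
                 lag = edges$lag, c_forward = edges$c_forward,
                 c_backward = edges$c_backward, asymmetry = edges$asymmetry),
      directed = TRUE)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
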