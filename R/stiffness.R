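# Pairwise stiffness from fluctuation covariances.
#
# Each residue pair (i, j) is modelled as a harmonic spring whose constant
# follows from the Gaussian network picture:
#
#   k_ij = kB * T / ( <|dR_i|^2> - 2 <dR_i . dR_j> + <|dR_j|^2> )
#
# where the denominator equals the mean squared fluctuation of the pair
# separation, <|dR_i - dR_j|^2> >= 0.  Averages are time averages over
# frames, squared terms are 3-D squared norms and the cross term the 3-D
# dot product.

# sites x sites matrix of time-averaged 3-D dot products <dR_i . dR_j>
dot_covariance_matrix <- function(fluct) {
  nf <- n_frames(fluct)
  G <- matrix(0, n_sites(fluct), n_sites(fluct))
  for (c in 1:3) {
    Xc <- matrix(fluct$deltas[, , c], nrow = nf)
    G <- G + crossprod(Xc)
  }
  G / nf
}

#' Pairwise spring-constant matrix
#'
#' Estimates the effective harmonic spring constant between every pair of
#' sites from the mean squared fluctuation of their separation. Pairs whose
#' separation does not fluctuate (rigidly co-moving sites) have infinite
#' stiffness: they are flagged `Inf` and excluded from all aggregations, as
#' is the (undefined) diagonal.
#'
#' @param fluct a [fluctuation_series()] from a superposed ensemble.
#' @param temperature absolute temperature, K (default 310, physiological).
#' @return An object of class `"spring_matrix"`: list with `k` (sites x
#'   sites, kcal/mol/A^2, diagonal `NA`), `flagged` (logical matrix of
#'   infinite-stiffness pairs), `temperature` and `site_labels`.
#' @export
pairwise_spring_constants <- function(fluct, temperature = 310) {
  stopifnot(inherits(fluct, "fluctuation_series"))
  if (n_sites(fluct) < 2) abort_argument("need at least 2 sites")
  if (!is.numeric(temperature) || temperature <= 0)
    abort_argument("temperature must be positive (K)")
  G <- dot_covariance_matrix(fluct)
  msf <- diag(G)
  D <- outer(msf, msf, "+") - 2 * G          # <|dR_i - dR_j|^2>
  D[D < 0] <- 0                              # numeric round-off only
  tol <- 1e-12 * max(msf, 1e-300)
  flagged <- D <= tol
  k <- .kB_kcal * temperature / D
  k[flagged] <- Inf
  diag(k) <- NA_real_
  diag(flagged) <- TRUE
  k[lower.tri(k)] <- t(k)[lower.tri(k)]      # exact symmetry
  if (any(flagged & upper.tri(flagged)))
    warning(sprintf("%d rigidly co-moving pair(s) flagged as infinite stiffness",
                    sum(flagged & upper.tri(flagged))))
  structure(list(k = k, flagged = flagged, temperature = temperature,
                 site_labels = fluct$site_labels),
            class = "spring_matrix")
}

#' @export
print.spring_matrix <- function(x, ...) {
  cat(sprintf("<spring_matrix> %d sites, T = %g K, %d flagged pairs\n",
              nrow(x$k), x$temperature, sum(x$flagged & upper.tri(x$flagged))))
  invisible(x)
}

usable_entries <- function(K) {
  ok <- !K$flagged
  diag(ok) <- FALSE
  ok
}

#' Per-site mean spring constant
#'
#' Each site is attached to the N-1 other sites by N-1 springs; the mean
#' over those partners measures how stiffly the site is coupled to the rest
#' of the molecule. Flagged (infinite) entries are skipped; a site whose
#' partners are all flagged gets `NA`.
#'
#' @param K a `spring_matrix` from [pairwise_spring_constants()].
#' @return Named numeric vector, kcal/mol/A^2.
#' @export
mean_spring_constant <- function(K) {
  stopifnot(inherits(K, "spring_matrix"))
  ok <- usable_entries(K)
  out <- vapply(seq_len(nrow(K$k)), function(i) {
    j <- ok[i, ]
    if (!any(j)) NA_real_ else mean(K$k[i, j])
  }, numeric(1))
  setNames(out, site_key(K$site_labels))
}

#' Overall spring constant of the complex
#'
#' Aggregates the pairwise matrix to a single stiffness number. `pair-mean`
#' (default) averages k_ij over all distinct unordered pairs; `site-mean`
#' averages the per-site means. The two agree for uniform matrices and
#' differ in general; both are exposed because either is a defensible
#' reading of an "overall" stiffness.
#'
#' @param K a `spring_matrix`.
#' @param method `"pair-mean"` or `"site-mean"`.
#' @return Scalar, kcal/mol/A^2, with attribute `method`.
#' @export
overall_spring_constant <- function(K, method = c("pair-mean", "site-mean")) {
  stopifnot(inherits(K, "spring_matrix"))
  method <- match.arg(method)
  val <- if (method == "pair-mean") {
    ok <- usable_entries(K) & upper.tri(K$k)
    mean(K$k[ok])
  } else {
    mean(mean_spring_constant(K), na.rm = TRUE)
  }
  structure(val, method = method)
}

#' Difference between two spring-constant matrices
#'
#' Computes `K_a - K_b` entry-wise (e.g. active minus inactive state) plus
#' the per-site mean differences. Flagged entries in either input propagate
#' as `NA`.
#'
#' @param K_a,K_b `spring_matrix` objects over identical sites and
#'   temperature.
#' @return List with `delta` (signed matrix), `mean_delta` (per-site vector)
#'   and `site_labels`.
#' @export
stiffness_difference <- function(K_a, K_b) {
  stopifnot(inherits(K_a, "spring_matrix"), inherits(K_b, "spring_matrix"))
  check_labels_match(K_a$site_labels, K_b$site_labels, "spring matrices")
  if (K_a$temperature != K_b$temperature)
    abort_alignment("spring matrices were computed at different temperatures")
  delta <- K_a$k - K_b$k
  delta[K_a$flagged | K_b$flagged] <- NA_real_
  diag(delta) <- NA_real_
  list(delta = delta,
       mean_delta = mean_spring_constant(K_a) - mean_spring_constant(K_b),
       site_labels = K_a$site_labels)
}

#' Convert stiffness units
#'
#' 1 kcal/mol/A^2 = 694.769 pN/nm (thermochemical calorie and Avogadro
#' constant; 4184 / 6.02214076 exactly, in these units).
#'
#' @param value numeric stiffness value(s).
#' @param direction `"to_pN_per_nm"` (default) or `"to_kcal_per_molA2"`.
#' @return Converted value(s).
#' @export
convert_stiffness_units <- function(value,
                                    direction = c("to_pN_per_nm", "to_kcal_per_molA2")) {
  direction <- match.arg(direction)
  if (any(!is.finite(value[!is.na(value)])))
    abort_argument("stiffness value must be finite")
  if (direction == "to_pN_per_nm") value * .kcalA2_to_pNnm
  else value / .kcalA2_to_pNnm
}

#' Joint RMSF/stiffness stability classification
#'
#' A site is more stable in state A than state B when its RMSF is lower in
#' A *and* its mean spring constant is higher in A (small fluctuations plus
#' stiff coupling). Sites where both quantities agree within
#' `rel_tolerance` are "unchanged"; discordant combinations are "mixed".
#'
#' @param rmsf_a,rmsf_b per-site RMSF vectors (A) for the two states.
#' @param meank_a,meank_b per-site mean spring constants (kcal/mol/A^2).
#' @param rel_tolerance relative difference below which two values are
#'   considered equal (default 0.02).
#' @param site_labels optional label data.frame; names of `rmsf_a` used
#'   otherwise.
#' @return data.frame with the inputs and a `classification` column in
#'   `{more-stable-in-A, more-stable-in-B, mixed, unchanged}`.
#' @export
stability_report <- function(rmsf_a, rmsf_b, meank_a, meank_b,
                             rel_tolerance = 0.02, site_labels = NULL) {
  n <- length(rmsf_a)
  if (length(rmsf_b) != n || length(meank_a) != n || length(meank_b) != n)
    abort_alignment("stability inputs must have equal length")
  if (!is.null(names(rmsf_a)) && !is.null(names(rmsf_b)) &&
      any(names(rmsf_a) != names(rmsf_b)))
    abort_alignment("RMSF vectors are labelled for different sites")
  tie <- function(a, b) abs(a - b) <= rel_tolerance * pmax(abs(a), abs(b))
  r_tie <- tie(rmsf_a, rmsf_b); k_tie <- tie(meank_a, meank_b)
  r_lower_a <- !r_tie & rmsf_a < rmsf_b
  k_higher_a <- !k_tie & meank_a > meank_b
  r_lower_b <- !r_tie & rmsf_b < rmsf_a
  k_higher_b <- !k_tie & meank_b > meank_a
  cls <- rep("mixed", n)
  cls[r_tie & k_tie] <- "unchanged"
  cls[r_lower_a & k_higher_a] <- "more-stable-in-A"
  cls[r_lower_b & k_higher_b] <- "more-stable-in-B"
  site <- if (!is.null(site_labels)) site_key(site_labels)
          else names(rmsf_a) %||% as.character(seq_len(n))
  data.frame(site = site, rmsf_a = unname(rmsf_a), rmsf_b = unname(rmsf_b),
             mean_k_a = unname(meank_a), mean_k_b = unname(meank_b),
             classification = cls, stringsAsFactors = FALSE)
}
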