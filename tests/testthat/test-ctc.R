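test_that("connectivity vectors are element-wise fluctuation differences", {
  fl <- random_fluct(60, 3, seed = 22)
  v <- connectivity_fluctuation(fl, 1, 3)
  expect_equal(unclass(v)[, ],
               matrix(fl$deltas[, 1, ] - fl$deltas[, 3, ], ncol = 3),
               ignore_attr = TRUE)
  fl$deltas[, 2, ] <- fl$deltas[, 1, ]
  expect_true(all(connectivity_fluctuation(fl, 1, 2) == 0))
  expect_error(connectivity_fluctuation(fl, 2, 2), class = "ctcdyn_argument_error")
})

test_that("autocorrelation is 1 at zero lag and small for white noise", {
  fl <- random_fluct(1e4, 1, seed = 23)
  v <- as_vector_series(matrix(fl$deltas[, 1, ], ncol = 3), fl$dt)
  cu <- delayed_autocorrelation(v, max_lag = 20)
  expect_identical(cu$values[1], 1)
  expect_lt(max(abs(cu$values[-1])), 3 / sqrt(1e4))
  expect_error(delayed_autocorrelation(v, max_lag = 1e4),
               class = "ctcdyn_argument_error")
  expect_error(delayed_autocorrelation(v, max_lag = 5, lag_stride = 0.3),
               class = "ctcdyn_argument_error")
})

test_that("decay_time interpolates the first downward crossing", {
  lags <- seq(0, 6, by = 0.1)
  cu <- make_curve(lags, exp(-lags / 3))
  expect_equal(as.numeric(decay_time(cu)), 3.0, tolerance = 0.01)
  flat <- make_curve(lags, rep(1, length(lags)))
  dtv <- decay_time(flat)
  expect_true(is.na(dtv))
  expect_false(attr(dtv, "reached"))
  raw <- make_curve(lags, exp(-lags), normalized = FALSE)
  expect_error(decay_time(raw), class = "ctcdyn_argument_error")
  # custom level
  expect_equal(as.numeric(decay_time(cu, level = 0.5)), 3 * log(2), tolerance = 0.01)
})

test_that("zero-lag exchange symmetry holds exactly", {
  fl <- random_fluct(200, 4, seed = 24)
  for (i in 1:3) for (j in (i + 1):4) {
    cij <- delayed_cross_correlation(fl, i, j, lags = 0, normalization = "none")
    cji <- delayed_cross_correlation(fl, j, i, lags = 0, normalization = "none")
    expect_identical(cij$values[1], cji$values[1])
  }
})

test_that("a pure delay puts the forward peak at the shift", {
  withr::with_seed(25, {
    d <- 7L; T_ <- 3000L
    z <- matrix(rnorm((T_ + d) * 3), ncol = 3)
    deltas <- array(0, c(T_, 2, 3))
    deltas[, 1, ] <- z[(d + 1):(T_ + d), ]   # site 1 leads
    deltas[, 2, ] <- z[1:T_, ]               # site 2 = site 1 delayed by d
  })
  deltas <- sweep(deltas, c(2, 3), apply(deltas, c(2, 3), mean))
  fl <- fluctuation_series(deltas, matrix(0, 2, 3), 1, ctcdyn:::synthetic_labels(2))
  lags <- 0:15
  fwd <- delayed_cross_correlation(fl, 1, 2, lags, normalization = "pearson")
  bwd <- delayed_cross_correlation(fl, 2, 1, lags, normalization = "pearson")
  expect_equal(lags[which.max(fwd$values)], 7)
  expect_gt(max(fwd$values), 0.9)
  expect_lt(max(abs(bwd$values[-1])), 0.1)   # reverse direction decays from 0
})

test_that("direct estimator equals the brute-force loop oracle", {
  fl <- random_fluct(200, 5, seed = 26)
  for (pair in list(c(1, 2), c(2, 5), c(3, 3))) {
    i <- pair[1]; j <- pair[2]
    for (L in c(0L, 1L, 7L, 50L)) {
      direct <- if (i == j) {
        v <- as_vector_series(matrix(fl$deltas[, i, ], ncol = 3), fl$dt)
        delayed_autocorrelation(v, max_lag = L, lag_stride = max(L, 1),
                                normalize = FALSE)$values[if (L == 0) 1 else 2]
      } else {
        delayed_cross_correlation(fl, i, j, lags = L, normalization = "none")$values[1]
      }
      expect_equal(direct, brute_force_lagged_correlation(fl, i, j, L),
                   tolerance = 1e-10)
    }
  }
})

test_that("binned conditional estimator agrees with the direct one", {
  spec <- ou_network_spec(matrix(c(1, 0, -0.5, 1), 2), diag(2),
                          dt = 0.1, n_steps = 5e4, seed = 27)
  fl <- simulate_ou_network(spec)
  lags <- seq(0, 3, by = 0.5)
  dir <- delayed_cross_correlation(fl, 1, 2, lags, estimator = "direct")
  bin <- delayed_cross_correlation(fl, 1, 2, lags, estimator = "binned")
  expect_lt(max(abs(dir$values - bin$values)), 0.05)
  expect_error(delayed_cross_correlation(fl, 1, 2, lags, estimator = "binned",
                                         n_bins = 49000),
               class = "ctcdyn_binning_error")
})

test_that("self cross-correlation curve equals the autocorrelation", {
  fl <- random_fluct(500, 2, seed = 28)
  lags <- 0:10
  self <- delayed_cross_correlation(fl, 1, 1, lags)  # c0-normalized
  v <- as_vector_series(matrix(fl$deltas[, 1, ], ncol = 3), fl$dt)
  auto <- delayed_autocorrelation(v, max_lag = 10)
  expect_equal(self$values, auto$values, tolerance = 1e-12)
})

test_that("frame reversal swaps the two directions exactly", {
  fl <- random_fluct(300, 3, seed = 29)
  rev_fl <- fl
  rev_fl$deltas <- fl$deltas[300:1, , , drop = FALSE]
  for (L in c(1, 5, 20)) {
    cij <- delayed_cross_correlation(fl, 1, 2, lags = L, normalization = "none")$values
    cji_rev <- delayed_cross_correlation(rev_fl, 2, 1, lags = L, normalization = "none")$values
    expect_equal(cij, cji_rev, tolerance = 1e-10)
  }
})

test_that("causality scan recovers a unidirectional 2-site coupling", {
  spec <- ou_network_spec(matrix(c(1, -0.5, 0, 1), 2), diag(2),
                          dt = 0.05, n_steps = 1e5, seed = 30,
                          ground_truth_edges = data.frame(driver = 1, follower = 2))
  fl <- simulate_ou_network(spec)
  edges <- causality_scan(fl, lag = 1)
  expect_edge_set(edges, data.frame(driver = 1, follower = 2))
  expect_gt(edges$asymmetry[1], 0)
  expect_equal(edges$strength[1], max(abs(edges$c_forward[1]), abs(edges$c_backward[1])))
})

test_that("symmetric bidirectional coupling yields no edge", {
  A <- matrix(c(1, -0.4, -0.4, 1), 2)
  for (s in 1:10) {
    fl <- simulate_ou_network(ou_network_spec(A, diag(2), dt = 0.05,
                                              n_steps = 2e4, seed = 300 + s))
    expect_equal(nrow(causality_scan(fl, lag = 1)), 0)
  }
})

test_that("independent sites give an empty edge list and argument checks fire", {
  fl <- random_fluct(5000, 3, seed = 31)
  edges <- causality_scan(fl, lag = 1)
  expect_equal(nrow(edges), 0)
  expect_error(causality_scan(fl, lag = 0), class = "ctcdyn_argument_error")
  expect_error(causality_scan(fl, lag = 5000), class = "ctcdyn_argument_error")
  expect_error(causality_scan(fl, lag = 1, min_strength = 2),
               class = "ctcdyn_argument_error")
})

test_that("edge lists export to GraphML", {
  ch <- make_driver_follower_chain(3, n_steps = 2e4, seed = 32)
  edges <- causality_scan(ch$fluct, lag = 1)
  path <- tempfile(fileext = ".graphml")
  write_edges_graphml(edges, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(edges))
  # empty list still yields a valid (empty) graph
  path2 <- tempfile(fileext = ".graphml")
  write_edges_graphml(causality_scan(random_fluct(2000, 2, seed = 33), lag = 1), path2)
  expect_equal(igraph::ecount(igraph::read_graph(path2, format = "graphml")), 0)
})
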