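test_that("multi-model PDB parses with verbatim numbering and file order", {
  pdb <- fixture_pdb(frames = 3)
  ens <- read_ensemble(pdb, pdb, selection = "all", dt = 1)
  expect_equal(dim(ens$coords), c(3, 16, 3))
  expect_equal(ens$site_labels$resno[1:2], c(10L, 10L))    # source numbering kept
  expect_equal(ens$site_labels$atom[1:2], c("N", "CA"))
  expect_equal(ens$site_labels$resno[16], 301L)
})

test_that("default selection keeps protein CA plus ligand heavy atoms", {
  pdb <- fixture_pdb()
  ens <- read_ensemble(pdb, pdb, dt = 1)     # protein-CA + hetero-heavy
  expect_equal(n_sites(ens), 8)              # 5 CA + 3 heavy GTP atoms
  expect_equal(sum(ens$site_labels$resname == "GTP"), 3)
  expect_false(any(ens$site_labels$resname %in% c("HOH", "MG")))
  expect_false(any(grepl("^H", ens$site_labels$atom[ens$site_labels$resname == "GTP"])))
})

test_that("selection mini-language filters and errors behave", {
  pdb <- fixture_pdb()
  ens <- read_ensemble(pdb, pdb, selection = "resno:10-12 name:CA", dt = 1)
  expect_equal(ens$site_labels$resno, 10:12)
  expect_error(read_ensemble(pdb, pdb, selection = "resname:XXX", dt = 1),
               class = "ctcdyn_selection_error")
  expect_error(read_ensemble(pdb, pdb, selection = "bogus:1", dt = 1),
               class = "ctcdyn_argument_error")
  expect_error(read_ensemble(pdb, pdb, dt = 0), class = "ctcdyn_argument_error")
})

test_that("unreadable and unsupported formats raise format errors naming the file", {
  expect_error(read_ensemble("nope.pdb", "nope.pdb"), class = "ctcdyn_format_error")
  expect_error(read_ensemble("nope.pdb", "nope.pdb"), "nope.pdb")
  pdb <- fixture_pdb()
  xtc <- tempfile(fileext = ".xtc"); file.create(xtc)
  expect_error(read_ensemble(xtc, pdb), class = "ctcdyn_format_error")
  junk <- tempfile(fileext = ".pdb"); writeLines("not a pdb", junk)
  expect_error(read_ensemble(junk, junk), class = "ctcdyn_format_error")
})

test_that("model atom-count mismatch raises an integrity error", {
  pdb <- fixture_pdb(frames = 2)
  lines <- readLines(pdb)
  atoms <- which(startsWith(lines, "ATOM"))
  writeLines(lines[-atoms[length(atoms)]], pdb)  # drop one atom from model 2
  expect_error(read_ensemble(pdb, pdb, selection = "all"),
               class = "ctcdyn_integrity_error")
})

test_that("DCD round trip matches the PDB topology path", {
  withr::with_seed(11, {
    pdb <- fixture_pdb(frames = 1)
    coords <- array(rnorm(4 * 16 * 3, sd = 5), c(4, 16, 3))
    dcd <- tempfile(fileext = ".dcd")
    ctcdyn:::write_dcd(coords, dcd)
    ens <- read_ensemble(dcd, pdb, selection = "all", dt = 2)
    expect_equal(dim(ens$coords), c(4, 16, 3))
    expect_lt(max(abs(ens$coords - coords)), 1e-5)  # float32 storage
    expect_equal(ens$dt, 2)
    # atom-count mismatch trajectory vs topology
    ctcdyn:::write_dcd(coords[, 1:10, ], dcd)
    expect_error(read_ensemble(dcd, pdb, selection = "all"),
                 class = "ctcdyn_integrity_error")
  })
})

test_that("superposition removes rigid-body motion and is idempotent", {
  withr::with_seed(5, {
    ref <- matrix(rnorm(30, sd = 4), 10, 3)
    nf <- 6
    coords <- array(NA_real_, c(nf, 10, 3))
    coords[1, , ] <- ref
    for (f in 2:nf) {
      R <- random_rotation()
      coords[f, , ] <- ref %*% R + matrix(rnorm(3, sd = 10), 10, 3, byrow = TRUE)
    }
    ens <- coordinate_ensemble(coords, ctcdyn:::synthetic_labels(10), dt = 1)
    sup <- superpose_to_reference(ens, 1)
    for (f in seq_len(nf))
      expect_lt(sqrt(mean((sup$coords[f, , ] - ref)^2)), 1e-8)
    sup2 <- superpose_to_reference(sup, 1)
    expect_lt(max(abs(sup2$coords - sup$coords)), 1e-10)
  })
})

test_that("pure translation is removed exactly", {
  ref <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), 4, 3, byrow = TRUE)
  coords <- array(NA_real_, c(3, 4, 3))
  for (f in 1:3) coords[f, , ] <- ref + (f - 1) * matrix(c(1, 2, 3), 4, 3, byrow = TRUE)
  ens <- coordinate_ensemble(coords, ctcdyn:::synthetic_labels(4), dt = 1)
  sup <- superpose_to_reference(ens, 1)
  for (f in 1:3) expect_lt(max(abs(sup$coords[f, , ] - ref)), 1e-10)
})

test_that("degenerate superposition geometries are rejected", {
  line <- cbind(1:5, 0, 0)  # collinear
  coords <- array(rep(line, each = 2), c(2, 5, 3))
  ens <- coordinate_ensemble(coords, ctcdyn:::synthetic_labels(5), dt = 1)
  expect_error(superpose_to_reference(ens), class = "ctcdyn_degenerate_error")
  two <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  ens2 <- coordinate_ensemble(two, ctcdyn:::synthetic_labels(2), dt = 1)
  expect_error(superpose_to_reference(ens2), class = "ctcdyn_degenerate_error")
})

test_that("fluctuations are exactly centered and RMSF has closed forms", {
  # 2 frames, one site moving (0,0,0) -> (2,0,0): deltas are -/+ (1,0,0)
  coords <- array(0, c(2, 3, 3))
  coords[2, 1, 1] <- 2
  coords[, 2, 2] <- c(0, 1); coords[, 3, 3] <- c(4, 4)
  ens <- coordinate_ensemble(coords, ctcdyn:::synthetic_labels(3), dt = 1)
  fl <- compute_fluctuations(ens)
  expect_equal(fl$deltas[, 1, 1], c(-1, 1))
  expect_equal(unname(compute_rmsf(fl)[1]), 1)        # +/- 1 A along x
  expect_equal(unname(compute_rmsf(fl)[3]), 0)        # static site
  # centering property on noise
  withr::with_seed(2, {
    ens2 <- coordinate_ensemble(array(rnorm(50 * 4 * 3), c(50, 4, 3)),
                                ctcdyn:::synthetic_labels(4), dt = 1)
    fl2 <- compute_fluctuations(ens2)
    expect_lt(max(abs(apply(fl2$deltas, c(2, 3), mean))), 1e-10)
  })
  expect_error(coordinate_ensemble(array(0, c(1, 3, 3)),
                                   ctcdyn:::synthetic_labels(3), dt = 1),
               class = "ctcdyn_insufficient_data_error")
})

test_that("isotropic Gaussian RMSF matches sqrt(3) sigma", {
  fl <- random_fluct(1e5, 1, seed = 9, S = matrix(0.25))
  expect_equal(unname(compute_rmsf(fl)), sqrt(3) * 0.5, tolerance = 0.01)
})

test_that("RMSF is invariant under a global rotation", {
  withr::with_seed(8, {
    coords <- array(rnorm(40 * 5 * 3, sd = 2), c(40, 5, 3))
    ens <- coordinate_ensemble(coords, ctcdyn:::synthetic_labels(5), dt = 1)
    r1 <- compute_rmsf(compute_fluctuations(superpose_to_reference(ens)))
    R <- random_rotation()
    rot <- coords
    for (f in 1:40) rot[f, , ] <- coords[f, , ] %*% R
    ens2 <- coordinate_ensemble(rot, ctcdyn:::synthetic_labels(5), dt = 1)
    r2 <- compute_rmsf(compute_fluctuations(superpose_to_reference(ens2)))
    expect_equal(unname(r1), unname(r2), tolerance = 1e-8)
  })
})

test_that("fluctuation text container round-trips exactly", {
  fl <- random_fluct(20, 3, seed = 4)
  prefix <- tempfile()
  write_fluctuations(fl, prefix)
  back <- read_fluctuations(prefix)
  expect_identical(dim(back$deltas), dim(fl$deltas))
  expect_identical(back$deltas, fl$deltas)   # %.17g round-trips doubles
  expect_equal(back$dt, fl$dt)
  expect_equal(back$site_labels$resno, fl$site_labels$resno)
  expect_error(read_fluctuations(tempfile()), class = "ctcdyn_format_error")
})
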