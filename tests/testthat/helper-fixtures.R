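# Programmatic fixtures: a small multi-model PDB (protein + ligand + water +
# ion), quick random fluctuation series, and a spring-matrix constructor for
# arithmetic examples.

fixture_pdb <- function(path = tempfile(fileext = ".pdb"), frames = 3) {
  protein <- data.frame(resno = 10:14, stringsAsFactors = FALSE)
  lines <- character(0)
  atom_line <- function(record, serial, name, resname, chain, resno, xyz) {
    nm4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
    sprintf("%-6s%5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            record, serial, nm4, resname, chain, resno, xyz[1], xyz[2], xyz[3])
  }
  for (f in seq_len(frames)) {
    lines <- c(lines, sprintf("MODEL     %4d", f))
    serial <- 0
    coord <- function(base) base + 0.1 * f
    for (r in seq_len(5)) {
      serial <- serial + 1
      lines <- c(lines, atom_line("ATOM", serial, "N", "ALA", "A", 9 + r,
                                  coord(c(3 * r, 0, 0))))
      serial <- serial + 1
      lines <- c(lines, atom_line("ATOM", serial, "CA", "ALA", "A", 9 + r,
                                  coord(c(3 * r + 1, 1, r))))
    }
    # 3 heavy ligand atoms + 1 hydrogen (hydrogen must be excluded)
    lig <- list(c("PA", c(20, 5, 1)), c("O1A", c(21, 5, 2)), c("O2A", c(22, 6, 1)))
    for (a in list(list("PA", c(20, 5, 1)), list("O1A", c(21, 5, 2)),
                   list("O2A", c(22, 6, 1)), list("H1", c(23, 6, 2)))) {
      serial <- serial + 1
      lines <- c(lines, atom_line("HETATM", serial, a[[1]], "GTP", "A", 200,
                                  coord(a[[2]])))
    }
    serial <- serial + 1
    lines <- c(lines, atom_line("HETATM", serial, "O", "HOH", "A", 300, coord(c(30, 0, 0))))
    serial <- serial + 1
    lines <- c(lines, atom_line("HETATM", serial, "MG", "MG", "A", 301, coord(c(31, 0, 0))))
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# quick i.i.d. Gaussian fluctuation series (identity covariance by default)
random_fluct <- function(n_frames, n_sites, seed, S = diag(n_sites), dt = 1) {
  sample_gaussian_ensemble(gaussian_ensemble_spec(n_sites, S, n_frames,
                                                  seed = seed, dt = dt))
}

# spring_matrix object from a plain symmetric matrix (for aggregation tests)
make_K <- function(k, temperature = 310) {
  n <- nrow(k)
  diag(k) <- NA_real_
  flagged <- !is.finite(k)
  diag(flagged) <- TRUE
  structure(list(k = k, flagged = flagged, temperature = temperature,
                 site_labels = ctcdyn:::synthetic_labels(n)),
            class = "spring_matrix")
}

# normalized correlation curve object with prescribed values
make_curve <- function(lags, values, normalized = TRUE) {
  ctcdyn:::new_delayed_curve(lags, values, NULL, normalized, "direct",
                             c0 = 1)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

expect_edge_set <- function(edges, expected) {
  got <- sort(paste(edges$driver, edges$follower, sep = "->"))
  want <- sort(paste(expected$driver, expected$follower, sep = "->"))
  expect_identical(got, want)
}
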