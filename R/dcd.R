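# Minimal CHARMM/NAMD DCD reader and writer (single-precision Fortran
# unformatted records).  Supports the common CHARMM-style header (version
# field set), with or without per-frame unit-cell records; X-PLOR
# double-delta headers are rejected with a format error.  No pre-installed
# R package reads DCD, hence this small self-contained implementation; it is
# round-trip tested and was cross-checked against MDAnalysis.

read_fortran_record <- function(con, what, size, swap) {
  endian <- if (swap) "swap" else .Platform$endian
  n1 <- readBin(con, "integer", 1, 4, endian = endian)
  if (length(n1) == 0) return(NULL)
  nitems <- n1 / size
  dat <- readBin(con, what, nitems, size, endian = endian)
  n2 <- readBin(con, "integer", 1, 4, endian = endian)
  if (length(n2) == 0 || n2 != n1) abort_format("corrupt Fortran record in DCD")
  dat
}

write_fortran_record <- function(con, dat, size) {
  nbytes <- length(dat) * size
  writeBin(as.integer(nbytes), con, 4)
  if (is.character(dat)) writeChar(paste(dat, collapse = ""), con, nchars = nbytes, eos = NULL)
  else writeBin(dat, con, size)
  writeBin(as.integer(nbytes), con, 4)
}

# Returns frames x atoms x 3 coordinate array (Angstrom).
read_dcd <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: '%s'", path))
  con <- file(path, "rb"); on.exit(close(con))
  first <- readBin(con, "integer", 1, 4)
  swap <- FALSE
  if (length(first) == 0) abort_format(sprintf("'%s' is empty", path))
  if (first != 84) {
    swapped <- readBin(con_raw <- rawConnection(rev(writeBin(first, raw(), 4))), "integer", 1, 4)
    close(con_raw)
    if (swapped == 84) swap <- TRUE
    else abort_format(sprintf("'%s' is not a DCD file (bad header record length)", path))
  }
  endian <- if (swap) "swap" else .Platform$endian
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "CORD"))
    abort_format(sprintf("'%s' is not a coordinate DCD (magic '%s')", path, magic))
  icntrl_raw <- readBin(con, "raw", 80)
  icntrl <- readBin(icntrl_raw, "integer", 20, 4, endian = endian)
  nframes <- icntrl[1]
  crystal <- icntrl[11] != 0
  version <- icntrl[20]
  if (version == 0)
    abort_format(sprintf("'%s': X-PLOR style DCD headers are not supported; rewrite as CHARMM/NAMD DCD", path))
  n2 <- readBin(con, "integer", 1, 4, endian = endian)
  if (n2 != 84) abort_format("corrupt DCD header")
  invisible(read_fortran_record(con, "raw", 1, swap))          # title block
  natom <- read_fortran_record(con, "integer", 4, swap)
  if (length(natom) != 1 || natom < 1) abort_format("bad atom-count record in DCD")
  frames <- list()
  repeat {
    if (crystal) {
      cell <- read_fortran_record(con, "numeric", 8, swap)
      if (is.null(cell)) break
    }
    x <- read_fortran_record(con, "numeric", 4, swap)
    if (is.null(x)) break
    y <- read_fortran_record(con, "numeric", 4, swap)
    z <- read_fortran_record(con, "numeric", 4, swap)
    if (length(x) != natom || length(y) != natom || length(z) != natom)
      abort_integrity(sprintf("frame %d of '%s' has %d atoms, expected %d",
                              length(frames) + 1L, path, length(x), natom))
    frames[[length(frames) + 1L]] <- cbind(x, y, z)
  }
  if (length(frames) == 0) abort_format(sprintf("'%s' contains no frames", path))
  if (nframes > 0 && length(frames) != nframes)
    warning(sprintf("DCD header declares %d frames but %d were read", nframes, length(frames)))
  coords <- array(NA_real_, c(length(frames), natom, 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  coords
}

write_dcd <- function(coords, path) {
  if (length(dim(coords)) != 3) abort_argument("coords must be frames x atoms x 3")
  nf <- dim(coords)[1]; natom <- dim(coords)[2]
  con <- file(path, "wb"); on.exit(close(con))
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[20] <- 24L                        # CHARMM-style header version
  writeBin(84L, con, 4)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  writeBin(icntrl[1:9], con, 4)
  writeBin(1, con, size = 4)               # DELTA as float32 (CHARMM layout)
  writeBin(icntrl[11:20], con, 4)
  writeBin(84L, con, 4)
  title <- sprintf("%-80s", "created by ctcdyn")
  writeBin(4L + 80L, con, 4)
  writeBin(1L, con, 4)
  writeChar(title, con, nchars = 80, eos = NULL)
  writeBin(4L + 80L, con, 4)
  write_fortran_record(con, as.integer(natom), 4)
  for (f in seq_len(nf)) {
    for (d in 1:3) {
      writeBin(as.integer(4 * natom), con, 4)
      writeBin(as.numeric(coords[f, , d]), con, size = 4)
      writeBin(as.integer(4 * natom), con, 4)
    }
  }
  invisible(path)
}
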