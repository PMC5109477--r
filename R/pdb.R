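# Minimal fixed-column PDB coordinate parsing (ATOM/HETATM, MODEL/ENDMDL).
# Only the fields the pipeline needs are read; residue numbering is kept
# verbatim from the file.

.water_resnames <- c("HOH", "WAT", "TIP", "TIP3", "SOL", "H2O")
.ion_resnames   <- c("NA", "CL", "K", "MG", "ZN", "MN", "FE", "CU", "CA2",
                     "SOD", "CLA", "POT", "CAL", "MG2")

parse_pdb_atom_lines <- function(lines, path) {
  name    <- trimws(substr(lines, 13, 16))
  resname <- trimws(substr(lines, 18, 21))
  chain   <- trimws(substr(lines, 22, 22))
  resno   <- suppressWarnings(as.integer(trimws(substr(lines, 23, 26))))
  x <- suppressWarnings(as.numeric(substr(lines, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(lines, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(lines, 47, 54)))
  elem <- trimws(substr(lines, 77, 78))
  if (any(is.na(x) | is.na(y) | is.na(z) | is.na(resno)))
    abort_format(sprintf("malformed ATOM/HETATM record in '%s'", path))
  chain[chain == ""] <- "A"
  record <- ifelse(startsWith(lines, "HETATM"), "HETATM", "ATOM")
  # element fallback: strip leading digits from the atom name ("1HB" -> H)
  guess <- substr(sub("^[0-9]+", "", name), 1, 1)
  elem <- ifelse(nzchar(elem), elem, guess)
  list(labels = make_site_labels(resno, resname, name, chain, record),
       coords = cbind(x, y, z), element = toupper(elem))
}

# Returns list(coords = frames x atoms x 3, labels, element).
read_pdb_models <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  if (!any(is_atom))
    abort_format(sprintf("'%s' contains no ATOM/HETATM records; not a PDB coordinate file", path))
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) == 0) {
    p <- parse_pdb_atom_lines(lines[is_atom], path)
    coords <- array(NA_real_, c(1, nrow(p$labels), 3))
    coords[1, , ] <- p$coords
    return(list(coords = coords, labels = p$labels, element = p$element))
  }
  model_ends <- which(startsWith(lines, "ENDMDL"))
  if (length(model_ends) != length(model_starts))
    abort_format(sprintf("unbalanced MODEL/ENDMDL records in '%s'", path))
  first <- NULL; frames <- list()
  for (m in seq_along(model_starts)) {
    seg <- lines[(model_starts[m] + 1):(model_ends[m] - 1)]
    seg <- seg[startsWith(seg, "ATOM") | startsWith(seg, "HETATM")]
    p <- parse_pdb_atom_lines(seg, path)
    if (is.null(first)) {
      first <- p
    } else if (nrow(p$labels) != nrow(first$labels) ||
               any(site_key(p$labels) != site_key(first$labels))) {
      abort_integrity(sprintf("model %d of '%s' has a different atom list than model 1", m, path))
    }
    frames[[m]] <- p$coords
  }
  coords <- array(NA_real_, c(length(frames), nrow(first$labels), 3))
  for (m in seq_along(frames)) coords[m, , ] <- frames[[m]]
  list(coords = coords, labels = first$labels, element = first$element)
}

# Multi-model PDB writer (fixtures, CLI topology output for synthetic runs).
write_pdb_models <- function(coords, labels, path) {
  if (length(dim(coords)) == 2) coords <- array(coords, c(1, dim(coords)))
  con <- file(path, "w"); on.exit(close(con))
  nf <- dim(coords)[1]
  for (f in seq_len(nf)) {
    if (nf > 1) writeLines(sprintf("MODEL     %4d", f), con)
    for (a in seq_len(nrow(labels))) {
      nm <- labels$atom[a]
      nm4 <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else substr(nm, 1, 4)
      writeLines(sprintf("%-6s%5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                         labels$record[a], a, nm4, substr(labels$resname[a], 1, 4),
                         substr(labels$chain[a], 1, 1), labels$resno[a],
                         coords[f, a, 1], coords[f, a, 2], coords[f, a, 3],
                         1, 0), con)
    }
    if (nf > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
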