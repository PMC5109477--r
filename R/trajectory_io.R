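#' Read a coordinate trajectory into an ensemble
#'
#' Reads a topology (PDB) plus a coordinate trajectory (multi-model PDB or
#' CHARMM/NAMD DCD) and applies a site selection. Residue numbering is
#' preserved verbatim from the source file; sites appear in file order.
#' XTC is not supported (its lossy compression needs a dedicated library);
#' convert such trajectories to DCD or multi-model PDB first.
#'
#' @param trajectory_path path to the trajectory (`.pdb` or `.dcd`).
#' @param topology_path path to the PDB topology naming the atoms. May equal
#'   `trajectory_path` for a multi-model PDB.
#' @param selection selection string, see [select_sites()]. Default keeps one
#'   C-alpha per protein residue plus all heavy atoms of non-water, non-ion
#'   hetero residues (e.g. a bound nucleotide).
#' @param dt time between stored frames, ps.
#' @return A [coordinate_ensemble()].
#' @export
read_ensemble <- function(trajectory_path, topology_path = trajectory_path,
                          selection = "protein-CA + hetero-heavy", dt = 1) {
  ext <- tolower(tools::file_ext(trajectory_path))
  if (ext == "xtc")
    abort_format(sprintf("'%s': XTC trajectories are not supported; convert to DCD or multi-model PDB",
                         trajectory_path))
  top <- read_pdb_models(topology_path)
  if (ext == "dcd") {
    coords <- read_dcd(trajectory_path)
    if (dim(coords)[2] != nrow(top$labels))
      abort_integrity(sprintf("trajectory '%s' has %d atoms per frame but topology '%s' has %d",
                              trajectory_path, dim(coords)[2], topology_path, nrow(top$labels)))
  } else if (ext %in% c("pdb", "ent", "")) {
    traj <- read_pdb_models(trajectory_path)
    if (nrow(traj$labels) != nrow(top$labels))
      abort_integrity(sprintf("trajectory and topology atom counts differ (%d vs %d)",
                              nrow(traj$labels), nrow(top$labels)))
    coords <- traj$coords
  } else {
    abort_format(sprintf("unrecognised trajectory format '.%s' for '%s'", ext, trajectory_path))
  }
  idx <- select_sites(top$labels, top$element, selection)
  coordinate_ensemble(coords[, idx, , drop = FALSE], top$labels[idx, , drop = FALSE],
                      dt = dt,
                      source = sprintf("%s [%s] selection='%s'",
                                       basename(trajectory_path),
                                       basename(topology_path), selection))
}

#' Resolve a site selection against atom labels
#'
#' The selection mini-language is a union of clauses joined by `+`. Each
#' clause is either a keyword -- `protein-CA` (C-alpha atoms of ATOM
#' records), `protein-heavy`, `hetero-heavy` / `ligand-heavy` (heavy atoms
#' of non-water, non-ion HETATM residues), `all` -- or a conjunction of
#' `field:value` filters with fields `chain`, `resno` (single number or
#' `lo-hi` range), `resname`, `name` (comma-separated atom names).
#' Example: `"protein-CA + resname:GTP"` or `"chain:A resno:25-40 name:CA"`.
#'
#' @param labels site-label data.frame (see [coordinate_ensemble()]).
#' @param element character vector of element symbols, one per atom.
#' @param selection selection string.
#' @return Integer indices of the selected atoms, in file order.
#' @export
select_sites <- function(labels, element, selection) {
  heavy <- !(toupper(substr(element, 1, 1)) == "H")
  is_het <- labels$record == "HETATM"
  resup <- toupper(labels$resname)
  is_water <- resup %in% .water_resnames
  is_ion <- resup %in% .ion_resnames & is_het
  clauses <- trimws(strsplit(selection, "+", fixed = TRUE)[[1]])
  clauses <- clauses[nzchar(clauses)]
  if (length(clauses) == 0) abort_argument("empty selection string")
  keep <- rep(FALSE, nrow(labels))
  for (cl in clauses) {
    if (cl == "all") {
      keep <- keep | TRUE
    } else if (cl == "protein-CA") {
      keep <- keep | (!is_het & labels$atom == "CA")
    } else if (cl == "protein-heavy") {
      keep <- keep | (!is_het & heavy)
    } else if (cl %in% c("hetero-heavy", "ligand-heavy")) {
      keep <- keep | (is_het & heavy & !is_water & !is_ion)
    } else {
      m <- rep(TRUE, nrow(labels))
      for (tok in strsplit(cl, "[[:space:]]+")[[1]]) {
        kv <- strsplit(tok, ":", fixed = TRUE)[[1]]
        if (length(kv) != 2)
          abort_argument(sprintf("cannot parse selection token '%s'", tok))
        val <- kv[2]
        m <- m & switch(kv[1],
          chain   = labels$chain %in% strsplit(val, ",")[[1]],
          resname = resup %in% toupper(strsplit(val, ",")[[1]]),
          name    = labels$atom %in% strsplit(val, ",")[[1]],
          resno   = {
            r <- as.integer(strsplit(val, "-", fixed = TRUE)[[1]])
            if (anyNA(r)) abort_argument(sprintf("bad resno range '%s'", val))
            if (length(r) == 1) labels$resno == r
            else labels$resno >= r[1] & labels$resno <= r[2]
          },
          abort_argument(sprintf("unknown selection field '%s'", kv[1])))
      }
      keep <- keep | m
    }
  }
  idx <- which(keep)
  if (length(idx) < 2) {
    avail <- unique(paste0(labels$chain, ":", labels$resno, "(", labels$resname, ")"))
    abort_selection(sprintf("selection '%s' matches %d atoms (need >= 2); available residues: %s",
                            selection, length(idx),
                            paste(head(avail, 25), collapse = " ")))
  }
  idx
}

#' Write / read a fluctuation series as a text container
#'
#' The container is a TSV of mean-centered displacements (one row per frame,
#' three columns per site, full double precision) plus a JSON sidecar
#' carrying site labels, frame spacing, per-site means and provenance.
#' `read_fluctuations()` inverts `write_fluctuations()` exactly.
#'
#' @param fluct a [fluctuation_series()].
#' @param prefix output path prefix; writes `<prefix>.tsv` and `<prefix>.json`.
#' @return `prefix`, invisibly (writer); a `fluctuation_series` (reader).
#' @export
write_fluctuations <- function(fluct, prefix) {
  stopifnot(inherits(fluct, "fluctuation_series"))
  nf <- n_frames(fluct); ns <- n_sites(fluct)
  flat <- matrix(aperm(fluct$deltas, c(1, 3, 2)), nrow = nf)  # x,y,z per site
  keys <- site_key(fluct$site_labels)
  hdr <- paste(rep(keys, each = 3), rep(c("x", "y", "z"), ns), sep = ".")
  con <- file(paste0(prefix, ".tsv"), "w"); on.exit(close(con))
  writeLines(paste(hdr, collapse = "\t"), con)
  writeLines(apply(flat, 1, function(r) paste(fmt_num(r), collapse = "\t")), con)
  write_json_file(list(format = "ctcdyn-fluctuations-v1",
                       dt_ps = fluct$dt,
                       n_frames = nf, n_sites = ns,
                       site_labels = fluct$site_labels,
                       means = lapply(seq_len(ns), function(i) unname(fluct$means[i, ])),
                       source = fluct$source),
                  paste0(prefix, ".json"))
  invisible(prefix)
}

#' @rdname write_fluctuations
#' @export
read_fluctuations <- function(prefix) {
  tsv <- paste0(prefix, ".tsv"); side <- paste0(prefix, ".json")
  if (!file.exists(tsv) || !file.exists(side))
    abort_format(sprintf("fluctuation container '%s' (.tsv + .json) not found", prefix))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!identical(meta$format, "ctcdyn-fluctuations-v1"))
    abort_format(sprintf("'%s' is not a ctcdyn fluctuation sidecar", side))
  flat <- as.matrix(read.csv(tsv, sep = "\t", check.names = FALSE))
  ns <- meta$n_sites
  deltas <- aperm(array(flat, c(nrow(flat), 3, ns)), c(1, 3, 2))
  means <- do.call(rbind, lapply(meta$means, as.numeric))
  labels <- as.data.frame(meta$site_labels)
  fluctuation_series(deltas, means, meta$dt_ps, labels, source = meta$source %||% "")
}
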