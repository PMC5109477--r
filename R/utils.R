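# Classed error conditions so callers (and tests) can distinguish failure
# modes without matching message text.
ctc_abort <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "ctcdyn_error", "error", "condition"),
                      call = call))
}

abort_format       <- function(msg) ctc_abort(msg, "ctcdyn_format_error")
abort_selection    <- function(msg) ctc_abort(msg, "ctcdyn_selection_error")
abort_integrity    <- function(msg) ctc_abort(msg, "ctcdyn_integrity_error")
abort_argument     <- function(msg) ctc_abort(msg, "ctcdyn_argument_error")
abort_alignment    <- function(msg) ctc_abort(msg, "ctcdyn_alignment_error")
abort_spec         <- function(msg) ctc_abort(msg, "ctcdyn_spec_error")
abort_degenerate   <- function(msg) ctc_abort(msg, "ctcdyn_degenerate_error")
abort_insufficient <- function(msg) ctc_abort(msg, "ctcdyn_insufficient_data_error")
abort_binning      <- function(msg) ctc_abort(msg, "ctcdyn_binning_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Site labels are carried as a data.frame with one row per site.
# resno keeps the source file numbering verbatim (1-based, never reindexed).
make_site_labels <- function(resno, resname, atom, chain, record = "ATOM") {
  data.frame(resno = as.integer(resno), resname = as.character(resname),
             atom = as.character(atom), chain = as.character(chain),
             record = rep_len(as.character(record), length(resno)),
             stringsAsFactors = FALSE)
}

site_key <- function(labels) {
  paste(labels$chain, labels$resno, labels$resname, labels$atom, sep = "/")
}

check_labels_match <- function(la, lb, what = "inputs") {
  ka <- site_key(la); kb <- site_key(lb)
  if (length(ka) != length(kb) || any(ka != kb)) {
    diff <- union(setdiff(ka, kb), setdiff(kb, ka))
    if (length(diff) == 0) diff <- "site order differs"
    abort_alignment(sprintf("site labels of %s do not match; differing sites: %s",
                            what, paste(head(diff, 10), collapse = ", ")))
  }
  invisible(TRUE)
}

# Deterministic numeric formatting for text artifacts (full double precision,
# identical bytes across runs with identical inputs).
fmt_num <- function(x) sprintf("%.17g", x)

write_matrix_csv <- function(m, labels, path) {
  df <- as.data.frame(m)
  names(df) <- site_key(labels)
  df <- cbind(site = site_key(labels), df)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}
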