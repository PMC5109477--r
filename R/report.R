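# Figure / HTML report generation.  Rendering is best-effort: a missing
# artifact is listed as absent and PNG devices that fail (headless setups
# without cairo) are skipped, but the HTML summary is always written.

.diverging_palette <- function(n = 64) {
  grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(n)
}

try_png <- function(path, expr, width = 700, height = 600) {
  ok <- tryCatch({
    grDevices::png(path, width = width, height = height)
    on.exit(grDevices::dev.off(), add = TRUE)
    expr
    TRUE
  }, error = function(e) FALSE)
  if (!ok && file.exists(path)) unlink(path)
  ok
}

read_matrix_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

plot_heatmap <- function(m, main, zlim = NULL, mask_values = NULL) {
  n <- nrow(m)
  if (!is.null(mask_values)) {
    z <- matrix(0, n, n)
    z[m == "positive"] <- 1
    z[m == "negative"] <- -1
    m <- z
    zlim <- c(-1, 1)
  } else {
    storage.mode(m) <- "double"
    m[!is.finite(m)] <- NA
  }
  if (is.null(zlim)) zlim <- range(m, na.rm = TRUE, finite = TRUE)
  if (!all(is.finite(zlim)) || diff(zlim) == 0) zlim <- zlim[1] + c(-1, 1)
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  col = .diverging_palette(), zlim = zlim,
                  xlab = "site index", ylab = "site index", main = main,
                  useRaster = TRUE)
}

cmd_report <- function(args) {
  flags <- parse_flags(args, c("dir"), c("dir"))
  render_report(flags$dir)
  0L
}

#' Render an HTML + PNG summary of pipeline artifacts
#'
#' Scans `outputs_dir` (recursively) for the CSV artifacts the CLI commands
#' produce and renders: stiffness and stiffness-difference heatmaps,
#' correlation maps with the two-threshold positive/negative mask, CTC
#' decay curves with a 1/e guide line, and the causality network. Absent
#' artifacts are listed as such; the report is still written.
#'
#' @param outputs_dir directory containing command outputs.
#' @return Path of the written `report.html`, invisibly.
#' @export
render_report <- function(outputs_dir) {
  if (!dir.exists(outputs_dir)) abort_format(sprintf("no such directory: '%s'", outputs_dir))
  find1 <- function(name) {
    hits <- list.files(outputs_dir, pattern = paste0("^", name, "$"),
                       recursive = TRUE, full.names = TRUE)
    if (length(hits) == 0) NULL else sort(hits)[1]
  }
  html <- c("<!DOCTYPE html><html><head><title>ctcdyn report</title></head><body>",
            "<h1>ctcdyn analysis report</h1>")
  section <- function(title, file, png, draw) {
    if (is.null(file)) {
      html <<- c(html, sprintf("<h2>%s</h2><p><em>artifact absent</em></p>", title))
      return(invisible(NULL))
    }
    png_path <- file.path(outputs_dir, png)
    ok <- try_png(png_path, draw(file))
    html <<- c(html, sprintf("<h2>%s</h2>", title),
               sprintf("<p>source: <code>%s</code></p>", basename(file)),
               if (ok) sprintf('<img src="%s" alt="%s"/>', png, title)
               else "<p><em>figure rendering unavailable</em></p>")
  }
  section("Pairwise stiffness map", find1("stiffness_matrix.csv"), "stiffness.png",
          function(f) plot_heatmap(read_matrix_csv(f), "k_ij (kcal/mol/A^2)"))
  section("Correlation map", find1("correlation_matrix.csv"), "correlation.png",
          function(f) plot_heatmap(read_matrix_csv(f), "C_ij", zlim = c(-1, 1)))
  section("Thresholded correlation mask", find1("correlation_mask.csv"), "correlation_mask.png",
          function(f) plot_heatmap(read_matrix_csv(f), "C_ij mask (red +, blue -)",
                                   mask_values = TRUE))
  section("Time-delayed correlation curves", find1("ctc_curve.csv"), "ctc_curves.png",
          function(f) {
            cu <- read.csv(f)
            graphics::matplot(cu$lag_ps, cbind(cu$c_forward, cu$c_backward),
                              type = "l", lty = 1, col = c("red", "black"),
                              xlab = "lag (ps)", ylab = "C(tau) / C(0)",
                              main = "CTC forward (red) vs backward (black)")
            graphics::abline(h = exp(-1), lty = 2, col = "grey40")
          })
  edges_file <- find1("edges.csv")
  if (!is.null(edges_file)) {
    ed <- read.csv(edges_file)
    if (nrow(ed) == 0) {
      html <- c(html, "<h2>Causality network</h2><p><em>no edges</em></p>")
    } else {
      section("Causality network", edges_file, "network.png", function(f) {
        e <- read.csv(f)
        g <- igraph::graph_from_data_frame(e[, c("driver_site", "follower_site")],
                                           directed = TRUE)
        igraph::plot.igraph(g, edge.arrow.size = 0.6,
                            vertex.color = "lightsteelblue",
                            main = "driver -> follower")
      })
    }
  } else {
    html <- c(html, "<h2>Causality network</h2><p><em>artifact absent</em></p>")
  }
  html <- c(html, "</body></html>")
  out <- file.path(outputs_dir, "report.html")
  writeLines(html, out)
  invisible(out)
}
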