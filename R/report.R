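# Static HTML + SVG report over evaluation curves. The report is a pure
# view: every number shown in the HTML is copied verbatim from a curve
# TSV cell, and each figure's underlying numbers sit in the adjacent
# TSV, so nothing exists only in a plot.

svg_header <- function(w, h) {
  c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            w, h, w, h),
    '<rect width="100%" height="100%" fill="white"/>')
}

.palette <- c("#1b6ca8", "#c23b22", "#2e8540", "#8e44ad", "#e67e22", "#555555")

# One polyline chart; series = named list of data.frames with x, y.
svg_chart <- function(series, xlab, ylab, xlim = c(0, 1), ylim = c(0, 1),
                      w = 480L, h = 360L) {
  m <- 50L  # margin
  sx <- function(x) m + (x - xlim[1]) / max(xlim[2] - xlim[1], 1e-9) * (w - 2L * m)
  sy <- function(y) (h - m) - (y - ylim[1]) / max(ylim[2] - ylim[1], 1e-9) * (h - 2L * m)
  out <- svg_header(w, h)
  out <- c(out,
           sprintf('<line x1="%g" y1="%g" x2="%g" y2="%g" stroke="black"/>',
                   sx(xlim[1]), sy(ylim[1]), sx(xlim[2]), sy(ylim[1])),
           sprintf('<line x1="%g" y1="%g" x2="%g" y2="%g" stroke="black"/>',
                   sx(xlim[1]), sy(ylim[1]), sx(xlim[1]), sy(ylim[2])),
           sprintf('<text x="%g" y="%g" font-size="12" text-anchor="middle">%s</text>',
                   sx(mean(xlim)), h - 8L, xlab),
           sprintf('<text x="12" y="%g" font-size="12" text-anchor="middle" transform="rotate(-90 12 %g)">%s</text>',
                   sy(mean(ylim)), sy(mean(ylim)), ylab))
  for (lim in list(c(xlim[1], TRUE), c(xlim[2], TRUE)))
    out <- c(out, sprintf('<text x="%g" y="%g" font-size="10" text-anchor="middle">%g</text>',
                          sx(lim[1]), sy(ylim[1]) + 14L, lim[1]))
  for (lim in ylim)
    out <- c(out, sprintf('<text x="%g" y="%g" font-size="10" text-anchor="end">%g</text>',
                          sx(xlim[1]) - 4L, sy(lim) + 3L, lim))
  k <- 0L
  for (nm in names(series)) {
    k <- k + 1L
    col <- .palette[(k - 1L) %% length(.palette) + 1L]
    df <- series[[nm]]
    pts <- paste(sprintf("%g,%g", sx(df$x), sy(df$y)), collapse = " ")
    out <- c(out,
             sprintf('<polyline points="%s" fill="none" stroke="%s" stroke-width="2"/>', pts, col),
             sprintf('<circle cx="%g" cy="%g" r="2.5" fill="%s"/>', sx(df$x), sy(df$y), col),
             sprintf('<text x="%g" y="%g" font-size="11" fill="%s">%s</text>',
                     w - m - 120L, m + 14L * k, col, nm))
  }
  c(out, "</svg>")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a static HTML report over evaluation curves
#'
#' Writes `report.html` plus two SVG figures -- sensitivity vs false
#' discovery rate (MAPQ as the curve parameter, FDR on the x-axis) and
#' precision vs MAPQ threshold -- into `out_dir`. The HTML tables are
#' built from the raw text of the curve TSVs, cell for cell, so every
#' rendered number equals the corresponding TSV cell.
#'
#' @param curve_tsvs Named character vector: mapper name to curve TSV
#'   path (as written by [evaluate_mapper()]).
#' @param out_dir Output directory.
#' @param metadata Optional named character vector echoed in the report
#'   header (inputs, configuration, seed, version).
#' @return Invisible list with `html` and `svg` paths.
#' @export
render_report <- function(curve_tsvs, out_dir, metadata = character(0)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(names(curve_tsvs)))
    names(curve_tsvs) <- tools::file_path_sans_ext(basename(curve_tsvs))
  curves <- lapply(curve_tsvs, utils::read.delim, colClasses = "character")
  num <- function(df, col) as.numeric(df[[col]])

  sens_fdr <- lapply(curves, function(df)
    data.frame(x = num(df, "fdr"), y = num(df, "sensitivity")))
  prec_q <- lapply(curves, function(df)
    data.frame(x = num(df, "q"), y = num(df, "precision")))
  qmax <- max(1, unlist(lapply(prec_q, function(d) d$x)))
  svg1 <- file.path(out_dir, "sensitivity_fdr.svg")
  svg2 <- file.path(out_dir, "precision_mapq.svg")
  writeLines(svg_chart(sens_fdr, "false discovery rate", "sensitivity"), svg1)
  writeLines(svg_chart(prec_q, "MAPQ threshold", "precision",
                       xlim = c(0, qmax)), svg2)

  html <- c("<!DOCTYPE html>", "<html><head><meta charset='utf-8'>",
            "<title>Mapper evaluation report</title>",
            "<style>body{font-family:sans-serif;margin:2em}table{border-collapse:collapse}",
            "td,th{border:1px solid #999;padding:2px 8px;font-size:13px}</style>",
            "</head><body>", "<h1>Mapper evaluation report</h1>")
  if (length(metadata)) {
    html <- c(html, "<ul>")
    for (k in names(metadata))
      html <- c(html, sprintf("<li><b>%s</b>: %s</li>", html_escape(k),
                              html_escape(as.character(metadata[[k]]))))
    html <- c(html, "</ul>")
  }
  html <- c(html,
            "<h2>Sensitivity vs false discovery rate (MAPQ-parametrized)</h2>",
            "<img src='sensitivity_fdr.svg' alt='sensitivity vs FDR'/>",
            "<h2>Precision vs MAPQ threshold</h2>",
            "<img src='precision_mapq.svg' alt='precision vs MAPQ'/>")
  for (nm in names(curve_tsvs)) {
    lines <- readLines(curve_tsvs[[nm]])
    cells <- strsplit(lines, "\t", fixed = TRUE)
    html <- c(html, sprintf("<h2>%s</h2>", html_escape(nm)), "<table>")
    for (r in seq_along(cells)) {
      tag <- if (r == 1L) "th" else "td"
      html <- c(html, paste0("<tr>",
                             paste0("<", tag, ">", html_escape(cells[[r]]),
                                    "</", tag, ">", collapse = ""),
                             "</tr>"))
    }
    html <- c(html, "</table>")
  }
  html <- c(html, "</body></html>")
  out_html <- file.path(out_dir, "report.html")
  writeLines(html, out_html)
  invisible(list(html = out_html, svg = c(svg1, svg2)))
}
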