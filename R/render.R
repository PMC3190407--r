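## Fixed-precision coordinate formatting keeps SVG output byte-stable.
svg_num <- function(x) sprintf("%.4f", x)

## Clockwise-from-12-o'clock polar point in SVG pixel coordinates.
polar_xy <- function(cx, cy, r, angle_deg) {
  a <- angle_deg * pi / 180
  c(cx + r * sin(a), cy - r * cos(a))
}

## Path data for an annular wedge. A full circle is drawn as two half arcs
## because a single 360-degree SVG arc degenerates to nothing.
wedge_path <- function(cx, cy, r0, r1, theta, sweep) {
  arc <- function(r, a0, a1, sweep_flag) {
    p <- polar_xy(cx, cy, r, a1)
    large <- if (abs(a1 - a0) > 180) 1L else 0L
    sprintf("A %s %s 0 %d %d %s %s", svg_num(r), svg_num(r), large, sweep_flag,
            svg_num(p[1L]), svg_num(p[2L]))
  }
  if (sweep >= 360 - 1e-9) {
    mid <- theta + 180
    end <- theta + 360
    o0 <- polar_xy(cx, cy, r1, theta)
    i0 <- polar_xy(cx, cy, r0, theta)
    paste(
      sprintf("M %s %s", svg_num(o0[1L]), svg_num(o0[2L])),
      arc(r1, theta, mid, 1L), arc(r1, mid, end, 1L),
      sprintf("L %s %s", svg_num(i0[1L]), svg_num(i0[2L])),
      arc(r0, end, mid, 0L), arc(r0, mid, theta, 0L),
      "Z")
  } else {
    a1 <- theta + sweep
    o0 <- polar_xy(cx, cy, r1, theta)
    i1 <- polar_xy(cx, cy, r0, a1)
    paste(
      sprintf("M %s %s", svg_num(o0[1L]), svg_num(o0[2L])),
      arc(r1, theta, a1, 1L),
      sprintf("L %s %s", svg_num(i1[1L]), svg_num(i1[2L])),
      arc(r0, a1, theta, 0L),
      "Z")
  }
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

#' Render a laid-out chart to SVG
#'
#' Produces a square, self-contained SVG 1.1 document: one annular-wedge path
#' per sector with positive sweep, text elements per label placement, an
#' optional gradient legend, and an optional ancestor breadcrumb drawn
#' top-left. The chart circle is centered with radius 45\% of the canvas
#' edge. Output is a pure function of its inputs — identical inputs give
#' byte-identical documents.
#'
#' @param sectors Sector data frame from the layout step.
#' @param colors Data frame with `path` and `color` (hex) columns.
#' @param labels Optional label placements from [place_labels()].
#' @param legend Optional [gradient_spec()] (with resolved domain) to draw as
#'   a legend.
#' @param summary Optional character vector of ancestor names (breadcrumb).
#' @param canvas_px Canvas edge length in pixels.
#' @param font_px Label font size in pixels.
#' @return The SVG document as a single string.
#' @export
render_svg <- function(sectors, colors, labels = NULL, legend = NULL,
                       summary = NULL, canvas_px = 800, font_px = 11) {
  cx <- canvas_px / 2
  cy <- canvas_px / 2
  chart_r <- 0.45 * canvas_px
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                   'height="%d" viewBox="0 0 %d %d">'),
            canvas_px, canvas_px, canvas_px, canvas_px),
    sprintf('<rect width="%d" height="%d" fill="#ffffff"/>', canvas_px, canvas_px)
  )
  if (!is.null(legend)) {
    out <- c(out,
      "<defs>",
      '<linearGradient id="legend-gradient" x1="0" y1="0" x2="1" y2="0">',
      sprintf('<stop offset="0" stop-color="%s"/>', legend$low),
      sprintf('<stop offset="1" stop-color="%s"/>', legend$high),
      "</linearGradient>",
      "</defs>")
  }
  col <- colors$color[match(sectors$path, colors$path)]
  col[is.na(col)] <- "#bbbbbb"
  vis <- which(sectors$sweep > 0)
  for (i in vis) {
    s <- sectors[i, ]
    out <- c(out, sprintf(
      '<path d="%s" fill="%s" stroke="#ffffff" stroke-width="1"><title>%s</title></path>',
      wedge_path(cx, cy, s$r_inner * chart_r, s$r_outer * chart_r,
                 s$theta_start, s$sweep),
      col[i],
      xml_escape(sprintf("%s: %s", s$path, format_magnitude(s$magnitude)))))
  }
  if (!is.null(labels)) {
    shown <- labels[labels$mode != "hidden", , drop = FALSE]
    for (i in seq_len(nrow(shown))) {
      lb <- shown[i, ]
      p <- polar_xy(cx, cy, lb$radius_px, lb$angle)
      rot <- if (lb$mode == "radial") {
        (lb$angle - 90) %% 360
      } else {
        lb$angle %% 360
      }
      # flip upside-down text for readability
      if (rot > 90 && rot < 270) rot <- (rot + 180) %% 360
      anchor <- if (lb$mode == "radial") "start" else "middle"
      out <- c(out, sprintf(
        '<text x="%s" y="%s" font-size="%s" font-family="sans-serif" text-anchor="%s" transform="rotate(%s %s %s)">%s</text>',
        svg_num(p[1L]), svg_num(p[2L]), svg_num(font_px), anchor,
        svg_num(rot), svg_num(p[1L]), svg_num(p[2L]), xml_escape(lb$text)))
    }
  }
  if (!is.null(summary) && length(summary)) {
    out <- c(out, sprintf(
      '<text x="10" y="%s" font-size="%s" font-family="sans-serif" fill="#555555">%s</text>',
      svg_num(16 + font_px * (seq_along(summary) - 1) * 1.3), svg_num(font_px),
      xml_escape(summary)))
  }
  if (!is.null(legend)) {
    dom <- legend$domain
    out <- c(out,
      sprintf('<rect x="%d" y="%d" width="120" height="12" fill="url(#legend-gradient)" stroke="#555555"/>',
              canvas_px - 140, canvas_px - 40),
      sprintf('<text x="%d" y="%d" font-size="10" font-family="sans-serif">%s</text>',
              canvas_px - 140, canvas_px - 44, xml_escape(legend$attribute)),
      sprintf('<text x="%d" y="%d" font-size="10" font-family="sans-serif">%s</text>',
              canvas_px - 140, canvas_px - 16, xml_escape(format_magnitude(dom[[1L]]))),
      sprintf('<text x="%d" y="%d" font-size="10" font-family="sans-serif" text-anchor="end">%s</text>',
              canvas_px - 20, canvas_px - 16, xml_escape(format_magnitude(dom[[2L]]))))
  }
  out <- c(out, "</svg>")
  paste(out, collapse = "\n")
}

#' Wrap a chart and its SVG snapshot in a single HTML page
#'
#' Produces one self-contained HTML5 document embedding the chart's XML
#' (verbatim, as an inert `application/xml` script block, so the data travel
#' with the figure) and the static SVG snapshot. No network resources are
#' referenced.
#'
#' @param chart A `taxburst_chart`.
#' @param snapshot_svg SVG document text, e.g. from [render_svg()].
#' @param title Page title.
#' @return The HTML document as a single string.
#' @export
render_html <- function(chart, snapshot_svg, title = "taxburst chart") {
  xml_file <- tempfile(fileext = ".xml")
  on.exit(unlink(xml_file))
  write_chart_xml(chart, xml_file)
  chart_xml <- paste(readLines(xml_file, warn = FALSE), collapse = "\n")
  svg_body <- sub('^<\\?xml[^>]*\\?>\n?', "", snapshot_svg)
  paste(c(
    "<!DOCTYPE html>",
    '<html lang="en">',
    "<head>",
    '<meta charset="utf-8"/>',
    sprintf("<title>%s</title>", xml_escape(title)),
    "</head>",
    "<body>",
    sprintf("<h1>%s</h1>", xml_escape(title)),
    svg_body,
    '<script type="application/xml" id="chart-data">',
    chart_xml,
    "</script>",
    "</body>",
    "</html>"), collapse = "\n")
}

#' Human-readable magnitude formatting
#'
#' Thousands-separated; integral values are printed without decimals, others
#' with up to three decimal places (trailing zeros trimmed).
#'
#' @param value Finite numeric values.
#' @return Character vector.
#' @export
format_magnitude <- function(value) {
  vapply(value, function(v) {
    if (!is.finite(v)) stop("format_magnitude: value must be finite")
    if (v == round(v)) {
      formatC(v, format = "f", digits = 0, big.mark = ",")
    } else {
      s <- formatC(v, format = "f", digits = 3, big.mark = ",")
      sub("\\.?0+$", "", s)
    }
  }, character(1))
}
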