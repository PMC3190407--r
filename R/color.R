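#' Recursive magnitude-weighted hue assignment
#'
#' Implements the HSL coloring scheme that ties color to both lineage and
#' quantity. The root's immediate children split the hue range into equal
#' contiguous sub-ranges in sibling order; every deeper node subdivides its
#' own range among its children using subtree magnitudes as weights. Each node
#' is colored by the *minimum* of its range, so the largest (first, after
#' sorting) child of every generation inherits its parent's hue — dominant
#' lineages keep a consistent color from the center outward. Generations are
#' distinguished by lightness, which increases linearly with depth while
#' saturation stays constant.
#'
#' @param root Root `chart_node`, sorted with [sort_tree()].
#' @param dataset Dataset index for the magnitude weights.
#' @param hue_range Half-open hue interval `[h0, h1)` in degrees.
#' @param depth_for_lightness Depth at which lightness reaches its maximum
#'   (typically the visible depth).
#' @param lightness_range `c(L_min, L_max)` mapped over depths 1..
#'   `depth_for_lightness`.
#' @param saturation Constant saturation.
#' @return Data frame: `path`, `hue`, `saturation`, `lightness`, plus the
#'   node's hue interval (`hue_lo`, `hue_hi`).
#' @export
assign_hues <- function(root, dataset = 1L, hue_range = c(0, 360),
                        depth_for_lightness = NULL,
                        lightness_range = c(0.45, 0.80), saturation = 0.70) {
  if (is.null(depth_for_lightness)) depth_for_lightness <- tree_height(root)
  l_min <- lightness_range[[1L]]; l_max <- lightness_range[[2L]]
  lightness_at <- function(depth) {
    if (depth_for_lightness <= 1L) return(l_min)
    l_min + (l_max - l_min) * min(depth - 1, depth_for_lightness - 1) /
      (depth_for_lightness - 1)
  }
  rows <- list()
  walk <- function(node, lo, hi, depth, path, equal_split) {
    path <- if (nzchar(path)) paste(path, node$name, sep = "/") else node$name
    rows[[length(rows) + 1L]] <<- data.frame(
      path = path, hue = lo %% 360, saturation = saturation,
      lightness = lightness_at(depth), hue_lo = lo, hue_hi = hi,
      stringsAsFactors = FALSE)
    kids <- node$children
    if (length(kids) == 0L) return()
    if (equal_split) {
      widths <- rep((hi - lo) / length(kids), length(kids))
    } else {
      w <- vapply(kids, magnitude_total, numeric(1), dataset)
      # an all-zero family still partitions its range (equal split) so the
      # sibling ranges always tile the parent; individual zero-total children
      # among weighted siblings get zero-width ranges at the running minimum
      widths <- if (sum(w) > 0) (hi - lo) * w / sum(w) else
        rep((hi - lo) / length(kids), length(kids))
    }
    cursor <- lo
    for (k in seq_along(kids)) {
      walk(kids[[k]], cursor, cursor + widths[[k]], depth + 1L, path,
           equal_split = FALSE)
      cursor <- cursor + widths[[k]]
    }
  }
  walk(root, hue_range[[1L]], hue_range[[2L]], 1L, "", equal_split = TRUE)
  do.call(rbind, rows)
}

#' Gradient specification for value-mapped coloring
#'
#' @param attribute Attribute name whose per-node aggregate drives the color.
#' @param low,high Hex colors for the domain ends (default low = red,
#'   high = green).
#' @param domain `c(min, max)` or `NULL` to resolve from the data at render
#'   time.
#' @return A list of class `gradient_spec`.
#' @export
gradient_spec <- function(attribute, low = "#ff0000", high = "#00cc00",
                          domain = NULL) {
  if (!is.null(domain)) {
    if (length(domain) != 2L || !all(is.finite(domain)) || domain[[1L]] >= domain[[2L]]) {
      stop("gradient_spec: domain must be c(min, max) with min < max")
    }
  }
  structure(list(attribute = attribute, low = low, high = high,
                 domain = domain), class = "gradient_spec")
}

#' Map a value onto a color gradient
#'
#' Linear interpolation between the gradient's end colors, per RGB channel;
#' values outside the domain are clamped. A degenerate domain (min == max)
#' maps everything to the low color with a warning.
#'
#' @param value Numeric values.
#' @param spec A [gradient_spec()] with an explicit or resolved domain.
#' @return Hex color strings.
#' @export
gradient_color <- function(value, spec) {
  dom <- spec$domain
  if (is.null(dom)) stop("gradient_color: gradient domain is unresolved")
  lo <- grDevices::col2rgb(spec$low)[, 1L]
  hi <- grDevices::col2rgb(spec$high)[, 1L]
  if (dom[[1L]] == dom[[2L]]) {
    warning("gradient_color: degenerate domain; using the low color")
    f <- rep(0, length(value))
  } else {
    f <- pmin(1, pmax(0, (value - dom[[1L]]) / (dom[[2L]] - dom[[1L]])))
  }
  rgb_mat <- outer(f, hi - lo) + matrix(lo, nrow = length(f), ncol = 3L, byrow = TRUE)
  grDevices::rgb(rgb_mat[, 1L], rgb_mat[, 2L], rgb_mat[, 3L], maxColorValue = 255)
}

#' Convert HSL to a hex color
#'
#' Standard hue-saturation-lightness to RGB conversion (the color model used
#' by the recursive hue assignment; base R provides HSV, not HSL).
#'
#' @param h Hue in degrees.
#' @param s Saturation in [0, 1].
#' @param l Lightness in [0, 1].
#' @return Hex color strings.
#' @export
hsl_to_hex <- function(h, s, l) {
  h <- (h %% 360) / 60
  c_ <- (1 - abs(2 * l - 1)) * s
  x <- c_ * (1 - abs(h %% 2 - 1))
  m <- l - c_ / 2
  i <- floor(h) %% 6
  r <- c_ * (i == 0 | i == 5) + x * (i == 1 | i == 4)
  g <- c_ * (i == 1 | i == 2) + x * (i == 0 | i == 3)
  b <- c_ * (i == 3 | i == 4) + x * (i == 2 | i == 5)
  grDevices::rgb(r + m, g + m, b + m)
}
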