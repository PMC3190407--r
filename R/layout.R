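#' Magnitude-proportional angular layout
#'
#' Computes one sector per node: the sweep is `360 * magnitude_total(node) /
#' magnitude_total(root)` degrees, children are packed contiguously from their
#' parent's start angle in sibling order, and the trailing uncovered interval
#' inside each parent represents the magnitude assigned directly to it (the
#' unassigned remainder). Angles are measured clockwise from 12 o'clock.
#' Zero-magnitude nodes receive sweep 0 and are hidden at render time, so
#' switching datasets never changes the tree structure.
#'
#' @param root Root `chart_node`, already ordered with [sort_tree()].
#' @param dataset Dataset index.
#' @param start_angle Root start angle in degrees.
#' @return Data frame of sectors: `path`, `name`, `depth`, `theta_start`,
#'   `sweep`, `magnitude` (subtree total), with `r_inner`/`r_outer` left `NA`
#'   until [compute_radii()].
#' @export
compute_angles <- function(root, dataset = 1L, start_angle = 0) {
  total <- magnitude_total(root, dataset)
  if (!is.finite(total) || total <= 0) {
    stop("compute_angles: chart has zero total magnitude")
  }
  rows <- list()
  walk <- function(node, theta, depth, path) {
    path <- if (nzchar(path)) paste(path, node$name, sep = "/") else node$name
    m <- magnitude_total(node, dataset)
    sweep <- 360 * m / total
    rows[[length(rows) + 1L]] <<- data.frame(
      path = path, name = node$name, depth = depth,
      theta_start = theta %% 360, sweep = sweep, magnitude = m,
      r_inner = NA_real_, r_outer = NA_real_, stringsAsFactors = FALSE)
    cursor <- theta
    for (ch in node$children) {
      walk(ch, cursor, depth + 1L, path)
      cursor <- cursor + 360 * magnitude_total(ch, dataset) / total
    }
  }
  walk(root, start_angle, 1L, "")
  do.call(rbind, rows)
}

#' Assign radial bands with outward compression
#'
#' Each depth occupies one annular band. Band widths follow
#' `compression^max(0, depth - full_label_depth)` and are normalized to sum to
#' 1, so levels beyond `full_label_depth` get geometrically thinner bands —
#' the deep, information-rich ranks stay visible in relation to the root while
#' intermediate labels shrink. Sectors deeper than `visible_depth` are
#' dropped (their magnitude is still represented by ancestor sweeps when the
#' tree was pruned upstream).
#'
#' @param sectors Output of [compute_angles()].
#' @param visible_depth Deepest band drawn.
#' @param full_label_depth Last depth with an uncompressed band.
#' @param compression Per-level width ratio beyond `full_label_depth`, in
#'   (0, 1].
#' @return The sectors with `r_inner` / `r_outer` filled in, as fractions of
#'   the chart radius.
#' @export
compute_radii <- function(sectors, visible_depth = max(sectors$depth),
                          full_label_depth = 3, compression = 0.7) {
  if (visible_depth < 1) stop("compute_radii: visible_depth must be >= 1")
  if (compression <= 0 || compression > 1) {
    stop("compute_radii: compression must be in (0, 1]")
  }
  sectors <- sectors[sectors$depth <= visible_depth, , drop = FALSE]
  d <- seq_len(visible_depth)
  w <- compression^pmax(0, d - full_label_depth)
  w <- w / sum(w)
  outer <- cumsum(w)
  inner <- c(0, outer[-length(outer)])
  sectors$r_inner <- inner[sectors$depth]
  sectors$r_outer <- outer[sectors$depth]
  rownames(sectors) <- NULL
  sectors
}

#' Place labels with collision-based shortening
#'
#' Labels in the outermost visible band run along radii; inner labels run
#' tangentially at their band's mid-radius. Text width is estimated as
#' `0.6 * font_px` per character (a deterministic, renderer-independent
#' stand-in for font metrics). A tangential label must fit its sector's arc
#' length, a radial label the radial span from its band to the canvas edge,
#' and both need one text height of angular clearance. Oversize labels are
#' shortened step-wise to the longest prefix plus an ellipsis that fits, and
#' hidden when fewer than 4 characters fit.
#'
#' @param sectors Laid-out sectors (after [compute_radii()]).
#' @param canvas_radius_px Canvas half-edge in pixels; the chart circle itself
#'   spans 90\% of it.
#' @param font_px Font size in pixels.
#' @return Data frame: `path`, `mode` (`"radial"`, `"tangential"`,
#'   `"hidden"`), `angle` (label mid-angle, degrees), `radius_px`, `text`.
#' @export
place_labels <- function(sectors, canvas_radius_px = 400, font_px = 11) {
  chart_r <- 0.9 * canvas_radius_px
  outer_depth <- max(sectors$depth)
  char_w <- 0.6 * font_px
  n <- nrow(sectors)
  mode <- character(n); angle <- numeric(n); radius <- numeric(n)
  text <- character(n)
  for (i in seq_len(n)) {
    s <- sectors[i, ]
    mid_angle <- (s$theta_start + s$sweep / 2) %% 360
    nm <- s$name
    if (s$sweep <= 0) {
      mode[i] <- "hidden"; angle[i] <- mid_angle; radius[i] <- 0; text[i] <- ""
      next
    }
    if (s$depth == outer_depth && s$depth > 1L) {
      r0 <- s$r_inner * chart_r
      clearance <- s$sweep * pi / 180 * r0
      avail <- canvas_radius_px - r0
      if (clearance < font_px) {
        fit <- 0L
      } else {
        fit <- floor(avail / char_w)
      }
      placed <- shorten_label(nm, fit)
      mode[i] <- if (is.na(placed)) "hidden" else "radial"
      angle[i] <- mid_angle
      radius[i] <- r0
      text[i] <- if (is.na(placed)) "" else placed
    } else {
      r_mid <- (s$r_inner + s$r_outer) / 2 * chart_r
      band_px <- (s$r_outer - s$r_inner) * chart_r
      arc <- s$sweep * pi / 180 * r_mid
      fit <- if (band_px < font_px) 0L else floor(arc / char_w)
      placed <- shorten_label(nm, fit)
      mode[i] <- if (is.na(placed)) "hidden" else "tangential"
      angle[i] <- mid_angle
      radius[i] <- r_mid
      text[i] <- if (is.na(placed)) "" else placed
    }
  }
  data.frame(path = sectors$path, mode = mode, angle = angle,
             radius_px = radius, text = text, stringsAsFactors = FALSE)
}

## Longest prefix + ellipsis that fits `fit` character slots; NA if < 4 fit.
shorten_label <- function(name, fit) {
  if (fit >= nchar(name)) return(name)
  if (fit < 4L) return(NA_character_)
  paste0(substr(name, 1L, fit - 1L), "…")
}

#' Group tiny adjacent siblings
#'
#' Siblings whose sweep falls below `threshold` degrees are merged into a
#' single trailing `"N more..."` sector per parent (they are adjacent because
#' siblings are sorted by decreasing magnitude), reducing clutter the way a
#' semantic zoom joins small nodes into discernible regions.
#'
#' @param sectors Laid-out sectors.
#' @param threshold Minimum sweep, degrees.
#' @return The sectors with tiny siblings replaced by group sectors.
#' @export
group_small_sectors <- function(sectors, threshold = 1) {
  parent_of <- function(p) sub("/[^/]*$", "", p)
  has_parent <- grepl("/", sectors$path, fixed = TRUE)
  tiny <- sectors$sweep < threshold & sectors$sweep > 0 & has_parent
  # drop descendants of grouped sectors too
  tiny_paths <- sectors$path[tiny]
  if (length(tiny_paths) == 0L) return(sectors)
  under_tiny <- Reduce(`|`, lapply(paste0(tiny_paths, "/"),
                                   function(p) startsWith(sectors$path, p)),
                       accumulate = FALSE, init = rep(FALSE, nrow(sectors)))
  groups <- split(which(tiny), parent_of(sectors$path[tiny]))
  extra <- lapply(names(groups), function(par) {
    idx <- groups[[par]]
    data.frame(
      path = paste0(par, "/", length(idx), " more…"),
      name = sprintf("%d more…", length(idx)),
      depth = sectors$depth[idx[1L]],
      theta_start = min(sectors$theta_start[idx]),
      sweep = sum(sectors$sweep[idx]),
      magnitude = sum(sectors$magnitude[idx]),
      r_inner = sectors$r_inner[idx[1L]],
      r_outer = sectors$r_outer[idx[1L]],
      stringsAsFactors = FALSE)
  })
  out <- rbind(sectors[!(tiny | under_tiny), , drop = FALSE], do.call(rbind, extra))
  out <- out[order(out$depth, out$theta_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Polar-coordinate zoom as a static transform
#'
#' Interpolates linearly, in polar coordinates, between the overview layout
#' (`t = 0`) and a layout recomputed with `focus` as the root (`t = 1`, where
#' the focus sweeps the full circle). Nodes outside the focus subtree shrink
#' toward sweep 0 while keeping their overview position, giving the fisheye
#' effect as a family of static layouts parameterized by `t`.
#'
#' @param root Sorted root `chart_node`.
#' @param focus `/`-joined path of the focus node (root name first); the root
#'   path gives the identity transform.
#' @param t Interpolation parameter in [0, 1].
#' @param dataset Dataset index.
#' @param start_angle Root start angle, degrees.
#' @param full_label_depth,compression Passed to [compute_radii()].
#' @return Sector data frame in overview paths.
#' @export
zoom_layout <- function(root, focus, t, dataset = 1L, start_angle = 0,
                        full_label_depth = 3, compression = 0.7) {
  if (t < 0 || t > 1) stop("zoom_layout: t must be in [0, 1]")
  s0 <- compute_radii(compute_angles(root, dataset, start_angle),
                      full_label_depth = full_label_depth,
                      compression = compression)
  if (t == 0) return(s0)
  focus_node <- subtree_at(root, focus)
  s1 <- compute_radii(compute_angles(focus_node, dataset, start_angle),
                      full_label_depth = full_label_depth,
                      compression = compression)
  # re-express focus-rooted paths in overview coordinates
  prefix <- sub("/[^/]*$", "", focus)
  if (!grepl("/", focus, fixed = TRUE)) prefix <- ""
  s1$path <- if (nzchar(prefix)) paste(prefix, s1$path, sep = "/") else s1$path
  if (t == 1) return(s1)
  j <- match(s0$path, s1$path)
  present <- !is.na(j)
  out <- s0
  lerp <- function(a, b) (1 - t) * a + t * b
  out$theta_start[present] <- lerp(s0$theta_start[present], s1$theta_start[j[present]])
  out$sweep[present]       <- lerp(s0$sweep[present],       s1$sweep[j[present]])
  out$r_inner[present]     <- lerp(s0$r_inner[present],     s1$r_inner[j[present]])
  out$r_outer[present]     <- lerp(s0$r_outer[present],     s1$r_outer[j[present]])
  out$sweep[!present]      <- lerp(s0$sweep[!present], 0)
  out
}
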