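demo_layout <- function() {
  root <- sort_tree(build_tree(list(
    list(lineage = c("R", "A"), magnitude = 60),
    list(lineage = c("R", "B"), magnitude = 30),
    list(lineage = "R", magnitude = 10))))
  sectors <- compute_radii(compute_angles(root))
  hues <- assign_hues(root)
  colors <- data.frame(path = hues$path,
                       color = hsl_to_hex(hues$hue, hues$saturation, hues$lightness))
  list(root = root, sectors = sectors, colors = colors)
}

test_that("render_svg emits one path per visible sector and parses as XML", {
  d <- demo_layout()
  svg <- render_svg(d$sectors, d$colors)
  n_paths <- length(gregexpr("<path ", svg, fixed = TRUE)[[1]])
  expect_equal(n_paths, sum(d$sectors$sweep > 0))
  doc <- xml2::read_xml(svg)
  expect_equal(xml2::xml_name(doc), "svg")

  # random layouts also stay well-formed
  for (seed in 1:5) {
    root <- sort_tree(random_tree(sample(10:60, 1), seed = seed))
    if (magnitude_total(root, 1) == 0) next
    s <- compute_radii(compute_angles(root))
    h <- assign_hues(root)
    cols <- data.frame(path = h$path,
                       color = hsl_to_hex(h$hue, h$saturation, h$lightness))
    svg <- render_svg(s, cols, labels = place_labels(s))
    expect_silent(xml2::read_xml(svg))
    expect_equal(length(gregexpr("<path ", svg, fixed = TRUE)[[1]]),
                 sum(s$sweep > 0))
  }
})

test_that("rendering is deterministic and handles the full-circle wedge", {
  d <- demo_layout()
  lab <- place_labels(d$sectors)
  svg1 <- render_svg(d$sectors, d$colors, labels = lab)
  svg2 <- render_svg(d$sectors, d$colors, labels = lab)
  expect_identical(svg1, svg2)

  # the root is a full-circle sector: drawn as two half arcs (4 A commands)
  root_path <- regmatches(svg1, regexpr('<path d="M[^"]*"', svg1))
  expect_equal(length(gregexpr(" A ", root_path, fixed = TRUE)[[1]]), 4)

  # wedge midpoints lie inside the chart circle
  canvas <- 800; chart_r <- 0.45 * canvas
  for (i in seq_len(nrow(d$sectors))) {
    s <- d$sectors[i, ]
    if (s$sweep == 0) next
    mid_r <- (s$r_inner + s$r_outer) / 2 * chart_r
    expect_lte(mid_r, chart_r)
  }
})

test_that("gradient legends and breadcrumbs appear when requested", {
  d <- demo_layout()
  spec <- gradient_spec("confidence", domain = c(0, 1))
  svg <- render_svg(d$sectors, d$colors, legend = spec,
                    summary = c("R", "A"))
  expect_match(svg, "legend-gradient")
  expect_match(svg, "confidence")
  expect_silent(xml2::read_xml(svg))
})

test_that("render_html embeds the chart XML verbatim and parses as HTML", {
  ch <- chart(demo_layout()$root, dataset_names = "d1")
  svg <- render_svg(demo_layout()$sectors, demo_layout()$colors)
  html <- render_html(ch, svg, title = "demo")
  p <- tempfile(fileext = ".xml")
  write_chart_xml(ch, p)
  embedded <- paste(readLines(p, warn = FALSE), collapse = "\n")
  expect_true(grepl(embedded, html, fixed = TRUE))
  expect_silent(xml2::read_html(html))
  # self-contained: nothing is fetched from the network
  expect_false(grepl("src=\"http", html, fixed = TRUE))
  expect_false(grepl("<link", html, fixed = TRUE))
})

test_that("format_magnitude separates thousands and trims decimals", {
  expect_equal(format_magnitude(110467), "110,467")
  expect_equal(format_magnitude(0), "0")
  expect_equal(format_magnitude(1234.5), "1,234.5")
  expect_equal(format_magnitude(2.25), "2.25")
  expect_equal(format_magnitude(1e6), "1,000,000")
  expect_error(format_magnitude(Inf), "finite")
})

test_that("render_chart runs the full display pipeline", {
  root <- build_tree(list(
    list(lineage = c("R", "Bacteria", "Proteobacteria", "Gamma"), magnitude = 50,
         attributes = list(confidence = 0.9)),
    list(lineage = c("R", "Archaea"), magnitude = 20,
         attributes = list(confidence = 0.4))))
  ch <- chart(root, attribute_defs = list(
    attribute_def("confidence", gradient = gradient_spec("confidence",
                                                         domain = c(0, 1)))))
  svg <- render_chart(ch)
  expect_silent(xml2::read_xml(svg))

  # depth cap: only two rings rendered, totals conserved in the tooltip sum
  svg2 <- render_chart(ch, max_depth = 2, collapse = FALSE)
  doc <- xml2::read_xml(svg2)
  titles <- xml2::xml_text(xml2::xml_find_all(doc, "//*[local-name()='title']"))
  expect_true(any(grepl("^R: 70$", titles)))
  expect_true(all(lengths(strsplit(sub(":.*", "", titles), "/")) <= 2))

  # zoom contract: the focused node spans the full circle
  svg3 <- render_chart(ch, zoom = "Bacteria", collapse = FALSE)
  doc3 <- xml2::read_xml(svg3)
  titles3 <- xml2::xml_text(xml2::xml_find_all(doc3, "//*[local-name()='title']"))
  expect_true(any(grepl("^Bacteria: 50$", titles3)))
  expect_false(any(grepl("Archaea", titles3)))

  # gradient coloring adds a legend
  svg4 <- render_chart(ch, color_by = "confidence")
  expect_match(svg4, "legend-gradient")

  # ambiguous zoom target errors with candidates
  root2 <- build_tree(list(
    list(lineage = c("R", "A", "dup"), magnitude = 1),
    list(lineage = c("R", "B", "dup"), magnitude = 1)))
  ch2 <- chart(root2)
  expect_error(render_chart(ch2, zoom = "dup", collapse = FALSE),
               "ambiguous.*R/A/dup.*R/B/dup")
})
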