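test_that("compute_angles is magnitude-proportional with a trailing remainder", {
  root <- build_tree(list(
    list(lineage = c("R", "A"), magnitude = 60),
    list(lineage = c("R", "B"), magnitude = 30),
    list(lineage = "R", magnitude = 10)))
  s <- compute_angles(sort_tree(root))
  expect_equal(s$sweep[s$name == "R"], 360)
  expect_equal(s$sweep[s$name == "A"], 216)
  expect_equal(s$sweep[s$name == "B"], 108)
  # remainder: parent's sweep minus children's = 36 degrees
  expect_equal(360 - 216 - 108, 36)
  expect_equal(s$theta_start[s$name == "A"], 0)
  expect_equal(s$theta_start[s$name == "B"], 216)

  one <- build_tree(list(list(lineage = c("R", "A"), magnitude = 5)))
  expect_equal(compute_angles(one)$sweep, c(360, 360))

  empty <- chart_node("R")
  expect_error(compute_angles(empty), "zero total")
})

test_that("angular conservation holds on randomized trees", {
  for (seed in 1:25) {
    root <- random_tree(sample(10:200, 1), seed = seed, integer_mag = FALSE)
    if (magnitude_total(root, 1) == 0) next
    s <- compute_angles(root, start_angle = runif(1, 0, 360))
    tab <- oracle_tree_table(root)
    total <- tab$total[tab$depth == 1]
    for (i in seq_len(nrow(s))) {
      kids <- s[startsWith(s$path, paste0(s$path[i], "/")) &
                  s$depth == s$depth[i] + 1L, , drop = FALSE]
      assigned <- tab$assigned[tab$path == s$path[i]]
      expect_lt(abs(s$sweep[i] - sum(kids$sweep) - 360 * assigned / total), 1e-9)
    }
    # total angular coverage: all assigned magnitudes together span 360
    expect_lt(abs(sum(360 * tab$assigned / total) - 360), 1e-9)
  }
})

test_that("compute_radii compresses bands geometrically and normalizes", {
  s <- data.frame(path = c("R", "R/a", "R/a/b"), name = c("R", "a", "b"),
                  depth = 1:3, theta_start = 0, sweep = 360,
                  magnitude = 1, r_inner = NA_real_, r_outer = NA_real_)
  r1 <- compute_radii(s, visible_depth = 3, full_label_depth = 3, compression = 1)
  expect_equal(r1$r_outer - r1$r_inner, rep(1 / 3, 3))

  r2 <- compute_radii(s, visible_depth = 3, full_label_depth = 1, compression = 0.5)
  expect_equal(r2$r_outer - r2$r_inner, c(4 / 7, 2 / 7, 1 / 7))
  expect_equal(max(r2$r_outer), 1)

  # deeper-than-visible sectors are dropped
  r3 <- compute_radii(s, visible_depth = 2)
  expect_equal(nrow(r3), 2)
  expect_equal(max(r3$r_outer), 1)
})

test_that("labels fit their sectors and never collide", {
  # sweep 180 deg at ~100 px: a 10-char name fits in full
  root <- build_tree(list(
    list(lineage = c("R", "Abcdefghij"), magnitude = 50),
    list(lineage = c("R", "Tiny"), magnitude = 50)))
  s <- compute_radii(compute_angles(sort_tree(root)))
  lab <- place_labels(s, canvas_radius_px = 200, font_px = 10)
  expect_equal(lab$text[lab$path == "R/Abcdefghij"], "Abcdefghij")

  # a 2-degree sliver hides its label
  root2 <- build_tree(list(
    list(lineage = c("R", "Enormous"), magnitude = 358),
    list(lineage = c("R", "Slivername"), magnitude = 2)))
  s2 <- compute_radii(compute_angles(sort_tree(root2)))
  lab2 <- place_labels(s2, canvas_radius_px = 200, font_px = 10)
  expect_equal(lab2$mode[lab2$path == "R/Slivername"], "hidden")

  # shortened labels are a prefix plus ellipsis
  long <- build_tree(list(
    list(lineage = c("R", strrep("x", 60)), magnitude = 30),
    list(lineage = c("R", "other"), magnitude = 30)))
  s3 <- compute_radii(compute_angles(sort_tree(long)))
  lab3 <- place_labels(s3, canvas_radius_px = 120, font_px = 12)
  shown <- lab3[lab3$mode != "hidden" & grepl("x", lab3$text), ]
  if (nrow(shown)) {
    expect_true(all(grepl("^x+…$", shown$text)))
  }

  # brute-force pairwise overlap check on random layouts
  for (seed in 1:10) {
    root <- random_tree(sample(10:80, 1), seed = seed)
    if (magnitude_total(root, 1) == 0) next
    s <- compute_radii(compute_angles(sort_tree(root)))
    lab <- place_labels(s, canvas_radius_px = 300, font_px = 11)
    lab <- lab[lab$mode != "hidden", , drop = FALSE]
    if (nrow(lab) < 2) next
    boxes <- lapply(seq_len(nrow(lab)), function(i) {
      l <- lab[i, ]
      w <- 0.6 * 11 * nchar(l$text)
      if (l$mode == "tangential") {
        half_ang <- (w / l$radius_px) / 2 * 180 / pi
        list(a0 = l$angle - half_ang, a1 = l$angle + half_ang,
             r0 = l$radius_px - 5.5, r1 = l$radius_px + 5.5)
      } else {
        half_ang <- (11 / l$radius_px) / 2 * 180 / pi
        list(a0 = l$angle - half_ang, a1 = l$angle + half_ang,
             r0 = l$radius_px, r1 = l$radius_px + w)
      }
    })
    overlaps <- 0L
    for (i in seq_along(boxes)) {
      for (j in seq_len(i - 1L)) {
        a <- boxes[[i]]; b <- boxes[[j]]
        ang <- a$a0 < b$a1 && b$a0 < a$a1
        rad <- a$r0 < b$r1 && b$r0 < a$r1
        if (ang && rad) overlaps <- overlaps + 1L
      }
    }
    expect_equal(overlaps, 0L)
  }
})

test_that("group_small_sectors merges slivers into one group per parent", {
  root <- build_tree(c(
    list(list(lineage = c("R", "Big"), magnitude = 356)),
    lapply(1:4, function(i) list(lineage = c("R", paste0("tiny", i)),
                                 magnitude = 1))))
  s <- compute_radii(compute_angles(sort_tree(root)))
  g <- group_small_sectors(s, threshold = 1.5)
  expect_true("4 more…" %in% g$name)
  expect_false(any(grepl("tiny", g$name)))
  expect_equal(g$sweep[g$name == "4 more…"], 4)
  expect_equal(sum(g$sweep[g$depth == 2]), sum(s$sweep[s$depth == 2]))
})

test_that("zoom interpolates linearly between overview and focus layouts", {
  root <- sort_tree(build_tree(list(
    list(lineage = c("R", "A", "X"), magnitude = 20),
    list(lineage = c("R", "A", "Y"), magnitude = 5),
    list(lineage = c("R", "B"), magnitude = 75))))
  s0 <- compute_radii(compute_angles(root))

  # t = 0: bit-identical to the overview
  expect_identical(zoom_layout(root, "R/A", 0), s0)

  # t = 1: the focus sweeps the full circle and matches a fresh layout
  s1 <- zoom_layout(root, "R/A", 1)
  expect_equal(s1$sweep[s1$path == "R/A"], 360)
  fresh <- compute_radii(compute_angles(sort_tree(taxburst:::subtree_at(root, "R/A"))))
  expect_equal(s1$sweep, fresh$sweep)
  expect_equal(s1$theta_start, fresh$theta_start)

  # focus with a 90-degree sweep reaches 225 at the midpoint
  expect_equal(s0$sweep[s0$path == "R/A"], 90)
  sm <- zoom_layout(root, "R/A", 0.5)
  expect_equal(sm$sweep[sm$path == "R/A"], 225)

  # zooming on the root is the identity at every t
  for (t in c(0, 0.25, 1)) {
    sr <- zoom_layout(root, "R", t)
    expect_equal(sr$sweep, s0$sweep)
    expect_equal(sr$theta_start, s0$theta_start)
  }

  # nodes outside the focus shrink toward zero sweep
  expect_equal(sm$sweep[sm$path == "R/B"], s0$sweep[s0$path == "R/B"] / 2)

  expect_error(zoom_layout(root, "R/nonexistent", 1), "not found")
})
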