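test_that("build_tree accumulates magnitudes and sums subtrees", {
  root <- build_tree(list(
    list(lineage = c("R", "A"), magnitude = 3),
    list(lineage = c("R", "A"), magnitude = 2)
  ))
  expect_equal(root$name, "R")
  expect_equal(root$children[["A"]]$magnitude, 5)
  expect_equal(magnitude_total(root, 1), 5)

  root2 <- build_tree(list(
    list(lineage = c("R", "A", "X"), magnitude = 1),
    list(lineage = c("R", "B"), magnitude = 1)
  ))
  expect_equal(magnitude_total(root2, 1), 2)
  expect_equal(root2$magnitude, 0)

  # oracle: root total equals the direct sum of the inputs
  set.seed(42)
  lin <- replicate(100, c("R", sample(LETTERS[1:5], sample(1:4, 1))),
                   simplify = FALSE)
  mags <- runif(100, 0, 10)
  asg <- Map(function(l, m) list(lineage = l, magnitude = m), lin, mags)
  root3 <- build_tree(asg)
  expect_equal(magnitude_total(root3, 1), sum(mags))

  expect_error(build_tree(list()), "empty")
  expect_error(build_tree(list(list(lineage = "R", magnitude = -1))),
               "non-negative")
})

test_that("lineages with different first levels get a synthetic root", {
  root <- build_tree(list(
    list(lineage = "Bacteria", magnitude = 1),
    list(lineage = "Archaea", magnitude = 2)
  ))
  expect_equal(root$name, "root")
  expect_setequal(names(root$children), c("Bacteria", "Archaea"))
  expect_equal(magnitude_total(root, 1), 3)
})

test_that("build_tree aggregates attributes as magnitude-weighted means", {
  root <- build_tree(list(
    list(lineage = c("R", "A"), magnitude = 3,
         attributes = list(score = -10)),
    list(lineage = c("R", "A"), magnitude = 1,
         attributes = list(score = -30))
  ))
  agg <- root$children[["A"]]$attributes$score
  expect_equal(agg$mean, (-10 * 3 + -30 * 1) / 4)
  expect_equal(agg$weight, 4)
})

test_that("collapse_linear absorbs zero-assignment unary chains", {
  root <- build_tree(list(list(
    lineage = c("R", "Mammalia", "Primates", "Hominidae", "Homo sapiens"),
    magnitude = 7)))
  out <- collapse_linear(root)
  expect_equal(out$name, "R")
  expect_equal(names(out$children), "Homo sapiens")
  expect_equal(vapply(out$children[[1]]$collapsed, `[[`, character(1), "name"),
               c("Mammalia", "Primates", "Hominidae"))
  expect_equal(magnitude_total(out, 1), 7)

  # a branching node is untouched
  root2 <- build_tree(list(
    list(lineage = c("R", "A"), magnitude = 1),
    list(lineage = c("R", "B"), magnitude = 1)))
  expect_equal(collapse_linear(root2), root2)

  # idempotent
  expect_equal(collapse_linear(out), out)
})

test_that("collapse_linear keeps assigned nodes even in unary chains", {
  root <- build_tree(list(
    list(lineage = c("R", "A", "B", "C"), magnitude = 2),
    list(lineage = c("R", "A"), magnitude = 1)))
  out <- collapse_linear(root)
  # A has assigned magnitude, so only B is absorbed into C
  expect_equal(names(out$children), "A")
  expect_equal(names(out$children[["A"]]$children), "C")
  expect_equal(vapply(out$children[["A"]]$children[["C"]]$collapsed,
                      `[[`, character(1), "name"), "B")
})

test_that("prune_depth folds deep magnitudes into the retained ancestor", {
  root <- build_tree(list(list(lineage = c("R", "A", "B", "C"), magnitude = 7)))
  out <- prune_depth(root, 2)
  expect_equal(names(out$children), "A")
  expect_equal(out$children[["A"]]$magnitude, 7)
  expect_length(out$children[["A"]]$children, 0)
  expect_equal(magnitude_total(out, 1), 7)

  # deeper than the tree: identity
  expect_equal(prune_depth(root, 10), root)
  expect_error(prune_depth(root, 0), "positive")
})

test_that("prune_depth merges attribute aggregates weight-proportionally", {
  root <- build_tree(list(
    list(lineage = c("R", "A", "X"), magnitude = 3,
         attributes = list(score = -10)),
    list(lineage = c("R", "A", "Y"), magnitude = 1,
         attributes = list(score = -30))
  ))
  out <- prune_depth(root, 2)
  agg <- out$children[["A"]]$attributes$score
  pooled <- aggregate_attribute(c(-10, -30), c(3, 1))
  expect_equal(agg$mean, pooled$mean)
  expect_equal(agg$weight, pooled$weight)
})

test_that("sort_tree orders by decreasing total with case-insensitive ties", {
  root <- chart_node("R")
  for (nm in c("x", "y", "z")) root$children[[nm]] <- chart_node(nm)
  root$children[["x"]]$magnitude <- 2
  root$children[["y"]]$magnitude <- 9
  root$children[["z"]]$magnitude <- 5
  expect_equal(names(sort_tree(root)$children), c("y", "z", "x"))

  root2 <- chart_node("R")
  root2$children[["b"]] <- chart_node("b")
  root2$children[["A"]] <- chart_node("A")
  root2$children[["b"]]$magnitude <- 1
  root2$children[["A"]]$magnitude <- 1
  expect_equal(names(sort_tree(root2)$children), c("A", "b"))

  # sorting twice is a no-op
  s1 <- sort_tree(root)
  expect_equal(sort_tree(s1), s1)
})

test_that("search honors visibility depth and collapsed names", {
  root <- build_tree(list(
    list(lineage = c("root", "Bacteria", "Proteobacteria", "Gamma"), magnitude = 1),
    list(lineage = c("root", "Archaea"), magnitude = 1)))
  res <- search_tree(root, "proteo", visible_depth = 6)
  expect_equal(res$matched, "root/Bacteria/Proteobacteria")
  expect_length(res$hidden_ancestors, 0)

  res2 <- search_tree(root, "proteo", visible_depth = 2)
  expect_length(res2$matched, 0)
  expect_equal(res2$hidden_ancestors, "root/Bacteria")

  res3 <- search_tree(root, "no such taxon")
  expect_length(res3$matched, 0)
  expect_length(res3$hidden_ancestors, 0)

  # collapsed names keep matching after compression
  col <- collapse_linear(build_tree(list(
    list(lineage = c("root", "Mammalia", "Primates", "Homo"), magnitude = 1))))
  res4 <- search_tree(col, "primates")
  expect_equal(res4$matched, "root/Homo")

  expect_error(search_tree(root, ""), "non-empty")
})

test_that("tree edits conserve totals and commute with sorting", {
  for (seed in 1:20) {
    root <- random_tree(sample(10:120, 1), n_datasets = 2, seed = seed)
    before <- oracle_assigned_sum(root)
    expect_identical(magnitude_total(root), before)
    expect_identical(magnitude_total(collapse_linear(root)), before)
    expect_identical(magnitude_total(prune_depth(root, 3)), before)

    # pruning commutes with sorting in final sibling order
    a2 <- sort_tree(prune_depth(root, 4))
    b2 <- prune_depth(sort_tree(root), 4)
    expect_equal(a2, b2)
    # collapsing renames chains to their deepest node, so the display
    # pipeline sorts afterwards; pre-sorting must not change that result
    a <- sort_tree(collapse_linear(root))
    b <- sort_tree(collapse_linear(sort_tree(root)))
    expect_equal(a, b)
  }
})

test_that("collapse never removes assigned or branching nodes", {
  for (seed in 21:30) {
    root <- random_tree(80, seed = seed)
    removable <- character(0)
    walk <- function(n, is_root) {
      if (!is_root && length(n$children) == 1L && all(n$magnitude == 0)) {
        removable <<- c(removable, n$name)
      }
      for (ch in n$children) walk(ch, FALSE)
    }
    walk(root, TRUE)
    surviving <- character(0)
    walk2 <- function(n) {
      surviving <<- c(surviving, n$name)
      for (ch in n$children) walk2(ch)
    }
    walk2(collapse_linear(root))
    kept_wrongly <- intersect(surviving, removable)
    expect_length(kept_wrongly, 0)
    # and everything that is not removable survives
    all_names <- character(0)
    walk3 <- function(n) { all_names <<- c(all_names, n$name); lapply(n$children, walk3) }
    walk3(root)
    expect_setequal(surviving, setdiff(all_names, removable))
  }
})
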