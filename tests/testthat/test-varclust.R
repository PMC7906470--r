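test_that("single-variable groups reproduce the standardized variable", {
  set.seed(1)
  D <- mixed_dataset(data.frame(x = rnorm(50)))
  r <- pcamix_first_pc(D, "x")
  n <- 50
  zs <- (D$df$x - mean(D$df$x)) / (sd(D$df$x) * sqrt((n - 1) / n))
  expect_equal(r$scores, zs, tolerance = 1e-10)
  expect_equal(r$homogeneity, 1, tolerance = 1e-10)
})

test_that("perfectly correlated pairs have homogeneity 2", {
  set.seed(2)
  x <- rnorm(60)
  D <- mixed_dataset(data.frame(x = x, y = 2 * x + 1))
  expect_equal(pcamix_first_pc(D)$homogeneity, 2, tolerance = 1e-10)
  Dneg <- mixed_dataset(data.frame(x = x, y = -3 * x))
  expect_equal(pcamix_first_pc(Dneg)$homogeneity, 2, tolerance = 1e-10)
})

test_that("all-quantitative PCAmix equals plain principal components", {
  set.seed(3)
  n <- 120
  X <- matrix(rnorm(n * 4), n)
  X[, 2] <- 0.7 * X[, 1] + sqrt(1 - 0.49) * X[, 2]
  X[, 4] <- -0.5 * X[, 3] + X[, 4]
  D <- mixed_dataset(as.data.frame(X))
  r <- pcamix_first_pc(D)
  pc <- princomp(as.data.frame(X), cor = TRUE)
  expect_equal(r$homogeneity, unname(pc$sdev[1]^2), tolerance = 1e-8)
  expect_lt(min(max(abs(r$scores - pc$scores[, 1])),
                max(abs(r$scores + pc$scores[, 1]))), 1e-8)
  # eigenvalue oracle: largest eigenvalue of the sample correlation matrix
  expect_equal(r$homogeneity, eigen(cor(X))$values[1], tolerance = 1e-8)
  # homogeneity identity: sum of squared member correlations with scores
  expect_equal(r$homogeneity, sum(cor(X, r$scores)^2), tolerance = 1e-8)
})

test_that("homogeneity identity holds for mixed groups and is bounded", {
  set.seed(4)
  n <- 150
  L <- rnorm(n)
  D <- mixed_dataset(data.frame(
    x = L + rnorm(n, 0, .6),
    y = -L + rnorm(n, 0, .8),
    g = ifelse(L + rnorm(n, 0, .7) > 0, "hi", "lo"),
    stringsAsFactors = FALSE))
  r <- pcamix_first_pc(D)
  h <- cor(D$df$x, r$scores)^2 + cor(D$df$y, r$scores)^2 +
    groupnets:::eta_squared(r$scores, D$df$g)
  expect_equal(r$homogeneity, h, tolerance = 1e-8)
  expect_gte(r$homogeneity, 0)
  expect_lte(r$homogeneity, 3 + 1e-12)
  expect_equal(mean(r$scores), 0, tolerance = 1e-10)
  # degenerate members are rejected
  expect_error(pcamix_first_pc(
    mixed_dataset(data.frame(a = rep(1, 10), b = rnorm(10)))), "zero-variance")
  expect_error(pcamix_first_pc(
    mixed_dataset(data.frame(g = rep("a", 10), stringsAsFactors = FALSE))),
    "single-level")
})

test_that("stored loadings reproduce training scores and project new rows", {
  set.seed(5)
  n <- 100
  D <- mixed_dataset(data.frame(
    x = rnorm(n), y = rnorm(n),
    g = sample(c("a", "b", "c"), n, TRUE), stringsAsFactors = FALSE))
  r <- pcamix_first_pc(D)
  expect_equal(project_representative(r, D), r$scores, tolerance = 1e-8)
  Dnew <- mixed_dataset(D$df[1:10, ])
  expect_equal(project_representative(r, Dnew), r$scores[1:10],
               tolerance = 1e-8)
  expect_error(project_representative(r, mixed_dataset(D$df[, 1:2])),
               "missing required")
})

test_that("the medoid minimizes total dissimilarity, ties to column order", {
  set.seed(6)
  n <- 200
  v1 <- rnorm(n)
  D <- mixed_dataset(data.frame(v1 = v1, v2 = v1 + rnorm(n, 0, .1),
                                v3 = rnorm(n)))
  r <- medoid_representative(D)
  expect_true(r$medoid %in% c("v1", "v2"))
  expect_equal(r$members, c("v1", "v2", "v3"))
  # singleton group: that variable is the medoid
  r1 <- medoid_representative(D, "v3")
  expect_equal(r1$medoid, "v3")
  # exact tie: duplicated columns; first in order wins
  Dtie <- mixed_dataset(data.frame(u = v1, w = v1))
  expect_equal(medoid_representative(Dtie)$medoid, "u")
})

test_that("clustering merges a duplicated pair first at height ~0", {
  set.seed(7)
  n <- 80
  x <- rnorm(n)
  D <- mixed_dataset(data.frame(p = rnorm(n), q = x, r = rnorm(n), s = x))
  H <- cluster_variables(D)
  expect_equal(nrow(H$merges), 3L)
  first <- sort(H$leaves[-H$merges[1, ]])
  expect_equal(first, c("q", "s"))
  expect_lt(H$raw_heights[1], 1e-8)
})

test_that("two correlated blocks are recovered by the k = 2 cut", {
  hits <- 0L
  for (s in 1:20) {
    D <- two_block_data(n = 500, r_within = 0.9, seed = s)
    H <- cluster_variables(D)
    g <- cut_dendrogram(H, 2)
    blocks <- lapply(g$groups, sort)
    ok <- any(vapply(blocks, identical, logical(1),
                     y = c("a1", "a2", "a3"))) &&
      any(vapply(blocks, identical, logical(1), y = c("b1", "b2", "b3")))
    hits <- hits + ok
  }
  expect_gte(hits, 19L)
})

test_that("merge losses are nonnegative and heights nondecreasing", {
  set.seed(8)
  n <- 120
  D <- mixed_dataset(data.frame(
    a = rnorm(n), b = rnorm(n), c = rnorm(n),
    g = sample(c("x", "y"), n, TRUE), h = sample(c("u", "v", "w"), n, TRUE),
    stringsAsFactors = FALSE))
  H <- cluster_variables(D)
  expect_true(all(H$raw_heights > -1e-8))
  expect_true(all(diff(H$heights) >= 0))
  expect_error(cluster_variables(mixed_dataset(data.frame(a = rnorm(10)))),
               "at least 2")
})

test_that("cut and split keep the grouping an antichain cut of the tree", {
  D <- two_block_data(n = 200, seed = 9)
  H <- cluster_variables(D)
  p <- length(H$leaves)
  expect_equal(names(cut_dendrogram(H, 1)$groups), paste0("G", p - 1))
  expect_equal(length(cut_dendrogram(H, p)$groups), p)
  for (k in 1:p) {
    g <- cut_dendrogram(H, k)
    expect_equal(length(g$groups), k)
    # partition of all leaves
    expect_setequal(unlist(g$groups), H$leaves)
    # each group's node reproduces exactly its member set
    for (id in names(g$groups)) {
      expect_setequal(groupnets:::node_leaves(H, g$nodes[[id]]),
                      g$groups[[id]])
    }
  }
  expect_error(cut_dendrogram(H, 0), "out of range")
  expect_error(cut_dendrogram(H, p + 1), "out of range")

  g2 <- cut_dendrogram(H, 2)
  b <- names(g2$groups)[1]
  g3 <- split_group(H, g2, b)
  expect_equal(length(g3$groups), 3L)
  new_ids <- setdiff(names(g3$groups), names(g2$groups))
  expect_setequal(unlist(g3$groups[new_ids]), g2$groups[[b]])
  # splitting a pair yields singletons; singletons are unsplittable
  gp <- cut_dendrogram(H, p - 1)
  pair <- names(gp$groups)[lengths(gp$groups) == 2][1]
  gs <- split_group(H, gp, pair)
  expect_equal(length(gs$groups), p)
  single <- names(gs$groups)[lengths(gs$groups) == 1][1]
  expect_error(split_group(H, gs, single), "unsplittable")
})

test_that("aggregation levels mirror the merge heights in reverse", {
  D <- two_block_data(n = 300, seed = 10)
  H <- cluster_variables(D)
  lev <- aggregation_levels(H)
  expect_equal(lev$height, rev(H$heights))
  expect_equal(lev$k, 2:length(H$leaves))
  # two-block fixture: large drop after k = 2
  expect_gt(lev$height[lev$k == 2], 5 * lev$height[lev$k == 3])
  # minimal case p = 2
  D2 <- mixed_dataset(data.frame(x = rnorm(20), y = rnorm(20)))
  expect_equal(nrow(aggregation_levels(cluster_variables(D2))), 1L)
})

test_that("separated variables are excluded before clustering", {
  D <- two_block_data(n = 100, seed = 11)
  H <- cluster_variables(D, exclude = c("a1", "b2"))
  expect_setequal(H$leaves, c("a2", "a3", "b1", "b3"))
})
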