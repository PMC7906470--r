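# end-to-end fixture: two latent binary factors driving two variable blocks,
# a noise block, and a binary target tied to the first factor
latent_target_data <- function(n = 400, seed = 1, flip = 0.1) {
  set.seed(seed)
  L1 <- rbinom(n, 1, .5)
  L2 <- rbinom(n, 1, .5)
  mk <- function(L, s = .5) L + rnorm(n, 0, s)
  df <- data.frame(a1 = mk(L1), a2 = mk(L1), a3 = mk(L1),
                   b1 = mk(L2), b2 = mk(L2), b3 = mk(L2),
                   t = ifelse(runif(n) < flip, 1 - L1, L1))
  df$t <- as.character(df$t)
  mixed_dataset(df)
}

test_that("the model has one node per group plus the separated variables", {
  D <- latent_target_data(seed = 2)
  H <- cluster_variables(D, exclude = "t")
  g <- cut_dendrogram(H, 2)
  M <- build_group_bn(D, g, "t", cfg = fast_cfg(), seed = 1)
  expect_s3_class(M, "group_bn_model")
  expect_setequal(M$bn$dag$nodes, c(names(g$groups), "t"))
  expect_equal(length(M$bn$dag$nodes), length(g$groups) + 1L)
  # group node states are the bins of its discretization map
  for (id in names(g$groups)) {
    expect_equal(M$bn$states[[id]], disc_bins(M$disc_maps[[id]]))
  }
  expect_error(build_group_bn(D, g, "a1", cfg = fast_cfg()),
               "must not be group members")
})

test_that("a group driving the target is linked to it in the structure", {
  hits <- 0L
  for (s in 1:10) {
    net <- generate_two_layer(4, 3, noise = 0.1, frac_discrete_children = 1,
                              seed = 300 + s)
    samp <- forward_sample(net, 500, seed = 400 + s)
    target <- net$children$child[1]
    true_group <- net$children$group[1]
    D <- samp$layer0
    H <- cluster_variables(D, exclude = target)
    g <- cut_dendrogram(H, 4)
    M <- build_group_bn(D, g, target, cfg = fast_cfg(), seed = 500 + s)
    # group holding the target's true siblings
    sibs <- setdiff(net$true_grouping[[true_group]], target)
    gid <- names(g$groups)[vapply(g$groups, function(m)
      any(sibs %in% m), logical(1))][1]
    mb <- markov_blanket(M$bn$dag, target)
    hits <- hits + (gid %in% mb)
  }
  expect_gte(hits, 8L)
})

test_that("an independent target ends with an empty Markov blanket", {
  hits <- 0L
  for (s in 1:10) {
    set.seed(600 + s)
    D0 <- two_block_data(n = 400, seed = 600 + s)
    df <- D0$df
    df$t <- as.character(rbinom(400, 1, .5))
    D <- mixed_dataset(df)
    H <- cluster_variables(D, exclude = "t")
    g <- cut_dendrogram(H, 2)
    M <- build_group_bn(D, g, "t", cfg = fast_cfg(), seed = 700 + s)
    hits <- hits + (length(markov_blanket(M$bn$dag, "t")) == 0L)
  }
  expect_gte(hits, 8L)
})

test_that("training rows re-encode exactly as at fit time", {
  D <- latent_target_data(seed = 3)
  H <- cluster_variables(D, exclude = "t")
  M <- build_group_bn(D, cut_dendrogram(H, 2), "t", cfg = fast_cfg(),
                      seed = 2)
  ev <- encode_evidence(M, D, include_target = TRUE)
  expect_equal(ev, M$disc_data[names(ev)])
  # held-out projection consistency through stored loadings
  for (id in names(M$representatives)) {
    expect_equal(project_representative(M$representatives[[id]], D),
                 M$representatives[[id]]$scores, tolerance = 1e-8)
  }
})

test_that("prediction is row-order invariant and duplicates agree", {
  D <- latent_target_data(n = 120, seed = 4)
  H <- cluster_variables(D, exclude = "t")
  M <- build_group_bn(D, cut_dendrogram(H, 2), "t", cfg = fast_cfg(),
                      seed = 3)
  Dnew <- mixed_dataset(D$df[c(5, 1, 5), ])
  p <- predict(M, Dnew, n_particles = 3000, runs = 4, seed = 9)
  # identical rows get identical estimates up to Monte-Carlo error
  expect_equal(p[1, ], p[3, ], tolerance = 0.05)
  perm <- predict(M, mixed_dataset(D$df[c(1, 5, 5), ]),
                  n_particles = 3000, runs = 4, seed = 9)
  expect_equal(sort(p[1, ]), sort(perm[2, ]), tolerance = 0.05)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-10)
  expect_error(predict(M, mixed_dataset(D$df[, c("a1", "t")])),
               "missing required")
})

test_that("a target with empty blanket receives its marginal everywhere", {
  set.seed(5)
  df <- data.frame(x = rnorm(200), y = rnorm(200),
                   t = as.character(rbinom(200, 1, .3)),
                   stringsAsFactors = FALSE)
  D <- mixed_dataset(df)
  H <- cluster_variables(D, exclude = "t")
  M <- build_group_bn(D, cut_dendrogram(H, 2), "t", cfg = fast_cfg(),
                      seed = 4)
  if (length(markov_blanket(M$bn$dag, "t")) == 0L) {
    p <- predict(M, D, n_particles = 5000, runs = 4, seed = 1)
    marg <- as.numeric(M$bn$cpts$t)
    # likelihood weighting reduces to prior sampling: marginal up to MC error
    expect_true(all(abs(sweep(p, 2, marg)) < 0.05))
    # agreement with the exact posterior
    ev <- encode_evidence(M, D)
    pe <- posterior_exact(M$bn, "t", as.list(ev[1, , drop = FALSE]))
    expect_equal(as.numeric(pe), marg, tolerance = 1e-12)
  } else {
    succeed("structure learning linked an independent target in this seed")
  }
})

test_that("models rebuild bit-identically and survive JSON round trips", {
  D <- latent_target_data(n = 150, seed = 6)
  H <- cluster_variables(D, exclude = "t")
  g <- cut_dendrogram(H, 2)
  M1 <- build_group_bn(D, g, "t", cfg = fast_cfg(), seed = 11)
  M2 <- build_group_bn(D, g, "t", cfg = fast_cfg(), seed = 11)
  j1 <- model_to_json(M1)
  expect_identical(as.character(j1), as.character(model_to_json(M2)))
  M3 <- model_from_json(j1)
  expect_equal(M3$bn$cpts, M1$bn$cpts, tolerance = 1e-12)
  expect_equal(M3$bn$dag$A, M1$bn$dag$A)
  expect_equal(lapply(M3$grouping$groups, sort),
               lapply(M1$grouping$groups, sort))
  # restored model predicts like the original
  M3$cfg <- M1$cfg
  p1 <- predict(M1, D, n_particles = 500, runs = 2, seed = 3)
  p3 <- predict(M3, D, n_particles = 500, runs = 2, seed = 3)
  expect_equal(unclass(p1), unclass(p3), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("network export writes DOT and GraphML with group metadata", {
  D <- latent_target_data(n = 100, seed = 7)
  H <- cluster_variables(D, exclude = "t")
  M <- build_group_bn(D, cut_dendrogram(H, 2), "t", cfg = fast_cfg(),
                      seed = 5)
  f1 <- withr::local_tempfile(fileext = ".dot")
  f2 <- withr::local_tempfile(fileext = ".graphml")
  export_group_network(M, f1, "dot")
  export_group_network(M, f2, "graphml")
  expect_gt(file.size(f1), 0)
  expect_true(any(grepl("members", readLines(f2))))
})
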