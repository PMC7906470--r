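test_that("local BIC matches hand computations", {
  df <- data.frame(x = c("0", "1", "1", "1"), stringsAsFactors = FALSE)
  expect_equal(bic_local("x", character(0), df),
               3 * log(3 / 4) + log(1 / 4) - 0.5 * log(4), tolerance = 1e-12)
  df2 <- data.frame(x = c("0", "0", "1", "1"), stringsAsFactors = FALSE)
  expect_equal(bic_local("x", character(0), df2),
               -2.7726 - 0.6931, tolerance = 1e-4)
})

test_that("local BIC agrees with a count-based oracle on random data", {
  for (s in 1:50) {
    df <- random_discrete_df(n = 60, p = 4, seed = s)
    pa <- sample(c("v2", "v3", "v4"), sample(0:2, 1))
    expect_equal(bic_local("v1", pa, df), bic_local_oracle("v1", pa, df),
                 tolerance = 1e-9)
  }
})

test_that("the network score decomposes into local scores", {
  set.seed(1)
  df <- random_discrete_df(n = 100, p = 5, seed = 99)
  dag <- empty_dag(names(df),
                   arcs = cbind(c("v1", "v2", "v2"), c("v2", "v3", "v5")))
  total <- sum(vapply(names(df), function(v)
    bic_local(v, parents(dag, v), df), numeric(1)))
  expect_equal(bic_score(dag, df), total, tolerance = 1e-9)
})

test_that("a parent whose likelihood gain beats the penalty is added", {
  set.seed(2)
  x <- sample(c("a", "b"), 100, TRUE)
  df <- data.frame(p = x, x = x, stringsAsFactors = FALSE)
  gain <- bic_local("x", "p", df) - bic_local("x", character(0), df)
  gain_oracle <- bic_local_oracle("x", "p", df) -
    bic_local_oracle("x", character(0), df)
  expect_equal(gain, gain_oracle, tolerance = 1e-9)
  expect_gt(gain, 0)  # deterministic copy: gain dominates the penalty
})

test_that("hill climbing leaves independent variables unconnected", {
  set.seed(3)
  df <- data.frame(x = sample(c("a", "b"), 1000, TRUE),
                   y = sample(c("a", "b"), 1000, TRUE),
                   stringsAsFactors = FALSE)
  g <- hill_climb(df, restarts = 3, seed = 1)
  expect_equal(nrow(dag_arcs(g)), 0L)
})

test_that("hill climbing finds a deterministic dependency, ignores noise", {
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    x <- sample(c("a", "b"), 200, TRUE)
    df <- data.frame(x1 = x, x2 = x,
                     x3 = sample(c("a", "b"), 200, TRUE),
                     stringsAsFactors = FALSE)
    g <- hill_climb(df, restarts = 2, seed = s)
    cp <- cpdag(g)
    has_edge <- cp$undirected["x1", "x2"] || cp$directed["x1", "x2"] ||
      cp$directed["x2", "x1"]
    x3_clear <- !any(cp$undirected["x3", ] | cp$directed["x3", ] |
                       cp$directed[, "x3"])
    hits <- hits + (has_edge && x3_clear)
  }
  expect_gte(hits, 19L)
})

test_that("hill climbing never scores below its initial structure", {
  set.seed(4)
  net <- random_bn(4, seed = 11)
  df <- groupnets:::sample_bn(net, 150)
  df[] <- lapply(df, as.character)
  init <- net$dag
  g <- hill_climb(df, init = init, restarts = 2, seed = 5)
  expect_gte(attr(g, "score"), bic_score(init, df) - 1e-9)
  expect_false(groupnets:::has_cycle(g$A))
})

test_that("the adaptive threshold minimizes the L1 idealization distance", {
  # candidates 0, 0.02, 1: distances 0.98+0+0, 0.02, 2.02 -> t = 0.02
  expect_equal(adaptive_threshold(c(1, 1, 0.02)), 0.02)
  expect_equal(adaptive_threshold(numeric(0)), 0)
  expect_equal(adaptive_threshold(rep(0, 5)), 0)
})

test_that("bootstrap averaging keeps unit-strength arcs and drops noise", {
  set.seed(5)
  x <- sample(c("a", "b"), 300, TRUE)
  y <- ifelse(runif(300) < .05, sample(c("a", "b"), 300, TRUE), x)
  df <- data.frame(x = x, y = y, z = sample(c("a", "b"), 300, TRUE),
                   stringsAsFactors = FALSE)
  ba <- bootstrap_average(df, B = 40, restarts = 1, seed = 6)
  expect_true(ba$strength["x", "y"] > 0.9)
  arcs <- dag_arcs(ba$dag)
  expect_true(all(c("x", "y") %in% c(arcs)))
  expect_false("z" %in% c(arcs))
  # invariants: symmetry and direction complementarity
  expect_equal(ba$strength, t(ba$strength))
  nz <- ba$strength > 0
  expect_equal((ba$direction + t(ba$direction))[nz],
               rep(1, sum(nz)))
  expect_true(all(ba$strength >= 0 & ba$strength <= 1))
})

test_that("parameter fitting applies the uniform prior", {
  df <- data.frame(x = factor(c("0", "0", "1", "1")))
  bn <- fit_parameters(empty_dag("x"), df, iss = 1)
  expect_equal(as.numeric(bn$cpts$x), c(0.5, 0.5))
  df2 <- data.frame(x = factor(rep("1", 4), levels = c("0", "1")))
  expect_equal(as.numeric(fit_parameters(empty_dag("x"), df2)$cpts$x),
               c(0.1, 0.9))
  # unseen parent configuration -> uniform
  df3 <- data.frame(p = factor(rep("a", 10), levels = c("a", "b")),
                    x = factor(sample(c("0", "1"), 10, TRUE)))
  bn3 <- fit_parameters(empty_dag(c("p", "x"), cbind("p", "x")), df3)
  expect_equal(as.numeric(bn3$cpts$x[, "b"]), c(0.5, 0.5))
  # every CPT column sums to one
  set.seed(6)
  net <- random_bn(5, seed = 12)
  d5 <- groupnets:::sample_bn(net, 80)
  bn5 <- fit_parameters(net$dag, d5)
  for (v in bn5$dag$nodes) {
    m <- matrix(bn5$cpts[[v]], nrow = length(bn5$states[[v]]))
    expect_equal(colSums(m), rep(1, ncol(m)), tolerance = 1e-10)
  }
})

test_that("chains become undirected and colliders stay directed", {
  chain <- empty_dag(c("A", "B", "C"), cbind(c("A", "B"), c("B", "C")))
  cp <- cpdag(chain)
  expect_equal(sum(cp$directed), 0)
  expect_true(cp$undirected["A", "B"] && cp$undirected["B", "C"])
  coll <- empty_dag(c("A", "B", "C"), cbind(c("A", "B"), c("C", "C")))
  cp2 <- cpdag(coll)
  expect_true(cp2$directed["A", "C"] && cp2$directed["B", "C"])
  expect_equal(sum(cp2$undirected), 0)
  cp0 <- cpdag(empty_dag(c("A", "B")))
  expect_equal(cpdag_n_edges(cp0), 0)
})

test_that("CPDAGs match brute-force Markov-equivalence enumeration", {
  for (p in 2:4) {
    pool <- all_dags(p)
    sigs <- vapply(pool, dag_signature, character(1))
    nodes <- paste0("n", seq_len(p))
    for (cls_idx in split(seq_along(pool), sigs)) {
      cls <- pool[cls_idx]
      compelled <- Reduce(`&`, cls)
      anyA <- Reduce(`|`, cls)
      undir <- anyA & t(anyA)
      dir <- compelled & !undir
      for (A in cls) {
        dimnames(A) <- list(nodes, nodes)
        cp <- cpdag(structure(list(nodes = nodes, A = A), class = "bn_dag"))
        expect_identical(unname(cp$directed), dir)
        expect_identical(unname(cp$undirected), undir)
      }
    }
  }
})

test_that("Markov blankets and moral adjacency coincide", {
  chain <- empty_dag(c("A", "B", "C"), cbind(c("A", "B"), c("B", "C")))
  expect_setequal(markov_blanket(chain, "B"), c("A", "C"))
  coll <- empty_dag(c("A", "B", "C"), cbind(c("A", "B"), c("C", "C")))
  expect_setequal(markov_blanket(coll, "A"), c("B", "C"))
  iso <- empty_dag(c("A", "B"))
  expect_equal(markov_blanket(iso, "A"), character(0))
  expect_error(markov_blanket(iso, "Z"), "unknown node")
  expect_true(moralize(coll)["A", "B"])  # marriage edge
  M <- moralize(chain)
  expect_false(M["A", "C"])
  for (s in 1:100) {
    net <- random_bn(6, seed = s)
    Mo <- moralize(net$dag)
    for (v in net$dag$nodes) {
      expect_setequal(net$dag$nodes[Mo[v, ]], markov_blanket(net$dag, v))
    }
  }
})

test_that("the exact posterior matches full joint enumeration", {
  for (s in 1:20) {
    net <- random_bn(sample(3:6, 1), seed = 100 + s)
    tgt <- sample(net$dag$nodes, 1)
    others <- setdiff(net$dag$nodes, tgt)
    row <- lapply(others, function(v) sample(net$states[[v]], 1))
    names(row) <- others
    pe <- posterior_exact(net, tgt, row)
    expect_equal(as.numeric(pe), posterior_enumeration(net, tgt, row),
                 tolerance = 1e-10)
  }
  # hand-enumerated chain A -> T -> B
  dag <- empty_dag(c("A", "T", "B"), cbind(c("A", "T"), c("T", "B")))
  states <- list(A = c("0", "1"), T = c("0", "1"), B = c("0", "1"))
  cpts <- list(
    A = array(c(.6, .4), 2, dimnames = list(c("0", "1"))),
    T = array(c(.8, .2, .3, .7), c(2, 2),
              dimnames = list(c("0", "1"), c("0", "1"))),
    B = array(c(.9, .1, .4, .6), c(2, 2),
              dimnames = list(c("0", "1"), c("0", "1"))))
  bn <- structure(list(dag = dag, states = states, cpts = cpts),
                  class = "discrete_bn")
  # P(T | A=0, B=1) prop to P(T|A=0) P(B=1|T): (.8*.1, .2*.6)
  pe <- posterior_exact(bn, "T", list(A = "0", B = "1"))
  expect_equal(as.numeric(pe), c(.08, .12) / .2, tolerance = 1e-12)
  # isolated target returns its marginal
  iso <- structure(list(
    dag = empty_dag(c("T", "X")),
    states = list(T = c("0", "1"), X = c("0", "1")),
    cpts = list(T = array(c(.3, .7), 2, dimnames = list(c("0", "1"))),
                X = array(c(.5, .5), 2, dimnames = list(c("0", "1"))))),
    class = "discrete_bn")
  expect_equal(as.numeric(posterior_exact(iso, "T", list(X = "0"))),
               c(.3, .7))
})

test_that("likelihood weighting converges to the exact posterior", {
  dag <- empty_dag(c("A", "T"), cbind("A", "T"))
  bn <- structure(list(
    dag = dag, states = list(A = c("a", "b"), T = c("0", "1")),
    cpts = list(A = array(c(.5, .5), 2, dimnames = list(c("a", "b"))),
                T = array(c(.1, .9, .6, .4), c(2, 2),
                          dimnames = list(c("0", "1"), c("a", "b"))))),
    class = "discrete_bn")
  arr <- predict_lw(bn, "T", data.frame(A = "a"), n_particles = 5000,
                    runs = 20, seed = 1)
  expect_equal(dim(arr), c(1, 2, 20))
  expect_true(all(abs(apply(arr, 3, function(m) m[2]) - 0.9) < 0.03))
  # probabilities normalize per row and run
  expect_equal(unname(apply(arr, c(1, 3), sum)), matrix(1, 1, 20),
               tolerance = 1e-12)

  set.seed(2)
  mads <- vapply(1:50, function(s) {
    net <- random_bn(6, seed = 200 + s)
    tgt <- sample(net$dag$nodes, 1)
    others <- setdiff(net$dag$nodes, tgt)
    row <- lapply(others, function(v) sample(net$states[[v]], 1))
    names(row) <- others
    pe <- posterior_exact(net, tgt, row)
    est <- predict_lw(net, tgt, as.data.frame(row, stringsAsFactors = FALSE),
                      n_particles = 5000, runs = 1, seed = s)
    mean(abs(est[1, , 1] - as.numeric(pe)))
  }, numeric(1))
  expect_lte(mean(mads), 0.05)
})

test_that("zero-probability evidence yields a uniform posterior with warning", {
  dag <- empty_dag(c("A", "T"), cbind("A", "T"))
  bn <- structure(list(
    dag = dag, states = list(A = c("a", "b"), T = c("0", "1")),
    cpts = list(A = array(c(1, 0), 2, dimnames = list(c("a", "b"))),
                T = array(c(.1, .9, .6, .4), c(2, 2),
                          dimnames = list(c("0", "1"), c("a", "b"))))),
    class = "discrete_bn")
  expect_warning(pe <- posterior_exact(bn, "T", list(A = "b")),
                 "zero-probability")
  expect_equal(as.numeric(pe), c(.5, .5))
  expect_warning(arr <- predict_lw(bn, "T", data.frame(A = "b"),
                                   n_particles = 100, runs = 2, seed = 1),
                 "zero-probability")
  expect_true(all(arr == 0.5))
})
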