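# Fixtures and independent oracles shared across the test files. Everything
# is generated in code; no data files.

# two independent blocks of correlated quantitative variables plus labels
two_block_data <- function(n = 500, r_within = 0.9, seed = 1) {
  set.seed(seed)
  L1 <- rnorm(n); L2 <- rnorm(n)
  s <- sqrt(1 / r_within - 1)
  df <- data.frame(a1 = L1 + rnorm(n, 0, s), a2 = L1 + rnorm(n, 0, s),
                   a3 = L1 + rnorm(n, 0, s), b1 = L2 + rnorm(n, 0, s),
                   b2 = L2 + rnorm(n, 0, s), b3 = L2 + rnorm(n, 0, s))
  mixed_dataset(df)
}

# random discrete dataset for score-oracle comparisons
random_discrete_df <- function(n, p, max_card = 3, seed = 1) {
  set.seed(seed)
  cols <- lapply(seq_len(p), function(j) {
    r <- sample(2:max_card, 1)
    sample(letters[seq_len(r)], n, replace = TRUE)
  })
  names(cols) <- paste0("v", seq_len(p))
  as.data.frame(cols, stringsAsFactors = FALSE)
}

# independent count-based local BIC (oracle; interaction/table based)
bic_local_oracle <- function(node, parents, data) {
  n <- nrow(data)
  x <- as.character(data[[node]])
  r <- length(sort(unique(x)))
  if (length(parents) == 0L) {
    tab <- table(x)
    ll <- sum(tab * log(tab / n))
    q <- 1
  } else {
    pa <- interaction(lapply(data[parents], as.character), drop = FALSE)
    tab <- table(x, pa)
    nj <- colSums(tab)
    ll <- 0
    for (j in seq_len(ncol(tab))) {
      if (nj[j] == 0) next
      for (k in seq_len(nrow(tab))) {
        if (tab[k, j] > 0) ll <- ll + tab[k, j] * log(tab[k, j] / nj[j])
      }
    }
    q <- prod(vapply(data[parents],
                     function(z) length(unique(as.character(z))), numeric(1)))
  }
  unname(ll - q * (r - 1) / 2 * log(n))
}

# enumerate all labelled DAG adjacency matrices on p nodes (p small)
all_dags <- function(p) {
  slots <- which(diag(p) == 0)
  out <- list()
  for (code in 0:(2^length(slots) - 1)) {
    A <- matrix(FALSE, p, p)
    A[slots] <- bitwAnd(code, 2^(seq_along(slots) - 1)) > 0
    if (!groupnets:::has_cycle(A)) out[[length(out) + 1L]] <- A
  }
  out
}

# skeleton + v-structure signature of an adjacency matrix
dag_signature <- function(A) {
  p <- nrow(A)
  skel <- A | t(A)
  vs <- character(0)
  for (k in seq_len(p)) {
    pa <- which(A[, k])
    if (length(pa) >= 2) {
      for (a in seq_len(length(pa) - 1)) for (b in seq((a + 1), length(pa))) {
        if (!skel[pa[a], pa[b]])
          vs <- c(vs, paste(pa[a], pa[b], k, sep = "-"))
      }
    }
  }
  paste(c(paste(which(skel & upper.tri(skel)), collapse = ","),
          paste(sort(vs), collapse = ";")), collapse = "|")
}

# brute-force CPDAG: union of orientations over the Markov equivalence class
cpdag_oracle <- function(A, dag_pool) {
  sig <- dag_signature(A)
  cls <- Filter(function(B) dag_signature(B) == sig, dag_pool)
  D <- Reduce(`&`, lapply(cls, identity))
  anyA <- Reduce(`|`, cls)
  U <- anyA & t(anyA)
  list(directed = D & !U, undirected = U)
}

# random discrete BN with the given node count (binary by default),
# Dirichlet(1) CPT columns; built from exported pieces only
random_bn <- function(p, cardinality = 2, seed = 1) {
  set.seed(seed)
  dag <- sample_uniform_dag(p, nodes = paste0("n", seq_len(p)))
  states <- lapply(dag$nodes, function(v) letters[seq_len(cardinality)])
  names(states) <- dag$nodes
  cpts <- lapply(dag$nodes, function(v) {
    pa <- parents(dag, v)
    q <- cardinality^length(pa)
    raw <- matrix(rgamma(cardinality * q, 1), nrow = cardinality)
    theta <- sweep(raw, 2, colSums(raw), `/`)
    dn <- c(list(states[[v]]), states[pa])
    names(dn) <- c(v, pa)
    array(theta, dim = c(cardinality, rep(cardinality, length(pa))),
          dimnames = dn)
  })
  names(cpts) <- dag$nodes
  structure(list(dag = dag, states = states, cpts = cpts),
            class = "discrete_bn")
}

# exact joint-enumeration posterior (independent inference oracle)
posterior_enumeration <- function(bn, target, row) {
  states <- bn$states
  grid <- expand.grid(states, stringsAsFactors = FALSE)
  names(grid) <- names(states)
  jp <- apply(grid, 1, function(r) {
    r <- as.list(r)
    pr <- 1
    for (v in bn$dag$nodes) {
      pa <- parents(bn$dag, v)
      idx <- c(list(match(r[[v]], states[[v]])),
               lapply(pa, function(u) match(r[[u]], states[[u]])))
      pr <- pr * do.call(`[`, c(list(bn$cpts[[v]]), idx))
    }
    pr
  })
  keep <- apply(grid[names(row)], 1,
                function(g) all(g == unlist(row)))
  post <- tapply(jp[keep], grid[[target]][keep], sum)
  post <- post[states[[target]]]
  as.numeric(post / sum(post))
}

# random partition of p items into at most kmax blocks, as a named list
random_partition <- function(items, kmax = 4, seed = 1) {
  set.seed(seed)
  memb <- sample.int(kmax, length(items), replace = TRUE)
  split(items, memb)
}

# split-advantage refinement fixture: two-layer ground truth, one discrete
# child as target, coarse initial cut so the target's relevant group starts
# merged with irrelevant ones
refinement_case <- function(seed, n_groups = 10, group_size = 5, noise = 0.1,
                            n = 500, n_test = 200) {
  net <- generate_two_layer(n_groups, group_size, noise,
                            frac_discrete_children = 1, seed = seed)
  samp <- forward_sample(net, n, seed = seed + 1)
  target <- net$children$child[1]
  test <- forward_sample(net, n_test, seed = seed + 2)
  list(net = net, train = samp$layer0, test = test$layer0, target = target)
}

# misclassification of the target on a held-out mixed dataset
heldout_error <- function(M, D_test, seed = 1) {
  prob <- predict(M, D_test, seed = seed)
  pred <- colnames(prob)[max.col(prob, ties.method = "first")]
  mean(pred != as.character(D_test$df[[M$target]]))
}

# desk-scale learner settings used across pipeline tests
fast_cfg <- function(...) {
  groupbn_control(B = 30L, restarts = 2L, n_particles = 1000L, runs = 10L,
                  ...)
}
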