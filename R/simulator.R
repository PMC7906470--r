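# Two-layered ground-truth network simulator: a latent group layer (uniform
# random DAG, Dirichlet CPTs) emitting noisy heterogeneous observed children,
# forward sampling, and the "standard network inference" baseline
# (hierarchical community detection plus arc projection).

#' Sample a uniformly distributed random DAG
#'
#' Markov-chain sampler: repeatedly pick a random ordered node pair; if the
#' arc is present remove it, otherwise add it when acyclicity is preserved.
#' The chain's stationary distribution is uniform over all labelled DAGs.
#'
#' @param n number of nodes.
#' @param seed optional integer seed.
#' @param burnin number of pair proposals (default `10 * n^2`).
#' @param nodes optional node names (default `"G1"` ...).
#' @return A `bn_dag`.
#' @export
sample_uniform_dag <- function(n, seed = NULL, burnin = NULL, nodes = NULL) {
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(nodes)) nodes <- paste0("G", seq_len(n))
  if (is.null(burnin)) burnin <- 10L * n^2
  A <- matrix(FALSE, n, n)
  if (n >= 2L) {
    is <- sample.int(n, burnin, replace = TRUE)
    js <- sample.int(n - 1L, burnin, replace = TRUE)
    js <- js + (js >= is)  # uniform ordered pair i != j
    for (s in seq_len(burnin)) {
      i <- is[s]; j <- js[s]
      if (A[i, j]) {
        A[i, j] <- FALSE
      } else if (!dag_path_exists(A, j, i)) {
        A[i, j] <- TRUE
      }
    }
  }
  dimnames(A) <- list(nodes, nodes)
  structure(list(nodes = nodes, A = A), class = "bn_dag")
}

# DFS: directed path from -> to?
dag_path_exists <- function(A, from, to) {
  if (A[from, to]) return(TRUE)
  stack <- which(A[from, ])
  visited <- logical(nrow(A))
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v == to) return(TRUE)
    if (visited[v]) next
    visited[v] <- TRUE
    stack <- c(stack, which(A[v, ] & !visited))
  }
  FALSE
}

# CPT arrays with symmetric Dirichlet(alpha) columns for every node of dag
random_dirichlet_cpts <- function(dag, cardinality, alpha = 1) {
  states <- lapply(dag$nodes, function(v) paste0("s", seq_len(cardinality)))
  names(states) <- dag$nodes
  cpts <- lapply(dag$nodes, function(v) {
    pa <- parents(dag, v)
    q <- cardinality^length(pa)
    raw <- matrix(stats::rgamma(cardinality * q, shape = alpha),
                  nrow = cardinality)
    theta <- sweep(raw, 2L, colSums(raw), `/`)
    dn <- c(list(states[[v]]), states[pa])
    names(dn) <- c(v, pa)
    array(theta, dim = c(cardinality, rep(cardinality, length(pa))),
          dimnames = dn)
  })
  names(cpts) <- dag$nodes
  structure(list(dag = dag, states = states, cpts = cpts),
            class = "discrete_bn")
}

#' Generate a two-layer ground-truth network
#'
#' Layer 1 is a uniform random DAG over `n_groups` latent group variables
#' with symmetric Dirichlet(1) conditional probability tables. Each group
#' emits `group_size` observed children: a discrete child copies its
#' parent's state with probability `1 - noise` and otherwise takes a
#' uniformly random other state; a continuous child has state-specific means
#' at 0, 1, ..., `cardinality - 1` with Gaussian noise whose standard
#' deviation sets the adjacent-state Bayes error to `noise`
#' (`sigma = -1 / (2 qnorm(noise))`).
#'
#' @param n_groups number of latent groups (>= 2).
#' @param group_size children per group.
#' @param noise emission noise level in `[0, 1)`.
#' @param frac_discrete_children probability that a child is discrete.
#' @param cardinality states per group variable.
#' @param seed optional integer seed.
#' @return A `two_layer_network`: `layer1` (a `discrete_bn`), `children`
#'   (data.frame: child, group, kind, noise), `true_grouping` (named list of
#'   child names per group), `sigma`, `cardinality`.
#' @export
generate_two_layer <- function(n_groups, group_size, noise,
                               frac_discrete_children = 0.5,
                               cardinality = 3L, seed = NULL) {
  stopifnot(n_groups >= 2L, group_size >= 1L, noise >= 0, noise < 1)
  if (!is.null(seed)) set.seed(seed)
  dag <- sample_uniform_dag(n_groups)
  layer1 <- random_dirichlet_cpts(dag, cardinality)
  child <- expand.grid(j = seq_len(group_size), group = dag$nodes,
                       stringsAsFactors = FALSE)
  child$child <- paste0(child$group, "_c", child$j)
  child$kind <- ifelse(stats::runif(nrow(child)) < frac_discrete_children,
                       "discrete", "continuous")
  sigma <- if (noise == 0) 0 else -1 / (2 * stats::qnorm(noise))
  true_grouping <- split(child$child, child$group)
  structure(list(layer1 = layer1,
                 children = child[, c("child", "group", "kind")],
                 noise = noise, sigma = sigma, cardinality = cardinality,
                 true_grouping = true_grouping[dag$nodes]),
            class = "two_layer_network")
}

#' @export
print.two_layer_network <- function(x, ...) {
  cat("two_layer_network:", length(x$layer1$dag$nodes), "groups x",
      nrow(x$children) / length(x$layer1$dag$nodes),
      "children, noise", x$noise, "\n")
  invisible(x)
}

# ancestral sampling of a discrete_bn; returns data.frame of factors
sample_bn <- function(bn, n) {
  ord <- topological_order(bn$dag)
  out <- vector("list", length(ord))
  names(out) <- ord
  for (v in ord) {
    pa <- parents(bn$dag, v)
    states <- bn$states[[v]]
    cpt <- bn$cpts[[v]]
    if (length(pa) == 0L) {
      out[[v]] <- sample(states, n, replace = TRUE, prob = as.numeric(cpt))
    } else {
      conf <- rep(1L, n)
      mult <- 1L
      for (u in pa) {
        conf <- conf + (match(out[[u]], bn$states[[u]]) - 1L) * mult
        mult <- mult * length(bn$states[[u]])
      }
      theta <- matrix(cpt, nrow = length(states))
      u01 <- stats::runif(n)
      cum <- apply(theta, 2L, cumsum)
      pick <- integer(n)
      for (cf in unique(conf)) {
        rows <- which(conf == cf)
        pick[rows] <- findInterval(u01[rows], c(0, cum[, cf]),
                                   rightmost.closed = TRUE)
      }
      pick[pick < 1L] <- 1L
      pick[pick > length(states)] <- length(states)
      out[[v]] <- states[pick]
    }
  }
  as.data.frame(lapply(out[bn$dag$nodes], function(s)
    factor(s, levels = bn$states[[1]])), check.names = FALSE)
}

#' Forward-sample a two-layer network
#'
#' Samples layer 1 ancestrally, then each child given its parent group's
#' state according to its emission kind.
#'
#' @param net a `two_layer_network`.
#' @param n number of rows.
#' @param seed optional integer seed.
#' @return list with `layer0` (a [mixed_dataset()]: discrete children
#'   qualitative, continuous children quantitative) and `layer1`
#'   (data.frame of group states).
#' @export
forward_sample <- function(net, n, seed = NULL) {
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  l1 <- sample_bn(net$layer1, n)
  r <- net$cardinality
  states <- paste0("s", seq_len(r))
  cols <- vector("list", nrow(net$children))
  names(cols) <- net$children$child
  for (i in seq_len(nrow(net$children))) {
    g <- net$children$group[i]
    parent_idx <- match(as.character(l1[[g]]), states)
    if (net$children$kind[i] == "discrete") {
      flip <- stats::runif(n) < net$noise
      val <- parent_idx
      if (any(flip)) {
        shift <- sample.int(r - 1L, sum(flip), replace = TRUE)
        val[flip] <- ((parent_idx[flip] - 1L + shift) %% r) + 1L
      }
      cols[[i]] <- states[val]
    } else {
      cols[[i]] <- (parent_idx - 1) + stats::rnorm(n, sd = net$sigma)
    }
  }
  kinds <- stats::setNames(ifelse(net$children$kind == "discrete",
                                  "qual", "quant"), net$children$child)
  list(layer0 = mixed_dataset(as.data.frame(cols, check.names = FALSE),
                              kinds = kinds),
       layer1 = l1)
}

#' Network-based baseline grouping and group DAG
#'
#' The baseline for group network inference from a detailed layer-0
#' structure: greedy-modularity hierarchical community detection on the
#' moralized skeleton yields a dendrogram which is cut at every level; the
#' cut closest to the true grouping under the partition metric is selected
#' (a deliberately charitable choice). Group arcs are obtained by projecting
#' the detailed arcs through the TRUE grouping: an arc A -> B is added
#' whenever at least one detailed arc runs from a member of A to a member of
#' B; opposite directions keep the better-supported one, exact ties collapse
#' to the lexicographically smaller direction.
#'
#' @param detailed a `bn_dag` over the layer-0 variables.
#' @param true_grouping named list of member names per true group.
#' @return list with `grouping` (named list), `dag` (a `bn_dag` over the
#'   true group names) and `partition_distance`.
#' @export
network_baseline_grouping <- function(detailed, true_grouping) {
  Mo <- moralize(detailed)
  g <- igraph::graph_from_adjacency_matrix(Mo * 1, mode = "undirected")
  vars <- detailed$nodes
  best <- list(dist = Inf, grouping = NULL)
  if (igraph::ecount(g) > 0) {
    comm <- igraph::cluster_fast_greedy(g)
    for (k in seq_len(length(vars))) {
      memb <- try(suppressWarnings(igraph::cut_at(comm, no = k)),
                  silent = TRUE)
      if (inherits(memb, "try-error")) next
      grp <- split(vars, memb)
      dist <- partition_metric(grp, true_grouping)
      if (dist < best$dist) best <- list(dist = dist, grouping = grp)
    }
  }
  if (is.null(best$grouping)) {
    best <- list(dist = partition_metric(as.list(stats::setNames(vars, vars)),
                                         true_grouping),
                 grouping = split(vars, vars))
  }
  # arc projection through the true grouping
  gnames <- names(true_grouping)
  memb_true <- stats::setNames(rep(gnames, lengths(true_grouping)),
                               unlist(true_grouping))
  p <- length(gnames)
  counts <- matrix(0L, p, p, dimnames = list(gnames, gnames))
  arcs <- dag_arcs(detailed)
  if (nrow(arcs)) {
    fa <- memb_true[arcs[, 1]]
    ta <- memb_true[arcs[, 2]]
    cross <- fa != ta
    for (idx in which(cross)) counts[fa[idx], ta[idx]] <-
        counts[fa[idx], ta[idx]] + 1L
  }
  A <- matrix(FALSE, p, p, dimnames = list(gnames, gnames))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i >= j) next
    if (counts[i, j] == 0L && counts[j, i] == 0L) next
    if (counts[i, j] > counts[j, i]) A[i, j] <- TRUE
    else if (counts[j, i] > counts[i, j]) A[j, i] <- TRUE
    else A[min(i, j), max(i, j)] <- TRUE  # tie: lexicographically smaller
  }
  A <- break_cycles(A, (counts + t(counts)) / max(1, sum(counts)))
  list(grouping = best$grouping,
       dag = structure(list(nodes = gnames, A = A), class = "bn_dag"),
       partition_distance = best$dist)
}
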