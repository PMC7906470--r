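# Discrete Bayesian network machinery: BIC scoring, hill-climbing structure
# search with restarts/perturbations, bootstrap model averaging with adaptive
# thresholding, Bayesian parameter estimation, CPDAG / moralization / Markov
# blanket graph operations, and likelihood-weighting prediction with an
# exact single-node oracle.

# ---- DAG container --------------------------------------------------------

#' Construct a directed acyclic graph
#'
#' @param nodes character vector of node names.
#' @param arcs two-column character matrix (from, to); may have zero rows.
#' @return A `bn_dag` with fields `nodes` and a logical adjacency matrix `A`
#'   (`A[i, j]` means an arc i -> j).
#' @export
empty_dag <- function(nodes, arcs = NULL) {
  p <- length(nodes)
  A <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  d <- structure(list(nodes = nodes, A = A), class = "bn_dag")
  if (!is.null(arcs) && nrow(arcs) > 0) {
    for (r in seq_len(nrow(arcs))) d <- add_arc(d, arcs[r, 1], arcs[r, 2])
  }
  d
}

#' Arcs of a DAG
#' @param dag a `bn_dag`.
#' @return two-column character matrix (from, to).
#' @export
dag_arcs <- function(dag) {
  idx <- which(dag$A, arr.ind = TRUE)
  cbind(from = dag$nodes[idx[, 1]], to = dag$nodes[idx[, 2]])
}

add_arc <- function(dag, from, to) {
  if (from == to) stop("self-loop ", from)
  dag$A[from, to] <- TRUE
  if (has_cycle(dag$A)) stop("arc ", from, " -> ", to, " creates a cycle")
  dag
}

# TRUE iff directed graph given by adjacency matrix has a cycle
has_cycle <- function(A) {
  p <- nrow(A)
  indeg <- colSums(A)
  queue <- which(indeg == 0L)
  seen <- 0L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    seen <- seen + 1L
    ch <- which(A[v, ])
    indeg[ch] <- indeg[ch] - 1L
    queue <- c(queue, ch[indeg[ch] == 0L])
  }
  seen < p
}

# reachability: R[i, j] TRUE iff a directed path i ->* j (j != i) exists
reach_matrix <- function(A) {
  p <- nrow(A)
  R <- A
  repeat {
    R2 <- R | (R %*% A > 0)
    if (all(R2 == R)) return(R)
    R <- R2
  }
}

# path from -> to avoiding the direct arc (used for reversal legality)
path_avoiding_arc <- function(A, from, to) {
  A[from, to] <- FALSE
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

topological_order <- function(dag) {
  A <- dag$A
  p <- nrow(A)
  indeg <- colSums(A)
  order <- integer(0)
  queue <- sort(which(indeg == 0L))
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    ch <- which(A[v, ])
    indeg[ch] <- indeg[ch] - 1L
    queue <- sort(c(queue, ch[indeg[ch] == 0L]))
  }
  if (length(order) < p) stop("graph is cyclic")
  dag$nodes[order]
}

#' Parents / children of a node
#' @param dag a `bn_dag`.
#' @param v node name.
#' @return character vector of node names.
#' @export
parents <- function(dag, v) dag$nodes[dag$A[, v]]

#' @rdname parents
#' @export
children <- function(dag, v) dag$nodes[dag$A[v, ]]

#' Markov blanket of a node
#'
#' Parents, children and the children's other parents.
#'
#' @param dag a `bn_dag`.
#' @param v node name.
#' @return character vector.
#' @export
markov_blanket <- function(dag, v) {
  if (!v %in% dag$nodes) stop("unknown node '", v, "'")
  ch <- children(dag, v)
  spouses <- unlist(lapply(ch, function(c) parents(dag, c)))
  setdiff(unique(c(parents(dag, v), ch, spouses)), v)
}

#' Moral graph of a DAG
#'
#' The skeleton plus "marriage" edges between co-parents; every node is
#' adjacent to exactly its Markov blanket.
#'
#' @param dag a `bn_dag`.
#' @return symmetric logical adjacency matrix.
#' @export
moralize <- function(dag) {
  A <- dag$A
  M <- A | t(A)
  for (v in seq_len(nrow(A))) {
    pa <- which(A[, v])
    if (length(pa) >= 2L) {
      for (i in seq_len(length(pa) - 1L)) for (j in seq((i + 1L), length(pa))) {
        M[pa[i], pa[j]] <- M[pa[j], pa[i]] <- TRUE
      }
    }
  }
  diag(M) <- FALSE
  M
}

# ---- discrete data --------------------------------------------------------

# data.frame of factors/characters -> list(X integer matrix, r cardinalities,
# levels per column)
as_int_data <- function(df) {
  if (nrow(df) == 0L) stop("empty data")
  lev <- lapply(df, function(col) {
    if (is.factor(col)) levels(col) else sort(unique(as.character(col)))
  })
  X <- vapply(names(df), function(v)
    as.integer(factor(as.character(df[[v]]), levels = lev[[v]])),
    integer(nrow(df)))
  if (!is.matrix(X)) X <- matrix(X, nrow = nrow(df),
                                 dimnames = list(NULL, names(df)))
  list(X = X, r = vapply(lev, length, integer(1)), levels = lev)
}

# 1-based linear parent-configuration index
parent_config <- function(X, r, parents_idx) {
  n <- nrow(X)
  if (length(parents_idx) == 0L) return(list(conf = rep(1L, n), q = 1L))
  conf <- rep(1L, n)
  mult <- 1L
  for (pi in parents_idx) {
    conf <- conf + (X[, pi] - 1L) * mult
    mult <- mult * r[pi]
  }
  list(conf = conf, q = as.integer(mult))
}

#' Local BIC score of a node given a parent set
#'
#' `sum_jk N_ijk log(N_ijk / N_ij.) - q (r - 1)/2 log N` with
#' `0 log 0 = 0`; higher is better, and the score of a network decomposes
#' as the sum of its local scores.
#'
#' @param node node name.
#' @param parents character vector of parent names (may be empty).
#' @param data data.frame of discrete (factor/character) variables.
#' @return numeric score.
#' @export
bic_local <- function(node, parents, data) {
  d <- as_int_data(data)
  bic_local_idx(d$X, d$r, match(node, colnames(d$X)),
                match(parents, colnames(d$X)))
}

bic_local_idx <- function(X, r, i, parents_idx) {
  n <- nrow(X)
  ri <- unname(r[i])
  pc <- parent_config(X, r, parents_idx)
  idx <- X[, i] + ri * (pc$conf - 1L)
  N <- tabulate(idx, nbins = ri * pc$q)
  Nm <- matrix(N, nrow = ri)
  Nj <- colSums(Nm)
  pos <- N > 0L
  ll <- sum(N[pos] * log(N[pos])) - sum(Nj[Nj > 0] * log(Nj[Nj > 0]))
  ll - pc$q * (ri - 1) / 2 * log(n)
}

#' Total BIC of a DAG
#' @param dag a `bn_dag`.
#' @param data discrete data.frame over the DAG's nodes.
#' @return numeric; the sum of the local scores.
#' @export
bic_score <- function(dag, data) {
  d <- as_int_data(data[, dag$nodes, drop = FALSE])
  sum(vapply(seq_along(dag$nodes), function(i)
    bic_local_idx(d$X, d$r, i, which(dag$A[, i])), numeric(1)))
}

# ---- hill climbing --------------------------------------------------------

# memoised local score: cache environment keyed by node and sorted parents
make_scorer <- function(X, r) {
  cache <- new.env(hash = TRUE, parent = emptyenv())
  function(i, parents_idx) {
    key <- paste0(i, "|", paste(sort(parents_idx), collapse = ","))
    val <- cache[[key]]
    if (!is.null(val)) return(val)
    val <- bic_local_idx(X, r, i, parents_idx)
    cache[[key]] <- val
    val
  }
}

# one greedy climb from A; returns list(A, score). Strict improvement only.
climb_once <- function(A, sc, p) {
  local_scores <- vapply(seq_len(p), function(i) sc(i, which(A[, i])),
                         numeric(1))
  # delta caches; NA = stale
  d_add <- matrix(NA_real_, p, p)
  d_del <- matrix(NA_real_, p, p)
  refresh <- function(cols) {
    for (j in cols) {
      paj <- which(A[, j])
      for (i in seq_len(p)) {
        if (i == j) next
        if (A[i, j]) {
          d_del[i, j] <<- sc(j, setdiff(paj, i)) - local_scores[j]
          d_add[i, j] <<- NA_real_
        } else {
          d_add[i, j] <<- sc(j, c(paj, i)) - local_scores[j]
          d_del[i, j] <<- NA_real_
        }
      }
    }
  }
  refresh(seq_len(p))
  eps <- 1e-8
  repeat {
    R <- reach_matrix(A)
    best_delta <- eps
    best <- NULL
    for (j in seq_len(p)) for (i in seq_len(p)) {
      if (i == j) next
      if (A[i, j]) {
        dd <- d_del[i, j]
        if (dd > best_delta) { best_delta <- dd; best <- c(1L, i, j) }
        # reversal i->j  =>  j->i: delete at j plus add at i
        if (!path_avoiding_arc(A, i, j)) {
          dr <- d_del[i, j] + sc(i, c(which(A[, i]), j)) - local_scores[i]
          if (dr > best_delta) { best_delta <- dr; best <- c(3L, i, j) }
        }
      } else if (!A[j, i] && !R[j, i]) {
        da <- d_add[i, j]
        if (da > best_delta) { best_delta <- da; best <- c(2L, i, j) }
      }
    }
    if (is.null(best)) break
    i <- best[2L]; j <- best[3L]
    if (best[1L] == 1L) {            # delete i -> j
      A[i, j] <- FALSE
      local_scores[j] <- sc(j, which(A[, j]))
      refresh(j)
    } else if (best[1L] == 2L) {     # add i -> j
      A[i, j] <- TRUE
      local_scores[j] <- sc(j, which(A[, j]))
      refresh(j)
    } else {                         # reverse i -> j
      A[i, j] <- FALSE
      A[j, i] <- TRUE
      local_scores[j] <- sc(j, which(A[, j]))
      local_scores[i] <- sc(i, which(A[, i]))
      refresh(c(i, j))
    }
  }
  list(A = A, score = sum(local_scores))
}

# apply k random legal single-arc perturbations to A
perturb_dag <- function(A, k) {
  p <- nrow(A)
  for (s in seq_len(k)) {
    R <- reach_matrix(A)
    cand <- list()
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (i == j) next
      if (A[i, j]) {
        cand[[length(cand) + 1L]] <- c(1L, i, j)
        if (!path_avoiding_arc(A, i, j)) cand[[length(cand) + 1L]] <- c(3L, i, j)
      } else if (!A[j, i] && !R[j, i]) {
        cand[[length(cand) + 1L]] <- c(2L, i, j)
      }
    }
    if (!length(cand)) break
    mv <- cand[[sample.int(length(cand), 1L)]]
    if (mv[1L] == 1L) A[mv[2L], mv[3L]] <- FALSE
    else if (mv[1L] == 2L) A[mv[2L], mv[3L]] <- TRUE
    else { A[mv[2L], mv[3L]] <- FALSE; A[mv[3L], mv[2L]] <- TRUE }
  }
  A
}

#' BIC hill-climbing structure search
#'
#' Greedy search over single-arc additions, deletions and reversals
#' maximizing the total BIC, accepting strictly improving moves only. At a
#' local optimum the best DAG so far is perturbed by random legal arc moves
#' (10% of the current arc count, at least 1) and the climb restarts; the
#' best-scoring DAG over all restarts is returned.
#'
#' @param data data.frame of discrete variables.
#' @param init optional `bn_dag` to start from (default: empty graph).
#' @param restarts number of random restarts.
#' @param perturbations perturbations per restart; default
#'   `max(1, round(0.1 * arcs))`.
#' @param seed optional integer seed.
#' @return A `bn_dag` with attribute `"score"`.
#' @export
hill_climb <- function(data, init = NULL, restarts = 10L,
                       perturbations = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- as_int_data(data)
  nodes <- colnames(d$X)
  p <- length(nodes)
  sc <- make_scorer(d$X, d$r)
  A0 <- if (is.null(init)) matrix(FALSE, p, p) else init$A[nodes, nodes]
  res <- climb_once(A0, sc, p)
  best <- res
  for (rst in seq_len(restarts)) {
    k <- if (is.null(perturbations)) max(1L, round(0.1 * sum(best$A))) else perturbations
    A1 <- perturb_dag(best$A, k)
    res <- climb_once(A1, sc, p)
    if (res$score > best$score + 1e-9) best <- res
  }
  dimnames(best$A) <- list(nodes, nodes)
  structure(list(nodes = nodes, A = best$A), class = "bn_dag",
            score = best$score)
}

# ---- bootstrap model averaging --------------------------------------------

#' Adaptive strength threshold
#'
#' Chooses the threshold `t` (among the observed strengths and 0) that
#' minimizes the L1 distance between the empirical arc-strength vector and
#' its thresholded 0/1 idealization, smallest `t` on ties.
#'
#' @param strengths numeric vector of arc inclusion frequencies in `[0, 1]`.
#' @return numeric threshold.
#' @export
adaptive_threshold <- function(strengths) {
  s <- strengths[strengths > 0]
  if (length(s) == 0L) return(0)
  cand <- sort(unique(c(0, s)))
  l1 <- vapply(cand, function(t) sum(abs(s - as.numeric(s > t))), numeric(1))
  cand[which.min(l1)]  # which.min: first (= smallest t) on ties
}

#' Bootstrap model averaging of hill-climbed structures
#'
#' Learns a structure on each of `B` nonparametric bootstrap resamples of
#' the rows, records arc inclusion frequencies (strength: either direction;
#' direction: conditional orientation frequency), thresholds the strengths
#' adaptively, orients retained arcs by majority direction and breaks any
#' directed cycle by dropping its weakest arc.
#'
#' @param data discrete data.frame.
#' @param B number of bootstrap replicates.
#' @param init optional `bn_dag` passed to each [hill_climb()] call.
#' @param restarts restarts per hill climb.
#' @param seed optional integer seed.
#' @return list with `strength` (symmetric matrix of pair strengths),
#'   `direction` (matrix of orientation frequencies given presence),
#'   `threshold`, and `dag` (the averaged `bn_dag`).
#' @export
bootstrap_average <- function(data, B = 200L, init = NULL, restarts = 10L,
                              seed = NULL) {
  stopifnot(B >= 1L)
  if (!is.null(seed)) set.seed(seed)
  nodes <- names(data)
  p <- length(nodes)
  counts <- matrix(0, p, p, dimnames = list(nodes, nodes))
  n <- nrow(data)
  for (b in seq_len(B)) {
    rows <- sample.int(n, n, replace = TRUE)
    g <- hill_climb(data[rows, , drop = FALSE], init = init,
                    restarts = restarts)
    counts <- counts + g$A
  }
  strength <- (counts + t(counts)) / B
  present <- counts + t(counts)
  direction <- matrix(0.5, p, p, dimnames = list(nodes, nodes))
  nz <- present > 0
  direction[nz] <- counts[nz] / present[nz]
  thr <- adaptive_threshold(strength[upper.tri(strength)])
  A <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  for (i in seq_len(p - 1L)) for (j in seq((i + 1L), p)) {
    if (strength[i, j] > thr) {
      if (direction[i, j] > 0.5) A[i, j] <- TRUE
      else if (direction[j, i] > 0.5) A[j, i] <- TRUE
      else A[i, j] <- TRUE  # exact tie: lexicographically smaller direction
    }
  }
  A <- break_cycles(A, strength)
  list(strength = strength, direction = direction, threshold = thr,
       dag = structure(list(nodes = nodes, A = A), class = "bn_dag"))
}

# remove the weakest arc on each directed cycle until acyclic
break_cycles <- function(A, strength) {
  while (has_cycle(A)) {
    cyc <- find_cycle(A)
    arcs <- cbind(cyc, c(cyc[-1L], cyc[1L]))
    w <- strength[arcs]
    drop <- which.min(w)
    A[arcs[drop, 1L], arcs[drop, 2L]] <- FALSE
  }
  A
}

# return node indices of one directed cycle
find_cycle <- function(A) {
  p <- nrow(A)
  color <- integer(p)  # 0 white, 1 grey, 2 black
  stack <- integer(0)
  found <- NULL
  visit <- function(v) {
    color[v] <<- 1L
    stack <<- c(stack, v)
    for (w in which(A[v, ])) {
      if (!is.null(found)) return()
      if (color[w] == 1L) {
        found <<- stack[which(stack == w):length(stack)]
        return()
      }
      if (color[w] == 0L) visit(w)
    }
    color[v] <<- 2L
    stack <<- stack[-length(stack)]
  }
  for (v in seq_len(p)) {
    if (color[v] == 0L && is.null(found)) visit(v)
  }
  found
}

# ---- parameter learning ---------------------------------------------------

#' Bayesian parameter estimation with a uniform prior
#'
#' `theta(X = k | j) = (N_jk + iss/(r q)) / (N_j. + iss/q)` with imaginary
#' sample size `iss` (default 1); unseen parent configurations receive the
#' uniform distribution.
#'
#' @param dag a `bn_dag`.
#' @param data discrete data.frame over the DAG's nodes.
#' @param iss imaginary sample size.
#' @return A `discrete_bn`: `dag`, `states` (named list) and `cpts` (named
#'   list of arrays, first dimension the node's states, remaining dimensions
#'   its parents' states).
#' @export
fit_parameters <- function(dag, data, iss = 1) {
  d <- as_int_data(data[, dag$nodes, drop = FALSE])
  cpts <- vector("list", length(dag$nodes))
  names(cpts) <- dag$nodes
  for (i in seq_along(dag$nodes)) {
    v <- dag$nodes[i]
    pa_idx <- which(dag$A[, i])
    ri <- unname(d$r[i])
    pc <- parent_config(d$X, d$r, pa_idx)
    idx <- d$X[, i] + ri * (pc$conf - 1L)
    N <- matrix(tabulate(idx, nbins = ri * pc$q), nrow = ri)
    theta <- sweep(N + iss / (ri * pc$q), 2L,
                   colSums(N) + iss / pc$q, `/`)
    dims <- c(ri, unname(d$r[pa_idx]))
    dn <- c(list(d$levels[[i]]), d$levels[pa_idx])
    names(dn) <- c(v, dag$nodes[pa_idx])
    cpts[[v]] <- array(theta, dim = dims, dimnames = dn)
  }
  structure(list(dag = dag, states = d$levels, cpts = cpts),
            class = "discrete_bn")
}

#' @export
print.discrete_bn <- function(x, ...) {
  cat("discrete_bn:", length(x$dag$nodes), "nodes,", sum(x$dag$A), "arcs\n")
  invisible(x)
}

# P(x_v = value | parent values), vectorized over a list of candidate values
cpt_lookup <- function(bn, v, value, pa_values) {
  cpt <- bn$cpts[[v]]
  pa <- parents(bn$dag, v)
  idx <- c(list(match(value, bn$states[[v]])),
           lapply(pa, function(u) match(pa_values[[u]], bn$states[[u]])))
  do.call(`[`, c(list(cpt), idx))
}

# ---- CPDAG ----------------------------------------------------------------

#' Completed partially directed acyclic graph of a DAG
#'
#' V-structure arcs are directed, the orientation closure rules are applied,
#' and every remaining edge is undirected; the result represents the DAG's
#' Markov equivalence class.
#'
#' @param dag a `bn_dag`.
#' @return A `bn_cpdag`: `nodes`, `directed` (logical matrix) and
#'   `undirected` (symmetric logical matrix).
#' @export
cpdag <- function(dag) {
  A <- dag$A
  p <- nrow(A)
  skel <- A | t(A)
  Dm <- matrix(FALSE, p, p, dimnames = dimnames(A))
  # v-structures: i -> k <- j with i, j nonadjacent
  for (k in seq_len(p)) {
    pa <- which(A[, k])
    if (length(pa) >= 2L) {
      for (a in seq_len(length(pa) - 1L)) for (b in seq((a + 1L), length(pa))) {
        i <- pa[a]; j <- pa[b]
        if (!skel[i, j]) { Dm[i, k] <- TRUE; Dm[j, k] <- TRUE }
      }
    }
  }
  Um <- skel & !(Dm | t(Dm))
  closed <- meek_closure(Dm, Um)
  structure(list(nodes = dag$nodes, directed = closed$D,
                 undirected = closed$U), class = "bn_cpdag")
}

# Meek orientation rules R1-R3 applied to fixpoint
meek_closure <- function(Dm, Um) {
  p <- nrow(Dm)
  adj <- function(i, j) Um[i, j] || Dm[i, j] || Dm[j, i]
  repeat {
    changed <- FALSE
    for (a in seq_len(p)) for (b in seq_len(p)) {
      if (!Um[a, b]) next
      orient <- FALSE
      # R1: c -> a, a - b, c and b nonadjacent
      for (c in which(Dm[, a])) if (!adj(c, b)) { orient <- TRUE; break }
      # R2: a -> c -> b and a - b
      if (!orient) {
        for (c in which(Dm[a, ])) if (Dm[c, b]) { orient <- TRUE; break }
      }
      # R3: a - c1 -> b, a - c2 -> b, c1, c2 nonadjacent
      if (!orient) {
        cs <- which(Um[a, ] & Dm[, b])
        if (length(cs) >= 2L) {
          for (x in seq_len(length(cs) - 1L)) for (y in seq((x + 1L), length(cs))) {
            if (!adj(cs[x], cs[y])) { orient <- TRUE }
          }
        }
      }
      if (orient) {
        Dm[a, b] <- TRUE
        Um[a, b] <- Um[b, a] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(D = Dm, U = Um)
}

#' @export
print.bn_cpdag <- function(x, ...) {
  cat("bn_cpdag:", length(x$nodes), "nodes,", sum(x$directed),
      "directed arcs,", sum(x$undirected) / 2, "undirected edges\n")
  invisible(x)
}

#' Number of edges of a CPDAG
#' @param cp a `bn_cpdag`.
#' @return integer (each undirected edge counted once).
#' @export
cpdag_n_edges <- function(cp) sum(cp$directed) + sum(cp$undirected) / 2

# ---- inference ------------------------------------------------------------

# log-probability contributions of all evidence nodes except the target and
# its children (constant in the target; zero-probability detection)
evidence_const_logp <- function(bn, target, row) {
  other <- setdiff(bn$dag$nodes, c(target, children(bn$dag, target)))
  lp <- 0
  for (v in other) {
    pav <- parents(bn$dag, v)
    pr <- cpt_lookup(bn, v, row[[v]], row[pav])
    if (is.na(pr) || pr == 0) return(-Inf)
    lp <- lp + log(pr)
  }
  lp
}

# unnormalized posterior weights over target states given full evidence:
# P(t | pa(t)) * prod over children c of P(x_c | pa(c) with t)
target_state_weights <- function(bn, target, row) {
  states <- bn$states[[target]]
  pa_t <- parents(bn$dag, target)
  prior <- vapply(states, function(s)
    cpt_lookup(bn, target, s, row[pa_t]), numeric(1))
  lik <- rep(1, length(states))
  for (ch in children(bn$dag, target)) {
    pa_c <- parents(bn$dag, ch)
    for (k in seq_along(states)) {
      pav <- row[pa_c]
      pav[[target]] <- states[k]
      lik[k] <- lik[k] * cpt_lookup(bn, ch, row[[ch]], pav)
    }
  }
  list(prior = prior, weights = prior * lik)
}

#' Exact posterior of a single unobserved node
#'
#' With every node but the target observed, the posterior factorizes as
#' `P(t | rest) proportional to P(t | parents(t)) * prod_c P(x_c | parents(c))`
#' over the target's children `c`.
#'
#' @param bn a `discrete_bn`.
#' @param target node name.
#' @param row named list/one-row data.frame giving every other node's value.
#' @return named numeric vector of class probabilities.
#' @export
posterior_exact <- function(bn, target, row) {
  row <- as.list(row)
  states <- bn$states[[target]]
  if (!is.finite(evidence_const_logp(bn, target, row))) {
    warning("zero-probability evidence; returning uniform posterior")
    return(stats::setNames(rep(1 / length(states), length(states)), states))
  }
  tw <- target_state_weights(bn, target, row)
  s <- sum(tw$weights)
  if (s == 0) {
    warning("zero-probability evidence; returning uniform posterior")
    return(stats::setNames(rep(1 / length(states), length(states)), states))
  }
  stats::setNames(tw$weights / s, states)
}

#' Likelihood-weighting prediction of a target node
#'
#' All non-target nodes are fixed as evidence; per run, `n_particles`
#' weighted samples of the target are drawn from its conditional prior and
#' reweighted by the likelihood of the evidence, yielding a normalized
#' posterior estimate per row and run.
#'
#' @param bn a `discrete_bn`.
#' @param target node name (must not be a column of `rows`, or is ignored).
#' @param rows data.frame of evidence over all non-target nodes.
#' @param n_particles particles per run.
#' @param runs number of independent runs.
#' @param seed optional integer seed.
#' @return numeric array `[rows, target states, runs]`.
#' @export
predict_lw <- function(bn, target, rows, n_particles = 5000L, runs = 1L,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  states <- bn$states[[target]]
  need <- setdiff(bn$dag$nodes, target)
  miss <- setdiff(need, names(rows))
  if (length(miss)) stop("missing evidence column(s): ",
                         paste(miss, collapse = ", "))
  n <- nrow(rows)
  out <- array(NA_real_, dim = c(n, length(states), runs),
               dimnames = list(NULL, states, NULL))
  warned <- FALSE
  for (rr in seq_len(n)) {
    row <- lapply(rows[rr, need, drop = FALSE], as.character)
    bad <- !is.finite(evidence_const_logp(bn, target, row))
    tw <- target_state_weights(bn, target, row)
    if (bad || sum(tw$weights) == 0) {
      if (!warned) {
        warning("zero-probability evidence; returning uniform posterior")
        warned <- TRUE
      }
      out[rr, , ] <- 1 / length(states)
      next
    }
    prior <- tw$prior / sum(tw$prior)
    w_state <- tw$weights / tw$prior  # evidence likelihood per target state
    w_state[tw$prior == 0] <- 0
    for (run in seq_len(runs)) {
      counts <- as.numeric(stats::rmultinom(1L, n_particles, prior))
      wsum <- counts * w_state
      if (sum(wsum) == 0) out[rr, , run] <- 1 / length(states)
      else out[rr, , run] <- wsum / sum(wsum)
    }
  }
  out
}

# ---- export ---------------------------------------------------------------

dag_to_igraph <- function(dag) {
  igraph::graph_from_adjacency_matrix(dag$A * 1, mode = "directed")
}

#' Export a DAG to DOT or GraphML
#'
#' @param dag a `bn_dag`.
#' @param path output file.
#' @param format `"dot"` or `"graphml"`.
#' @param strength optional symmetric strength matrix stored as the edge
#'   attribute `strength`.
#' @export
export_dag <- function(dag, path, format = c("dot", "graphml"),
                       strength = NULL) {
  format <- match.arg(format)
  g <- dag_to_igraph(dag)
  if (!is.null(strength)) {
    el <- igraph::as_edgelist(g)
    igraph::E(g)$strength <- strength[el]
  }
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
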