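# Adaptive, target-specific refinement of a group Bayesian network by hill
# climbing over dendrogram splits, scored by class-weighted cross-entropy
# with a Monte-Carlo uncertainty band.

#' Class-weighted cross-entropy (log-loss)
#'
#' `H = -sum_i w_i log(p_i)` where `p_i` is the predicted probability of row
#' i's observed class and `w_i = 1 / (2 #\{j : o_j = o_i\})`, so each
#' outcome class contributes total weight 1/2 regardless of imbalance.
#' Lower is better; `H = 0` iff every `p_i = 1`. With
#' `literal_weights = TRUE` the raw class-proportion weights
#' `w_i = #\{o = o_i\} / N` are used instead (comparison only; they
#' overweight the majority class).
#'
#' @param o binary observed labels (two distinct values required).
#' @param p predicted probability of each row's observed class, clipped to
#'   `[1e-12, 1]`.
#' @param literal_weights see above.
#' @return nonnegative number.
#' @export
weighted_cross_entropy <- function(o, p, literal_weights = FALSE) {
  stopifnot(length(o) == length(p), length(o) >= 1L)
  o <- as.character(o)
  counts <- table(o)
  if (length(counts) < 2L) stop("degenerate target: single observed class")
  p <- pmin(pmax(p, 1e-12), 1)
  w <- if (literal_weights) as.numeric(counts[o]) / length(o)
       else 1 / (2 * as.numeric(counts[o]))
  -sum(w * log(p))
}

# probability assigned to each row's observed class
prob_of_observed <- function(prob_matrix, observed) {
  states <- colnames(prob_matrix)
  idx <- match(as.character(observed), states)
  prob_matrix[cbind(seq_along(idx), idx)]
}

#' Score a group BN model by weighted cross-entropy with uncertainty band
#'
#' Runs `runs` independent likelihood-weighting predictions of the target
#' on `D`, computes the class-weighted cross-entropy per run, and returns
#' the mean together with the (min, max) band that the refinement uses as
#' acceptance threshold.
#'
#' @param M a `group_bn_model`.
#' @param D a `mixed_dataset` containing the observed target.
#' @param runs number of Monte-Carlo runs.
#' @param n_particles particles per run.
#' @param seed optional integer seed.
#' @return list with `mean`, `band = c(low, high)` and `per_run`.
#' @export
score_model <- function(M, D, runs = NULL, n_particles = NULL, seed = NULL) {
  nr <- if (is.null(runs)) M$cfg$runs else runs
  np <- if (is.null(n_particles)) M$cfg$n_particles else n_particles
  obs <- as.character(D$df[[M$target]])
  if (!is.null(M$sep_maps[[M$target]]))
    obs <- apply_discretization(D$df[[M$target]], M$sep_maps[[M$target]])
  arr <- predict_lw(M$bn, M$target, encode_evidence(M, D),
                    n_particles = np, runs = nr, seed = seed)
  per_run <- vapply(seq_len(nr), function(k) {
    pm <- arr[, , k, drop = FALSE]
    dim(pm) <- dim(arr)[1:2]
    colnames(pm) <- dimnames(arr)[[2]]
    weighted_cross_entropy(obs, prob_of_observed(pm, obs),
                           literal_weights = M$cfg$literal_weights)
  }, numeric(1))
  list(mean = mean(per_run), band = c(min(per_run), max(per_run)),
       per_run = per_run)
}

# splittable groups among the refinement candidates: Markov blanket of the
# target, optionally widened to a moralized-graph distance
refinement_candidates <- function(M, max_distance = NULL) {
  dag <- M$bn$dag
  if (is.null(max_distance)) {
    cand <- markov_blanket(dag, M$target)
  } else {
    Mo <- moralize(dag)
    g <- igraph::graph_from_adjacency_matrix(Mo * 1, mode = "undirected")
    dist <- igraph::distances(g, v = match(M$target, dag$nodes))
    cand <- dag$nodes[dist[1, ] <= max_distance & dag$nodes != M$target]
  }
  cand <- intersect(cand, names(M$grouping$groups))
  sort(cand[vapply(cand, function(b) M$grouping$nodes[[b]] > 0L, logical(1))])
}

#' Adaptive refinement of a group Bayesian network
#'
#' Builds an initial model on the `k`-group cut of the dendrogram, then
#' repeatedly evaluates, for every splittable group in the target's Markov
#' blanket (or within `cfg$max_distance` in the moralized graph), the model
#' obtained by splitting that group along the dendrogram. Each candidate's
#' structure search is initialized with the incumbent structure, the two new
#' groups inheriting the split group's arcs. The best candidate is accepted
#' only when its loss falls below the lower end of the incumbent's
#' Monte-Carlo uncertainty band; the loop stops otherwise.
#'
#' @param D a [mixed_dataset()].
#' @param H a `var_dendrogram` over the non-separated variables.
#' @param k initial number of groups (at least 2).
#' @param target name of the binary target (separated).
#' @param separated_extra further separated variables.
#' @param cfg a [groupbn_control()].
#' @param seed integer seed; per-candidate sub-seeds are derived
#'   deterministically.
#' @param verbose print one progress line per candidate evaluation.
#' @return The refined `group_bn_model`, with `$refinement` holding the
#'   initial loss/band and one record per accepted split (losses strictly
#'   decreasing).
#' @export
refine <- function(D, H, k, target, separated_extra = NULL,
                   cfg = groupbn_control(), seed = 1L, verbose = FALSE) {
  stopifnot(k >= 2L)
  g <- cut_dendrogram(H, k)
  M <- build_group_bn(D, g, target, separated_extra, cfg = cfg,
                      seed = subseed(seed, 0L))
  sc <- score_model(M, D, seed = subseed(seed, 1L))
  initial_loss <- sc$mean
  history <- list()
  iter <- 0L
  if (length(refinement_candidates(M, cfg$max_distance)) == 0L)
    message("no splittable candidate in the target's neighborhood; ",
            "returning the initial model")
  repeat {
    iter <- iter + 1L
    cand <- refinement_candidates(M, cfg$max_distance)
    if (length(cand) == 0L) break
    best <- NULL
    for (ci in seq_along(cand)) {
      b <- cand[ci]
      g_b <- split_group(H, M$grouping, b)
      init <- embed_split(M$bn$dag, b, setdiff(names(g_b$groups),
                                               names(M$grouping$groups)))
      M_b <- build_group_bn(D, g_b, target, separated_extra, cfg = cfg,
                            init = init, seed = subseed(seed, 100L * iter + ci))
      sc_b <- score_model(M_b, D, seed = subseed(seed, 100L * iter + ci + 50L))
      if (verbose)
        message(sprintf("iter %d candidate %s: loss %.4f band [%.4f, %.4f] %s",
                        iter, b, sc_b$mean, sc$band[1], sc$band[2],
                        if (sc_b$mean < sc$band[1]) "improves" else "rejected"))
      if (is.null(best) || sc_b$mean < best$sc$mean)
        best <- list(b = b, M = M_b, sc = sc_b)
    }
    if (!is.null(best) && best$sc$mean < sc$band[1]) {
      history[[length(history) + 1L]] <-
        list(split = best$b, loss = best$sc$mean, band = best$sc$band)
      M <- best$M
      sc <- best$sc
    } else break
  }
  M$refinement <- list(initial_loss = initial_loss, history = history,
                       final_loss = sc$mean, final_band = sc$band, k0 = k)
  M
}

# incumbent structure with group b replaced by the two split halves, both
# inheriting b's arcs (dropped if they would create a cycle, which cannot
# happen for a simple node split)
embed_split <- function(dag, b, new_ids) {
  keep <- setdiff(dag$nodes, b)
  nodes <- c(keep, new_ids)
  p <- length(nodes)
  A <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  A[keep, keep] <- dag$A[keep, keep]
  for (nid in new_ids) {
    A[nid, keep] <- dag$A[b, keep]
    A[keep, nid] <- dag$A[keep, b]
  }
  structure(list(nodes = nodes, A = A), class = "bn_dag")
}

# deterministic 32-bit sub-seed derivation
subseed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}
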