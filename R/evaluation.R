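# Evaluation metrics and experiment harnesses: entropy-based partition
# metric (variation of information), normalized structural Hamming distance
# on CPDAGs, AUROC/AUPRC, stratified cross-validation, and the simulation
# study driver.

as_partition <- function(g) {
  if (inherits(g, "var_grouping")) g <- g$groups
  lapply(g, as.character)
}

#' Entropy-based partition metric (variation of information)
#'
#' `VI(g1, g2) = H(g1 | g2) + H(g2 | g1)` in natural log units: zero iff
#' the groupings are identical, symmetric, and satisfying the triangle
#' inequality.
#'
#' @param g1,g2 groupings over the same variable universe (`var_grouping`
#'   objects or named lists of member vectors).
#' @return nonnegative number.
#' @export
partition_metric <- function(g1, g2) {
  g1 <- as_partition(g1); g2 <- as_partition(g2)
  u1 <- sort(unlist(g1, use.names = FALSE))
  u2 <- sort(unlist(g2, use.names = FALSE))
  if (!identical(u1, u2)) stop("groupings cover different variable sets")
  n <- length(u1)
  m1 <- rep(seq_along(g1), lengths(g1))[order(unlist(g1, use.names = FALSE))]
  m2 <- rep(seq_along(g2), lengths(g2))[order(unlist(g2, use.names = FALSE))]
  tab <- table(m1, m2) / n
  r <- rowSums(tab); c <- colSums(tab)
  h1 <- -sum(r[r > 0] * log(r[r > 0]))
  h2 <- -sum(c[c > 0] * log(c[c > 0]))
  pos <- tab > 0
  mi <- sum(tab[pos] * log(tab[pos] / (r[row(tab)[pos]] * c[col(tab)[pos]])))
  max(0, h1 + h2 - 2 * mi)
}

# edge state of a CPDAG for an ordered node index pair:
# 0 none, 1 i->j, 2 j->i, 3 undirected
cpdag_edge_state <- function(cp, i, j) {
  if (cp$directed[i, j]) 1L
  else if (cp$directed[j, i]) 2L
  else if (cp$undirected[i, j]) 3L
  else 0L
}

#' Structural Hamming distance between CPDAGs, normalized
#'
#' Counts the node pairs whose edge state (absent, directed either way,
#' undirected) differs — every insertion, deletion or orientation change
#' counts one — and divides by the number of edges of the ground-truth
#' CPDAG.
#'
#' @param learned,truth `bn_cpdag` objects over the same nodes.
#' @return nonnegative number.
#' @export
shd_normalized <- function(learned, truth) {
  stopifnot(setequal(learned$nodes, truth$nodes))
  ne <- cpdag_n_edges(truth)
  if (ne == 0) stop("ground-truth CPDAG has no edges; normalization undefined")
  shd_count(learned, truth) / ne
}

#' @rdname shd_normalized
#' @export
shd_count <- function(learned, truth) {
  nodes <- truth$nodes
  li <- match(nodes, learned$nodes)
  shd <- 0L
  p <- length(nodes)
  for (i in seq_len(p - 1L)) for (j in seq((i + 1L), p)) {
    s1 <- cpdag_edge_state(learned, li[i], li[j])
    s2 <- cpdag_edge_state(truth, i, j)
    if (s1 != s2) shd <- shd + 1L
  }
  shd
}

#' AUROC and AUPRC
#'
#' AUROC via the rank-sum statistic with tie correction (midranks); AUPRC
#' as the interpolated precision-recall integral over the positive class's
#' recall (trapezoid between successive distinct-score operating points,
#' starting from recall 0 at the precision of the highest-scoring point).
#'
#' @param labels binary labels; `positive` names the positive class.
#' @param scores predicted positive-class scores.
#' @param positive value of `labels` treated as positive (default: the
#'   larger of the two sorted distinct values).
#' @return named numeric vector `c(auroc = ..., auprc = ...)`.
#' @export
auc_metrics <- function(labels, scores, positive = NULL) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop("labels must contain exactly two classes")
  if (is.null(positive)) positive <- classes[2L]
  pos <- labels == positive
  npos <- sum(pos); nneg <- sum(!pos)
  r <- rank(scores)  # midranks handle ties
  auroc <- (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
  # precision-recall curve over decreasing score thresholds
  ord <- order(scores, decreasing = TRUE)
  lab <- pos[ord]
  sc <- scores[ord]
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)  # last index of each tie block
  tp <- tp[keep]; fp <- fp[keep]
  recall <- tp / npos
  precision <- tp / (tp + fp)
  rec <- c(0, recall)
  prec <- c(precision[1L], precision)
  auprc <- sum(diff(rec) * (prec[-1L] + prec[-length(prec)]) / 2)
  c(auroc = auroc, auprc = auprc)
}

# stratified fold assignment: each class spread evenly over folds
stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Stratified cross-validation of the group network workflow
#'
#' Per fold, the full pipeline — variable clustering, dendrogram cut,
#' group BN learning and optionally adaptive refinement — is fit on the
#' training rows only; test rows are projected through the training-fold
#' loadings and discretization maps. The same seed yields the same folds
#' for every compared method.
#'
#' @param D a [mixed_dataset()] with a binary target.
#' @param target target variable name.
#' @param k initial number of groups (`NULL`: elbow of the aggregation
#'   levels per training fold).
#' @param separated_extra further separated variables.
#' @param cfg a [groupbn_control()].
#' @param folds number of folds.
#' @param refine_model run the adaptive refinement on each training fold.
#' @param seed integer seed controlling folds and learning.
#' @return list with `fold_metrics` (data.frame: fold, auroc, auprc),
#'   `mean`, `sd`.
#' @export
crossvalidate <- function(D, target, k = NULL, separated_extra = NULL,
                          cfg = groupbn_control(), folds = 10L,
                          refine_model = FALSE, seed = 1L) {
  if (any(D$missing_mask)) D <- impute_simple(D)
  labels <- as.character(D$df[[target]])
  if (length(unique(labels)) != 2L) stop("target must be binary")
  fold <- stratified_folds(labels, folds, seed)
  res <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    if (length(unique(labels[tr])) < 2L) stop("single-class training fold")
    Dtr <- mixed_dataset(D$df[tr, , drop = FALSE], kinds = D$kinds)
    Dte <- mixed_dataset(D$df[te, , drop = FALSE], kinds = D$kinds)
    H <- cluster_variables(Dtr, exclude = c(target, separated_extra))
    kf <- if (is.null(k)) suggest_k(H) else k
    if (refine_model) {
      M <- refine(Dtr, H, max(2L, kf), target, separated_extra, cfg = cfg,
                  seed = subseed(seed, f))
    } else {
      g <- cut_dendrogram(H, max(2L, kf))
      M <- build_group_bn(Dtr, g, target, separated_extra, cfg = cfg,
                          seed = subseed(seed, f))
    }
    prob <- predict(M, Dte, seed = subseed(seed, 1000L + f))
    pos_state <- colnames(prob)[ncol(prob)]
    obs <- labels[te]
    if (!is.null(M$sep_maps[[target]]))
      obs <- apply_discretization(D$df[[target]][te], M$sep_maps[[target]])
    res[[f]] <- c(fold = f, auc_metrics(obs, prob[, pos_state],
                                        positive = pos_state))
  }
  tab <- as.data.frame(do.call(rbind, res))
  list(fold_metrics = tab,
       mean = colMeans(tab[, c("auroc", "auprc")]),
       sd = apply(tab[, c("auroc", "auprc")], 2L, stats::sd))
}

# map learned groups to true group labels by majority member overlap and
# return the learned group CPDAG relabelled onto the true group names
map_cpdag_to_truth <- function(learned_dag, learned_grouping, true_grouping) {
  cp <- cpdag(learned_dag)
  tg <- as_partition(true_grouping)
  lg <- as_partition(learned_grouping)
  memb_true <- stats::setNames(rep(names(tg), lengths(tg)), unlist(tg))
  map <- vapply(names(lg), function(id) {
    hits <- table(memb_true[lg[[id]]])
    names(hits)[which.max(hits)]  # ties: first alphabetically
  }, character(1))
  gnames <- names(tg)
  p <- length(gnames)
  Dm <- matrix(FALSE, p, p, dimnames = list(gnames, gnames))
  Um <- matrix(FALSE, p, p, dimnames = list(gnames, gnames))
  lnodes <- cp$nodes
  for (i in seq_along(lnodes)) for (j in seq_along(lnodes)) {
    if (i >= j) next
    st <- cpdag_edge_state(cp, i, j)
    if (st == 0L) next
    a <- map[[lnodes[i]]]; b <- map[[lnodes[j]]]
    if (is.null(a) || is.null(b) || a == b) next
    if (st == 1L) {
      if (Dm[b, a] || Um[a, b]) { Um[a, b] <- Um[b, a] <- TRUE
        Dm[a, b] <- Dm[b, a] <- FALSE } else Dm[a, b] <- TRUE
    } else if (st == 2L) {
      if (Dm[a, b] || Um[a, b]) { Um[a, b] <- Um[b, a] <- TRUE
        Dm[a, b] <- Dm[b, a] <- FALSE } else Dm[b, a] <- TRUE
    } else {
      Um[a, b] <- Um[b, a] <- TRUE
      Dm[a, b] <- Dm[b, a] <- FALSE
    }
  }
  structure(list(nodes = gnames, directed = Dm, undirected = Um),
            class = "bn_cpdag")
}

# discretize a sampled layer-0 table for detailed structure learning
discretize_layer0 <- function(D) {
  cols <- lapply(names(D$kinds), function(v) {
    if (D$kinds[[v]] == "qual")
      factor(D$df[[v]], levels = D$levels[[v]])
    else {
      disc <- discretize_density_kmeans(D$df[[v]])
      factor(disc$labels, levels = disc_bins(disc$map))
    }
  })
  names(cols) <- names(D$kinds)
  as.data.frame(cols, check.names = FALSE)
}

#' Desk-scale simulation study of group network inference
#'
#' For each scenario and replicate, simulates a two-layer network, samples
#' data, and runs the requested arms: group network inference with
#' principal-component (`pc`) or medoid (`med`) aggregation, network-based
#' baseline (`network_baseline`: detailed structure learning followed by
#' community detection and arc projection), and structure learning on the
#' latent layer itself (`ground_truth_grouping`). Records the partition
#' metric to the true grouping, the normalized SHD of the mapped group
#' CPDAG to the true CPDAG, and (optionally) the held-out misclassification
#' error of predicting one randomly chosen discrete child through the group
#' model.
#'
#' @param scenarios data.frame with columns `n_groups`, `group_size`,
#'   `noise`, `n`.
#' @param reps replicates per scenario.
#' @param arms subset of `c("pc", "med", "network_baseline",
#'   "ground_truth_grouping")`.
#' @param measure_prediction compute the prediction-error arm (group model
#'   with PC aggregation, one discrete child as target, fresh test sample).
#' @param n_test held-out rows for the prediction error.
#' @param cfg learner settings used by every arm (desk scale by default).
#' @param seed integer seed.
#' @return data.frame of evaluation records, one per scenario x replicate x
#'   arm.
#' @export
run_simulation_study <- function(scenarios = data.frame(n_groups = 10,
                                                        group_size = 5,
                                                        noise = 0.05,
                                                        n = 500),
                                 reps = 20L,
                                 arms = c("pc", "med", "network_baseline",
                                          "ground_truth_grouping"),
                                 measure_prediction = FALSE, n_test = 200L,
                                 cfg = groupbn_control(B = 50L, restarts = 2L,
                                                       n_particles = 1000L,
                                                       runs = 5L),
                                 seed = 1L) {
  records <- list()
  for (sc in seq_len(nrow(scenarios))) {
    pars <- scenarios[sc, ]
    for (rep_i in seq_len(reps)) {
      sd0 <- subseed(seed, 10000L * sc + 10L * rep_i)
      net <- generate_two_layer(pars$n_groups, pars$group_size, pars$noise,
                                seed = sd0)
      samp <- forward_sample(net, pars$n, seed = subseed(sd0, 1L))
      truth_cp <- cpdag(net$layer1$dag)
      truth_edges <- cpdag_n_edges(truth_cp)
      rec <- function(method, pd, shd, perr) {
        data.frame(n_groups = pars$n_groups, group_size = pars$group_size,
                   noise = pars$noise, n = pars$n, method = method,
                   partition_distance = pd, normalized_shd = shd,
                   prediction_error = perr, replicate = rep_i, seed = sd0)
      }
      H <- NULL
      if (any(c("pc", "med") %in% arms)) {
        H <- cluster_variables(samp$layer0)
        g <- cut_dendrogram(H, pars$n_groups)
      }
      for (arm in intersect(arms, c("pc", "med"))) {
        rep_fun <- if (arm == "pc") pcamix_first_pc else medoid_representative
        cols <- list()
        ok <- TRUE
        for (id in names(g$groups)) {
          r <- try(rep_fun(samp$layer0, g$groups[[id]], id = id),
                   silent = TRUE)
          if (inherits(r, "try-error")) { ok <- FALSE; break }
          disc <- try(discretize_density_kmeans(r$scores), silent = TRUE)
          if (inherits(disc, "try-error")) { ok <- FALSE; break }
          cols[[id]] <- factor(disc$labels, levels = disc_bins(disc$map))
        }
        pd <- partition_metric(g, net$true_grouping)
        shd <- NA_real_
        if (ok && truth_edges > 0) {
          dd <- as.data.frame(cols, check.names = FALSE)
          set.seed(subseed(sd0, 2L))
          avg <- bootstrap_average(dd, B = cfg$B, restarts = cfg$restarts)
          mapped <- map_cpdag_to_truth(avg$dag, g, net$true_grouping)
          shd <- shd_normalized(mapped, truth_cp)
        }
        records[[length(records) + 1L]] <- rec(arm, pd, shd, NA_real_)
      }
      if ("ground_truth_grouping" %in% arms && truth_edges > 0) {
        set.seed(subseed(sd0, 3L))
        avg <- bootstrap_average(samp$layer1, B = cfg$B,
                                 restarts = cfg$restarts)
        shd <- shd_normalized(cpdag(avg$dag), truth_cp)
        records[[length(records) + 1L]] <-
          rec("ground_truth_grouping", 0, shd, NA_real_)
      }
      if ("network_baseline" %in% arms) {
        dd <- discretize_layer0(samp$layer0)
        detailed <- hill_climb(dd, restarts = 1L, seed = subseed(sd0, 4L))
        base <- network_baseline_grouping(detailed, net$true_grouping)
        shd <- if (truth_edges > 0)
          shd_normalized(cpdag(base$dag), truth_cp) else NA_real_
        records[[length(records) + 1L]] <-
          rec("network_baseline", base$partition_distance, shd, NA_real_)
      }
      if (measure_prediction) {
        perr <- prediction_error_arm(net, samp, n_test, cfg,
                                     seed = subseed(sd0, 5L))
        records[[length(records) + 1L]] <- rec("pc_prediction", NA_real_,
                                               NA_real_, perr)
      }
    }
  }
  do.call(rbind, records)
}

# held-out misclassification of one randomly chosen discrete child, taken
# as separated target of a group model with PC aggregation
prediction_error_arm <- function(net, samp, n_test, cfg, seed) {
  set.seed(seed)
  disc_children <- net$children$child[net$children$kind == "discrete"]
  if (length(disc_children) == 0L) return(NA_real_)
  target <- sample(disc_children, 1L)
  D <- samp$layer0
  H <- cluster_variables(D, exclude = target)
  g <- cut_dendrogram(H, length(net$true_grouping))
  M <- build_group_bn(D, g, target, cfg = cfg, seed = seed + 1L)
  test <- forward_sample(net, n_test, seed = seed + 2L)
  prob <- predict(M, test$layer0, seed = seed + 3L)
  pred <- colnames(prob)[max.col(prob, ties.method = "first")]
  mean(pred != as.character(test$layer0$df[[target]]))
}
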