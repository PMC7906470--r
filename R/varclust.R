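# Agglomerative similarity-based hierarchical clustering of mixed variables
# with PCAmix-style synthetic central variables, plus the dendrogram
# cut/split operations used by the adaptive refinement search.

# ---- PCAmix design blocks -------------------------------------------------

# Standardized design block of one variable under the PCAmix metric:
# quantitative -> (x - mean)/sd_n (population sd); qualitative -> centered
# indicator columns each divided by sqrt(level proportion). Returns the
# block plus the constants needed to rebuild it on new data.
pcamix_block <- function(x, kind, var) {
  n <- length(x)
  if (kind == "quant") {
    if (any(is.na(x))) stop("missing values in '", var, "'; impute first")
    s <- stats::sd(x) * sqrt((n - 1) / n)
    if (s == 0) stop("zero-variance quantitative variable '", var, "'")
    m <- mean(x)
    list(Z = matrix((x - m) / s, ncol = 1), kind = "quant",
         center = m, scale = s, levels = NULL, props = NULL)
  } else {
    x <- as.character(x)
    if (any(is.na(x))) stop("missing values in '", var, "'; impute first")
    lev <- sort(unique(x))
    if (length(lev) < 2L) stop("single-level qualitative variable '", var, "'")
    G <- outer(x, lev, `==`) * 1
    p <- colMeans(G)
    Z <- sweep(sweep(G, 2L, p, `-`), 2L, sqrt(p), `/`)
    list(Z = Z, kind = "qual", center = NULL, scale = NULL,
         levels = lev, props = p)
  }
}

pcamix_design <- function(D, vars) {
  blocks <- lapply(vars, function(v)
    pcamix_block(D$df[[v]], D$kinds[[v]], v))
  names(blocks) <- vars
  Z <- do.call(cbind, lapply(blocks, `[[`, "Z"))
  list(Z = Z, blocks = blocks,
       block_sizes = vapply(blocks, function(b) ncol(b$Z), integer(1)))
}

#' First PCAmix component of a variable group
#'
#' Builds the PCAmix design (standardized quantitative columns; centered
#' indicator columns divided by the square root of the category proportion
#' for qualitative variables), and returns the observation scores of the
#' first principal direction, scaled so that their (population) variance
#' equals the first eigenvalue. The first eigenvalue equals the cluster
#' homogeneity: the sum over member variables of the squared correlation
#' (quantitative) or correlation ratio (qualitative) with the scores.
#'
#' @param D a fully observed [mixed_dataset()].
#' @param vars character vector of member variable names (default: all).
#' @param id group identifier stored on the result.
#' @return A `group_representative`: `id`, `members`, `scores` (zero-mean,
#'   length N), `loadings` (per-member constants and coefficients sufficient
#'   to recompute scores on new data) and `homogeneity`.
#' @export
pcamix_first_pc <- function(D, vars = names(D$kinds), id = "G") {
  stopifnot(length(vars) >= 1L, n_obs(D) >= 2L)
  des <- pcamix_design(D, vars)
  n <- nrow(des$Z)
  e <- eigen(crossprod(des$Z) / n, symmetric = TRUE)
  v <- e$vectors[, 1L]
  # orient: first coefficient of the first member variable nonnegative
  if (v[1L] < 0) v <- -v
  scores <- as.numeric(des$Z %*% v)
  coefs <- split(v, rep(seq_along(vars), des$block_sizes))
  loadings <- lapply(seq_along(vars), function(i) {
    b <- des$blocks[[i]]
    list(var = vars[i], kind = b$kind, center = b$center, scale = b$scale,
         levels = b$levels, props = b$props, coef = as.numeric(coefs[[i]]))
  })
  names(loadings) <- vars
  structure(list(id = id, members = vars, scores = scores,
                 loadings = loadings, homogeneity = e$values[1L]),
            class = "group_representative")
}

#' Recompute representative scores on new data from stored loadings
#'
#' Applies the training-time centering/scaling constants (and, for
#' qualitative members, the training level proportions) so held-out rows are
#' projected exactly as the training rows were.
#'
#' @param rep a `group_representative`.
#' @param D a fully observed `mixed_dataset` containing every member.
#' @return numeric score vector of length `n_obs(D)`.
#' @export
project_representative <- function(rep, D) {
  missing_cols <- setdiff(rep$members, names(D$kinds))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  n <- n_obs(D)
  scores <- numeric(n)
  for (ld in rep$loadings) {
    x <- D$df[[ld$var]]
    if (ld$kind == "quant") {
      scores <- scores + ld$coef * (as.numeric(x) - ld$center) / ld$scale
    } else {
      x <- as.character(x)
      G <- outer(x, ld$levels, `==`) * 1
      Zb <- sweep(sweep(G, 2L, ld$props, `-`), 2L, sqrt(ld$props), `/`)
      scores <- scores + as.numeric(Zb %*% ld$coef)
    }
  }
  scores
}

# ---- association measures -------------------------------------------------

# squared correlation (quant) / correlation ratio eta^2 (qual) of a member
# with a numeric score vector
assoc_with_scores <- function(x, kind, scores) {
  if (kind == "quant") {
    stats::cor(as.numeric(x), scores)^2
  } else {
    eta_squared(scores, as.character(x))
  }
}

# between-category sum of squares over total sum of squares of y by groups g
eta_squared <- function(y, g) {
  mu <- mean(y)
  tot <- sum((y - mu)^2)
  if (tot == 0) return(0)
  means <- tapply(y, g, mean)
  counts <- tapply(y, g, length)
  sum(counts * (means - mu)^2) / tot
}

# symmetric squared association between two mixed variables:
# quant-quant r^2, mixed eta^2, qual-qual Cramer's V^2
assoc_squared <- function(x, kx, y, ky) {
  if (kx == "quant" && ky == "quant") {
    stats::cor(as.numeric(x), as.numeric(y))^2
  } else if (kx == "qual" && ky == "qual") {
    tab <- table(as.character(x), as.character(y))
    n <- sum(tab)
    chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
    as.numeric(chi2) / (n * (min(dim(tab)) - 1L))
  } else if (kx == "quant") {
    eta_squared(as.numeric(x), as.character(y))
  } else {
    eta_squared(as.numeric(y), as.character(x))
  }
}

#' Medoid representative of a variable group
#'
#' The member variable minimizing the total dissimilarity
#' `1 - association^2` to the other members (squared correlation between
#' quantitative pairs, correlation ratio for mixed pairs, squared Cramer's V
#' between qualitative pairs). Ties are broken by column order. A
#' quantitative medoid is returned standardized; a qualitative medoid is
#' represented by the first component of its own indicator block.
#'
#' @inheritParams pcamix_first_pc
#' @return A `group_representative` (see [pcamix_first_pc()]); its
#'   `homogeneity` is the sum of member associations with the medoid scores.
#' @export
medoid_representative <- function(D, vars = names(D$kinds), id = "G") {
  stopifnot(length(vars) >= 1L)
  if (length(vars) == 1L) {
    rep <- pcamix_first_pc(D, vars, id = id)
    rep$medoid <- vars
    return(rep)
  }
  p <- length(vars)
  diss <- matrix(0, p, p)
  for (i in seq_len(p - 1L)) for (j in seq((i + 1L), p)) {
    a <- assoc_squared(D$df[[vars[i]]], D$kinds[[vars[i]]],
                       D$df[[vars[j]]], D$kinds[[vars[j]]])
    diss[i, j] <- diss[j, i] <- 1 - a
  }
  med <- which.min(rowSums(diss))  # which.min: first index on ties
  rep <- pcamix_first_pc(D, vars[med], id = id)
  rep$members <- vars
  rep$medoid <- vars[med]
  rep$homogeneity <- sum(vapply(vars, function(v)
    assoc_with_scores(D$df[[v]], D$kinds[[v]], rep$scores), numeric(1)))
  rep
}

# ---- hierarchical clustering ----------------------------------------------

# homogeneity (first PCAmix eigenvalue) of a cluster, computed from cached
# per-variable design blocks
cluster_homogeneity <- function(Zlist, members) {
  Z <- do.call(cbind, Zlist[members])
  n <- nrow(Z)
  if (ncol(Z) == 1L) return(sum(Z^2) / n)
  eigen(crossprod(Z) / n, symmetric = TRUE, only.values = TRUE)$values[1L]
}

#' Hierarchical clustering of mixed variables
#'
#' Agglomerative clustering starting from singletons; each step merges the
#' cluster pair whose union loses the least homogeneity
#' (`hom(A) + hom(B) - hom(A + B)`), the loss being the merge height.
#' Homogeneity is the first PCAmix eigenvalue of the cluster, recomputed
#' exactly for every candidate merge. Ties are broken by the
#' lexicographically smallest pair of smallest member names.
#'
#' @param D a fully observed [mixed_dataset()].
#' @param exclude variable names (target, declared confounders) excluded
#'   before clustering.
#' @return A `var_dendrogram`: `leaves` (variable names), `merges`
#'   (two-column matrix in `hclust` convention: negative entries are leaves,
#'   positive entries earlier merges), `heights` (nondecreasing; cumulative
#'   maximum of the raw losses), `raw_heights`.
#' @export
cluster_variables <- function(D, exclude = character(0)) {
  vars <- setdiff(names(D$kinds), exclude)
  p <- length(vars)
  if (p < 2L) stop("need at least 2 variables to cluster")
  Zlist <- lapply(vars, function(v)
    pcamix_block(D$df[[v]], D$kinds[[v]], v)$Z)
  names(Zlist) <- vars

  # active clusters: node id (hclust convention), members, homogeneity
  node <- as.list(-seq_len(p))
  members <- as.list(vars)
  hom <- rep(1, p)
  for (i in seq_len(p)) if (ncol(Zlist[[vars[i]]]) > 1L)
    hom[i] <- cluster_homogeneity(Zlist, vars[i])
  active <- seq_len(p)

  loss <- matrix(NA_real_, p, p)
  pair_loss <- function(i, j) {
    hom[i] + hom[j] - cluster_homogeneity(Zlist, c(members[[i]], members[[j]]))
  }
  for (i in seq_len(p - 1L)) for (j in seq((i + 1L), p))
    loss[i, j] <- pair_loss(i, j)

  merges <- matrix(0L, p - 1L, 2L)
  raw_heights <- numeric(p - 1L)
  for (m in seq_len(p - 1L)) {
    act <- active
    best <- NULL
    best_loss <- Inf
    for (ii in seq_len(length(act) - 1L)) for (jj in seq((ii + 1L), length(act))) {
      i <- act[ii]; j <- act[jj]
      l <- loss[min(i, j), max(i, j)]
      if (l < best_loss - 1e-12) {
        best <- c(i, j); best_loss <- l
      } else if (abs(l - best_loss) <= 1e-12 && !is.null(best)) {
        # tie-break: lexicographically smallest (smallest member name) pair
        key_new <- sort(c(min(members[[i]]), min(members[[j]])))
        key_old <- sort(c(min(members[[best[1]]]), min(members[[best[2]]])))
        if (paste(key_new, collapse = "\r") < paste(key_old, collapse = "\r")) {
          best <- c(i, j); best_loss <- l
        }
      }
    }
    i <- best[1]; j <- best[2]
    merges[m, ] <- c(node[[i]], node[[j]])
    raw_heights[m] <- best_loss
    # merged cluster replaces slot i; slot j retired
    members[[i]] <- c(members[[i]], members[[j]])
    node[[i]] <- m
    hom[i] <- hom[i] + hom[j] - best_loss
    active <- setdiff(active, j)
    for (k in setdiff(active, i))
      loss[min(i, k), max(i, k)] <- pair_loss(i, k)
  }
  structure(list(leaves = vars, merges = merges,
                 heights = cummax(raw_heights), raw_heights = raw_heights),
            class = "var_dendrogram")
}

#' @export
print.var_dendrogram <- function(x, ...) {
  cat("var_dendrogram over", length(x$leaves), "variables;",
      nrow(x$merges), "merges\n")
  invisible(x)
}

# leaf names under a dendrogram node (negative = leaf index, positive =
# merge index, hclust convention)
node_leaves <- function(H, node) {
  if (node < 0L) return(H$leaves[-node])
  c(node_leaves(H, H$merges[node, 1L]), node_leaves(H, H$merges[node, 2L]))
}

group_id_for_node <- function(H, node) {
  if (node < 0L) H$leaves[-node] else paste0("G", node)
}

#' Cut a dendrogram into k groups
#'
#' Undoes the last `k - 1` merges; the resulting connected components are
#' the groups, each recorded with the dendrogram node whose leaf set equals
#' it (so the grouping is always an antichain cut of the hierarchy).
#' Singleton groups are named after their variable, merged groups
#' `"G<merge index>"`.
#'
#' @param H a `var_dendrogram`.
#' @param k number of groups, between 1 and the number of leaves.
#' @return A `var_grouping`: named list `groups` (member names per group id)
#'   and `nodes` (dendrogram node per group id).
#' @export
cut_dendrogram <- function(H, k) {
  p <- length(H$leaves)
  if (k < 1L || k > p) stop("k out of range [1, ", p, "]")
  kept <- seq_len(p - k)  # merges applied
  # top nodes: every node (leaf or kept merge) not consumed by a kept merge
  consumed <- if (length(kept)) as.vector(H$merges[kept, , drop = FALSE]) else integer(0)
  all_nodes <- c(-seq_len(p), kept)
  tops <- setdiff(all_nodes, consumed)
  groups <- lapply(tops, function(nd) node_leaves(H, nd))
  ids <- vapply(tops, function(nd) group_id_for_node(H, nd), character(1))
  names(groups) <- ids
  nodes <- stats::setNames(as.integer(tops), ids)
  ord <- order(match(vapply(groups, `[[`, character(1), 1L), H$leaves))
  structure(list(groups = groups[ord], nodes = nodes[ord]),
            class = "var_grouping")
}

#' @export
print.var_grouping <- function(x, ...) {
  cat("var_grouping with", length(x$groups), "groups:\n")
  for (id in names(x$groups))
    cat("  ", id, ": ", paste(x$groups[[id]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Split one group along the dendrogram
#'
#' Replaces group `b` by the two children of its dendrogram node; the result
#' is still a cut of `H` with one more group.
#'
#' @param H the `var_dendrogram` the grouping was cut from.
#' @param g a `var_grouping`.
#' @param b id of the group to split (must have at least 2 members).
#' @return A `var_grouping` with `length(g$groups) + 1` groups.
#' @export
split_group <- function(H, g, b) {
  if (!b %in% names(g$groups)) stop("unknown group '", b, "'")
  nd <- g$nodes[[b]]
  if (nd < 0L) stop("unsplittable singleton group '", b, "'")
  ch <- H$merges[nd, ]
  new_ids <- vapply(ch, function(x) group_id_for_node(H, x), character(1))
  groups <- g$groups[names(g$groups) != b]
  nodes <- g$nodes[names(g$nodes) != b]
  for (i in 1:2) {
    groups[[new_ids[i]]] <- node_leaves(H, ch[i])
    nodes[new_ids[i]] <- as.integer(ch[i])
  }
  ord <- order(match(vapply(groups, `[[`, character(1), 1L), H$leaves))
  structure(list(groups = groups[ord], nodes = nodes[ord]),
            class = "var_grouping")
}

#' Aggregation levels of a dendrogram
#'
#' The homogeneity loss removed when moving from `k - 1` to `k` groups;
#' plotted against `k` this curve helps choose an initial group count
#' (elbow = best compression/information trade-off).
#'
#' @param H a `var_dendrogram`.
#' @return data.frame with columns `k` (2 ... number of leaves) and
#'   `height` (nonincreasing).
#' @export
aggregation_levels <- function(H) {
  p <- length(H$leaves)
  data.frame(k = 2:p, height = rev(H$heights))
}

#' Elbow-based choice of the initial group count
#'
#' The largest second difference of the aggregation-level curve.
#'
#' @param H a `var_dendrogram`.
#' @return integer `k`.
#' @export
suggest_k <- function(H) {
  lev <- aggregation_levels(H)
  if (nrow(lev) < 3L) return(lev$k[1L])
  d2 <- diff(diff(lev$height))
  lev$k[which.max(d2) + 1L]
}

#' Export a variable dendrogram as Newick
#'
#' @param H a `var_dendrogram`.
#' @param path optional file; when `NULL` the Newick string is returned.
#' @return Newick string, invisibly when written to file.
#' @export
dendrogram_newick <- function(H, path = NULL) {
  rec <- function(node) {
    if (node < 0L) return(H$leaves[-node])
    paste0("(", rec(H$merges[node, 1L]), ",", rec(H$merges[node, 2L]),
           "):", format(H$heights[node], digits = 10))
  }
  nwk <- paste0("(", rec(nrow(H$merges)), ");")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}
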