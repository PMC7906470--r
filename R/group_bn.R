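# Building a group Bayesian network from a dataset, a grouping and a
# separated target; projecting new observations through the stored loadings
# and discretization maps for prediction.

#' Learning settings for group Bayesian networks
#'
#' @param representative `"pc"` (first PCAmix component) or `"medoid"`.
#' @param B bootstrap replicates for model averaging.
#' @param restarts hill-climbing restarts per structure search.
#' @param iss imaginary sample size of the parameter prior.
#' @param n_particles likelihood-weighting particles per run.
#' @param runs likelihood-weighting runs (the uncertainty band of the
#'   refinement objective is taken over these).
#' @param max_distance optional moralized-graph distance bounding the
#'   refinement candidate set (`NULL` = Markov blanket only).
#' @param literal_weights use the literal class-proportion weights in the
#'   cross-entropy objective instead of the equalizing inverse-frequency
#'   weights (comparison only).
#' @return list of class `groupbn_control`.
#' @export
groupbn_control <- function(representative = c("pc", "medoid"), B = 200L,
                            restarts = 10L, iss = 1, n_particles = 5000L,
                            runs = 20L, max_distance = NULL,
                            literal_weights = FALSE) {
  structure(list(representative = match.arg(representative), B = as.integer(B),
                 restarts = as.integer(restarts), iss = iss,
                 n_particles = as.integer(n_particles), runs = as.integer(runs),
                 max_distance = max_distance,
                 literal_weights = isTRUE(literal_weights)),
            class = "groupbn_control")
}

# discretized factor column for a variable kept as its own node
separated_column <- function(D, v) {
  if (D$kinds[[v]] == "qual") {
    list(values = factor(D$df[[v]], levels = D$levels[[v]]), map = NULL)
  } else {
    disc <- discretize_density_kmeans(D$df[[v]])
    list(values = factor(disc$labels, levels = disc_bins(disc$map)),
         map = disc$map)
  }
}

#' Build a group Bayesian network
#'
#' Computes one representative per group (first PCAmix component by default,
#' medoid optionally), discretizes each representative with the
#' density-approximative binning, assembles the discrete table of group bins
#' plus the separated variables (target first; separated quantitative
#' variables are discretized the same way, qualitative ones keep their
#' levels), learns the structure by bootstrap-averaged BIC hill climbing and
#' fits the parameters with a uniform prior.
#'
#' @param D a [mixed_dataset()]; imputed internally if missing cells remain.
#' @param g a `var_grouping` over the non-separated variables.
#' @param target name of the (binary) target variable; must not be a group
#'   member.
#' @param separated_extra further variables kept as own nodes (confounders).
#' @param cfg a [groupbn_control()].
#' @param init optional `bn_dag` initializing each structure search (used by
#'   the refinement to embed split groups into the incumbent structure).
#' @param seed optional integer seed.
#' @return A `group_bn_model`: `grouping`, `representatives`, `disc_maps`,
#'   `separated` (target first) with their maps, `bn` (a `discrete_bn` over
#'   group ids and separated names), `target`, `strength`, `threshold`,
#'   `training_meta`.
#' @export
build_group_bn <- function(D, g, target, separated_extra = NULL,
                           cfg = groupbn_control(), init = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  separated <- c(target, separated_extra)
  in_groups <- unlist(g$groups, use.names = FALSE)
  if (any(separated %in% in_groups))
    stop("separated variable(s) must not be group members: ",
         paste(intersect(separated, in_groups), collapse = ", "))
  if (any(D$missing_mask)) D <- impute_simple(D)
  tcol <- D$df[[target]]
  if (length(unique(tcol[!is.na(tcol)])) < 2L) stop("target is constant")

  rep_fun <- if (cfg$representative == "medoid") medoid_representative
             else pcamix_first_pc
  reps <- list()
  disc_maps <- list()
  cols <- list()
  for (id in names(g$groups)) {
    members <- g$groups[[id]]
    if (length(members) == 1L && D$kinds[[members]] == "qual") {
      # a singleton qualitative group is the variable itself: its levels
      # become the node states, no lossy score/binning step
      reps[[id]] <- structure(list(id = id, members = members,
                                   passthrough = members),
                              class = "group_representative")
      cols[[id]] <- factor(D$df[[members]], levels = D$levels[[members]])
    } else {
      reps[[id]] <- rep_fun(D, members, id = id)
      disc <- discretize_density_kmeans(reps[[id]]$scores)
      disc$map$var <- id
      disc_maps[[id]] <- disc$map
      cols[[id]] <- factor(disc$labels, levels = disc_bins(disc$map))
    }
  }
  sep_maps <- list()
  for (v in separated) {
    sp <- separated_column(D, v)
    if (!is.null(sp$map)) { sp$map$var <- v; sep_maps[[v]] <- sp$map }
    cols[[v]] <- sp$values
  }
  disc_data <- as.data.frame(cols, check.names = FALSE)

  avg <- bootstrap_average(disc_data, B = cfg$B, init = init,
                           restarts = cfg$restarts)
  bn <- fit_parameters(avg$dag, disc_data, iss = cfg$iss)
  structure(list(grouping = g, representatives = reps, disc_maps = disc_maps,
                 separated = separated, sep_maps = sep_maps, bn = bn,
                 target = target, strength = avg$strength,
                 threshold = avg$threshold, disc_data = disc_data,
                 cfg = cfg,
                 training_meta = list(n = n_obs(D), seed = seed,
                                      B = cfg$B, restarts = cfg$restarts,
                                      iss = cfg$iss)),
            class = "group_bn_model")
}

#' @export
print.group_bn_model <- function(x, ...) {
  cat("group_bn_model: target '", x$target, "', ",
      length(x$grouping$groups), " groups + ", length(x$separated),
      " separated node(s), ", sum(x$bn$dag$A), " arcs\n", sep = "")
  invisible(x)
}

#' Encode new observations as model evidence
#'
#' Projects rows onto each group's stored loadings (training-time
#' centering/scaling) and applies the stored discretization maps; separated
#' variables are encoded with their training maps/levels.
#'
#' @param M a `group_bn_model`.
#' @param D_new a `mixed_dataset` containing every variable the model uses
#'   (the target is optional).
#' @param include_target also encode the target column when present.
#' @return data.frame of factor evidence columns.
#' @export
encode_evidence <- function(M, D_new, include_target = FALSE) {
  if (any(D_new$missing_mask)) D_new <- impute_simple(D_new)
  cols <- list()
  for (id in names(M$representatives)) {
    rep <- M$representatives[[id]]
    if (!is.null(rep$passthrough)) {
      v <- rep$passthrough
      if (!v %in% names(D_new$kinds))
        stop("missing required column(s): ", v)
      vals <- as.character(D_new$df[[v]])
      if (any(!vals %in% M$bn$states[[id]]))
        stop("unseen level in group variable '", v, "'")
      cols[[id]] <- factor(vals, levels = M$bn$states[[id]])
    } else {
      sc <- project_representative(rep, D_new)
      cols[[id]] <- factor(apply_discretization(sc, M$disc_maps[[id]]),
                           levels = disc_bins(M$disc_maps[[id]]))
    }
  }
  sep <- M$separated
  if (!include_target) sep <- setdiff(sep, M$target)
  for (v in sep) {
    if (!v %in% names(D_new$kinds))
      stop("missing required column(s): ", v)
    if (!is.null(M$sep_maps[[v]])) {
      cols[[v]] <- factor(apply_discretization(D_new$df[[v]], M$sep_maps[[v]]),
                          levels = disc_bins(M$sep_maps[[v]]))
    } else {
      lev <- M$bn$states[[v]]
      vals <- as.character(D_new$df[[v]])
      if (any(!vals %in% lev))
        stop("unseen level in separated variable '", v, "'")
      cols[[v]] <- factor(vals, levels = lev)
    }
  }
  as.data.frame(cols, check.names = FALSE)
}

#' Predict target class probabilities from a group Bayesian network
#'
#' Encodes `D_new` through the stored loadings and discretization maps and
#' runs likelihood-weighting inference with all non-target nodes as
#' evidence; probabilities are averaged over the runs.
#'
#' @param object a `group_bn_model`.
#' @param D_new a `mixed_dataset` (or data.frame coerced through
#'   [mixed_dataset()]) with every variable the model uses.
#' @param n_particles,runs,seed override the model's control settings.
#' @param ... unused.
#' @return matrix rows x target states of run-averaged probabilities, with
#'   the per-run array in attribute `"runs"`.
#' @export
predict.group_bn_model <- function(object, D_new, n_particles = NULL,
                                   runs = NULL, seed = NULL, ...) {
  if (is.data.frame(D_new)) D_new <- mixed_dataset(D_new)
  np <- if (is.null(n_particles)) object$cfg$n_particles else n_particles
  nr <- if (is.null(runs)) object$cfg$runs else runs
  ev <- encode_evidence(object, D_new)
  arr <- predict_lw(object$bn, object$target, ev, n_particles = np,
                    runs = nr, seed = seed)
  avg <- apply(arr, c(1, 2), mean)
  attr(avg, "runs") <- arr
  avg
}

# ---- serialization --------------------------------------------------------

#' Serialize / restore a group BN model as JSON
#'
#' Full-precision, deterministic JSON so that rebuilding a model with the
#' same seed yields byte-identical output.
#'
#' @param M a `group_bn_model`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
model_to_json <- function(M, path = NULL) {
  ser <- list(
    target = M$target,
    separated = M$separated,
    groups = M$grouping$groups,
    nodes = as.list(M$grouping$nodes),
    representatives = lapply(M$representatives, function(r)
      list(id = r$id, members = as.list(r$members),
           passthrough = r$passthrough,
           homogeneity = r$homogeneity, scores = r$scores,
           loadings = lapply(r$loadings, function(ld)
             list(var = ld$var, kind = ld$kind, center = ld$center,
                  scale = ld$scale, levels = as.list(ld$levels),
                  props = as.list(ld$props), coef = ld$coef)))),
    disc_maps = lapply(M$disc_maps, unclass),
    sep_maps = lapply(M$sep_maps, unclass),
    dag = list(nodes = M$bn$dag$nodes,
               arcs = apply(dag_arcs(M$bn$dag), 1L, paste, collapse = "->")),
    states = M$bn$states,
    cpts = lapply(M$bn$cpts, function(cpt)
      list(dim = dim(cpt), values = as.numeric(cpt))),
    strength = as.numeric(M$strength),
    threshold = M$threshold,
    training_meta = M$training_meta)
  js <- jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname model_to_json
#' @param json JSON string or file path produced by [model_to_json()].
#' @export
model_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- readLines(json)
  ser <- jsonlite::fromJSON(json, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  nodes <- unlist(ser$dag$nodes)
  arcs <- do.call(rbind, lapply(ser$dag$arcs, function(a)
    strsplit(a, "->", fixed = TRUE)[[1]]))
  dag <- empty_dag(nodes, arcs)
  states <- lapply(ser$states, unlist)
  cpts <- lapply(names(ser$cpts), function(v) {
    x <- ser$cpts[[v]]
    pa <- nodes[dag$A[, v]]
    dn <- c(list(states[[v]]), states[pa])
    names(dn) <- c(v, pa)
    array(unlist(x$values), dim = unlist(x$dim), dimnames = dn)
  })
  names(cpts) <- names(ser$cpts)
  bn <- structure(list(dag = dag, states = states, cpts = cpts),
                  class = "discrete_bn")
  reps <- lapply(ser$representatives, function(r) {
    if (!is.null(r$passthrough))
      return(structure(list(id = r$id, members = unlist(r$members),
                            passthrough = r$passthrough),
                       class = "group_representative"))
    structure(list(id = r$id, members = unlist(r$members),
                   scores = unlist(r$scores),
                   loadings = lapply(r$loadings, function(ld)
                     list(var = ld$var, kind = ld$kind,
                          center = ld$center, scale = ld$scale,
                          levels = if (length(ld$levels)) unlist(ld$levels),
                          props = if (length(ld$props)) unlist(ld$props),
                          coef = unlist(ld$coef))),
                   homogeneity = r$homogeneity),
              class = "group_representative")
  })
  remap <- function(m) structure(
    list(var = m$var, method = m$method, boundaries = unlist(m$boundaries),
         n_bins = m$n_bins), class = "disc_map")
  p <- length(nodes)
  strength <- matrix(unlist(ser$strength), p, p,
                     dimnames = list(nodes, nodes))
  grouping <- structure(list(groups = lapply(ser$groups, unlist),
                             nodes = unlist(ser$nodes)),
                        class = "var_grouping")
  structure(list(grouping = grouping, representatives = reps,
                 disc_maps = lapply(ser$disc_maps, remap),
                 separated = unlist(ser$separated),
                 sep_maps = lapply(ser$sep_maps, remap),
                 bn = bn, target = ser$target, strength = strength,
                 threshold = ser$threshold, disc_data = NULL,
                 cfg = groupbn_control(),
                 training_meta = ser$training_meta),
            class = "group_bn_model")
}

#' Export the group network with member lists
#'
#' @param M a `group_bn_model`.
#' @param path output file.
#' @param format `"dot"` or `"graphml"`.
#' @export
export_group_network <- function(M, path, format = c("dot", "graphml")) {
  format <- match.arg(format)
  g <- dag_to_igraph(M$bn$dag)
  memb <- vapply(M$bn$dag$nodes, function(v) {
    if (v %in% names(M$grouping$groups))
      paste(M$grouping$groups[[v]], collapse = ";")
    else v
  }, character(1))
  igraph::V(g)$members <- memb
  igraph::V(g)$size <- vapply(M$bn$dag$nodes, function(v) {
    if (v %in% names(M$grouping$groups)) length(M$grouping$groups[[v]]) else 1L
  }, integer(1))
  el <- igraph::as_edgelist(g)
  if (nrow(el)) igraph::E(g)$strength <- M$strength[el]
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
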