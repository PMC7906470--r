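# Mixed-type tabular data model, CSV I/O, missing handling, and the
# density-approximative discretization applied to cluster representatives.

#' Construct a mixed dataset
#'
#' A `mixed_dataset` holds an N x p table of quantitative (numeric) and
#' qualitative (categorical) variables with missing values coded as `NA`.
#'
#' @param df data.frame; numeric columns are quantitative, character/factor
#'   columns qualitative.
#' @param kinds optional named character vector (`"quant"`/`"qual"`) per
#'   variable; inferred from column classes when `NULL`.
#' @param levels optional named list of ordered level labels per qualitative
#'   variable; defaults to sorted distinct observed labels.
#' @return An object of class `mixed_dataset` with fields `df`, `kinds`,
#'   `levels` and a logical `missing_mask`.
#' @export
mixed_dataset <- function(df, kinds = NULL, levels = NULL) {
  stopifnot(is.data.frame(df), nrow(df) >= 1L, ncol(df) >= 1L)
  nm <- names(df)
  if (anyDuplicated(nm)) stop("duplicate column names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (is.null(kinds)) {
    kinds <- vapply(df, function(col) if (is.numeric(col)) "quant" else "qual",
                    character(1))
  }
  kinds <- kinds[nm]
  if (any(is.na(kinds))) stop("kinds must cover every column")
  out_df <- df
  lev <- if (is.null(levels)) list() else levels
  for (v in nm) {
    col <- df[[v]]
    if (kinds[[v]] == "quant") {
      col <- suppressWarnings(as.numeric(as.character(col)))
      if (any(!is.finite(col) & !is.na(col)))
        stop("non-finite values in quantitative column '", v, "'")
      out_df[[v]] <- col
    } else {
      col <- as.character(col)
      col[!is.na(col) & col == ""] <- NA_character_
      if (is.null(lev[[v]])) lev[[v]] <- sort(unique(col[!is.na(col)]))
      bad <- !is.na(col) & !(col %in% lev[[v]])
      if (any(bad)) stop("value outside declared levels in column '", v, "'")
      out_df[[v]] <- col
    }
    if (all(is.na(col))) stop("all-missing column '", v, "'")
  }
  structure(list(df = out_df, kinds = kinds,
                 levels = lev[names(lev) %in% nm[kinds == "qual"]],
                 missing_mask = as.matrix(is.na(out_df))),
            class = "mixed_dataset")
}

#' @export
print.mixed_dataset <- function(x, ...) {
  cat("mixed_dataset: ", nrow(x$df), " observations x ", ncol(x$df),
      " variables (", sum(x$kinds == "quant"), " quantitative, ",
      sum(x$kinds == "qual"), " qualitative), ",
      sum(x$missing_mask), " missing cells\n", sep = "")
  invisible(x)
}

#' Number of observations / variables of a mixed dataset
#' @param D a `mixed_dataset`.
#' @return integer.
#' @export
n_obs <- function(D) nrow(D$df)

#' @rdname n_obs
#' @export
n_vars <- function(D) ncol(D$df)

#' Read a delimited table as a mixed dataset
#'
#' Columns fully parseable as numbers become quantitative unless overridden;
#' all others become qualitative with levels equal to the sorted distinct
#' observed labels. Empty cells and the sentinel strings are read as missing.
#'
#' @param path file path of a delimited text file with a header row.
#' @param kind_overrides optional named character vector mapping variable
#'   names to `"quant"` or `"qual"`.
#' @param sep field separator (default comma).
#' @param na_strings cell values treated as missing.
#' @return A [mixed_dataset()].
#' @export
read_mixed_table <- function(path, kind_overrides = NULL, sep = ",",
                             na_strings = c("", "NA")) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = na_strings, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "\"", comment.char = "")
  if (anyDuplicated(names(raw)))
    stop("duplicate column names in ", path)
  kinds <- vapply(names(raw), function(v) {
    if (!is.null(kind_overrides) && v %in% names(kind_overrides))
      return(match.arg(kind_overrides[[v]], c("quant", "qual")))
    col <- raw[[v]]
    obs <- col[!is.na(col)]
    if (length(obs) == 0L) stop("all-missing column '", v, "'")
    num <- suppressWarnings(as.numeric(obs))
    if (all(!is.na(num))) "quant" else "qual"
  }, character(1))
  for (v in names(raw)) if (kinds[[v]] == "quant")
    raw[[v]] <- suppressWarnings(as.numeric(raw[[v]]))
  mixed_dataset(raw, kinds = kinds)
}

#' Write a mixed dataset to a delimited file
#'
#' @param D a `mixed_dataset`.
#' @param path output file path.
#' @param sep field separator.
#' @export
write_mixed_table <- function(D, path, sep = ",") {
  utils::write.table(D$df, path, sep = sep, row.names = FALSE,
                     quote = which(D$kinds == "qual"), na = "NA")
  invisible(path)
}

#' Drop variables with too many missing values
#'
#' Keeps the variables whose missing fraction is at most
#' `max_missing_frac`, preserving column order.
#'
#' @param D a `mixed_dataset`.
#' @param max_missing_frac maximum tolerated fraction of missing cells per
#'   variable, in `[0, 1]` (0.2 drops variables measured for specific
#'   subgroups only).
#' @return A `mixed_dataset` restricted to the retained variables.
#' @export
filter_missing <- function(D, max_missing_frac = 0.2) {
  stopifnot(max_missing_frac >= 0, max_missing_frac <= 1)
  frac <- colMeans(D$missing_mask)
  keep <- names(frac)[frac <= max_missing_frac]
  if (length(keep) == 0L) stop("all variables exceed the missing threshold")
  mixed_dataset(D$df[, keep, drop = FALSE], kinds = D$kinds[keep],
                levels = D$levels[names(D$levels) %in% keep])
}

#' Median/mode imputation of residual missing values
#'
#' Quantitative missing cells are replaced by the variable's median,
#' qualitative ones by its mode (ties broken by level order).
#'
#' @param D a `mixed_dataset`.
#' @return A fully observed `mixed_dataset`.
#' @export
impute_simple <- function(D) {
  df <- D$df
  for (v in names(df)) {
    col <- df[[v]]
    miss <- is.na(col)
    if (!any(miss)) next
    if (D$kinds[[v]] == "quant") {
      col[miss] <- stats::median(col[!miss])
    } else {
      counts <- table(factor(col[!miss], levels = D$levels[[v]]))
      col[miss] <- names(counts)[which.max(counts)]
    }
    df[[v]] <- col
  }
  mixed_dataset(df, kinds = D$kinds, levels = D$levels)
}

# ---- discretization -------------------------------------------------------

#' Density-approximative discretization of a numeric vector
#'
#' Significant peaks of a Gaussian kernel density estimate (Silverman
#' bandwidth, 512-point grid) initialize a one-dimensional k-means whose
#' final centroid midpoints become the bin boundaries. A peak is significant
#' when its height is at least 10% of the density maximum and its prominence
#' (height above the higher flanking minimum) at least 5%. With a single
#' significant peak the sample quartiles are used instead, giving four bins.
#'
#' Bins are right-open intervals `[b[i-1], b[i])`: a value exactly on a
#' boundary belongs to the upper bin.
#'
#' @param x numeric vector with at least 8 non-missing values and non-zero
#'   variance.
#' @return list with `labels` (ordinal character labels `"bin1" < "bin2" <
#'   ...`) and `map`, a `disc_map` object (`var`, `method`, `boundaries`,
#'   `n_bins`).
#' @export
discretize_density_kmeans <- function(x) {
  x <- as.numeric(x)
  obs <- x[!is.na(x)]
  if (length(obs) < 8L) stop("need at least 8 non-missing values")
  if (stats::var(obs) == 0) stop("zero variance")
  xs <- (obs - mean(obs)) / stats::sd(obs)
  bw <- stats::bw.nrd0(xs)
  d <- stats::density(xs, bw = bw, n = 512L,
                      from = min(xs) - bw, to = max(xs) + bw)
  peaks <- significant_peaks(d$y)
  if (length(peaks) >= 2L) {
    centers_std <- d$x[peaks]
    centers <- centers_std * stats::sd(obs) + mean(obs)
    km <- suppressWarnings(
      stats::kmeans(obs, centers = matrix(sort(centers), ncol = 1),
                    iter.max = 100L))
    cen <- sort(as.numeric(km$centers))
    boundaries <- (cen[-length(cen)] + cen[-1]) / 2
    method <- "peak_kmeans"
  } else {
    boundaries <- unique(as.numeric(stats::quantile(obs, c(.25, .5, .75))))
    method <- "quartile"
  }
  boundaries <- prune_empty_bins(obs, boundaries)
  if (length(boundaries) < 1L) stop("could not form at least 2 non-empty bins")
  map <- structure(list(var = NA_character_, method = method,
                        boundaries = boundaries,
                        n_bins = length(boundaries) + 1L),
                   class = "disc_map")
  list(labels = apply_discretization(x, map), map = map)
}

# local maxima passing the relative-height (>= 10% of max) and prominence
# (>= 5% of max above the higher flanking minimum) rules
significant_peaks <- function(y) {
  n <- length(y)
  up <- c(TRUE, diff(y) > 0)
  down <- c(diff(y) < 0, TRUE)
  cand <- which(up & down)
  if (length(cand) == 0L) return(integer(0))
  ymax <- max(y)
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    p <- cand[i]
    if (y[p] < 0.1 * ymax) next
    left_min <- if (i == 1L) min(y[1:p]) else min(y[cand[i - 1L]:p])
    right_min <- if (i == length(cand)) min(y[p:n]) else min(y[p:cand[i + 1L]])
    prom <- y[p] - max(left_min, right_min)
    keep[i] <- prom >= 0.05 * ymax
  }
  cand[keep]
}

# drop boundaries that would leave an empty training bin
prune_empty_bins <- function(obs, boundaries) {
  boundaries <- sort(unique(boundaries))
  repeat {
    if (length(boundaries) == 0L) return(boundaries)
    counts <- tabulate(findInterval(obs, boundaries) + 1L,
                       nbins = length(boundaries) + 1L)
    if (all(counts > 0L)) return(boundaries)
    empty <- which(counts == 0L)[1L]
    drop <- if (empty > length(boundaries)) length(boundaries) else empty
    boundaries <- boundaries[-drop]
  }
}

#' Apply a fitted discretization map
#'
#' Values below the first boundary map to `"bin1"`, values at or above the
#' last to the last bin; a value exactly equal to a boundary falls into the
#' upper bin (right-open intervals).
#'
#' @param x numeric vector.
#' @param map a `disc_map` as returned by [discretize_density_kmeans()].
#' @return character vector of bin labels (`NA` preserved).
#' @export
apply_discretization <- function(x, map) {
  idx <- findInterval(as.numeric(x), map$boundaries) + 1L
  labs <- paste0("bin", idx)
  labs[is.na(x)] <- NA_character_
  labs
}

#' Bin labels of a discretization map
#' @param map a `disc_map`.
#' @return character vector `"bin1"` ... `"bin<n_bins>"`.
#' @export
disc_bins <- function(map) paste0("bin", seq_len(map$n_bins))
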