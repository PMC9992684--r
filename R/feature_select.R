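#' Parameters of the resampled voxel-selection procedure
#'
#' The procedure that picks age-informative "key voxels" per region: in each
#' of `n_outer` rounds, `n_inner` half-cohort subsamples are drawn; in every
#' subsample each voxel's Pearson correlation with age is computed and the
#' top `top_fraction` of voxels (by |r| unless `signed_ranking`) is kept; the
#' round's key-voxel set is the intersection over the `n_inner` subsamples.
#' A voxel selected in strictly more than `count_threshold` of the `n_outer`
#' rounds becomes a key feature.
#'
#' @param n_inner subsample trials per round (default 100).
#' @param n_outer rounds (default 100).
#' @param half_fraction fraction of subjects per subsample (default 0.5,
#'   drawn without replacement).
#' @param top_fraction fraction of voxels kept per trial (default 0.5).
#' @param count_threshold minimum round count, strict ">" (default 10).
#' @param signed_ranking rank by signed r instead of |r| (default FALSE:
#'   gray-matter and FA age correlations are predominantly negative, so
#'   absolute ranking is the default).
#' @return an object of class `selection_params`.
#' @export
selection_params <- function(n_inner = 100L, n_outer = 100L,
                             half_fraction = 0.5, top_fraction = 0.5,
                             count_threshold = 10L,
                             signed_ranking = FALSE) {
  stop_if_not_scalar_prob(half_fraction, "half_fraction")
  stop_if_not_scalar_prob(top_fraction, "top_fraction")
  if (half_fraction <= 0 || top_fraction <= 0) {
    stop("half_fraction and top_fraction must be positive", call. = FALSE)
  }
  if (count_threshold < 0 || count_threshold > n_outer) {
    stop("count_threshold must lie in [0, n_outer]", call. = FALSE)
  }
  structure(list(n_inner = as.integer(n_inner), n_outer = as.integer(n_outer),
                 half_fraction = half_fraction, top_fraction = top_fraction,
                 count_threshold = as.integer(count_threshold),
                 signed_ranking = isTRUE(signed_ranking)),
            class = "selection_params")
}

#' Per-voxel Pearson correlation with age
#'
#' Column-wise Pearson correlation between voxel values and chronological
#' age. A zero-variance voxel has undefined correlation; by convention it is
#' assigned r = 0 (and a message emitted) so it can never rank among the top
#' voxels.
#'
#' @param values subjects x voxels numeric matrix.
#' @param ages numeric vector of ages (non-constant, >= 3 subjects).
#' @param quiet suppress the zero-variance message.
#' @return numeric vector of correlations, one per voxel.
#' @export
voxel_age_corr <- function(values, ages, quiet = FALSE) {
  if (!is.matrix(values)) values <- as.matrix(values)
  n <- nrow(values)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (length(ages) != n) stop("ages length must match rows of values", call. = FALSE)
  a <- ages - mean(ages)
  sa <- sqrt(sum(a^2))
  if (sa == 0) stop("ages are constant; correlation undefined", call. = FALSE)
  X <- values - rep(colMeans(values), each = n)
  sx <- sqrt(colSums(X^2))
  r <- as.numeric(crossprod(X, a)) / (sx * sa)
  zero <- sx == 0
  if (any(zero)) {
    if (!quiet) message(sum(zero), " zero-variance voxel(s): r set to 0")
    r[zero] <- 0
  }
  r
}

# top-k voxel indices by ranking statistic; ties broken by lower voxel index
top_voxels <- function(r, k, signed = FALSE) {
  stat <- if (signed) r else abs(r)
  order(-stat, seq_along(stat))[seq_len(k)]
}

#' One round of key-voxel selection
#'
#' Runs `n_inner` half-cohort subsample trials and returns the intersection
#' of their top-voxel sets (possibly empty). Each trial draws
#' `floor(half_fraction * n)` subjects without replacement and keeps the
#' `ceiling(top_fraction * V)` voxels with the strongest age correlation.
#' Uses the current RNG stream; callers seed it.
#'
#' @param values subjects x voxels matrix.
#' @param ages ages vector.
#' @param params a [selection_params()].
#' @return sorted integer vector of voxel indices in the intersection.
#' @export
key_voxels_single_round <- function(values, ages, params = selection_params()) {
  if (!is.matrix(values)) values <- as.matrix(values)
  n <- nrow(values); V <- ncol(values)
  if (n < 4L) stop("need at least 4 subjects for half-sampling", call. = FALSE)
  m <- floor(params$half_fraction * n)
  k <- ceiling(params$top_fraction * V)
  keep <- rep(TRUE, V)
  for (t in seq_len(params$n_inner)) {
    idx <- sample.int(n, m)
    r <- voxel_age_corr(values[idx, , drop = FALSE], ages[idx], quiet = TRUE)
    top <- top_voxels(r, k, params$signed_ranking)
    sel <- rep(FALSE, V)
    sel[top] <- TRUE
    keep <- keep & sel
    if (!any(keep)) break
  }
  which(keep)
}

#' Select key features for one region
#'
#' Runs [key_voxels_single_round()] `n_outer` times on independent RNG
#' sub-streams, counts how often each voxel appears in a round's key-voxel
#' set, and selects voxels appearing strictly more than `count_threshold`
#' times. If the selected set is empty, the `max(count_threshold, 10)`
#' highest-count voxels are kept instead (downstream models need at least
#' one feature) and a warning is raised.
#'
#' @param values subjects x voxels matrix (training cohort).
#' @param ages ages vector.
#' @param params a [selection_params()].
#' @param seed integer seed for this region's selection (derive it from the
#'   master seed with [substream_seed()]).
#' @return object of class `feature_mask`: list with `selected_voxels`
#'   (sorted indices), `selection_counts` (per-voxel round counts) and
#'   `params`.
#' @export
select_features <- function(values, ages, params = selection_params(),
                            seed = 1L) {
  if (!is.matrix(values)) values <- as.matrix(values)
  V <- ncol(values)
  counts <- integer(V)
  for (round in seq_len(params$n_outer)) {
    sel <- with_seed(substream_seed(seed, "round", round),
                     key_voxels_single_round(values, ages, params))
    counts[sel] <- counts[sel] + 1L
  }
  selected <- which(counts > params$count_threshold)
  if (length(selected) == 0L) {
    n_keep <- min(V, max(params$count_threshold, 10L))
    selected <- order(-counts, seq_len(V))[seq_len(n_keep)]
    selected <- sort(selected)
    warning("no voxel exceeded the selection threshold; keeping the ",
            n_keep, " highest-count voxels", call. = FALSE)
  }
  structure(list(selected_voxels = selected, selection_counts = counts,
                 params = params),
            class = "feature_mask")
}

#' @export
print.feature_mask <- function(x, ...) {
  cat(sprintf("<feature_mask> %d/%d voxels selected (max count %d)\n",
              length(x$selected_voxels), length(x$selection_counts),
              max(x$selection_counts)))
  invisible(x)
}
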