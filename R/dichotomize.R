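#' Dichotomize one feature's expression into UP/DOWN groups by exact 1-D 2-means
#'
#' Splits the expression values of a single feature across samples into two
#' clusters minimizing the within-cluster sum of squares, then labels the
#' cluster with the higher median expression `UP` and the other `DOWN`.
#'
#' In one dimension the optimal 2-means partition is always a threshold split
#' of the sorted values, so the global optimum is found exactly by scanning
#' all admissible splits. No random initialization is involved and the result
#' is fully deterministic; a Lloyd-style k-means can only match or miss this
#' optimum. Ties in within-cluster sum of squares between two splits are
#' broken toward the split with the larger DOWN (lower) cluster.
#'
#' @param values numeric vector of expression values (log2 scale), one per
#'   sample. Names, if present, are carried through as sample ids.
#' @param sample_ids optional character vector of sample ids (defaults to
#'   `names(values)`).
#' @param min_cluster_size smallest admissible cluster (default 1: a single
#'   extreme sample may form its own cluster).
#' @param feature_id optional identifier stored in the result.
#' @param seed ignored; accepted for interface compatibility with stochastic
#'   clusterers. The threshold scan is exact, so no seed is needed.
#'
#' @return an object of class `dichotomy_result`: a list with `feature_id`,
#'   `labels` (character vector in `{"UP","DOWN"}` aligned with the input,
#'   named by sample id), `median_up`, `median_down`, `threshold` (midpoint
#'   between the clusters), `n_up`, `n_down`.
#'
#' @details Degenerate inputs (fewer than 2 samples, fewer than 2 distinct
#'   values, or no split satisfying `min_cluster_size`) raise an error of
#'   class `"degenerate_input"`; callers scoring many features should catch
#'   it and skip the feature.
#'
#' @examples
#' d <- kmeans_dichotomize(c(a = 0, b = 0, c = 0, d = 10, e = 10))
#' d$labels
#' d$threshold
#' @export
kmeans_dichotomize <- function(values, sample_ids = names(values),
                               min_cluster_size = 1L, feature_id = NA_character_,
                               seed = NULL) {
  if (!is.numeric(values)) {
    abort_coscore("`values` must be numeric", "validation_error")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    abort_coscore("`values` contains missing or non-finite entries", "validation_error")
  }
  n <- length(values)
  if (n < 2L) {
    abort_coscore("need at least 2 samples to dichotomize", "degenerate_input")
  }
  if (length(unique(values)) < 2L) {
    abort_coscore("constant expression vector cannot be dichotomized", "degenerate_input")
  }
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(n))

  ord <- order(values)
  x <- values[ord]
  cs <- cumsum(x)
  cs2 <- cumsum(x * x)
  tot <- cs[n]
  tot2 <- cs2[n]

  # admissible splits: between strictly increasing neighbours (a threshold
  # partition never separates tied values), respecting the minimum size
  ks <- which(x[-n] < x[-1L])
  ks <- ks[pmin(ks, n - ks) >= min_cluster_size]
  if (length(ks) == 0L) {
    abort_coscore("no admissible split satisfies `min_cluster_size`", "degenerate_input")
  }

  ssw <- (cs2[ks] - cs[ks]^2 / ks) +
    ((tot2 - cs2[ks]) - (tot - cs[ks])^2 / (n - ks))
  # exact-arithmetic ties resolved toward the larger DOWN (lower) cluster
  tol <- 1e-12 * max(abs(ssw), 1)
  k <- ks[max(which(ssw <= min(ssw) + tol))]

  low <- x[seq_len(k)]
  high <- x[(k + 1L):n]
  map <- assign_up_down(low, high)

  labels <- character(n)
  labels[ord] <- rep(c(map[["a"]], map[["b"]]), c(k, n - k))
  names(labels) <- sample_ids

  structure(list(
    feature_id = feature_id,
    labels = labels,
    median_up = max(stats::median(low), stats::median(high)),
    median_down = min(stats::median(low), stats::median(high)),
    threshold = (x[k] + x[k + 1L]) / 2,
    n_up = if (map[["a"]] == "UP") k else n - k,
    n_down = if (map[["a"]] == "DOWN") k else n - k
  ), class = "dichotomy_result")
}

#' Label two expression clusters UP and DOWN by median
#'
#' The cluster with the strictly higher median expression is labelled `UP`,
#' the other `DOWN`. Clusters with equal medians are unscorable and raise an
#' error of class `"median_tie"`.
#'
#' @param cluster_a,cluster_b numeric vectors of expression values; both
#'   non-empty.
#' @return named character vector `c(a = , b = )` with values `"UP"`/`"DOWN"`.
#' @export
assign_up_down <- function(cluster_a, cluster_b) {
  if (length(cluster_a) == 0L || length(cluster_b) == 0L) {
    abort_coscore("both clusters must be non-empty", "validation_error")
  }
  ma <- stats::median(cluster_a)
  mb <- stats::median(cluster_b)
  if (ma == mb) {
    abort_coscore("clusters have equal median expression; feature unscorable",
                  "median_tie")
  }
  if (ma > mb) c(a = "UP", b = "DOWN") else c(a = "DOWN", b = "UP")
}

#' @export
print.dichotomy_result <- function(x, ...) {
  cat(sprintf("1-D 2-means dichotomy%s: %d UP / %d DOWN, threshold %.4g\n",
              if (is.na(x$feature_id)) "" else paste0(" [", x$feature_id, "]"),
              x$n_up, x$n_down, x$threshold))
  cat(sprintf("  median UP %.4g, median DOWN %.4g\n", x$median_up, x$median_down))
  invisible(x)
}
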