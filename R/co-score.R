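#' Configuration for Clinical Outcome scoring
#'
#' @param n_repetitions number of permutation/subsampling repetitions used to
#'   build the null distribution of `P*` (default 10000).
#' @param removal_fraction fraction of samples removed uniformly at random,
#'   without replacement, at each repetition (default 0.10). The removal
#'   count is `floor(removal_fraction * n)`.
#' @param seed master integer seed. Per-feature sub-seeds are derived by
#'   hashing the feature id and endpoint, so scoring results do not depend on
#'   the order in which features are evaluated.
#' @param min_cluster_size smallest admissible expression cluster passed to
#'   [kmeans_dichotomize()] (default 1).
#' @param iid_relabel if `TRUE`, null labels are drawn i.i.d. Bernoulli at
#'   the observed UP frequency instead of permuting the observed label
#'   vector. The default (`FALSE`, permutation) preserves label counts and is
#'   the standard exchangeability-preserving choice.
#' @param per_subsample_p_true if `TRUE`, the observed significance is
#'   recomputed on each retained subsample (with the observed labels) and
#'   each `P*` is compared against its own subsample's observed value; a
#'   sensitivity-analysis mode. Default `FALSE`: `P_true` is computed once on
#'   the full sample.
#' @param co_threshold reporting threshold below which a CO score is flagged
#'   significant (default 0.05).
#' @return a list of class `score_config`.
#' @export
score_config <- function(n_repetitions = 10000L, removal_fraction = 0.10,
                         seed = 1L, min_cluster_size = 1L,
                         iid_relabel = FALSE, per_subsample_p_true = FALSE,
                         co_threshold = 0.05) {
  if (!is_count(n_repetitions)) {
    abort_coscore("`n_repetitions` must be a positive integer", "validation_error")
  }
  if (!is.numeric(removal_fraction) || length(removal_fraction) != 1L ||
      !is.finite(removal_fraction) || removal_fraction < 0 || removal_fraction >= 1) {
    abort_coscore("`removal_fraction` must lie in [0, 1)", "validation_error")
  }
  if (!is_count(min_cluster_size)) {
    abort_coscore("`min_cluster_size` must be a positive integer", "validation_error")
  }
  structure(list(
    n_repetitions = as.integer(n_repetitions),
    removal_fraction = removal_fraction,
    seed = as.integer(seed),
    min_cluster_size = as.integer(min_cluster_size),
    iid_relabel = isTRUE(iid_relabel),
    per_subsample_p_true = isTRUE(per_subsample_p_true),
    co_threshold = co_threshold
  ), class = "score_config")
}

#' Permutation/subsampling null distribution of the survival association
#'
#' For each repetition, `floor(removal_fraction * n)` samples are removed
#' uniformly at random without replacement, the observed UP/DOWN labels are
#' randomly permuted among the retained samples (preserving the retained
#' label counts), and the exponential likelihood-ratio significance `P*` is
#' computed on the relabelled subsample. Repetitions in which a label group
#' becomes empty or loses all exposure are dropped and counted rather than
#' imputed.
#'
#' @param time,event right-censored follow-up (see [fit_exponential()]).
#' @param labels observed `"UP"`/`"DOWN"` labels from [kmeans_dichotomize()].
#' @param config a [score_config()]. The RNG state at call time drives the
#'   draws; use [score_config()]'s seed via [evaluate_feature()] or set the
#'   seed yourself for reproducibility.
#' @return numeric vector of valid `P*` values (length `n_effective`), with
#'   attributes `n_dropped` (repetitions discarded as degenerate) and, when
#'   `config$per_subsample_p_true` is `TRUE`, `p_obs` (the per-subsample
#'   observed significances, aligned with the returned `P*`).
#' @export
permutation_null <- function(time, event, labels, config = score_config()) {
  check_survival_input(time, event)
  if (length(labels) != length(time) || !all(labels %in% c("UP", "DOWN"))) {
    abort_coscore("`labels` must be UP/DOWN and aligned with the records",
                  "validation_error")
  }
  time <- adjust_zero_times(time)
  n <- length(time)
  n_keep <- n - floor(config$removal_fraction * n)
  if (n_keep < 2L) {
    abort_coscore("fewer than 2 samples retained after removal", "validation_error")
  }
  is_up <- labels == "UP"
  frac_up <- mean(is_up)
  nrep <- config$n_repetitions

  p_star <- numeric(nrep)
  p_obs <- if (config$per_subsample_p_true) numeric(nrep) else NULL
  valid <- logical(nrep)
  subsampling <- n_keep < n

  for (i in seq_len(nrep)) {
    kept <- if (subsampling) sample.int(n, n_keep) else seq_len(n)
    t_k <- time[kept]
    e_k <- event[kept]
    tot_t <- sum(t_k)
    tot_d <- sum(e_k)

    n_up <- if (config$iid_relabel) {
      sum(stats::runif(n_keep) < frac_up)
    } else {
      sum(is_up[kept])
    }
    if (n_up == 0L || n_up == n_keep) next
    up_idx <- sample.int(n_keep, n_up)
    t_up <- sum(t_k[up_idx])
    d_up <- sum(e_k[up_idx])
    if (t_up <= 0 || tot_t - t_up <= 0) next

    p_star[i] <- exp_lrt_p(d_up, t_up, tot_d - d_up, tot_t - t_up)
    if (config$per_subsample_p_true) {
      obs_up <- is_up[kept]
      if (!any(obs_up) || all(obs_up)) next
      to_up <- sum(t_k[obs_up])
      if (to_up <= 0 || tot_t - to_up <= 0) next
      p_obs[i] <- exp_lrt_p(sum(e_k[obs_up]), to_up,
                            tot_d - sum(e_k[obs_up]), tot_t - to_up)
    }
    valid[i] <- TRUE
  }

  if (!any(valid)) {
    abort_coscore("no repetition produced a scorable null model", "unscorable")
  }
  out <- p_star[valid]
  attr(out, "n_dropped") <- sum(!valid)
  if (config$per_subsample_p_true) attr(out, "p_obs") <- p_obs[valid]
  out
}

#' Clinical Outcome score from an observed significance and its null
#'
#' The CO score is the empirical permutation p-value of the observed
#' significance against the null distribution:
#' `CO = |{i : P*_i <= P_true}| / n_effective`. A small CO means the observed
#' association is stronger than almost all null relabellings and is robust to
#' subsampling. The complement `1 - CO` is reported alongside by callers as a
#' "robustness" reading (larger = better).
#'
#' @param p_true observed significance from [compare_groups()]; may be a
#'   vector aligned with `p_star` when per-subsample observed significances
#'   are used.
#' @param p_star numeric vector of null significances from
#'   [permutation_null()].
#' @return the CO score, a number in `[0, 1]`.
#' @examples
#' compute_co(0.03, c(0.01, 0.02, 0.20, 0.80))  # 0.5
#' @export
compute_co <- function(p_true, p_star) {
  if (length(p_star) == 0L) {
    abort_coscore("`p_star` is empty; CO undefined", "validation_error")
  }
  if (!length(p_true) %in% c(1L, length(p_star))) {
    abort_coscore("`p_true` must be scalar or aligned with `p_star`",
                  "validation_error")
  }
  mean(p_star <= p_true)
}

#' Score one feature against clinical outcome
#'
#' Runs the full scoring procedure for a single feature: dichotomize its
#' expression by exact 1-D 2-means, compute the observed exponential-LRT
#' significance `P_true` on the full sample, build the
#' permutation/subsampling null of `P*`, and form the CO score — once per
#' endpoint type present in the clinical table.
#'
#' @param values named numeric vector of the feature's expression, names =
#'   sample ids.
#' @param clinical data frame with columns `sample_id`, `endpoint`
#'   (`"survival"`/`"metastasis"`), `time`, `event`.
#' @param config a [score_config()].
#' @param feature_id identifier for reporting and sub-seed derivation.
#' @return data frame with one row per endpoint: `feature_id`, `endpoint`,
#'   `n_up`, `n_down`, `lambda_up`, `lambda_down`, `lrt`, `p_true`, `co`,
#'   `co_complement`, `significant`, `n_effective`, `seed`.
#' @export
evaluate_feature <- function(values, clinical, config = score_config(),
                             feature_id = NA_character_) {
  if (is.null(names(values))) {
    abort_coscore("`values` must be named by sample id", "validation_error")
  }
  required <- c("sample_id", "endpoint", "time", "event")
  if (!all(required %in% names(clinical))) {
    abort_coscore("clinical table must have sample_id, endpoint, time, event",
                  "validation_error")
  }
  endpoints <- sort(unique(clinical$endpoint))
  rows <- lapply(endpoints, function(ep) {
    cl <- clinical[clinical$endpoint == ep, , drop = FALSE]
    cl <- cl[cl$sample_id %in% names(values), , drop = FALSE]
    if (nrow(cl) < 2L) {
      abort_coscore(sprintf("endpoint %s: fewer than 2 samples overlap the expression table", ep),
                    "validation_error")
    }
    v <- values[cl$sample_id]
    dich <- kmeans_dichotomize(v, sample_ids = cl$sample_id,
                               min_cluster_size = config$min_cluster_size,
                               feature_id = feature_id)
    obs <- compare_groups(cl$time, cl$event, dich$labels)
    sub_seed <- derive_seed(config$seed, feature_id, ep)
    p_star <- with_seed(sub_seed,
                        permutation_null(cl$time, cl$event, dich$labels, config))
    p_ref <- if (config$per_subsample_p_true) attr(p_star, "p_obs") else obs$p_true
    co <- compute_co(p_ref, as.numeric(p_star))
    data.frame(
      feature_id = feature_id,
      endpoint = ep,
      n_up = dich$n_up,
      n_down = dich$n_down,
      lambda_up = obs$fit_up$rate,
      lambda_down = obs$fit_down$rate,
      lrt = obs$lrt_stat,
      p_true = obs$p_true,
      co = co,
      co_complement = 1 - co,
      significant = co < config$co_threshold,
      n_effective = length(p_star),
      seed = sub_seed,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score every feature of an expression table against clinical outcome
#'
#' Applies [evaluate_feature()] to each feature column, separately per
#' endpoint, optionally restricted to a TNM T-stage subset, and returns a
#' table ranked by CO score (ties broken by `P_true`). Features whose
#' dichotomy is degenerate (constant expression, median ties, unsatisfiable
#' cluster sizes) are skipped with a machine-readable reason rather than
#' aborting the run.
#'
#' @param expression data frame, first column `sample_id`, remaining columns
#'   one feature each (log2 expression).
#' @param clinical clinical data frame (see [evaluate_feature()]); may also
#'   carry a `stage` column used by `stage_filter`.
#' @param config a [score_config()].
#' @param stage_filter optional TNM T category (e.g. `"T1"`); when given,
#'   scoring is restricted to samples of that stage.
#' @param endpoints optional subset of endpoints to score (default: all
#'   present).
#' @return data frame as in [evaluate_feature()] plus a `rank` column per
#'   endpoint, ordered by (`endpoint`, `co`, `p_true`); skipped features are
#'   recorded in `attr(, "skipped")` as a data frame
#'   (`feature_id`, `endpoint`, `reason`).
#' @export
evaluate_dataset <- function(expression, clinical, config = score_config(),
                             stage_filter = NULL, endpoints = NULL) {
  if (!is.data.frame(expression) || names(expression)[1] != "sample_id") {
    abort_coscore("`expression` must be a data frame with first column sample_id",
                  "validation_error")
  }
  if (!is.null(stage_filter)) {
    if (!"stage" %in% names(clinical)) {
      abort_coscore("stage filter requested but clinical table has no `stage` column",
                    "validation_error")
    }
    clinical <- clinical[!is.na(clinical$stage) & clinical$stage == stage_filter, ,
                         drop = FALSE]
    if (nrow(clinical) == 0L) {
      abort_coscore(sprintf("no samples with stage %s", stage_filter), "validation_error")
    }
  }
  if (!is.null(endpoints)) {
    clinical <- clinical[clinical$endpoint %in% endpoints, , drop = FALSE]
  }
  if (!any(clinical$sample_id %in% expression$sample_id)) {
    abort_coscore("expression and clinical tables share no sample ids", "data_error")
  }

  features <- names(expression)[-1]
  skipped <- list()
  rows <- list()
  for (f in features) {
    v <- stats::setNames(expression[[f]], expression$sample_id)
    res <- tryCatch(
      evaluate_feature(v, clinical, config, feature_id = f),
      coscore_error = function(e) {
        skipped[[length(skipped) + 1L]] <<- data.frame(
          feature_id = f, endpoint = NA_character_,
          reason = conditionMessage(e), stringsAsFactors = FALSE)
        NULL
      })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0L) {
    abort_coscore("every feature was skipped; nothing to rank", "data_error")
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$endpoint, out$co, out$p_true, out$feature_id), , drop = FALSE]
  out$rank <- stats::ave(seq_len(nrow(out)), out$endpoint, FUN = seq_along)
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(feature_id = character(), endpoint = character(),
               reason = character(), stringsAsFactors = FALSE)
  out
}
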