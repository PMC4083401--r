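# Multi-cohort clinical harmonization: deduplicate, map heterogeneous raw
# outcome fields onto standardized survival/metastasis records in months,
# split cohorts into test/validation by publication year, subset by T stage.

#' Deduplicate a multi-cohort sample table
#'
#' Keeps one record per `sample_id` and drops samples carrying no outcome
#' information at all (every listed outcome field missing). When duplicated
#' ids disagree in their outcome fields, the copy from the highest-priority
#' cohort is kept and the conflict is reported.
#'
#' @param samples data frame with `sample_id`, `cohort`, and raw outcome
#'   columns.
#' @param outcome_fields character vector naming the raw outcome columns
#'   that define "has outcome information".
#' @param cohort_priority optional character vector; earlier cohorts win
#'   conflicts (default: order of first appearance).
#' @return deduplicated data frame with `attr(, "report")`: a list with
#'   `n_input`, `n_duplicates_removed`, `n_no_outcome`, `n_conflicts`, and
#'   `conflicts` (the conflicting sample ids).
#' @export
deduplicate <- function(samples, outcome_fields, cohort_priority = NULL) {
  if (!all(c("sample_id", "cohort") %in% names(samples))) {
    abort_coscore("samples must have sample_id and cohort columns", "validation_error")
  }
  missing_fields <- setdiff(outcome_fields, names(samples))
  if (length(missing_fields)) {
    abort_coscore(paste("outcome fields absent from table:",
                        paste(missing_fields, collapse = ", ")), "validation_error")
  }
  n_input <- nrow(samples)

  has_outcome <- rowSums(!is.na(samples[, outcome_fields, drop = FALSE])) > 0
  n_no_outcome <- sum(!has_outcome)
  samples <- samples[has_outcome, , drop = FALSE]

  if (is.null(cohort_priority)) cohort_priority <- unique(samples$cohort)
  pr <- match(samples$cohort, cohort_priority)
  pr[is.na(pr)] <- length(cohort_priority) + 1L
  samples <- samples[order(pr, seq_len(nrow(samples))), , drop = FALSE]

  dup <- duplicated(samples$sample_id)
  # a duplicate conflicts if any outcome field differs from the kept copy
  conflicts <- character()
  if (any(dup)) {
    kept <- samples[!dup, , drop = FALSE]
    for (id in unique(samples$sample_id[dup])) {
      grp <- samples[samples$sample_id == id, outcome_fields, drop = FALSE]
      if (nrow(unique(grp)) > 1L) conflicts <- c(conflicts, id)
    }
    if (length(conflicts)) {
      warn_coscore(sprintf("conflicting duplicate outcome(s) for %s; kept highest-priority cohort copy",
                           paste(conflicts, collapse = ", ")), "duplicate_conflict")
    }
  }
  out <- samples[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- list(n_input = n_input,
                              n_duplicates_removed = sum(dup),
                              n_no_outcome = n_no_outcome,
                              n_conflicts = length(conflicts),
                              conflicts = conflicts)
  out
}

#' Standardize heterogeneous raw outcomes into survival/metastasis records
#'
#' Each cohort names its clinical fields differently; the mapping declares,
#' per cohort and endpoint, which raw columns carry the follow-up time and
#' event indicator and in which unit the time is expressed. Every sample
#' gains up to two standardized records (one per endpoint), with times
#' converted to months. A sample lacking the raw fields of one endpoint
#' simply contributes no record for it and stays usable for the other. Each
#' output row carries a `provenance` column naming the raw fields it came
#' from, so no standardized event is ever invented.
#'
#' @param samples deduplicated data frame with `sample_id`, `cohort` and the
#'   cohorts' raw columns; `stage` and `pub_year` are carried through when
#'   present.
#' @param mapping named list, one entry per cohort, each a named list over
#'   endpoints (`survival`, `metastasis`) of
#'   `list(time = <column>, event = <column>, unit = "months"|"years"|"days")`.
#' @return standardized clinical data frame (`sample_id`, `endpoint`,
#'   `time`, `event`, `stage`, `cohort`, `pub_year`, `provenance`) with
#'   `attr(, "n_unmapped")` counting sample x endpoint slots with missing
#'   raw values.
#' @export
standardize_outcomes <- function(samples, mapping) {
  cohorts <- unique(samples$cohort)
  absent <- setdiff(cohorts, names(mapping))
  if (length(absent)) {
    abort_coscore(paste("no outcome mapping for cohort(s):",
                        paste(absent, collapse = ", ")), "validation_error")
  }
  unit_factor <- c(months = 1, years = 12, days = 1 / 30.4375)

  rows <- list()
  n_unmapped <- 0L
  for (co in cohorts) {
    sub <- samples[samples$cohort == co, , drop = FALSE]
    for (ep in names(mapping[[co]])) {
      spec_ep <- mapping[[co]][[ep]]
      if (!all(c("time", "event", "unit") %in% names(spec_ep)) ||
          !spec_ep$unit %in% names(unit_factor)) {
        abort_coscore(sprintf("mapping for cohort %s endpoint %s must give time, event and a unit in {months, years, days}",
                              co, ep), "validation_error")
      }
      if (!all(c(spec_ep$time, spec_ep$event) %in% names(sub))) {
        abort_coscore(sprintf("cohort %s: mapped column(s) %s/%s not in table",
                              co, spec_ep$time, spec_ep$event), "validation_error")
      }
      tv <- sub[[spec_ep$time]]
      ev <- sub[[spec_ep$event]]
      usable <- !is.na(tv) & !is.na(ev)
      n_unmapped <- n_unmapped + sum(!usable)
      if (!any(usable)) next
      tv <- as.numeric(tv[usable]) * unit_factor[[spec_ep$unit]]
      ev <- as.integer(ev[usable])
      if (any(tv < 0)) {
        abort_coscore(sprintf("cohort %s endpoint %s: negative follow-up time", co, ep),
                      "validation_error")
      }
      if (!all(ev %in% c(0L, 1L))) {
        abort_coscore(sprintf("cohort %s endpoint %s: event indicator must be 0/1", co, ep),
                      "validation_error")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sub$sample_id[usable],
        endpoint = ep,
        time = tv,
        event = ev,
        stage = if ("stage" %in% names(sub)) sub$stage[usable] else NA_character_,
        cohort = co,
        pub_year = if ("pub_year" %in% names(sub)) sub$pub_year[usable] else NA_integer_,
        provenance = paste(spec_ep$time, spec_ep$event, sep = "/"),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    abort_coscore("no usable outcome records after standardization", "data_error")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Split a meta-dataset into test and validation groups by publication year
#'
#' The split is by whole cohort, never within a cohort: cohorts published in
#' or before `year_threshold` form the test group, later cohorts the
#' validation group. Requiring a hit to replicate across the two
#' independently assembled groups is the pipeline's guard against
#' cohort-specific artifacts.
#'
#' @param clinical data frame with `cohort` and `pub_year` columns (e.g. the
#'   output of [standardize_outcomes()]).
#' @param year_threshold last publication year assigned to the test group
#'   (default 2009).
#' @return list with `test` and `validation` data frames; row counts always
#'   sum to the input count.
#' @export
split_test_validation <- function(clinical, year_threshold = 2009) {
  if (!all(c("cohort", "pub_year") %in% names(clinical))) {
    abort_coscore("clinical table must have cohort and pub_year columns",
                  "validation_error")
  }
  if (anyNA(clinical$pub_year)) {
    bad <- unique(clinical$cohort[is.na(clinical$pub_year)])
    abort_coscore(paste("cohort(s) missing pub_year:", paste(bad, collapse = ", ")),
                  "validation_error")
  }
  in_test <- clinical$pub_year <= year_threshold
  if (!any(in_test) || all(in_test)) {
    warn_coscore("publication-year split leaves one group empty", "degenerate_split")
  }
  list(test = clinical[in_test, , drop = FALSE],
       validation = clinical[!in_test, , drop = FALSE])
}

#' Subset clinical records to one TNM T category
#'
#' Keeps the samples whose primary-tumor category equals `category`
#' (default `"T1"`, the early-stage subset used to ask whether an
#' association is already present in small tumors). Records with missing
#' stage are excluded and counted.
#'
#' @param clinical data frame with a `stage` column.
#' @param category TNM T category to keep.
#' @return the subset, with `attr(, "n_missing_stage")`; a warning is issued
#'   when the subset is empty.
#' @export
subset_early_stage <- function(clinical, category = "T1") {
  if (!"stage" %in% names(clinical)) {
    abort_coscore("clinical table has no `stage` column", "validation_error")
  }
  missing <- is.na(clinical$stage)
  out <- clinical[!missing & clinical$stage == category, , drop = FALSE]
  if (nrow(out) == 0L) {
    warn_coscore(sprintf("no samples with stage %s", category), "empty_subset")
  }
  rownames(out) <- NULL
  attr(out, "n_missing_stage") <- sum(missing)
  out
}
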