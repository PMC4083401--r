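#' Filter a gene-level differential-expression table
#'
#' Retains genes passing the significance and fold-change thresholds with
#' strict inequalities: `fdr < fdr_max` and `log2fc > lfc_min`
#' (`direction = "up"`, the default, keeps only up-regulated genes) or
#' `|log2fc| > lfc_min` (`direction = "both"`). Rows sitting exactly on a
#' threshold are excluded.
#'
#' @param records data frame with columns `feature_id`, `log2fc`, `fdr`
#'   (optionally `pvalue`, `level`).
#' @param fdr_max FDR threshold (default 0.1, i.e. FDR < 10%).
#' @param lfc_min log2 fold-change threshold (default 1).
#' @param direction `"up"` or `"both"`.
#' @return the retained subset of `records`.
#' @export
filter_gene_level <- function(records, fdr_max = 0.1, lfc_min = 1,
                              direction = c("up", "both")) {
  direction <- match.arg(direction)
  check_de_table(records)
  if (nrow(records) == 0L) {
    warn_coscore("empty differential-expression table; nothing to filter",
                 "empty_input")
    return(records)
  }
  fc_ok <- if (direction == "up") records$log2fc > lfc_min else
    abs(records$log2fc) > lfc_min
  out <- records[records$fdr < fdr_max & fc_ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse an exon-level differential-expression table to qualifying genes
#'
#' Returns the genes having at least one exon passing `fdr < fdr_max` (and,
#' by default, `|log2fc| > lfc_min`; set `use_lfc = FALSE` to apply the FDR
#' criterion alone).
#'
#' @param records exon-level data frame; must carry a `gene_id` grouping
#'   column in addition to the `DERecord` columns.
#' @param fdr_max FDR threshold (default 0.1).
#' @param lfc_min log2 fold-change threshold (default 1).
#' @param use_lfc apply the fold-change criterion as well as FDR (default
#'   `TRUE`).
#' @return character vector of unique gene ids with >= 1 differential exon.
#' @export
filter_exon_level <- function(records, fdr_max = 0.1, lfc_min = 1,
                              use_lfc = TRUE) {
  check_de_table(records)
  if (!"gene_id" %in% names(records)) {
    abort_coscore("exon-level records must carry a `gene_id` column", "validation_error")
  }
  if (nrow(records) == 0L) return(character())
  pass <- records$fdr < fdr_max
  if (use_lfc) pass <- pass & abs(records$log2fc) > lfc_min
  sort(unique(records$gene_id[pass]))
}

check_de_table <- function(records) {
  need <- c("feature_id", "log2fc", "fdr")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    abort_coscore("DE table must have columns feature_id, log2fc, fdr",
                  "validation_error")
  }
  if (nrow(records) > 0 && (any(records$fdr < 0, na.rm = TRUE) ||
                            any(records$fdr > 1, na.rm = TRUE))) {
    abort_coscore("`fdr` values must lie in [0, 1]", "validation_error")
  }
}

#' Restrict candidates to secreted/membrane proteins with a human ortholog
#'
#' Keeps features annotated to the plasma membrane or the secreted
#' compartment and, optionally, having a human ortholog — the accessibility
#' filter that makes a candidate targetable by antibodies and translatable
#' to patient cohorts. Features absent from the annotation are treated as
#' compartment `"other"` (and dropped) with a warning listing the coverage
#' gap.
#'
#' @param features character vector of feature ids to filter.
#' @param annotation data frame with columns `feature_id`, `compartment`
#'   (one of `"plasma_membrane"`, `"secreted"`, `"other"`), `human_ortholog`
#'   (`NA`/empty when absent).
#' @param require_ortholog drop features lacking a human ortholog (default
#'   `TRUE`).
#' @return data frame of retained features with their `compartment` and
#'   `human_ortholog`.
#' @export
annotate_compartment <- function(features, annotation, require_ortholog = TRUE) {
  need <- c("feature_id", "compartment", "human_ortholog")
  if (!is.data.frame(annotation) || !all(need %in% names(annotation))) {
    abort_coscore("annotation must have feature_id, compartment, human_ortholog",
                  "validation_error")
  }
  idx <- match(features, annotation$feature_id)
  missing <- features[is.na(idx)]
  if (length(missing)) {
    warn_coscore(sprintf("%d feature(s) missing from annotation, treated as compartment 'other': %s",
                         length(missing), paste(missing, collapse = ", ")),
                 "annotation_gap")
  }
  out <- data.frame(
    feature_id = features,
    compartment = ifelse(is.na(idx), "other", annotation$compartment[idx]),
    human_ortholog = ifelse(is.na(idx), NA_character_, annotation$human_ortholog[idx]),
    stringsAsFactors = FALSE
  )
  keep <- out$compartment %in% c("plasma_membrane", "secreted")
  if (require_ortholog) {
    keep <- keep & !is.na(out$human_ortholog) & nzchar(out$human_ortholog)
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
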