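#' Assemble an end-to-end pipeline configuration
#'
#' Collects the inputs and parameters for [run_pipeline()]. Every table
#' argument accepts either a data frame or a path to a TSV in the package's
#' table formats; `expression` and `clinical` are required, the rest switch
#' their stage on when supplied.
#'
#' @param expression samples x features log2 expression table (or path).
#' @param clinical standardized clinical table (or path); must carry
#'   `cohort` and `pub_year` for the test/validation split.
#' @param de_gene optional gene-level differential-expression table used to
#'   pre-select candidate features.
#' @param compartment_annotation optional annotation for
#'   [annotate_compartment()].
#' @param fusion_mt,fusion_wt optional lists of tumor/control fusion-call
#'   tables.
#' @param gene_models gene models for fusion classification (required when
#'   fusion tables are given).
#' @param score a [score_config()].
#' @param fdr_max,lfc_min,direction thresholds for [filter_gene_level()].
#' @param require_ortholog passed to [annotate_compartment()].
#' @param stage_filter TNM T category scored in addition to the full cohort
#'   (default `"T1"`; `NULL` disables the stage-restricted pass).
#' @param year_threshold cohort split year for [split_test_validation()].
#' @param readthrough_max_gap passed to [run_fusion_filter()].
#' @param out_dir output directory; `NULL` keeps results in memory only.
#' @param overwrite allow writing into a non-empty `out_dir`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, clinical, de_gene = NULL,
                            compartment_annotation = NULL,
                            fusion_mt = NULL, fusion_wt = NULL,
                            gene_models = NULL,
                            score = score_config(),
                            fdr_max = 0.1, lfc_min = 1, direction = "up",
                            require_ortholog = TRUE,
                            stage_filter = "T1", year_threshold = 2009,
                            readthrough_max_gap = 200000,
                            out_dir = NULL, overwrite = FALSE) {
  if (missing(expression) || is.null(expression)) {
    abort_coscore("`expression` is required", "validation_error")
  }
  if (missing(clinical) || is.null(clinical)) {
    abort_coscore("`clinical` is required", "validation_error")
  }
  structure(list(
    expression = expression, clinical = clinical, de_gene = de_gene,
    compartment_annotation = compartment_annotation,
    fusion_mt = fusion_mt, fusion_wt = fusion_wt, gene_models = gene_models,
    score = score, fdr_max = fdr_max, lfc_min = lfc_min,
    direction = direction, require_ortholog = require_ortholog,
    stage_filter = stage_filter, year_threshold = year_threshold,
    readthrough_max_gap = readthrough_max_gap,
    out_dir = out_dir, overwrite = overwrite
  ), class = "pipeline_config")
}

load_table <- function(x, reader = read_tsv_table) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

#' Run the candidate-prioritization pipeline end to end
#'
#' Executes, in order: candidate selection from the gene-level
#' differential-expression table (threshold filter, then the
#' secreted/membrane + ortholog filter when an annotation is supplied);
#' cohort-level test/validation split of the clinical table by publication
#' year; CO scoring of the candidate features on each split, for every
#' endpoint present, on the full cohort and on the `stage_filter` subset;
#' and, when fusion inputs are given, the fusion post-filter. A manifest of
#' every parameter and seed is included (and written) so a run can be
#' reproduced exactly; with a fixed seed, reruns are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with `candidates`, `co_tables` (named
#'   `<split>` / `<split>_<stage>`), `fusion` (audit + retained, or `NULL`),
#'   `split_sizes`, and `manifest`. When `config$out_dir` is set each table
#'   is also written there as TSV.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort_coscore("`config` must come from pipeline_config()", "validation_error")
  }
  expression <- load_table(config$expression, read_expression_table)
  names(expression)[1] <- "sample_id"
  clinical <- load_table(config$clinical, read_clinical_table)

  # -- candidate selection -------------------------------------------------
  candidates <- NULL
  if (!is.null(config$de_gene)) {
    de <- load_table(config$de_gene)
    candidates <- filter_gene_level(de, fdr_max = config$fdr_max,
                                    lfc_min = config$lfc_min,
                                    direction = config$direction)
    if (!is.null(config$compartment_annotation)) {
      ann <- load_table(config$compartment_annotation)
      kept <- annotate_compartment(candidates$feature_id, ann,
                                   require_ortholog = config$require_ortholog)
      candidates <- merge(candidates, kept, by = "feature_id", sort = TRUE)
    }
    feature_cols <- intersect(names(expression)[-1], candidates$feature_id)
    if (length(feature_cols) == 0L) {
      abort_coscore("no candidate feature has an expression column", "data_error")
    }
    expression <- expression[, c("sample_id", feature_cols), drop = FALSE]
  }

  # -- split and score -----------------------------------------------------
  if (!all(c("cohort", "pub_year") %in% names(clinical))) {
    abort_coscore("clinical table needs cohort and pub_year for the split",
                  "validation_error")
  }
  splits <- split_test_validation(clinical, config$year_threshold)
  splits <- Filter(function(s) nrow(s) > 0, splits)

  co_tables <- list()
  for (split_name in names(splits)) {
    cl <- splits[[split_name]]
    co_tables[[split_name]] <-
      evaluate_dataset(expression, cl, config$score)
    if (!is.null(config$stage_filter)) {
      co_tables[[paste0(split_name, "_", config$stage_filter)]] <-
        evaluate_dataset(expression, cl, config$score,
                         stage_filter = config$stage_filter)
    }
  }

  # -- fusion post-filter --------------------------------------------------
  fusion <- NULL
  if (!is.null(config$fusion_mt)) {
    if (is.null(config$gene_models)) {
      abort_coscore("fusion filtering requires `gene_models`", "validation_error")
    }
    mt <- lapply(if (is.data.frame(config$fusion_mt)) list(config$fusion_mt) else
      config$fusion_mt, load_table)
    wt <- lapply(if (is.data.frame(config$fusion_wt)) list(config$fusion_wt) else
      if (is.null(config$fusion_wt)) list() else config$fusion_wt, load_table)
    fusion <- run_fusion_filter(mt, wt, load_table(config$gene_models),
                                readthrough_max_gap = config$readthrough_max_gap)
  }

  manifest <- data.frame(
    key = c("package_version", "seed", "n_repetitions", "removal_fraction",
            "min_cluster_size", "fdr_max", "lfc_min", "direction",
            "require_ortholog", "stage_filter", "year_threshold",
            "readthrough_max_gap", "n_samples_expression", "n_features_scored",
            paste0("n_records_", names(splits))),
    value = as.character(c(
      as.character(utils::packageVersion("coscore")),
      config$score$seed, config$score$n_repetitions,
      config$score$removal_fraction, config$score$min_cluster_size,
      config$fdr_max, config$lfc_min, config$direction,
      config$require_ortholog,
      if (is.null(config$stage_filter)) "none" else config$stage_filter,
      config$year_threshold, config$readthrough_max_gap,
      nrow(expression), ncol(expression) - 1L,
      vapply(splits, nrow, integer(1)))),
    stringsAsFactors = FALSE
  )

  result <- list(candidates = candidates, co_tables = co_tables,
                 fusion = fusion,
                 split_sizes = vapply(splits, function(s)
                   length(unique(s$sample_id)), integer(1)),
                 manifest = manifest)

  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(result, config$out_dir, config$overwrite)
  }
  invisible(result)
}

write_pipeline_outputs <- function(result, out_dir, overwrite) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite) {
    abort_coscore(sprintf("output directory %s is non-empty; set overwrite = TRUE to replace",
                          out_dir), "validation_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(result$candidates)) {
    write_tsv_table(result$candidates, file.path(out_dir, "candidates.tsv"))
  }
  for (nm in names(result$co_tables)) {
    write_tsv_table(result$co_tables[[nm]],
                    file.path(out_dir, paste0("co_", nm, ".tsv")))
  }
  if (!is.null(result$fusion)) {
    write_tsv_table(result$fusion$audit, file.path(out_dir, "fusion_audit.tsv"))
    write_tsv_table(result$fusion$retained,
                    file.path(out_dir, "fusion_retained.tsv"))
  }
  write_tsv_table(result$manifest, file.path(out_dir, "manifest.tsv"))
  invisible(out_dir)
}
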