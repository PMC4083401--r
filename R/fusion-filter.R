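# Fusion-call post-filtering. Call identity throughout is the ordered
# (gene5p, gene3p) pair: upstream callers report several breakpoints per
# pair, and replicate concordance / artifact reasoning operates at gene-pair
# level.

fusion_key <- function(calls) paste(calls$gene5p, calls$gene3p, sep = "\r")

check_fusion_table <- function(calls) {
  if (!is.data.frame(calls) || !all(c("gene5p", "gene3p") %in% names(calls))) {
    abort_coscore("fusion call table must have columns gene5p and gene3p",
                  "validation_error")
  }
}

# one row per (gene5p, gene3p) pair; numeric fields summarized symmetrically
collapse_pairs <- function(calls) {
  check_fusion_table(calls)
  if (nrow(calls) == 0L) {
    return(calls[, intersect(c("gene5p", "gene3p", "support_reads"), names(calls)),
                 drop = FALSE])
  }
  key <- fusion_key(calls)
  first <- !duplicated(key)
  out <- calls[first, setdiff(names(calls), c("replicate_id", "support_reads")),
               drop = FALSE]
  if ("support_reads" %in% names(calls)) {
    out$support_reads <- as.integer(tapply(calls$support_reads, key, min)[key[first]])
  }
  rownames(out) <- NULL
  out
}

#' Intersect fusion calls between two replicates
#'
#' Keeps the putative fusions whose ordered (5', 3') gene pair is reported in
#' both replicates; everything seen in only one replicate is treated as a
#' likely caller artifact. Symmetric in its two arguments. When several
#' breakpoints are reported for one gene pair they are collapsed to a single
#' pair-level row (minimum supporting reads across calls).
#'
#' @param calls_rep1,calls_rep2 call data frames with at least `gene5p`,
#'   `gene3p` (optionally the full call-table columns).
#' @return pair-level data frame of the common calls.
#' @export
intersect_replicates <- function(calls_rep1, calls_rep2) {
  a <- collapse_pairs(calls_rep1)
  b <- collapse_pairs(calls_rep2)
  common <- intersect(fusion_key(a), fusion_key(b))
  pooled <- rbind(a[fusion_key(a) %in% common, , drop = FALSE],
                  b[fusion_key(b) %in% common, , drop = FALSE])
  collapse_pairs(pooled[order(fusion_key(pooled)), , drop = FALSE])
}

#' Remove tumor fusion calls that also appear in any control replicate
#'
#' A putative tumor-specific fusion reported in wild-type tissue as well is
#' not somatic; such calls are classified `control_shared` and set aside.
#' The union over all control replicates is used — a pair reported by any
#' control removes the tumor call.
#'
#' @param mt_common pair-level tumor calls (e.g. from
#'   [intersect_replicates()]).
#' @param wt_calls a call data frame or list of per-replicate data frames
#'   from control tissue.
#' @return list with `retained` (tumor-specific pairs) and `control_shared`
#'   (removed pairs, with `classification` set).
#' @export
subtract_control <- function(mt_common, wt_calls) {
  mt_common <- collapse_pairs(mt_common)
  if (is.data.frame(wt_calls)) wt_calls <- list(wt_calls)
  wt_keys <- unique(unlist(lapply(wt_calls, function(w) {
    check_fusion_table(w)
    fusion_key(w)
  })))
  shared <- fusion_key(mt_common) %in% wt_keys
  removed <- mt_common[shared, , drop = FALSE]
  if (nrow(removed)) removed$classification <- "control_shared"
  list(retained = mt_common[!shared, , drop = FALSE], control_shared = removed)
}

#' Classify a fusion call as read-through, homologue pair, or retained
#'
#' Applies the two artifact rules that explain most recurrent false fusion
#' calls:
#'
#' * **read-through** — the partners lie on the same chromosome and strand,
#'   do not overlap, appear in transcriptional order (the 5' partner
#'   upstream of the 3' partner in strand orientation), and are separated by
#'   at most `readthrough_max_gap` bases: the chimera is parsimoniously a
#'   transcript running through adjacent genes, not a rearrangement.
#' * **homologue pair** — the partners share a homology group: chimeric
#'   reads between paralogues are typically mapping artifacts.
#'
#' Anything else is `retained` as a candidate somatic fusion. Calls whose
#' partners are missing from the gene models are flagged `unclassifiable`
#' (and kept downstream) with a warning.
#'
#' @param call one-row data frame (or list) with `gene5p`, `gene3p`.
#' @param models gene-model data frame: `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `homology_group` (`NA` when the gene
#'   belongs to no family).
#' @param readthrough_max_gap maximum intergenic gap (bases) for the
#'   read-through call; default 200000.
#' @param adjacent_only if `TRUE`, additionally require that no other
#'   annotated gene lies strictly between the partners on the same strand.
#' @return one of `"read_through"`, `"homologue_pair"`, `"retained"`,
#'   `"unclassifiable"`.
#' @export
classify_artifact <- function(call, models, readthrough_max_gap = 200000,
                              adjacent_only = FALSE) {
  g5 <- models[models$gene_id == call$gene5p, , drop = FALSE]
  g3 <- models[models$gene_id == call$gene3p, , drop = FALSE]
  if (nrow(g5) == 0L || nrow(g3) == 0L) {
    warn_coscore(sprintf("fusion partner(s) missing from gene models: %s",
                         paste(setdiff(c(call$gene5p, call$gene3p), models$gene_id),
                               collapse = ", ")),
                 "unclassifiable_call")
    return("unclassifiable")
  }
  g5 <- g5[1, ]; g3 <- g3[1, ]

  if (g5$chrom == g3$chrom && g5$strand == g3$strand) {
    gap <- if (g5$strand == "+") g3$start - g5$end else g5$start - g3$end
    if (gap >= 0 && gap <= readthrough_max_gap) {
      intervening <- if (adjacent_only) {
        lo <- min(g5$end, g3$end); hi <- max(g5$start, g3$start)
        any(models$chrom == g5$chrom & models$strand == g5$strand &
              models$start >= lo & models$end <= hi &
              !models$gene_id %in% c(call$gene5p, call$gene3p))
      } else FALSE
      if (!intervening) return("read_through")
    }
  }
  if (!is.na(g5$homology_group) && !is.na(g3$homology_group) &&
      g5$homology_group == g3$homology_group) {
    return("homologue_pair")
  }
  "retained"
}

#' Run the full fusion post-filter
#'
#' Intersects calls across all tumor replicates, subtracts anything reported
#' in any control replicate, and classifies the survivors as read-through,
#' homologue-pair, or retained candidate somatic fusions. With a single
#' tumor replicate the intersection step is the identity (a warning is
#' issued, since replicate concordance is the main error control).
#'
#' @param mt_reps list of tumor-replicate call data frames (>= 1).
#' @param wt_reps list of control-replicate call data frames (possibly
#'   empty).
#' @param models gene models as in [classify_artifact()].
#' @param readthrough_max_gap,adjacent_only passed to [classify_artifact()].
#' @return list with `audit` (every replicate-common pair with its final
#'   `classification`) and `retained` (candidate somatic fusions, including
#'   unclassifiable calls kept conservatively).
#' @export
run_fusion_filter <- function(mt_reps, wt_reps = list(), models,
                              readthrough_max_gap = 200000,
                              adjacent_only = FALSE) {
  if (is.data.frame(mt_reps)) mt_reps <- list(mt_reps)
  if (is.data.frame(wt_reps)) wt_reps <- list(wt_reps)
  if (length(mt_reps) == 0L) {
    abort_coscore("at least one tumor replicate is required", "validation_error")
  }
  if (length(mt_reps) == 1L) {
    warn_coscore("single tumor replicate: replicate intersection is the identity",
                 "single_replicate")
    common <- collapse_pairs(mt_reps[[1]])
  } else {
    common <- Reduce(intersect_replicates, mt_reps)
  }

  sub <- if (length(wt_reps)) subtract_control(common, wt_reps) else
    list(retained = common,
         control_shared = common[0, , drop = FALSE])

  tumor_specific <- sub$retained
  cls <- if (nrow(tumor_specific)) {
    vapply(seq_len(nrow(tumor_specific)), function(i) {
      classify_artifact(tumor_specific[i, , drop = FALSE], models,
                        readthrough_max_gap, adjacent_only)
    }, character(1))
  } else character()
  tumor_specific$classification <- cls

  audit <- rbind(tumor_specific, if (nrow(sub$control_shared)) sub$control_shared)
  rownames(audit) <- NULL
  list(audit = audit,
       retained = tumor_specific[cls %in% c("retained", "unclassifiable"), ,
                                 drop = FALSE])
}
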