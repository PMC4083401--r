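#' Configuration for the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated expression/outcome cohort:
#' each feature's expression is a two-component Gaussian mixture (a low and a
#' high component separated by `mixture_delta` on the log2 scale), and event
#' times are exponential with a hazard that, for "true" outcome-associated
#' features, is multiplied by `hazard_ratio` in the high-expression group.
#' Follow-up is administratively censored at `censor_time`.
#'
#' All "true" features share one latent risk partition of the samples (their
#' mixture membership is that partition); null features draw independent
#' memberships, so their expression is independent of outcome.
#'
#' @param n_samples number of samples.
#' @param n_features number of expression features.
#' @param frac_true fraction of features truly associated with outcome
#'   (`round(frac_true * n_features)` features, chosen at random).
#' @param hazard_ratio hazard multiplier for high-expression samples of true
#'   features (> 0).
#' @param baseline_rate events per month in the low-expression group.
#' @param mixture_delta separation of the two expression components (log2
#'   units).
#' @param mixture_sd common within-component standard deviation.
#' @param frac_up fraction of samples in the high-expression component, in
#'   (0, 1).
#' @param censor_time administrative censoring horizon (months).
#' @param endpoint_types subset of `c("survival", "metastasis")`.
#' @param seed master integer seed; per-feature and per-endpoint sub-streams
#'   are derived from it, so adding features never perturbs existing ones.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 300L, n_features = 10L,
                              frac_true = 0.2, hazard_ratio = 4,
                              baseline_rate = 0.02, mixture_delta = 4,
                              mixture_sd = 1, frac_up = 0.3,
                              censor_time = 60,
                              endpoint_types = c("survival", "metastasis"),
                              seed = 1L) {
  chk <- function(ok, field, what) {
    if (!ok) abort_coscore(sprintf("`%s` %s", field, what), "validation_error")
  }
  scalar_ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(is_count(n_samples), "n_samples", "must be a positive integer")
  chk(is_count(n_features), "n_features", "must be a positive integer")
  chk(scalar_ok(frac_true) && frac_true >= 0 && frac_true <= 1,
      "frac_true", "must lie in [0, 1]")
  chk(scalar_ok(hazard_ratio) && hazard_ratio > 0, "hazard_ratio", "must be > 0")
  chk(scalar_ok(baseline_rate) && baseline_rate > 0, "baseline_rate", "must be > 0")
  chk(scalar_ok(mixture_delta) && mixture_delta >= 0, "mixture_delta", "must be >= 0")
  chk(scalar_ok(mixture_sd) && mixture_sd > 0, "mixture_sd", "must be > 0")
  chk(scalar_ok(frac_up) && frac_up > 0 && frac_up < 1, "frac_up", "must lie in (0, 1)")
  chk(scalar_ok(censor_time) && censor_time > 0, "censor_time", "must be > 0")
  chk(length(endpoint_types) >= 1 &&
        all(endpoint_types %in% c("survival", "metastasis")),
      "endpoint_types", "must be a non-empty subset of {survival, metastasis}")
  structure(list(
    n_samples = as.integer(n_samples), n_features = as.integer(n_features),
    frac_true = frac_true, hazard_ratio = hazard_ratio,
    baseline_rate = baseline_rate, mixture_delta = mixture_delta,
    mixture_sd = mixture_sd, frac_up = frac_up, censor_time = censor_time,
    endpoint_types = unique(endpoint_types), seed = as.integer(seed)
  ), class = "simulation_config")
}

# baseline mean of the low-expression component, log2 scale; typical
# mid-range microarray intensity
.base_expr_mean <- 6

#' Generate a synthetic expression/clinical cohort with known ground truth
#'
#' Draws a cohort per [simulation_config()]: a samples-by-features log2
#' expression table, a long clinical table with one row per sample and
#' endpoint (time, 0/1 event, TNM T stage, cohort, publication year), and a
#' truth table flagging which features were generated with a real outcome
#' association. Samples are assigned to three synthetic cohorts with
#' publication years on both sides of 2009 so the cohort-level
#' test/validation split is exercised.
#'
#' @param config a [simulation_config()].
#' @return list of class `synthetic_cohort` with elements `expression`,
#'   `clinical`, `truth`, and `latent_risk` (the generating UP/DOWN
#'   partition shared by true features).
#' @export
generate_cohort <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config")) config <- do.call(simulation_config, config)
  n <- config$n_samples
  p <- config$n_features
  sample_ids <- sprintf("S%04d", seq_len(n))
  feature_ids <- sprintf("gene_%03d", seq_len(p))

  cohort_defs <- data.frame(
    cohort = c("cohort_A", "cohort_B", "cohort_C"),
    pub_year = c(2006L, 2008L, 2012L),
    stringsAsFactors = FALSE
  )

  sample_frame <- with_seed(derive_seed(config$seed, "samples"), {
    latent <- ifelse(stats::runif(n) < config$frac_up, "UP", "DOWN")
    stage <- sample(c("T1", "T2", "T3", "T4"), n, replace = TRUE,
                    prob = c(0.45, 0.35, 0.15, 0.05))
    cohort_idx <- sample(1:3, n, replace = TRUE, prob = c(0.35, 0.35, 0.30))
    data.frame(sample_id = sample_ids, latent = latent, stage = stage,
               cohort = cohort_defs$cohort[cohort_idx],
               pub_year = cohort_defs$pub_year[cohort_idx],
               stringsAsFactors = FALSE)
  })

  n_true <- round(config$frac_true * p)
  true_idx <- with_seed(derive_seed(config$seed, "truth"),
                        sort(sample.int(p, n_true)))
  is_true <- seq_len(p) %in% true_idx

  expr <- matrix(NA_real_, nrow = n, ncol = p,
                 dimnames = list(sample_ids, feature_ids))
  for (j in seq_len(p)) {
    expr[, j] <- with_seed(derive_seed(config$seed, "feature", feature_ids[j]), {
      member <- if (is_true[j]) {
        sample_frame$latent == "UP"
      } else {
        stats::runif(n) < config$frac_up
      }
      stats::rnorm(n, mean = .base_expr_mean + config$mixture_delta * member,
                   sd = config$mixture_sd)
    })
  }

  risk_rate <- config$baseline_rate *
    ifelse(sample_frame$latent == "UP" & n_true > 0, config$hazard_ratio, 1)
  clinical <- do.call(rbind, lapply(config$endpoint_types, function(ep) {
    with_seed(derive_seed(config$seed, "endpoint", ep), {
      raw <- stats::rexp(n, rate = risk_rate)
      data.frame(sample_id = sample_ids, endpoint = ep,
                 time = pmin(raw, config$censor_time),
                 event = as.integer(raw <= config$censor_time),
                 stage = sample_frame$stage,
                 cohort = sample_frame$cohort,
                 pub_year = sample_frame$pub_year,
                 stringsAsFactors = FALSE)
    })
  }))
  rownames(clinical) <- NULL

  structure(list(
    expression = data.frame(sample_id = sample_ids, expr,
                            stringsAsFactors = FALSE, check.names = FALSE),
    clinical = clinical,
    truth = data.frame(feature_id = feature_ids, is_true_target = is_true,
                       true_hazard_ratio = ifelse(is_true, config$hazard_ratio, 1),
                       stringsAsFactors = FALSE),
    latent_risk = stats::setNames(sample_frame$latent, sample_ids),
    config = config
  ), class = "synthetic_cohort")
}

#' Generate a fusion-call fixture with planted event classes
#'
#' Builds two tumor (MT) and two wild-type (WT) replicate call tables, a gene
#' annotation, and the expected retained set, with known composition:
#'
#' * `n_common` genuine inter-chromosomal events present in both MT
#'   replicates and absent from WT — exactly the calls a correct filter
#'   retains;
#' * `n_mt_only_single` events in a single MT replicate (removed by
#'   replicate intersection);
#' * `n_wt_shared` events present in MT and WT replicates (removed by
#'   control subtraction);
#' * `n_readthrough` replicate-common, WT-absent events between adjacent
#'   same-strand genes (discarded as transcriptional read-through);
#' * `n_homologue` replicate-common, WT-absent events between genes sharing
#'   a homology group (discarded as homologue-pair artifacts).
#'
#' Setting `n_common = 0` with non-zero read-through/homologue counts
#' reproduces the situation where every replicate-concordant, tumor-specific
#' call is an artifact and the retained set is empty.
#'
#' @param n_common,n_mt_only_single,n_wt_shared,n_readthrough,n_homologue
#'   non-negative event counts.
#' @param seed integer seed for breakpoints and read support.
#' @return list with `mt` (list of 2 call data frames), `wt` (list of 2),
#'   `annotation`, and `expected_retained` (data frame of gene5p/gene3p
#'   pairs).
#' @export
generate_fusion_fixture <- function(n_common = 3L, n_mt_only_single = 2L,
                                    n_wt_shared = 2L, n_readthrough = 0L,
                                    n_homologue = 0L, seed = 1L) {
  counts <- c(n_common, n_mt_only_single, n_wt_shared, n_readthrough, n_homologue)
  if (any(!vapply(counts, function(x) is.numeric(x) && length(x) == 1 &&
                    is.finite(x) && x >= 0 && x == floor(x), logical(1)))) {
    abort_coscore("all event counts must be non-negative integers", "validation_error")
  }

  with_seed(seed, {
    genes <- list()
    calls <- list()  # each: gene5p, gene3p, class
    gi <- 0
    new_gene <- function(chrom, start, end, strand, homology = NA_character_) {
      gi <<- gi + 1
      id <- sprintf("gene%02d", gi)
      genes[[gi]] <<- data.frame(gene_id = id, chrom = chrom, start = start,
                                 end = end, strand = strand,
                                 homology_group = homology,
                                 stringsAsFactors = FALSE)
      id
    }
    # distinct-chromosome, distinct-family pairs for non-artifact events
    clean_pair <- function() {
      c(new_gene("chr1", s <- sample(1e6:5e7, 1), s + 2e4, "+"),
        new_gene("chr2", s2 <- sample(1e6:5e7, 1), s2 + 2e4, "-"))
    }
    add_calls <- function(pair, cls) {
      calls[[length(calls) + 1]] <<- data.frame(gene5p = pair[1], gene3p = pair[2],
                                                class = cls, stringsAsFactors = FALSE)
    }

    for (i in seq_len(n_common)) add_calls(clean_pair(), "common_clean")
    for (i in seq_len(n_mt_only_single)) add_calls(clean_pair(), "mt_single")
    for (i in seq_len(n_wt_shared)) add_calls(clean_pair(), "wt_shared")
    for (i in seq_len(n_readthrough)) {
      # adjacent same-strand genes, 10 kb apart, in transcriptional order
      s <- sample(1e6:5e7, 1)
      g5 <- new_gene("chr3", s, s + 3e4, "+")
      g3 <- new_gene("chr3", s + 4e4, s + 7e4, "+")
      add_calls(c(g5, g3), "read_through")
    }
    for (i in seq_len(n_homologue)) {
      grp <- sprintf("fam%02d", i)
      g5 <- new_gene("chr4", s <- sample(1e6:5e7, 1), s + 2e4, "+", grp)
      g3 <- new_gene("chr5", s2 <- sample(1e6:5e7, 1), s2 + 2e4, "+", grp)
      add_calls(c(g5, g3), "homologue")
    }
    # WT-only background noise so control tables are non-trivial
    wt_noise <- replicate(2, clean_pair(), simplify = FALSE)

    annotation <- do.call(rbind, genes)
    call_df <- if (length(calls)) do.call(rbind, calls) else
      data.frame(gene5p = character(), gene3p = character(), class = character(),
                 stringsAsFactors = FALSE)

    render <- function(pairs, replicate_id) {
      if (nrow(pairs) == 0L) {
        return(data.frame(replicate_id = character(), gene5p = character(),
                          chrom5p = character(), breakpoint5p = integer(),
                          strand5p = character(), gene3p = character(),
                          chrom3p = character(), breakpoint3p = integer(),
                          strand3p = character(), support_reads = integer(),
                          stringsAsFactors = FALSE))
      }
      a5 <- annotation[match(pairs$gene5p, annotation$gene_id), ]
      a3 <- annotation[match(pairs$gene3p, annotation$gene_id), ]
      data.frame(replicate_id = replicate_id,
                 gene5p = pairs$gene5p, chrom5p = a5$chrom,
                 breakpoint5p = a5$end, strand5p = a5$strand,
                 gene3p = pairs$gene3p, chrom3p = a3$chrom,
                 breakpoint3p = a3$start, strand3p = a3$strand,
                 support_reads = sample(3:50, nrow(pairs), replace = TRUE),
                 stringsAsFactors = FALSE)
    }

    in_both_mt <- call_df$class %in% c("common_clean", "wt_shared",
                                       "read_through", "homologue")
    mt1 <- render(call_df[in_both_mt | call_df$class == "mt_single", ], "MT_rep1")
    mt2 <- render(call_df[in_both_mt, ], "MT_rep2")
    wt_pairs <- call_df[call_df$class == "wt_shared", c("gene5p", "gene3p")]
    noise_df <- data.frame(gene5p = vapply(wt_noise, `[`, "", 1),
                           gene3p = vapply(wt_noise, `[`, "", 2),
                           stringsAsFactors = FALSE)
    wt1 <- render(rbind(wt_pairs, noise_df[1, ]), "WT_rep1")
    wt2 <- render(rbind(wt_pairs, noise_df[2, ]), "WT_rep2")

    list(mt = list(mt1, mt2), wt = list(wt1, wt2), annotation = annotation,
         expected_retained = call_df[call_df$class == "common_clean",
                                     c("gene5p", "gene3p"), drop = FALSE])
  })
}

#' Generate a differential-expression table with known pass/fail composition
#'
#' Plants rows so that exactly `n_pass` survive the up-regulation filter
#' (FDR < 0.1 and log2FC > 1). Boundary rows are planted deliberately: the
#' first FDR-failing row has FDR exactly 0.1 and the first fold-change-failing
#' row has log2FC exactly 1, pinning the strict-inequality semantics.
#'
#' @param n_pass rows passing the up-regulated filter.
#' @param n_fail_fdr up-regulated rows failing on FDR (first at FDR = 0.1).
#' @param n_fail_lfc low-FDR rows failing on fold change (first at log2FC = 1).
#' @param n_down significantly down-regulated rows (log2FC < -1, low FDR).
#' @param seed integer seed.
#' @return data frame with `feature_id`, `level`, `log2fc`, `pvalue`, `fdr`
#'   and the ground-truth column `expected_pass`.
#' @export
generate_de_table <- function(n_pass = 5L, n_fail_fdr = 3L, n_fail_lfc = 2L,
                              n_down = 4L, seed = 1L) {
  counts <- c(n_pass, n_fail_fdr, n_fail_lfc, n_down)
  if (any(counts < 0 | counts != floor(counts))) {
    abort_coscore("all row counts must be non-negative integers", "validation_error")
  }
  with_seed(seed, {
    mk <- function(k, lfc_lo, lfc_hi, fdr_lo, fdr_hi, tag, pass) {
      if (k == 0) return(NULL)
      data.frame(tag = tag,
                 log2fc = stats::runif(k, lfc_lo, lfc_hi),
                 fdr = stats::runif(k, fdr_lo, fdr_hi),
                 expected_pass = pass, stringsAsFactors = FALSE)
    }
    rows <- rbind(
      mk(n_pass, 1.2, 4, 0.001, 0.09, "pass", TRUE),
      mk(n_fail_fdr, 1.2, 4, 0.10, 0.9, "fail_fdr", FALSE),
      mk(n_fail_lfc, 0, 1, 0.001, 0.09, "fail_lfc", FALSE),
      mk(n_down, -4, -1.2, 0.001, 0.09, "down", FALSE)
    )
    if (is.null(rows)) {
      return(data.frame(feature_id = character(), level = character(),
                        log2fc = numeric(), pvalue = numeric(), fdr = numeric(),
                        expected_pass = logical(), stringsAsFactors = FALSE))
    }
    # pin the boundary rows exactly at the printed thresholds
    i <- which(rows$tag == "fail_fdr")
    if (length(i)) rows$fdr[i[1]] <- 0.1
    i <- which(rows$tag == "fail_lfc")
    if (length(i)) rows$log2fc[i[1]] <- 1
    data.frame(feature_id = sprintf("de_gene_%03d", seq_len(nrow(rows))),
               level = "gene",
               log2fc = rows$log2fc,
               pvalue = rows$fdr * stats::runif(nrow(rows), 0.3, 1),
               fdr = rows$fdr,
               expected_pass = rows$expected_pass,
               stringsAsFactors = FALSE)
  })
}
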