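test_that("config validation names the offending field", {
  expect_error(simulation_config(frac_up = 0), "frac_up",
               class = "validation_error")
  expect_error(simulation_config(hazard_ratio = -1), "hazard_ratio",
               class = "validation_error")
  expect_error(simulation_config(frac_true = 1.2), "frac_true",
               class = "validation_error")
  expect_error(simulation_config(baseline_rate = Inf), "baseline_rate",
               class = "validation_error")
  expect_error(simulation_config(endpoint_types = "os"), "endpoint_types",
               class = "validation_error")
})

test_that("generation is byte-identical for identical config and seed", {
  cfg <- simulation_config(n_samples = 50, n_features = 5, seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
})

test_that("per-feature sub-streams keep early features stable when more are added", {
  # with a fixed truth assignment (all null) each feature's draws depend
  # only on its own sub-stream, not on how many features exist
  small <- generate_cohort(simulation_config(n_samples = 40, n_features = 3,
                                             frac_true = 0, seed = 6))
  large <- generate_cohort(simulation_config(n_samples = 40, n_features = 8,
                                             frac_true = 0, seed = 6))
  for (f in c("gene_001", "gene_002", "gene_003")) {
    expect_identical(small$expression[[f]], large$expression[[f]])
  }
})

test_that("every feature appears exactly once in the truth table", {
  cc <- generate_cohort(simulation_config(n_samples = 20, n_features = 15,
                                          frac_true = 0.4, seed = 3))
  expect_equal(sort(cc$truth$feature_id), sort(names(cc$expression)[-1]))
  expect_equal(anyDuplicated(cc$truth$feature_id), 0L)
  expect_equal(sum(cc$truth$is_true_target), round(0.4 * 15))
  expect_true(all(cc$truth$true_hazard_ratio[!cc$truth$is_true_target] == 1))
})

test_that("null cohort event rate matches the censored exponential formula", {
  cfg <- simulation_config(n_samples = 3000, n_features = 1, frac_true = 0,
                           baseline_rate = 0.02, censor_time = 60, seed = 8,
                           endpoint_types = "survival")
  cc <- generate_cohort(cfg)
  expected <- 1 - exp(-0.02 * 60)
  frac <- mean(cc$clinical$event)
  se <- sqrt(expected * (1 - expected) / 3000)
  expect_lt(abs(frac - expected), 3 * se)
  expect_true(all(cc$clinical$time <= 60))
})

test_that("a huge censoring horizon leaves no censored samples", {
  cc <- generate_cohort(simulation_config(n_samples = 200, n_features = 1,
                                          frac_true = 0, censor_time = 1e9,
                                          seed = 4, endpoint_types = "survival"))
  expect_true(all(cc$clinical$event == 1))
})

test_that("feature means follow the mixture law of large numbers", {
  cfg <- simulation_config(n_samples = 10000, n_features = 2, frac_true = 0,
                           mixture_delta = 4, mixture_sd = 1, frac_up = 0.3,
                           seed = 10, endpoint_types = "survival")
  cc <- generate_cohort(cfg)
  mu_expected <- 6 + 0.3 * 4  # frac_up * mu_up + (1 - frac_up) * mu_down
  # variance of the mixture: sd^2 + delta^2 * frac_up * (1 - frac_up)
  se <- sqrt((1 + 16 * 0.3 * 0.7) / 10000)
  for (f in names(cc$expression)[-1]) {
    expect_lt(abs(mean(cc$expression[[f]]) - mu_expected), 3 * se)
  }
})

test_that("flat config gives uniform downstream p_true across features", {
  cc <- generate_cohort(simulation_config(
    n_samples = 200, n_features = 200, frac_true = 0, mixture_delta = 0,
    hazard_ratio = 1, seed = 15, endpoint_types = "survival"))
  cl <- cc$clinical
  p <- vapply(names(cc$expression)[-1], function(f) {
    v <- setNames(cc$expression[[f]], cc$expression$sample_id)
    d <- kmeans_dichotomize(v)
    compare_groups(cl$time, cl$event, d$labels)$p_true
  }, numeric(1))
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("true features share the latent risk partition, null features do not", {
  cc <- generate_cohort(simulation_config(
    n_samples = 400, n_features = 8, frac_true = 0.5, mixture_delta = 6,
    mixture_sd = 0.5, seed = 22))
  latent_up <- cc$latent_risk == "UP"
  for (i in seq_len(nrow(cc$truth))) {
    f <- cc$truth$feature_id[i]
    v <- cc$expression[[f]]
    agreement <- mean((v > 6 + 3) == latent_up)
    if (cc$truth$is_true_target[i]) {
      expect_gt(agreement, 0.95)
    } else {
      expect_lt(abs(agreement - (0.3 * 0.3 + 0.7 * 0.7)), 0.15)
    }
  }
})

test_that("fusion fixture composition matches the requested counts", {
  fx <- generate_fusion_fixture(n_common = 3, n_mt_only_single = 2,
                                n_wt_shared = 2, n_readthrough = 0,
                                n_homologue = 0, seed = 1)
  expect_equal(nrow(fx$expected_retained), 3)
  # common events are in both MT tables, absent from both WT tables
  key <- function(df) paste(df$gene5p, df$gene3p)
  for (k in key(fx$expected_retained)) {
    expect_true(k %in% key(fx$mt[[1]]))
    expect_true(k %in% key(fx$mt[[2]]))
    expect_false(k %in% key(fx$wt[[1]]))
    expect_false(k %in% key(fx$wt[[2]]))
  }
  # wt-shared events appear in MT and WT
  fx2 <- generate_fusion_fixture(n_common = 0, n_wt_shared = 5, seed = 2,
                                 n_mt_only_single = 0)
  expect_equal(nrow(fx2$expected_retained), 0)
  shared <- intersect(key(fx2$mt[[1]]), key(fx2$wt[[1]]))
  expect_length(shared, 5)
})

test_that("planted read-through pairs are adjacent same-strand genes", {
  fx <- generate_fusion_fixture(n_common = 0, n_mt_only_single = 0,
                                n_wt_shared = 0, n_readthrough = 2,
                                n_homologue = 1, seed = 3)
  expect_equal(nrow(fx$expected_retained), 0)
  ann <- fx$annotation
  common <- fx$mt[[2]]  # all rep2 events are replicate-common by construction
  for (i in seq_len(nrow(common))) {
    g5 <- ann[ann$gene_id == common$gene5p[i], ]
    g3 <- ann[ann$gene_id == common$gene3p[i], ]
    same_family <- !is.na(g5$homology_group) && !is.na(g3$homology_group) &&
      g5$homology_group == g3$homology_group
    readthrough <- g5$chrom == g3$chrom && g5$strand == g3$strand &&
      g3$start > g5$end && g3$start - g5$end < 2e5
    expect_true(same_family || readthrough)
  }
})

test_that("DE fixture plants exact pass counts and boundary rows", {
  de <- generate_de_table(n_pass = 5, n_fail_fdr = 3, n_fail_lfc = 2,
                          n_down = 4, seed = 1)
  expect_equal(nrow(de), 14)
  expect_equal(sum(de$expected_pass), 5)
  expect_true(any(de$fdr == 0.1))        # boundary FDR row
  expect_true(any(de$log2fc == 1))       # boundary fold-change row
  expect_true(all(de$log2fc[de$expected_pass] > 1))
  expect_true(all(de$fdr[de$expected_pass] < 0.1))
  expect_identical(de, generate_de_table(5, 3, 2, 4, seed = 1))
})
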