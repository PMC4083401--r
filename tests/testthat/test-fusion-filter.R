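call_row <- function(g5, g3, rep_id = "r1", support = 10) {
  data.frame(replicate_id = rep_id, gene5p = g5, gene3p = g3,
             support_reads = support, stringsAsFactors = FALSE)
}

test_that("replicate intersection keeps only shared gene pairs", {
  r1 <- rbind(call_row("A", "B"), call_row("C", "D"))
  r2 <- rbind(call_row("A", "B", "r2"), call_row("E", "F", "r2"))
  common <- intersect_replicates(r1, r2)
  expect_equal(nrow(common), 1)
  expect_equal(common$gene5p, "A")
  # symmetric, idempotent, empty on disjoint sets
  expect_equal(intersect_replicates(r2, r1)$gene5p, "A")
  expect_equal(nrow(intersect_replicates(r1, r1)), 2)
  expect_equal(nrow(intersect_replicates(call_row("A", "B"), call_row("X", "Y"))), 0)
  # ordered pairs: A:B does not match B:A
  expect_equal(nrow(intersect_replicates(call_row("A", "B"), call_row("B", "A"))), 0)
})

test_that("intersection is associative across three replicates", {
  r1 <- rbind(call_row("A", "B"), call_row("C", "D"), call_row("E", "F"))
  r2 <- rbind(call_row("A", "B"), call_row("C", "D"))
  r3 <- rbind(call_row("A", "B"), call_row("E", "F"))
  left <- intersect_replicates(intersect_replicates(r1, r2), r3)
  right <- intersect_replicates(r1, intersect_replicates(r2, r3))
  expect_equal(left$gene5p, right$gene5p)
  expect_equal(left$gene5p, "A")
})

test_that("control subtraction removes pairs seen in any WT replicate", {
  mt <- rbind(call_row("A", "B"), call_row("C", "D"))
  out <- subtract_control(mt, call_row("C", "D", "wt1"))
  expect_equal(out$retained$gene5p, "A")
  expect_equal(out$control_shared$classification, "control_shared")
  # empty control is the identity; full overlap empties the set
  expect_equal(nrow(subtract_control(mt, mt[0, ])$retained), 2)
  expect_equal(nrow(subtract_control(mt, list(call_row("A", "B"), mt))$retained), 0)
})

test_that("artifact classification follows the read-through and homology rules", {
  models <- data.frame(
    gene_id = c("up1", "dn1", "minus_up", "minus_dn", "par_a", "par_b", "far"),
    chrom = c("chr1", "chr1", "chr2", "chr2", "chr3", "chr7", "chr1"),
    start = c(1000, 15000, 50000, 20000, 100, 100, 9e6),
    end = c(9000, 22000, 60000, 30000, 5000, 5000, 9.1e6),
    strand = c("+", "+", "-", "-", "+", "+", "+"),
    homology_group = c(NA, NA, NA, NA, "famX", "famX", NA),
    stringsAsFactors = FALSE)

  # + strand, 6 kb gap, transcriptional order -> read-through
  expect_equal(classify_artifact(list(gene5p = "up1", gene3p = "dn1"), models),
               "read_through")
  # wrong order on + strand is not read-through
  expect_equal(classify_artifact(list(gene5p = "dn1", gene3p = "up1"), models),
               "retained")
  # - strand: upstream means higher coordinate
  expect_equal(classify_artifact(list(gene5p = "minus_up", gene3p = "minus_dn"),
                                 models), "read_through")
  # shared homology group, different chromosomes -> homologue pair
  expect_equal(classify_artifact(list(gene5p = "par_a", gene3p = "par_b"), models),
               "homologue_pair")
  # same chrom/strand but beyond the gap limit -> retained
  expect_equal(classify_artifact(list(gene5p = "up1", gene3p = "far"), models),
               "retained")
  expect_equal(classify_artifact(list(gene5p = "up1", gene3p = "far"), models,
                                 readthrough_max_gap = 1e7), "read_through")
  # partner missing from the models -> flagged unclassifiable
  expect_warning(
    cls <- classify_artifact(list(gene5p = "up1", gene3p = "ghost"), models),
    class = "unclassifiable_call")
  expect_equal(cls, "unclassifiable")
})

test_that("adjacent-only mode rejects pairs with an intervening gene", {
  models <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    chrom = "chr1", start = c(1000, 20000, 40000),
    end = c(9000, 30000, 50000), strand = "+",
    homology_group = NA_character_, stringsAsFactors = FALSE)
  call <- list(gene5p = "g1", gene3p = "g3")
  expect_equal(classify_artifact(call, models), "read_through")
  expect_equal(classify_artifact(call, models, adjacent_only = TRUE), "retained")
  expect_equal(classify_artifact(list(gene5p = "g1", gene3p = "g2"), models,
                                 adjacent_only = TRUE), "read_through")
})

test_that("full filter reproduces the all-artifact outcome on the planted fixture", {
  # every replicate-common, tumor-specific call is read-through or
  # homologue -> nothing survives
  fx <- generate_fusion_fixture(n_common = 0, n_mt_only_single = 2,
                                n_wt_shared = 2, n_readthrough = 2,
                                n_homologue = 1, seed = 11)
  res <- run_fusion_filter(fx$mt, fx$wt, fx$annotation)
  expect_equal(nrow(res$retained), 0)
  expect_setequal(unique(res$audit$classification),
                  c("read_through", "homologue_pair", "control_shared"))
})

test_that("a genuine inter-chromosomal event is the only call retained", {
  fx <- generate_fusion_fixture(n_common = 1, n_mt_only_single = 2,
                                n_wt_shared = 2, n_readthrough = 2,
                                n_homologue = 2, seed = 12)
  res <- run_fusion_filter(fx$mt, fx$wt, fx$annotation)
  expect_equal(nrow(res$retained), 1)
  expect_equal(res$retained$gene5p, fx$expected_retained$gene5p)
  expect_equal(res$retained$gene3p, fx$expected_retained$gene3p)
})

test_that("retained calls are always a subset of MT-common minus WT", {
  for (seed in 1:5) {
    fx <- generate_fusion_fixture(n_common = 3, n_mt_only_single = 1,
                                  n_wt_shared = 2, n_readthrough = 1,
                                  n_homologue = 1, seed = seed)
    res <- run_fusion_filter(fx$mt, fx$wt, fx$annotation)
    key <- function(df) paste(df$gene5p, df$gene3p)
    common <- intersect(key(fx$mt[[1]]), key(fx$mt[[2]]))
    wt_all <- unique(c(key(fx$wt[[1]]), key(fx$wt[[2]])))
    expect_true(all(key(res$retained) %in% setdiff(common, wt_all)))
    expect_setequal(key(res$retained), key(fx$expected_retained))
  }
})

test_that("a single MT replicate skips intersection with a warning", {
  fx <- generate_fusion_fixture(n_common = 2, n_mt_only_single = 0,
                                n_wt_shared = 0, seed = 13)
  expect_warning(res <- run_fusion_filter(fx$mt[[1]], fx$wt, fx$annotation),
                 class = "single_replicate")
  expect_equal(nrow(res$retained), 2)
})
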