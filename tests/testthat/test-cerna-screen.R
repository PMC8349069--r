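test_that("prevalence is the fraction of named samples with count > 0", {
  row <- matrix(c(0, 0, 1, 2), nrow = 1,
                dimnames = list("g", paste0("s", 1:4)))
  expect_equal(prevalence(row, paste0("s", 1:4)), 0.5)   # kept: 0.5 >= 0.5
  row2 <- matrix(c(0, 0, 0, 1), nrow = 1,
                 dimnames = list("g", paste0("s", 1:4)))
  expect_equal(prevalence(row2, paste0("s", 1:4)), 0.25)
  row3 <- matrix(rep(0, 4), nrow = 1, dimnames = list("g", paste0("s", 1:4)))
  expect_equal(prevalence(row3, paste0("s", 1:4)), 0)
  expect_error(prevalence(row, character(0)), "non-empty")
  expect_error(prevalence(row, "s9"), "unknown sample")
})

test_that("screen_thresholds validates its ranges", {
  expect_error(screen_thresholds(prevalence_min = 0), "prevalence_min")
  expect_error(screen_thresholds(score_min = 1.2), "score_min")
  expect_error(screen_thresholds(min_sites_lncrna = 0), "min_sites_lncrna")
})

# Hand-built fixture: two miRNAs, one lncRNA, one mRNA, controllable metrics.
make_screen_fixture <- function(lnc_score = 0.9, lnc_sites = 5L,
                                pcc = 0.6, passes = TRUE) {
  counts <- matrix(c(5, 6, 7, 8), nrow = 1,
                   dimnames = list("MIRX", paste0("t", 1:4)))
  il <- data.frame(mirna_id = "MIRX", target_id = "LNCX",
                   target_class = "lncRNA", n_8mer = 3L, n_7mer_m8 = 2L,
                   n_7mer_a1 = 0L, n_6mer = 0L, n_sites = lnc_sites,
                   score = lnc_score, stringsAsFactors = FALSE)
  im <- data.frame(mirna_id = "MIRX", target_id = "PCGX",
                   target_class = "mRNA_3UTR", n_8mer = 1L, n_7mer_m8 = 0L,
                   n_7mer_a1 = 0L, n_6mer = 0L, n_sites = 1L, score = 0.6,
                   stringsAsFactors = FALSE)
  corr <- data.frame(lncrna_id = "LNCX", pcg_id = "PCGX", pcc = pcc,
                     p_raw = 1e-5, p_adj = 1e-4, passes = passes,
                     stringsAsFactors = FALSE)
  list(counts = counts, il = il, im = im, corr = corr,
       tumor_ids = paste0("t", 1:4))
}

test_that("screen_axes assembles triples and enforces every filter", {
  fx <- make_screen_fixture()
  ax <- screen_axes("LNCX", "PCGX", fx$il, fx$im, fx$counts, fx$tumor_ids,
                    fx$corr)
  expect_equal(nrow(ax), 1)
  expect_true(ax$final_pass)
  expect_equal(ax$mirna_prevalence, 1)

  # score forced just below the cut-off: only the score filter fails
  fx2 <- make_screen_fixture(lnc_score = 0.84)
  ax2 <- screen_axes("LNCX", "PCGX", fx2$il, fx2$im, fx2$counts, fx2$tumor_ids,
                     fx2$corr)
  expect_false(ax2$final_pass)
  tr <- parse_trace(ax2$filter_trace)
  expect_false(tr[["lnc_score"]])
  expect_true(all(tr[setdiff(names(tr), "lnc_score")]))

  # missing correlation record is a filter failure, not an exception
  fx3 <- make_screen_fixture()
  empty_corr <- fx3$corr[0, ]
  ax3 <- screen_axes("LNCX", "PCGX", fx3$il, fx3$im, fx3$counts, fx3$tumor_ids,
                     empty_corr)
  expect_false(ax3$final_pass)
  expect_false(parse_trace(ax3$filter_trace)[["positive_correlation"]])

  # empty interaction lists give an empty axis table
  ax4 <- screen_axes("LNCX", "PCGX", fx$il[0, ], fx$im, fx$counts,
                     fx$tumor_ids, fx$corr)
  expect_equal(nrow(ax4), 0)
})

test_that("tightening any threshold never adds a passing axis", {
  coh <- generate_cohort(small_config(seed = 23))
  res <- run_pipeline(coh)
  base_pass <- axis_key(res$axes[res$axes$final_pass, 1:3])
  tumor_ids <- coh$samples$sample_id[coh$samples$tissue == "tumor"]
  tighter <- list(screen_thresholds(prevalence_min = 0.8),
                  screen_thresholds(score_min = 0.99),
                  screen_thresholds(min_sites_lncrna = 6))
  for (th in tighter) {
    ax <- screen_axes(res$candidate_lncrnas, res$candidate_mrnas,
                      res$interactions_lnc, res$interactions_mrna,
                      coh$counts, tumor_ids, res$correlations, th)
    expect_true(all(axis_key(ax[ax$final_pass, 1:3]) %in% base_pass))
  }
})

test_that("filters are conjunctive: the trace order never changes final_pass", {
  coh <- generate_cohort(small_config(seed = 29))
  res <- run_pipeline(coh)
  ax <- res$axes
  for (i in seq_len(nrow(ax))) {
    tr <- parse_trace(ax$filter_trace[i])
    expect_equal(ax$final_pass[i], all(tr))  # order-free conjunction
  }
})

test_that("rank_axes orders deterministically with tie-breaks", {
  ax <- data.frame(
    lncrna_id = c("b", "a", "c"), mirna_id = "m", mrna_id = "p",
    mirna_prevalence = 1, lnc_score = c(0.9, 0.9, 0.95),
    lnc_site_count = 5L, mrna_score = 0.5, mrna_site_count = 1L,
    lnc_mrna_pcc = c(0.5, 0.5, 0.6), filter_trace = "x=1:pass",
    final_pass = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  r <- rank_axes(ax)
  expect_equal(r$lncrna_id, c("a", "b", "c"))  # 0.5-tie broken by id; fail last
  expect_equal(nrow(rank_axes(ax[0, ])), 0)
  ax2 <- ax; ax2$lnc_mrna_pcc <- c(0.5, 0.6, 0.7); ax2$final_pass <- TRUE
  expect_equal(rank_axes(ax2)$lnc_mrna_pcc, c(0.7, 0.6, 0.5))
})

test_that("screen_funnel counts survivors stage by stage", {
  fx <- make_screen_fixture()
  ax <- screen_axes("LNCX", "PCGX", fx$il, fx$im, fx$counts, fx$tumor_ids,
                    fx$corr)
  fun <- screen_funnel(ax)
  expect_equal(fun$count[fun$stage == "candidate_triples"], 1)
  expect_equal(fun$count[fun$stage == "final_pass"], 1)
  fun0 <- screen_funnel(empty <- ax[0, ])
  expect_true(all(fun0$count == 0))
})
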