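test_that("config validation names the offending field", {
  expect_error(cohort_config(n_olnm_pos = 53), "n_olnm_pos")
  expect_error(cohort_config(n_paired_normal = 99), "n_paired_normal")
  expect_error(cohort_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(cohort_config(effect_log2fc = -1), "effect_log2fc")
  expect_error(cohort_config(survival_hr = 0), "survival_hr")
  expect_error(cohort_config(mirna_len = 7), "mirna_len")
  expect_error(cohort_config(n_lncrna = 5), "n_lncrna")
})

test_that("default cohort has the reference design: 53 tumours, 13 normals", {
  coh <- generate_cohort(cohort_config(seed = 1))
  expect_equal(sum(coh$samples$tissue == "tumor"), 53)
  expect_equal(sum(coh$samples$tissue == "normal"), 13)
  expect_equal(sum(coh$samples$olnm == "pos", na.rm = TRUE), 18)
  expect_equal(ncol(coh$counts), 66)
  expect_true(all(coh$counts >= 0))
  # every planted id exists in counts and sequences
  expect_true(all(coh$truth$lncrna_id %in% rownames(coh$counts)))
  expect_true(all(coh$truth$mirna_id %in% names(coh$sequences$mirna)))
  expect_true(all(coh$truth$mrna_id %in% names(coh$sequences$utr3)))
})

test_that("generation is deterministic for identical config and seed", {
  a <- generate_cohort(small_config(seed = 42))
  b <- generate_cohort(small_config(seed = 42))
  expect_identical(a$counts, b$counts)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$samples, b$samples)
  c <- generate_cohort(small_config(seed = 43))
  expect_false(identical(a$counts, c$counts))
})

test_that("null-effect config plants no group differences, decoys only", {
  coh <- generate_cohort(small_config(seed = 5, effect_log2fc = 0,
                                      n_true_axes = 0))
  expect_true(all(coh$truth$role != "TRUE_AXIS"))
  expect_setequal(unique(coh$truth$role),
                  c("DECOY_LOW_PREVALENCE", "DECOY_LOW_SCORE",
                    "DECOY_FEW_SITES", "DECOY_NEGATIVE_CORRELATION",
                    "DECOY_NOT_DE"))
  expect_true(all(coh$planted_effects$log2fc_per_activity == 0))
})

test_that("miRNA prevalence properties hold on generated data", {
  coh <- generate_cohort(small_config(seed = 11))
  tumor_ids <- coh$samples$sample_id[coh$samples$tissue == "tumor"]
  tr <- coh$truth
  for (i in seq_len(nrow(tr))) {
    pv <- prevalence(coh$counts[tr$mirna_id[i], , drop = FALSE], tumor_ids)
    if (tr$role[i] == "DECOY_LOW_PREVALENCE") expect_lt(pv, 0.5)
    if (tr$role[i] == "TRUE_AXIS") expect_gt(pv, 0.5)
  }
})

test_that("the scanner recovers at least the planted site counts", {
  coh <- generate_cohort(small_config(seed = 13))
  tr <- coh$truth
  for (i in seq_len(nrow(tr))) {
    mir <- coh$sequences$mirna[[tr$mirna_id[i]]]
    lnc_sites <- find_seed_sites(mir, coh$sequences$lncrna[[tr$lncrna_id[i]]])
    utr_sites <- find_seed_sites(mir, coh$sequences$utr3[[tr$mrna_id[i]]])
    cnt <- function(sites, type) sum(sites$site_type == type)
    expect_gte(cnt(lnc_sites, "8mer"), tr$lnc_8mer[i])
    expect_gte(cnt(lnc_sites, "7mer-m8"), tr$lnc_7mer_m8[i])
    expect_gte(cnt(lnc_sites, "6mer"), tr$lnc_6mer[i])
    expect_gte(cnt(utr_sites, "8mer"), tr$utr_8mer[i])
    expect_gte(cnt(utr_sites, "7mer-m8"), tr$utr_7mer_m8[i])
    # planting is exact by construction (windows + scrubbing)
    expect_equal(nrow(lnc_sites),
                 tr$lnc_8mer[i] + tr$lnc_7mer_m8[i] + tr$lnc_7mer_a1[i] +
                   tr$lnc_6mer[i])
  }
})

test_that("write_cohort round-trips and is byte-identical on rewrite", {
  coh <- generate_cohort(small_config(seed = 3))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  manifest <- write_cohort(coh, d1)
  expect_length(manifest, 7)
  expect_true(all(file.exists(manifest)))
  back <- read_cohort(d1)
  expect_identical(coh$counts, back$counts)
  expect_identical(coh$gene_class, back$gene_class)
  expect_identical(coh$sequences, back$sequences)
  expect_identical(coh$gene_sets, back$gene_sets)
  expect_equal(coh$samples, back$samples)
  expect_equal(coh$truth, back$truth)
  write_cohort(coh, d2)
  for (f in basename(manifest))
    expect_identical(readBin(file.path(d1, f), "raw", 5e6),
                     readBin(file.path(d2, f), "raw", 5e6),
                     label = f)
})

test_that("an empty (0-gene) cohort serialises to valid header-only files", {
  coh <- generate_cohort(cohort_config(
    n_lncrna = 0, n_pcg = 0, n_mirna = 0, n_true_axes = 0,
    n_decoys_per_class = 0, n_tumor = 2, n_paired_normal = 0, n_olnm_pos = 1,
    seed = 3))
  d <- withr::local_tempdir()
  write_cohort(coh, d)
  back <- read_cohort(d)
  expect_equal(nrow(back$counts), 0)
  expect_equal(ncol(back$counts), 2)
  expect_equal(nrow(back$truth), 0)
})

test_that("load_truth validates roles and counts by role", {
  d <- withr::local_tempdir()
  coh <- generate_cohort(small_config(seed = 2))
  paths <- write_cohort(coh, d)
  tr <- load_truth(paths[["truth"]])
  expect_equal(tr, coh$truth)
  expect_equal(sum(tr$role == "TRUE_AXIS"), 2)
  expect_equal(sum(tr$role != "TRUE_AXIS"), 5)

  bad <- coh$truth
  bad$role[3] <- "BAD"
  f <- file.path(d, "bad_truth.tsv")
  write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_truth(f), "unknown role 'BAD'.*line 4")
})
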