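test_that("median_split assigns ties at the median to 'low'", {
  v34 <- setNames(seq_len(34), paste0("s", 1:34))
  sp <- median_split(v34)
  expect_equal(sum(sp == "low"), 17)
  expect_equal(sum(sp == "high"), 17)
  all_equal <- setNames(rep(3, 5), paste0("s", 1:5))
  expect_true(all(median_split(all_equal) == "low"))
  v5 <- setNames(1:5, paste0("s", 1:5))
  sp5 <- median_split(v5)
  expect_equal(names(sp5[sp5 == "low"]), paste0("s", 1:3))
  expect_error(median_split(setNames(1, "a")), "at least 2")
})

test_that("fisher_exact_2x2 reproduces printed and derived p-values", {
  expect_equal(round(fisher_exact_2x2(matrix(c(11, 6, 7, 10), 2)), 3), 0.303)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(signif(fisher_exact_2x2(matrix(c(14, 5, 3, 12), 2,
                                              byrow = TRUE)), 2), 0.0049)
  expect_error(fisher_exact_2x2(matrix(1:6, 2)), "freeman_halton")
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 1, 2), 2)), "margins")
})

test_that("fisher_exact_2x2 agrees with fisher.test and is swap-invariant", {
  set.seed(9)
  for (i in 1:60) {
    m <- matrix(rpois(4, 8) + 1, 2)
    p <- fisher_exact_2x2(m)
    expect_equal(p, fisher.test(m)$p.value, tolerance = 1e-9)
    expect_equal(fisher_exact_2x2(m[2:1, 2:1]), p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(t(m)), p, tolerance = 1e-12)
  }
})

test_that("chi2_test matches the printed clinical-table p-values", {
  olnm <- matrix(c(14, 3, 5, 12), 2)   # rows: low/high is columns here
  r <- chi2_test(olnm, yates = TRUE)
  expect_equal(round(r$p, 3), 0.006)
  pn <- matrix(c(14, 1, 2, 5, 8, 4), 3)
  r2 <- chi2_test(pn)
  expect_equal(r2$df, 2)
  expect_equal(round(r2$p, 3), 0.006)
  # a table equal to its expected values has statistic 0
  flat <- matrix(c(6, 6, 6, 6), 2)
  expect_equal(chi2_test(flat)$statistic, 0)
  expect_equal(chi2_test(flat)$p, 1)
  # oracle: chisq.test
  set.seed(10)
  for (i in 1:20) {
    m <- matrix(rpois(6, 10) + 1, 2)
    expect_equal(chi2_test(m)$statistic,
                 unname(suppressWarnings(chisq.test(m, correct = FALSE))$statistic),
                 tolerance = 1e-12)
  }
  expect_error(chi2_test(matrix(c(14, 1, 2, 5, 8, 4), 3), yates = TRUE),
               "2x2")
})

test_that("freeman_halton_exact reduces to Fisher on 2x2 and enumerates r x c", {
  expect_equal(freeman_halton_exact(matrix(c(3, 0, 0, 3), 2)), 0.1,
               tolerance = 1e-12)
  set.seed(11)
  for (i in 1:20) {
    m <- matrix(rpois(4, 6) + 1, 2)
    expect_equal(freeman_halton_exact(m), fisher_exact_2x2(m),
                 tolerance = 1e-12)
  }
  # proportional rows are the modal table: p = 1
  prop <- matrix(c(2, 4, 3, 6), 2)
  expect_equal(freeman_halton_exact(prop), 1, tolerance = 1e-7)
  # r x c against the fisher.test exact oracle
  for (i in 1:10) {
    m <- matrix(rpois(6, 4) + 1, nrow = 3)
    expect_equal(freeman_halton_exact(m), fisher.test(m)$p.value,
                 tolerance = 1e-7)
  }
  expect_error(freeman_halton_exact(matrix(30, 4, 4)), "too large")
})

test_that("km_logrank matches the hand-computed example and survdiff", {
  r <- km_logrank(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(r$statistic, 2.882, tolerance = 1e-3)
  expect_equal(r$df, 1L)
  # identical groups: statistic 0, p 1
  r0 <- km_logrank(rep(c(2, 5, 9), 2), rep(c(1, 0, 1), 2),
                   rep(c("A", "B"), each = 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  # S(t) = 1 before the first event; curves non-increasing, start <= 1
  set.seed(12)
  tt <- rexp(40, 0.1); ev <- rbinom(40, 1, 0.7)
  gg <- rep(c("A", "B"), 20)
  r2 <- km_logrank(tt, ev, gg)
  for (g in c("A", "B")) {
    cv <- r2$curves[r2$curves$group == g, ]
    expect_true(all(diff(cv$surv) <= 1e-12))
    first_event <- min(cv$time[cv$n_event > 0])
    expect_true(all(cv$surv[cv$time < first_event] == 1))
  }
  # oracles: survival::survdiff and survfit
  sd <- survival::survdiff(survival::Surv(tt, ev) ~ gg)
  expect_equal(r2$statistic, sd$chisq, tolerance = 1e-9)
  sf <- survival::survfit(survival::Surv(tt, ev) ~ gg)
  expect_equal(r2$curves$surv[r2$curves$group == "A"],
               sf[1]$surv, tolerance = 1e-12)
  # all-censored input warns and returns p = 1
  expect_warning(r3 <- km_logrank(c(1, 2, 3, 4), rep(0, 4),
                                  c("A", "A", "B", "B")), "no events")
  expect_equal(r3$p, 1)
})

test_that("delta_delta_ct computes fold changes with reciprocal symmetry", {
  m <- data.frame(target = "g", condition = c("case", "control"),
                  target_ct = c(24, 26), reference_ct = c(20, 20))
  r <- delta_delta_ct(m, "case", "control")
  expect_equal(r$ddct, -2)
  expect_equal(r$fold_change, 4)
  expect_equal(delta_delta_ct(m, "control", "case")$fold_change, 1 / 4)
  m2 <- data.frame(target = "g", condition = c("case", "control"),
                   target_ct = c(25, 25), reference_ct = c(20, 20))
  expect_equal(delta_delta_ct(m2, "case", "control")$fold_change, 1)
  m3 <- m; m3$reference_ct[1] <- NA
  expect_error(delta_delta_ct(m3, "case", "control"), "missing reference")
})

test_that("table1_report identifies which test reproduces each printed p", {
  rep <- table1_report()
  expect_equal(nrow(rep), 7)
  # the two headline associations reproduce under the chi-squared tests
  expect_equal(round(rep$chi2_p[rep$covariate == "olnm"], 3), 0.006)
  expect_equal(round(rep$chi2_p[rep$covariate == "pathologic_n"], 3), 0.006)
  expect_equal(round(rep$exact_p[rep$covariate == "smoking"], 3), 0.303)
  # the published age/sex p-values are transposed; neither matches directly
  expect_equal(rep$matches[rep$covariate == "age"], "")
  expect_equal(rep$matches[rep$covariate == "sex"], "")
  expect_equal(round(rep$exact_p[rep$covariate == "age"], 3), 0.494)
  expect_equal(round(rep$exact_p[rep$covariate == "sex"], 3), 1.000)
})
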