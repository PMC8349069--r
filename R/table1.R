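#' Printed clinicopathologic contingency tables (FFPE validation cohort)
#'
#' The fixed 34-patient validation-cohort tables relating low/high lncRNA
#' expression (median split, 17 vs 17) to clinical covariates, as printed in
#' the source clinical table. These are inputs to the clinical association
#' tests, not computed results. Columns are expression groups (low, high);
#' rows are covariate levels.
#'
#' @return named list of integer matrices with a `printed_p` attribute each
#'   (the p-value printed alongside the covariate).
#' @export
tscc_table1 <- function() {
  tab <- function(cells, rn, p) {
    m <- matrix(as.integer(cells), ncol = 2L, byrow = TRUE,
                dimnames = list(rn, c("low", "high")))
    attr(m, "printed_p") <- p
    m
  }
  list(
    age = tab(c(7, 10, 10, 7), c("<52", ">=52"), 1.000),
    sex = tab(c(4, 4, 13, 13), c("female", "male"), 0.493),
    smoking = tab(c(11, 7, 6, 10), c("no", "yes"), 0.303),
    clinical_t = tab(c(7, 3, 10, 13, 0, 1), c("T1", "T2", "T3"), 0.224),
    pathologic_t = tab(c(4, 1, 11, 13, 2, 3), c("T1", "T2", "T3"), 0.338),
    pathologic_n = tab(c(14, 5, 1, 8, 2, 4), c("N1", "N2", "N3"), 0.006),
    olnm = tab(c(14, 5, 3, 12), c("no", "yes"), 0.006))
}

#' Association report for the printed clinical tables
#'
#' Runs the exact test (Fisher for 2x2, Freeman-Halton otherwise) and the
#' chi-squared test (Yates-corrected on 2x2, Pearson otherwise) on each
#' covariate table and reports which test reproduces the printed p-value at 3
#' decimal places. The printed table mixes test choices (and transposes two
#' p-values), so the report makes the correspondence explicit.
#'
#' @param tables list of matrices as returned by [tscc_table1()].
#' @return data frame with `covariate`, `printed_p`, `exact_p`, `chi2_p`,
#'   `chi2_yates`, `matches`.
#' @export
table1_report <- function(tables = tscc_table1()) {
  rows <- lapply(names(tables), function(nm) {
    m <- tables[[nm]]
    exact_p <- if (nrow(m) == 2L) fisher_exact_2x2(m) else {
      # guard the enumeration against empty rows in the printed tables
      mm <- m[rowSums(m) > 0, , drop = FALSE]
      freeman_halton_exact(mm)
    }
    yates <- nrow(m) == 2L
    chi2_p <- tryCatch(chi2_test(m[rowSums(m) > 0, , drop = FALSE],
                                 yates = yates)$p,
                       error = function(e) NA_real_)
    printed <- attr(m, "printed_p")
    matches <- c(exact = !is.na(exact_p) && round(exact_p, 3) == printed,
                 chi2 = !is.na(chi2_p) && round(chi2_p, 3) == printed)
    data.frame(covariate = nm, printed_p = printed,
               exact_p = exact_p, chi2_p = chi2_p, chi2_yates = yates,
               matches = paste(names(matches)[matches], collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
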