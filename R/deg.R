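#' Median-of-ratios size factors
#'
#' Per-sample scale factors in the median-of-ratios convention: for each
#' sample, the median over reference genes of `count / geometric mean across
#' samples`, where the reference genes are those with all-positive counts.
#' Factors are reported unscaled (no recentring).
#'
#' @param counts non-negative gene-by-sample count matrix.
#' @return numeric vector of positive factors, one per sample.
#' @examples
#' size_factors(matrix(c(10, 20, 30, 20, 40, 60), nrow = 3))  # 0.7071 1.4142
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 1L) stop("counts must have at least one sample")
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref))
    stop("no gene has all-positive counts; filter genes or add a pseudocount ",
         "before computing size factors")
  logs <- log(counts[ref, , drop = FALSE])
  geomean <- exp(rowMeans(logs))
  apply(counts[ref, , drop = FALSE], 2L, function(col) median(col / geomean))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Two-group differential expression test on normalised log counts
#'
#' The count-based differential expression stage: values are transformed to
#' `x = log2(count / size_factor + 1)`; the test is a Welch two-sample t on
#' `x` (unpaired) or a one-sample t on per-pair differences (paired). The
#' reported `log2fc` is `log2((m_a + 1) / (m_b + 1))` with `m` the mean
#' normalised count per group. This stage is a deterministic, fully specified
#' stand-in for a negative-binomial GLM with dispersion shrinkage; see the
#' methods vignette.
#'
#' @param counts gene-by-sample count matrix with row and column names.
#' @param sf per-sample size factors from [size_factors()].
#' @param group_a,group_b disjoint character vectors of sample ids, each of
#'   size >= 2. For `paired = TRUE` they must have equal length with matched
#'   order.
#' @param paired logical; one-sample t on per-pair differences.
#' @return data frame with `gene_id`, `gene_class` (NA unless supplied via
#'   `gene_class`), `log2fc`, `p_raw`. Adjusted p-values are added by
#'   [call_and_intersect()] (or [bh_adjust()]).
#' @param gene_class optional named vector of gene classes.
#' @export
deg_test <- function(counts, sf, group_a, group_b, paired = FALSE,
                     gene_class = NULL) {
  counts <- as.matrix(counts)
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group must contain at least 2 samples")
  if (length(intersect(group_a, group_b)) > 0L)
    stop("groups must be disjoint")
  missing <- setdiff(c(group_a, group_b), colnames(counts))
  if (length(missing) > 0L)
    stop("unknown sample ids: ", paste(missing, collapse = ", "))
  if (paired && length(group_a) != length(group_b))
    stop("paired analysis requires equal group sizes in matched order")
  norm <- sweep(counts, 2L, sf, "/")
  x <- log2(norm + 1)
  xa <- x[, group_a, drop = FALSE]
  xb <- x[, group_b, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  if (paired) {
    d <- xa - xb
    md <- rowMeans(d)
    vd <- rowSums((d - md)^2) / (na - 1L)
    tstat <- md / sqrt(vd / na)
    p <- 2 * pt(-abs(tstat), df = na - 1L)
    p[vd == 0 & md == 0] <- 1
    p[vd == 0 & md != 0] <- 0
  } else {
    va <- rowSums((xa - ma)^2) / (na - 1L)
    vb <- rowSums((xb - mb)^2) / (nb - 1L)
    se2 <- va / na + vb / nb
    tstat <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
    p <- 2 * pt(-abs(tstat), df = df)
    zero <- va == 0 & vb == 0
    p[zero & ma == mb] <- 1
    p[zero & ma != mb] <- 0
  }
  mean_a <- rowMeans(norm[, group_a, drop = FALSE])
  mean_b <- rowMeans(norm[, group_b, drop = FALSE])
  log2fc <- log2((mean_a + 1) / (mean_b + 1))
  data.frame(gene_id = rownames(counts),
             gene_class = if (is.null(gene_class)) NA_character_
                          else unname(gene_class[rownames(counts)]),
             log2fc = unname(log2fc), p_raw = unname(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call DEGs per contrast and intersect the sets
#'
#' Applies the screening cut-offs (default `|log2FC| >= 1` inclusive and
#' BH-adjusted `p < 0.05` strict) to each contrast's [deg_test()] output,
#' optionally restricts to one gene class (lncRNA in the reference screen),
#' and intersects the DEG sets across contrasts with direction retained.
#'
#' @param records named list of data frames from [deg_test()], one per
#'   contrast, over the same gene universe.
#' @param fc_threshold inclusive threshold on `|log2fc|` (default 1).
#' @param alpha strict threshold on the BH-adjusted p (default 0.05).
#' @param class optional gene class filter applied after calling.
#' @return list with `records` (the inputs augmented with `p_adj`,
#'   `direction`, `is_deg`), `sets` (per-contrast DEG gene ids), and `common`
#'   (the intersection, a data frame with `gene_id` and per-contrast
#'   directions).
#' @export
call_and_intersect <- function(records, fc_threshold = 1, alpha = 0.05,
                               class = NULL) {
  stopifnot(is.list(records), length(records) >= 1L)
  universe <- records[[1L]]$gene_id
  for (r in records)
    if (!identical(sort(r$gene_id), sort(universe)))
      stop("all contrasts must share the same gene universe")
  out <- lapply(records, function(r) {
    r$p_adj <- bh_adjust(r$p_raw)
    r$direction <- ifelse(abs(r$log2fc) >= fc_threshold & r$p_adj < alpha,
                          ifelse(r$log2fc > 0, "up", "down"), "none")
    r$is_deg <- r$direction != "none"
    if (!is.null(class)) r$is_deg <- r$is_deg & !is.na(r$gene_class) &
        r$gene_class == class
    r
  })
  sets <- lapply(out, function(r) r$gene_id[r$is_deg])
  common <- Reduce(intersect, sets)
  common <- sort(common)
  dirs <- vapply(out, function(r)
    r$direction[match(common, r$gene_id)], character(length(common)))
  if (length(common) == 1L) dirs <- matrix(dirs, nrow = 1L,
                                           dimnames = list(NULL, names(out)))
  common_df <- data.frame(gene_id = common, stringsAsFactors = FALSE)
  if (length(common) > 0L)
    common_df <- cbind(common_df, as.data.frame(dirs, stringsAsFactors = FALSE))
  list(records = out, sets = sets, common = common_df)
}
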