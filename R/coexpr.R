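#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson r with the usual t-approximation p-value,
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom;
#' `r = +/-1` yields `p = 0`.
#'
#' @param x,y numeric vectors of equal length `n >= 3` with nonzero variance.
#' @return list with `r` and `p_raw`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance input")
  r <- cor(x, y)
  list(r = r, p_raw = cor_p(r, n))
}

# Two-sided p for a Pearson r at sample size n (vectorised).
cor_p <- function(r, n) {
  p <- numeric(length(r))
  exact <- abs(r) >= 1 - 1e-15
  p[exact] <- 0
  t <- r[!exact] * sqrt((n - 2) / (1 - r[!exact]^2))
  p[!exact] <- 2 * pt(-abs(t), df = n - 2)
  p
}

#' Correlate all lncRNA x PCG pairs
#'
#' Scores every pair of one lncRNA and one protein-coding gene on a
#' log2-normalised expression matrix, BH-adjusts over the full pair family,
#' and flags pairs passing the screen: `|PCC| > r_threshold` (strict) and both
#' raw and adjusted p below `alpha`.
#'
#' @param expr numeric matrix of `log2(normalised count + 1)` values, genes in
#'   rows, samples in columns.
#' @param lncrna_ids,pcg_ids row names to pair up.
#' @param r_threshold strict threshold on `|PCC|` (default 0.45).
#' @param alpha threshold on raw and adjusted p (default 0.05).
#' @return data frame of `lncrna_id`, `pcg_id`, `pcc`, `p_raw`, `p_adj`,
#'   `passes`, with attribute `positive_sets`: per-lncRNA character vectors of
#'   positively correlated passing PCGs (used by the axis screen).
#' @export
correlate_pairs <- function(expr, lncrna_ids, pcg_ids, r_threshold = 0.45,
                            alpha = 0.05) {
  missing <- setdiff(c(lncrna_ids, pcg_ids), rownames(expr))
  if (length(missing) > 0L)
    stop("unknown gene ids: ", paste(head(missing, 5L), collapse = ", "))
  if (length(lncrna_ids) == 0L || length(pcg_ids) == 0L) {
    out <- data.frame(lncrna_id = character(0), pcg_id = character(0),
                      pcc = numeric(0), p_raw = numeric(0), p_adj = numeric(0),
                      passes = logical(0), stringsAsFactors = FALSE)
    attr(out, "positive_sets") <- setNames(list(), character(0))
    return(out)
  }
  n <- ncol(expr)
  rmat <- cor(t(expr[lncrna_ids, , drop = FALSE]),
              t(expr[pcg_ids, , drop = FALSE]))
  out <- data.frame(
    lncrna_id = rep(lncrna_ids, times = length(pcg_ids)),
    pcg_id = rep(pcg_ids, each = length(lncrna_ids)),
    pcc = as.vector(rmat), stringsAsFactors = FALSE)
  out$p_raw <- cor_p(out$pcc, n)
  out$p_adj <- bh_adjust(out$p_raw)
  out$passes <- abs(out$pcc) > r_threshold & out$p_raw < alpha &
    out$p_adj < alpha
  pos <- lapply(setNames(lncrna_ids, lncrna_ids), function(l)
    sort(out$pcg_id[out$lncrna_id == l & out$passes & out$pcc > 0]))
  attr(out, "positive_sets") <- pos
  out
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test `P(X >= k)` of a query gene list against
#' each annotation term, BH-adjusted across all tested terms. Terms are
#' intersected with the universe before testing.
#'
#' @param query character vector of gene ids, a subset of `universe`.
#' @param gene_sets named list of character vectors (term -> genes).
#' @param universe character vector defining the background.
#' @param alpha enrichment threshold on the adjusted p (default 0.05).
#' @return data frame with `term_id`, `k` (overlap), `K` (term size), `n`
#'   (query size), `N` (universe size), `p_raw`, `p_adj`, `enriched`.
#' @export
hypergeom_ora <- function(query, gene_sets, universe, alpha = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query must be a subset of the universe")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(tid) {
    term <- intersect(unique(gene_sets[[tid]]), universe)
    K <- length(term)
    k <- length(intersect(term, query))
    p <- if (k == 0L) 1 else phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tid, k = k, K = K, n = n, N = N, p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(term_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_raw = numeric(0),
                      stringsAsFactors = FALSE)
  out$p_adj <- bh_adjust(out$p_raw)
  out$enriched <- out$p_adj < alpha
  out
}

#' Intersect two annotation terms within a candidate set
#'
#' @param term_a,term_b character vectors of gene ids.
#' @param candidates character vector; the result is
#'   `candidates & term_a & term_b`, sorted.
#' @return sorted character vector.
#' @export
intersect_terms <- function(term_a, term_b, candidates) {
  sort(intersect(intersect(unique(candidates), term_a), term_b))
}
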