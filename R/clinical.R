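#' Median dichotomization of expression values
#'
#' Splits samples into "low" and "high" groups at the median: values less
#' than or equal to the median go to "low" (ties at the median are assigned
#' to "low", which is deterministic and reproduces a 17/17 split of 34
#' distinct values).
#'
#' @param values named numeric vector keyed by sample id, length >= 2.
#' @return named character vector of "low"/"high".
#' @export
median_split <- function(values) {
  if (length(values) < 2L) stop("need at least 2 samples")
  med <- median(values)
  setNames(ifelse(values <= med, "low", "high"), names(values))
}

check_table <- function(x, exact = FALSE) {
  x <- as.matrix(x)
  if (any(x < 0) || any(x != round(x))) stop("cells must be non-negative integers")
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need at least 2 rows and 2 columns")
  if (exact && (any(rowSums(x) == 0) || any(colSums(x) == 0)))
    stop("exact tests require all margins > 0")
  x
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sums the hypergeometric point probabilities of every table with the same
#' margins whose probability does not exceed the observed table's (relative
#' tolerance 1e-7) — the dominant two-sided convention; no mid-p.
#'
#' @param x 2x2 matrix of non-negative integer counts with positive margins.
#' @return two-sided p-value in (0, 1\].
#' @examples
#' fisher_exact_2x2(matrix(c(11, 6, 7, 10), 2))  # 0.303
#' @export
fisher_exact_2x2 <- function(x) {
  x <- check_table(x, exact = TRUE)
  if (nrow(x) != 2L || ncol(x) != 2L)
    stop("table is not 2x2; use freeman_halton_exact for r x c tables")
  m <- sum(x[1L, ])          # row 1 margin
  n <- sum(x[2L, ])          # row 2 margin
  k <- sum(x[, 1L])          # column 1 margin
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(x[1L, 1L], m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Pearson chi-squared test with optional Yates correction
#'
#' `X^2 = sum (O - E)^2 / E` with expected cells from the margins; the Yates
#' continuity correction `(|O - E| - 0.5)^2` applies to 2x2 tables only.
#'
#' @param x r x c matrix of non-negative integer counts.
#' @param yates apply the continuity correction (2x2 only; default FALSE).
#' @return list with `statistic`, `df`, `p`.
#' @examples
#' chi2_test(matrix(c(14, 3, 5, 12), 2), yates = TRUE)$p   # rounds to 0.006
#' @export
chi2_test <- function(x, yates = FALSE) {
  x <- check_table(x)
  e <- outer(rowSums(x), colSums(x)) / sum(x)
  if (any(e == 0)) stop("zero expected cell; drop empty margins first")
  if (yates && (nrow(x) != 2L || ncol(x) != 2L))
    stop("Yates correction applies to 2x2 tables only")
  dev <- abs(x - e)
  if (yates) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / e)
  df <- (nrow(x) - 1L) * (ncol(x) - 1L)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

#' Freeman-Halton exact test for r x c tables
#'
#' Full enumeration of all tables with the observed margins; the two-sided p
#' is the sum of multivariate hypergeometric probabilities of tables no more
#' probable than the observed one (relative tolerance 1e-7). Reduces to
#' [fisher_exact_2x2()] on 2x2 tables.
#'
#' @param x r x c matrix with positive margins and total n <= 60.
#' @return two-sided p-value in (0, 1\].
#' @export
freeman_halton_exact <- function(x) {
  x <- check_table(x, exact = TRUE)
  n <- sum(x)
  if (n > 60) stop("table too large to enumerate; use chi2_test")
  rs <- rowSums(x); cs <- colSums(x)
  log_const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1)
  lp_obs <- log_const - sum(lgamma(x + 1))
  tol <- log1p(1e-7)  # p <= p_obs * (1 + 1e-7) in log space
  total <- 0
  acc <- 0            # running -sum(lgamma(cell + 1)) over the fixed rows
  # depth-first enumeration over rows; each row is a composition of its
  # margin bounded by the remaining column margins
  recurse <- function(row_idx, col_left) {
    if (row_idx == length(rs)) {
      lp <- log_const + acc - sum(lgamma(col_left + 1))
      if (lp <= lp_obs + tol) total <<- total + exp(lp)
      return(invisible())
    }
    for (comp in compositions(rs[row_idx], col_left)) {
      acc <<- acc - sum(lgamma(comp + 1))
      recurse(row_idx + 1L, col_left - comp)
      acc <<- acc + sum(lgamma(comp + 1))
    }
  }
  recurse(1L, cs)
  min(total, 1)
}

# All compositions of total `s` into length(bounds) non-negative parts with
# part i <= bounds[i]; returned as a list of integer vectors.
compositions <- function(s, bounds) {
  k <- length(bounds)
  if (k == 1L) {
    if (s <= bounds[1L]) return(list(as.integer(s)))
    return(list())
  }
  out <- list()
  lo <- max(0L, s - sum(bounds[-1L]))
  hi <- min(s, bounds[1L])
  if (lo > hi) return(out)
  for (v in lo:hi)
    for (rest in compositions(s - v, bounds[-1L]))
      out[[length(out) + 1L]] <- c(as.integer(v), rest)
  out
}

#' Kaplan-Meier curves and the log-rank test for two groups
#'
#' Product-limit survival estimates per group with right censoring (deaths
#' processed before censorings at tied times — the standard convention), and
#' the two-group log-rank chi-squared statistic on 1 df using the
#' hypergeometric variance at each distinct death time.
#'
#' @param time positive numeric follow-up times (months).
#' @param event 1 = death, 0 = censored.
#' @param group vector with exactly two levels.
#' @return list with `curves` (data frame `group`, `time`, `n_risk`,
#'   `n_event`, `surv`), `statistic`, `df` (1) and `p`. If both groups are
#'   fully censored the statistic is 0 and `p = 1`, with a warning.
#' @examples
#' km_logrank(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))$statistic
#' @export
km_logrank <- function(time, event, group) {
  if (any(time <= 0)) stop("times must be positive")
  group <- as.character(group)
  levels <- sort(unique(group))
  if (length(levels) != 2L) stop("exactly two non-empty groups required")
  event <- as.integer(event)

  curves <- do.call(rbind, lapply(levels, function(g) {
    tt <- time[group == g]; ee <- event[group == g]
    ts <- sort(unique(tt))
    n_risk <- vapply(ts, function(u) sum(tt >= u), 0L)
    n_event <- vapply(ts, function(u) sum(tt == u & ee == 1L), 0L)
    surv <- cumprod(1 - n_event / n_risk)
    data.frame(group = g, time = ts, n_risk = n_risk, n_event = n_event,
               surv = surv, stringsAsFactors = FALSE)
  }))

  dtimes <- sort(unique(time[event == 1L]))
  if (length(dtimes) == 0L) {
    warning("no events in either group; log-rank statistic is 0")
    return(list(curves = curves, statistic = 0, df = 1L, p = 1))
  }
  o1 <- e1 <- v <- 0
  for (u in dtimes) {
    n1 <- sum(time >= u & group == levels[1L])
    n2 <- sum(time >= u & group == levels[2L])
    d1 <- sum(time == u & event == 1L & group == levels[1L])
    d2 <- sum(time == u & event == 1L & group == levels[2L])
    n <- n1 + n2; d <- d1 + d2
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1L) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  stat <- if (v > 0) (o1 - e1)^2 / v else 0
  list(curves = curves, statistic = stat, df = 1L,
       p = pchisq(stat, 1L, lower.tail = FALSE))
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per condition, `dCt = mean(target Ct - reference Ct)` over replicates;
#' `ddCt = dCt_case - dCt_control`; fold change `2^(-ddCt)`.
#'
#' @param measurements data frame with columns `target`, `condition`,
#'   `target_ct`, `reference_ct` (one row per replicate measurement).
#' @param condition_case,condition_control condition labels to compare.
#' @return data frame with `target`, `ddct`, `fold_change`.
#' @examples
#' m <- data.frame(target = "g", condition = c("case", "control"),
#'                 target_ct = c(24, 26), reference_ct = c(20, 20))
#' delta_delta_ct(m, "case", "control")$fold_change  # 4
#' @export
delta_delta_ct <- function(measurements, condition_case, condition_control) {
  need <- c("target", "condition", "target_ct", "reference_ct")
  if (!all(need %in% names(measurements)))
    stop("measurements must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(measurements$target_ct)) ||
      any(!is.finite(measurements$reference_ct)))
    stop("missing reference or target Ct value")
  targets <- unique(measurements$target)
  rows <- lapply(targets, function(tg) {
    sub <- measurements[measurements$target == tg, ]
    dct <- function(cond) {
      s <- sub[sub$condition == cond, ]
      if (nrow(s) == 0L)
        stop(sprintf("no measurements for target '%s' in condition '%s'",
                     tg, cond))
      mean(s$target_ct - s$reference_ct)
    }
    ddct <- dct(condition_case) - dct(condition_control)
    data.frame(target = tg, ddct = ddct, fold_change = 2^(-ddct),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
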