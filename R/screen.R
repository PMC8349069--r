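#' Thresholds for the ceRNA axis screen
#'
#' The removal criteria of the multi-step filtration are stated strictly
#' ("expressed in less than 50% of samples", "interaction score < 0.85",
#' "< 5 binding sites in the target lncRNA"), so the keep-side comparisons
#' here are inclusive (`>=`).
#'
#' @param prevalence_min minimum fraction of tumour samples in which the
#'   miRNA has a nonzero count (default 0.5).
#' @param score_min minimum interaction score on the lncRNA (default 0.85).
#' @param min_sites_lncrna minimum seed-site count on the lncRNA (default 5).
#' @param require_positive_correlation final filter: the axis lncRNA and mRNA
#'   must form a passing, positively signed correlation record (default TRUE).
#' @param mrna_score_min,mrna_min_sites optional mRNA-side score/site-count
#'   thresholds; the reference screen filters the mRNA side by miRNA
#'   prevalence alone, so both default to off (`0` and `1`).
#' @return a `screen_thresholds` list.
#' @export
screen_thresholds <- function(prevalence_min = 0.5, score_min = 0.85,
                              min_sites_lncrna = 5L,
                              require_positive_correlation = TRUE,
                              mrna_score_min = 0, mrna_min_sites = 1L) {
  if (prevalence_min <= 0 || prevalence_min > 1)
    stop("prevalence_min must lie in (0, 1]")
  if (score_min < 0 || score_min > 1) stop("score_min must lie in [0, 1]")
  if (min_sites_lncrna < 1L) stop("min_sites_lncrna must be >= 1")
  structure(list(prevalence_min = prevalence_min, score_min = score_min,
                 min_sites_lncrna = as.integer(min_sites_lncrna),
                 require_positive_correlation = isTRUE(require_positive_correlation),
                 mrna_score_min = mrna_score_min,
                 mrna_min_sites = as.integer(mrna_min_sites)),
            class = "screen_thresholds")
}

#' Expression prevalence of a gene across named samples
#'
#' Fraction of the named samples in which the count is greater than zero
#' ("expressed" is defined as `count > 0`).
#'
#' @param counts_row named numeric vector (one gene's counts) or a
#'   single-row slice of the count matrix.
#' @param sample_ids samples over which to compute the fraction.
#' @return fraction in `[0, 1]`.
#' @export
prevalence <- function(counts_row, sample_ids) {
  if (length(sample_ids) == 0L) stop("sample_ids must be non-empty")
  counts_row <- drop(as.matrix(counts_row))
  missing <- setdiff(sample_ids, names(counts_row))
  if (length(missing) > 0L)
    stop("unknown sample(s): ", paste(missing, collapse = ", "))
  mean(counts_row[sample_ids] > 0)
}

#' Screen candidate ceRNA axes
#'
#' Assembles every (lncRNA, miRNA, mRNA) triple from the miRNA-lncRNA and
#' miRNA-mRNA interaction records that share a miRNA, and evaluates the
#' filter cascade on each: miRNA prevalence over tumour samples, interaction
#' score and seed-site count on the lncRNA side, optional mRNA-side
#' thresholds, and finally a positive, screen-passing lncRNA-mRNA correlation.
#' Every candidate axis is returned with its full filter trace (failures
#' included) so the funnel is auditable; `final_pass` is true only when every
#' filter passes. A missing correlation record is recorded as a filter
#' failure, not an error.
#'
#' @param lncrna_ids,mrna_ids candidate gene ids (e.g. the DEG-intersection
#'   lncRNAs and the two-term-overlap mRNAs).
#' @param interactions_lnc,interactions_mrna interaction records from
#'   [predict_interactions()] for the lncRNA transcripts and mRNA 3'UTRs.
#' @param counts count matrix used for miRNA prevalence.
#' @param tumor_ids samples over which prevalence is computed.
#' @param correlations correlation records from [correlate_pairs()].
#' @param thresholds a [screen_thresholds()] object.
#' @return data frame, one row per candidate axis: ids, `mirna_prevalence`,
#'   `lnc_score`, `lnc_site_count`, `mrna_score`, `mrna_site_count`,
#'   `lnc_mrna_pcc`, `filter_trace` (semicolon-joined `name=value:pass`
#'   tokens) and `final_pass`.
#' @export
screen_axes <- function(lncrna_ids, mrna_ids, interactions_lnc,
                        interactions_mrna, counts, tumor_ids, correlations,
                        thresholds = screen_thresholds()) {
  stopifnot(inherits(thresholds, "screen_thresholds"))
  li <- interactions_lnc[interactions_lnc$target_id %in% lncrna_ids, ,
                         drop = FALSE]
  mi <- interactions_mrna[interactions_mrna$target_id %in% mrna_ids, ,
                          drop = FALSE]
  if (nrow(li) == 0L || nrow(mi) == 0L) return(empty_axes())
  mirnas <- union(li$mirna_id, mi$mirna_id)
  prev <- vapply(mirnas, function(m)
    prevalence(counts[m, , drop = FALSE], tumor_ids), numeric(1))
  merged <- merge(li, mi, by = "mirna_id", suffixes = c("_lnc", "_mrna"))
  if (nrow(merged) == 0L) return(empty_axes())
  corr_key <- paste(correlations$lncrna_id, correlations$pcg_id)
  rows <- lapply(seq_len(nrow(merged)), function(i) {
    z <- merged[i, ]
    pv <- prev[[z$mirna_id]]
    ci <- match(paste(z$target_id_lnc, z$target_id_mrna), corr_key)
    pcc <- if (is.na(ci)) NA_real_ else correlations$pcc[ci]
    corr_ok <- !is.na(ci) && correlations$passes[ci] && correlations$pcc[ci] > 0
    trace <- list(
      c("mirna_prevalence", pv, pv >= thresholds$prevalence_min),
      c("lnc_score", z$score_lnc, z$score_lnc >= thresholds$score_min),
      c("lnc_sites", z$n_sites_lnc,
        z$n_sites_lnc >= thresholds$min_sites_lncrna),
      c("mrna_score", z$score_mrna, z$score_mrna >= thresholds$mrna_score_min),
      c("mrna_sites", z$n_sites_mrna,
        z$n_sites_mrna >= thresholds$mrna_min_sites))
    if (thresholds$require_positive_correlation)
      trace <- c(trace, list(c("positive_correlation",
                               ifelse(is.na(pcc), "NA", signif(pcc, 6)),
                               corr_ok)))
    pass <- all(vapply(trace, function(e) as.logical(e[3L]), TRUE))
    data.frame(lncrna_id = z$target_id_lnc, mirna_id = z$mirna_id,
               mrna_id = z$target_id_mrna, mirna_prevalence = pv,
               lnc_score = z$score_lnc, lnc_site_count = z$n_sites_lnc,
               mrna_score = z$score_mrna, mrna_site_count = z$n_sites_mrna,
               lnc_mrna_pcc = pcc,
               filter_trace = paste(vapply(trace, function(e)
                 sprintf("%s=%s:%s", e[1L], e[2L],
                         ifelse(as.logical(e[3L]), "pass", "fail")),
                 character(1)), collapse = ";"),
               final_pass = pass, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_axes <- function() {
  data.frame(lncrna_id = character(0), mirna_id = character(0),
             mrna_id = character(0), mirna_prevalence = numeric(0),
             lnc_score = numeric(0), lnc_site_count = integer(0),
             mrna_score = numeric(0), mrna_site_count = integer(0),
             lnc_mrna_pcc = numeric(0), filter_trace = character(0),
             final_pass = logical(0), stringsAsFactors = FALSE)
}

#' Rank screened axes
#'
#' Passing axes first; within each block, descending `(lnc_mrna_pcc,
#' lnc_score, lnc_site_count)` with lexicographic id tie-breaks. Deterministic.
#'
#' @param axes data frame from [screen_axes()].
#' @return the reordered data frame.
#' @export
rank_axes <- function(axes) {
  if (nrow(axes) == 0L) return(axes)
  pcc <- ifelse(is.na(axes$lnc_mrna_pcc), -Inf, axes$lnc_mrna_pcc)
  o <- order(!axes$final_pass, -pcc, -axes$lnc_score, -axes$lnc_site_count,
             axes$lncrna_id, axes$mirna_id, axes$mrna_id)
  out <- axes[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-stage survivor counts of the axis screen
#'
#' @param axes data frame from [screen_axes()].
#' @param thresholds the [screen_thresholds()] used.
#' @return data frame `stage`, `count`: candidate triples, survivors of each
#'   successive filter, and final passes.
#' @export
screen_funnel <- function(axes, thresholds = screen_thresholds()) {
  stages <- c("candidate_triples", "after_prevalence", "after_lnc_score",
              "after_lnc_sites", "after_mrna_filters", "final_pass")
  if (nrow(axes) == 0L)
    return(data.frame(stage = stages, count = 0L, stringsAsFactors = FALSE))
  keep <- rep(TRUE, nrow(axes))
  counts <- integer(0)
  counts <- c(counts, sum(keep))
  keep <- keep & axes$mirna_prevalence >= thresholds$prevalence_min
  counts <- c(counts, sum(keep))
  keep <- keep & axes$lnc_score >= thresholds$score_min
  counts <- c(counts, sum(keep))
  keep <- keep & axes$lnc_site_count >= thresholds$min_sites_lncrna
  counts <- c(counts, sum(keep))
  keep <- keep & axes$mrna_score >= thresholds$mrna_score_min &
    axes$mrna_site_count >= thresholds$mrna_min_sites
  counts <- c(counts, sum(keep))
  counts <- c(counts, sum(axes$final_pass))
  data.frame(stage = stages, count = counts, stringsAsFactors = FALSE)
}
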