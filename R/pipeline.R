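#' Analysis parameters for the ceRNA screening pipeline
#'
#' @param fc_threshold inclusive `|log2FC|` DEG cut-off (default 1).
#' @param alpha adjusted-p cut-off for DEG, correlation and enrichment calls
#'   (default 0.05).
#' @param r_threshold strict `|PCC|` cut-off (default 0.45).
#' @param thresholds a [screen_thresholds()] object.
#' @param weights MRE site weights from [mre_weights()].
#' @param terms the two annotation term ids whose gene intersection defines
#'   the candidate mRNA set (defaults to the generator's designated terms).
#' @param paired use the paired test for the tumour-vs-normal contrast
#'   (default FALSE; the reference analysis does not state a paired design).
#' @return a `pipeline_params` list.
#' @export
pipeline_params <- function(fc_threshold = 1, alpha = 0.05, r_threshold = 0.45,
                            thresholds = screen_thresholds(),
                            weights = mre_weights(),
                            terms = c("adhesion_like", "epidermis_like"),
                            paired = FALSE) {
  if (length(terms) != 2L) stop("exactly two term ids are required")
  structure(list(fc_threshold = fc_threshold, alpha = alpha,
                 r_threshold = r_threshold, thresholds = thresholds,
                 weights = weights, terms = terms, paired = isTRUE(paired)),
            class = "pipeline_params")
}

#' Run the full ceRNA screening pipeline in memory
#'
#' Executes the whole screen on a cohort: size factors and log2-normalised
#' expression; differential expression for the tumour-vs-paired-normal and
#' OLNM+ vs OLNM- contrasts with lncRNA-set intersection; lncRNA-PCG
#' correlation; gene-set over-representation and two-term intersection to fix
#' the candidate mRNAs; seed-site prediction on candidate lncRNA transcripts
#' and mRNA 3'UTRs; the multi-filter axis screen; and the clinical
#' association of the top passing lncRNA (median split vs OLNM, Kaplan-Meier
#' and log-rank).
#'
#' @param cohort a `synthetic_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param params a [pipeline_params()] object.
#' @param verbose emit per-stage log messages.
#' @return list with per-stage results: `size_factors`, `expr`, `deg`,
#'   `candidate_lncrnas`, `correlations`, `enrichment`, `candidate_mrnas`,
#'   `interactions_lnc`, `interactions_mrna`, `axes` (ranked), `funnel`,
#'   `clinical`.
#' @export
run_pipeline <- function(cohort, params = pipeline_params(), verbose = FALSE) {
  log_stage <- function(...) if (verbose) message("[cernascreen] ", sprintf(...))
  counts <- cohort$counts
  samples <- cohort$samples
  tumor_ids <- samples$sample_id[samples$tissue == "tumor"]
  normal_ids <- samples$sample_id[samples$tissue == "normal"]
  paired_tumors <- samples$sample_id[samples$tissue == "tumor" &
                                       !is.na(samples$pair_id)]
  olnm_pos <- samples$sample_id[samples$tissue == "tumor" &
                                  samples$olnm == "pos"]
  olnm_neg <- samples$sample_id[samples$tissue == "tumor" &
                                  samples$olnm == "neg"]

  sf <- size_factors(counts)
  expr <- log2(sweep(counts, 2L, sf, "/") + 1)
  log_stage("normalised %d genes x %d samples", nrow(counts), ncol(counts))

  recs <- list(
    tumor_vs_normal = deg_test(counts, sf, paired_tumors, normal_ids,
                               paired = params$paired,
                               gene_class = cohort$gene_class),
    olnm_pos_vs_neg = deg_test(counts, sf, olnm_pos, olnm_neg,
                               gene_class = cohort$gene_class))
  deg <- call_and_intersect(recs, fc_threshold = params$fc_threshold,
                            alpha = params$alpha, class = "lncRNA")
  cand_lnc <- deg$common$gene_id
  log_stage("DEG intersection: %d candidate lncRNAs", length(cand_lnc))

  pcg_ids <- names(cohort$gene_class)[cohort$gene_class == "PCG"]
  correlations <- correlate_pairs(expr[, tumor_ids, drop = FALSE],
                                  cand_lnc, pcg_ids,
                                  r_threshold = params$r_threshold,
                                  alpha = params$alpha)
  cand_pcg <- sort(unique(correlations$pcg_id[correlations$passes]))
  log_stage("correlation screen: %d correlated PCGs", length(cand_pcg))

  enrichment <- hypergeom_ora(cand_pcg, cohort$gene_sets, pcg_ids,
                              alpha = params$alpha)
  missing_terms <- setdiff(params$terms, names(cohort$gene_sets))
  if (length(missing_terms) > 0L)
    stop("term id(s) not in gene sets: ", paste(missing_terms, collapse = ", "))
  cand_mrna <- intersect_terms(cohort$gene_sets[[params$terms[1L]]],
                               cohort$gene_sets[[params$terms[2L]]], cand_pcg)
  log_stage("two-term intersection: %d candidate mRNAs", length(cand_mrna))

  interactions_lnc <- predict_interactions(
    cohort$sequences$mirna, cohort$sequences$lncrna[cand_lnc], "lncRNA",
    weights = params$weights)
  interactions_mrna <- predict_interactions(
    cohort$sequences$mirna, cohort$sequences$utr3[cand_mrna], "mRNA_3UTR",
    weights = params$weights)
  log_stage("MRE prediction: %d miRNA-lncRNA and %d miRNA-mRNA interactions",
            nrow(interactions_lnc), nrow(interactions_mrna))

  axes <- screen_axes(cand_lnc, cand_mrna, interactions_lnc, interactions_mrna,
                      counts, tumor_ids, correlations,
                      thresholds = params$thresholds)
  axes <- rank_axes(axes)
  funnel <- screen_funnel(axes, params$thresholds)
  log_stage("axis screen: %d candidate triples, %d final passes",
            nrow(axes), sum(axes$final_pass))

  clinical <- NULL
  top <- axes[axes$final_pass, , drop = FALSE]
  if (nrow(top) > 0L) {
    target <- top$lncrna_id[1L]
    split <- median_split(expr[target, tumor_ids])
    olnm_status <- samples$olnm[match(tumor_ids, samples$sample_id)]
    tab <- table(factor(olnm_status, c("neg", "pos")),
                 factor(split, c("low", "high")))
    fisher_p <- fisher_exact_2x2(unclass(tab))
    surv <- samples[match(tumor_ids, samples$sample_id), ]
    km <- if (!all(is.na(surv$time_months)))
      km_logrank(surv$time_months, surv$event, split) else NULL
    clinical <- list(target = target, split = split,
                     contingency = unclass(tab), fisher_p = fisher_p, km = km)
    log_stage("clinical: %s median split, Fisher p = %.3g, log-rank p = %.3g",
              target, fisher_p, if (is.null(km)) NA else km$p)
  }

  list(size_factors = sf, expr = expr, deg = deg,
       candidate_lncrnas = cand_lnc, correlations = correlations,
       enrichment = enrichment, candidate_mrnas = cand_mrna,
       interactions_lnc = interactions_lnc,
       interactions_mrna = interactions_mrna, axes = axes, funnel = funnel,
       clinical = clinical)
}
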