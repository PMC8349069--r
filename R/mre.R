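SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

#' Default noisy-OR site weights
#'
#' Per-site-type weights for [interaction_score()]. The defaults (8mer 0.6,
#' 7mer-m8 0.4, 7mer-A1 0.25, 6mer 0.1) follow the canonical efficacy ordering
#' of seed-site types and are calibrated so that five moderate sites clear an
#' interaction-score cut-off of 0.85 while sparse or weak sites do not.
#'
#' @param `8mer`,`7mer-m8`,`7mer-A1`,`6mer` weights in `[0, 1)`.
#' @return named numeric vector.
#' @export
mre_weights <- function(`8mer` = 0.6, `7mer-m8` = 0.4, `7mer-A1` = 0.25,
                        `6mer` = 0.1) {
  w <- c(`8mer` = `8mer`, `7mer-m8` = `7mer-m8`, `7mer-A1` = `7mer-A1`,
         `6mer` = `6mer`)
  if (any(w < 0 | w >= 1)) stop("site weights must lie in [0, 1)")
  w
}

# Classify core anchor positions on a normalised target sequence.
# `anchors` are 1-based start positions of the rc(2-7) core; returns a data
# frame of site_type and start (1-based, leftmost nucleotide of the site).
classify_anchors <- function(target, anchors, cm8) {
  if (length(anchors) == 0L)
    return(data.frame(site_type = character(0), start = integer(0),
                      stringsAsFactors = FALSE))
  L <- nchar(target)
  left <- ifelse(anchors > 1L, substring(target, anchors - 1L, anchors - 1L), "")
  right <- ifelse(anchors + 6L <= L, substring(target, anchors + 6L, anchors + 6L), "")
  has_m8 <- left == cm8
  has_a1 <- right == "A"
  type <- ifelse(has_m8 & has_a1, "8mer",
          ifelse(has_m8, "7mer-m8",
          ifelse(has_a1, "7mer-A1", "6mer")))
  start <- ifelse(has_m8, anchors - 1L, anchors)
  data.frame(site_type = type, start = as.integer(start),
             stringsAsFactors = FALSE)
}

#' Find miRNA seed sites on a target sequence
#'
#' Scans every position of the target (5'->3' sense strand) for canonical
#' seed matches to the miRNA: the match core is the reverse complement of
#' miRNA positions 2-7; adding the m8-complementary base on the 5' side and/or
#' an A opposite miRNA position 1 on the 3' side upgrades the site to
#' 7mer-m8, 7mer-A1 or 8mer. Each core anchor yields exactly one site of the
#' strongest applicable type. U and T are interchangeable; case is ignored.
#'
#' @param mirna_seq mature miRNA sequence, 5'->3', length >= 8.
#' @param target_seq target sequence (transcript or 3'UTR), 5'->3'.
#' @return data frame with `site_type` and `start` (1-based inclusive position
#'   of the leftmost site nucleotide on the target).
#' @examples
#' find_seed_sites("UGAGGUAGUAGGUUGUAUAGUU", "AAACTACCTCAGG")  # 8mer at 4
#' @export
find_seed_sites <- function(mirna_seq, target_seq) {
  m <- normalize_seq(mirna_seq, "miRNA sequence")
  if (nchar(m) < 8L) stop("miRNA sequence must be at least 8 nt")
  t <- normalize_seq(target_seq, "target sequence")
  core <- revcomp(substr(m, 2L, 7L))
  cm8 <- comp_base(substr(m, 8L, 8L))
  L <- nchar(t)
  n <- L - 5L
  if (n < 1L)
    return(data.frame(site_type = character(0), start = integer(0),
                      stringsAsFactors = FALSE))
  anchors <- which(substring(t, seq_len(n), seq_len(n) + 5L) == core)
  classify_anchors(t, anchors, cm8)
}

#' Noisy-OR interaction score for a set of seed sites
#'
#' `score = 1 - prod(1 - w_type)` over the sites: bounded in `[0, 1)`, zero
#' without sites, and strictly increasing in every added site.
#'
#' @param sites data frame with a `site_type` column (as from
#'   [find_seed_sites()]), or a character vector of site types.
#' @param weights named weights from [mre_weights()].
#' @return numeric score in `[0, 1)`.
#' @examples
#' interaction_score(rep("7mer-m8", 5))  # 1 - 0.6^5 = 0.92224
#' @export
interaction_score <- function(sites, weights = mre_weights()) {
  weights <- mre_weights(`8mer` = weights[["8mer"]],
                         `7mer-m8` = weights[["7mer-m8"]],
                         `7mer-A1` = weights[["7mer-A1"]],
                         `6mer` = weights[["6mer"]])
  types <- if (is.data.frame(sites)) sites$site_type else as.character(sites)
  if (length(types) == 0L) return(0)
  if (!all(types %in% SITE_TYPES))
    stop("unknown site type(s): ",
         paste(setdiff(types, SITE_TYPES), collapse = ", "))
  1 - prod(1 - weights[types])
}

#' Predict miRNA-target interactions for sequence collections
#'
#' Runs [find_seed_sites()] for every (miRNA, target) pair and summarises
#' pairs with at least one site into interaction records with per-type site
#' counts and the noisy-OR interaction score. Rows are ordered by
#' `(mirna_id, target_id)`.
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param targets named character vector of target sequences.
#' @param target_class label stored on the records, e.g. `"lncRNA"` or
#'   `"mRNA_3UTR"`.
#' @param weights site weights from [mre_weights()].
#' @return data frame with `mirna_id`, `target_id`, `target_class`, per-type
#'   counts `n_8mer`, `n_7mer_m8`, `n_7mer_a1`, `n_6mer`, `n_sites`, `score`.
#' @export
predict_interactions <- function(mirnas, targets,
                                 target_class = c("lncRNA", "mRNA_3UTR"),
                                 weights = mre_weights()) {
  target_class <- match.arg(target_class)
  if (length(mirnas) && (is.null(names(mirnas)) || anyDuplicated(names(mirnas))))
    stop("miRNA sequences must have unique ids")
  if (length(targets) && (is.null(names(targets)) || anyDuplicated(names(targets))))
    stop("target sequences must have unique ids")
  if (length(mirnas) == 0L || length(targets) == 0L)
    return(empty_interactions())
  mirnas <- vapply(mirnas, normalize_seq, character(1), what = "miRNA sequence")
  targets <- vapply(targets, normalize_seq, character(1),
                    what = "target sequence")
  cores <- vapply(mirnas, function(m) revcomp(substr(m, 2L, 7L)), character(1))
  cm8s <- vapply(mirnas, function(m) comp_base(substr(m, 8L, 8L)), character(1))
  if (any(nchar(mirnas) < 8L)) stop("miRNA sequences must be at least 8 nt")
  rows <- list()
  for (tid in names(targets)) {
    tseq <- targets[[tid]]
    L <- nchar(tseq)
    if (L < 6L) next
    tab <- substring(tseq, seq_len(L - 5L), seq_len(L - 5L) + 5L)
    for (mid in names(mirnas)) {
      anchors <- which(tab == cores[[mid]])
      if (length(anchors) == 0L) next
      sites <- classify_anchors(tseq, anchors, cm8s[[mid]])
      cnt <- table(factor(sites$site_type, levels = SITE_TYPES))
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = mid, target_id = tid, target_class = target_class,
        n_8mer = as.integer(cnt[["8mer"]]),
        n_7mer_m8 = as.integer(cnt[["7mer-m8"]]),
        n_7mer_a1 = as.integer(cnt[["7mer-A1"]]),
        n_6mer = as.integer(cnt[["6mer"]]),
        n_sites = nrow(sites),
        score = interaction_score(sites, weights),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty_interactions())
  out <- do.call(rbind, rows)
  out <- out[order(out$mirna_id, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_interactions <- function() {
  data.frame(mirna_id = character(0), target_id = character(0),
             target_class = character(0), n_8mer = integer(0),
             n_7mer_m8 = integer(0), n_7mer_a1 = integer(0),
             n_6mer = integer(0), n_sites = integer(0), score = numeric(0),
             stringsAsFactors = FALSE)
}
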