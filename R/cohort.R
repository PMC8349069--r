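#' Configuration for the synthetic cohort generator
#'
#' Describes a desk-scale cohort with the design of a clinically node-negative
#' (cN0) tongue-cancer study: tumour samples with a paired-normal subset, an
#' occult-lymph-node-metastasis (OLNM) split within the tumours, negative
#' binomial counts, planted lncRNA/miRNA/mRNA ceRNA axes, and decoy axes that
#' each violate exactly one screening filter.
#'
#' @param n_tumor number of tumour samples (default 53, the cN0M0 cohort size).
#' @param n_paired_normal number of adjacent-normal samples, paired with the
#'   first `n_paired_normal` tumours (default 13 pairs).
#' @param n_olnm_pos number of tumours flagged OLNM-positive; must be smaller
#'   than `n_tumor`. Default 18 (about a third of 53, mid-range of the 20-40%
#'   occult-metastasis rate reported for cN0 necks).
#' @param n_lncrna,n_pcg,n_mirna gene counts per class (defaults 300, 2000, 150).
#' @param n_true_axes number of planted true ceRNA axes (default 3).
#' @param n_decoys_per_class number of decoy axes per decoy role (default 2);
#'   there are five decoy roles, one per screening filter.
#' @param nb_dispersion negative binomial dispersion (default 0.15; counts are
#'   drawn with `size = 1/nb_dispersion`).
#' @param effect_log2fc planted log2 fold change per unit of latent activity
#'   (default 2). Latent activity is 0 for normals, 1 for OLNM- tumours, 2 for
#'   OLNM+ tumours, so one parameter couples both contrasts and the positive
#'   lncRNA-mRNA correlation.
#' @param lib_size_sigma log-normal sd of per-sample library size factors
#'   (default 0.15).
#' @param lncrna_len,utr_len,mirna_len sequence lengths in nt
#'   (defaults 1500, 800, 22).
#' @param survival_hr hazard ratio applied to tumours above the median count of
#'   the first true-axis lncRNA (default 2.5); 1 disables the survival signal.
#' @param seed integer seed; identical config + seed gives identical cohorts.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_tumor = 53L, n_paired_normal = 13L,
                          n_olnm_pos = 18L,
                          n_lncrna = 300L, n_pcg = 2000L, n_mirna = 150L,
                          n_true_axes = 3L, n_decoys_per_class = 2L,
                          nb_dispersion = 0.15, effect_log2fc = 2,
                          lib_size_sigma = 0.15,
                          lncrna_len = 1500L, utr_len = 800L, mirna_len = 22L,
                          survival_hr = 2.5, seed = 1L) {
  cfg <- list(n_tumor = as.integer(n_tumor),
              n_paired_normal = as.integer(n_paired_normal),
              n_olnm_pos = as.integer(n_olnm_pos),
              n_lncrna = as.integer(n_lncrna), n_pcg = as.integer(n_pcg),
              n_mirna = as.integer(n_mirna),
              n_true_axes = as.integer(n_true_axes),
              n_decoys_per_class = as.integer(n_decoys_per_class),
              nb_dispersion = nb_dispersion, effect_log2fc = effect_log2fc,
              lib_size_sigma = lib_size_sigma,
              lncrna_len = as.integer(lncrna_len),
              utr_len = as.integer(utr_len), mirna_len = as.integer(mirna_len),
              survival_hr = survival_hr, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

DECOY_ROLES <- c("DECOY_LOW_PREVALENCE", "DECOY_LOW_SCORE", "DECOY_FEW_SITES",
                 "DECOY_NEGATIVE_CORRELATION", "DECOY_NOT_DE")
AXIS_ROLES <- c("TRUE_AXIS", DECOY_ROLES)

validate_cohort_config <- function(cfg) {
  for (f in c("n_tumor", "n_paired_normal", "n_olnm_pos", "n_lncrna", "n_pcg",
              "n_mirna", "n_true_axes", "n_decoys_per_class", "lncrna_len",
              "utr_len", "mirna_len", "seed"))
    assert_scalar_number(cfg[[f]], f)
  for (f in c("nb_dispersion", "effect_log2fc", "lib_size_sigma",
              "survival_hr"))
    assert_scalar_number(cfg[[f]], f)
  if (cfg$n_tumor < 2L) stop_config("n_tumor", "must be >= 2")
  if (cfg$n_olnm_pos < 0L || cfg$n_olnm_pos >= cfg$n_tumor)
    stop_config("n_olnm_pos", "must be non-negative and < n_tumor")
  if (cfg$n_paired_normal < 0L || cfg$n_paired_normal > cfg$n_tumor)
    stop_config("n_paired_normal", "must be between 0 and n_tumor")
  for (f in c("n_lncrna", "n_pcg", "n_mirna", "n_true_axes",
              "n_decoys_per_class"))
    if (cfg[[f]] < 0L) stop_config(f, "must be >= 0")
  n_axes <- cfg$n_true_axes + 5L * cfg$n_decoys_per_class
  if (cfg$n_lncrna < n_axes) stop_config("n_lncrna", "must be >= number of planted axes")
  if (cfg$n_pcg < n_axes) stop_config("n_pcg", "must be >= number of planted axes")
  if (cfg$n_mirna < n_axes) stop_config("n_mirna", "must be >= number of planted axes")
  if (cfg$nb_dispersion <= 0) stop_config("nb_dispersion", "must be > 0")
  if (cfg$effect_log2fc < 0) stop_config("effect_log2fc", "must be >= 0")
  if (cfg$lib_size_sigma < 0) stop_config("lib_size_sigma", "must be >= 0")
  if (cfg$survival_hr <= 0) stop_config("survival_hr", "must be > 0")
  if (cfg$mirna_len < 8L) stop_config("mirna_len", "must be >= 8 (seed region)")
  if (n_axes > 0L && (cfg$lncrna_len < 80L || cfg$utr_len < 80L))
    stop_config("lncrna_len", "and utr_len must be >= 80 when axes are planted")
  cfg
}

# ---- seed-site planting helpers ---------------------------------------------

# Planted-site window strings for one miRNA (DNA, 5'->3' on the target).
# Window contents pin down the flanking bases that define each site type, so
# the scanner classifies planted sites exactly as designed.
site_windows <- function(mirna_dna) {
  core <- revcomp(substr(mirna_dna, 2L, 7L))    # matches miRNA positions 2-7
  rc28 <- revcomp(substr(mirna_dna, 2L, 8L))    # adds the m8-complementary base
  cm8 <- substr(rc28, 1L, 1L)
  not_cm8 <- setdiff(DNA_BASES, cm8)[1L]
  list(`8mer` = paste0(rc28, "A"),
       `7mer-m8` = paste0(rc28, "C"),
       `7mer-A1` = paste0(not_cm8, core, "A"),
       `6mer` = paste0(not_cm8, core, "C"))
}

# Site plan per planted-axis role: counts by type for the lncRNA transcript
# and for the mRNA 3'UTR. True-like axes carry 5 strong lncRNA sites
# (noisy-OR score 0.977 >= 0.85); the score decoy carries five weak 6mers
# (score 0.410 < 0.85 but still 5 sites); the site-count decoy carries 4
# strong sites (score 0.962 but < 5 sites).
site_plan <- function(role) {
  strong_lnc <- c(`8mer` = 3L, `7mer-m8` = 2L, `7mer-A1` = 0L, `6mer` = 0L)
  utr <- c(`8mer` = 1L, `7mer-m8` = 1L, `7mer-A1` = 0L, `6mer` = 0L)
  lnc <- switch(role,
    DECOY_LOW_SCORE = c(`8mer` = 0L, `7mer-m8` = 0L, `7mer-A1` = 0L, `6mer` = 5L),
    DECOY_FEW_SITES = c(`8mer` = 3L, `7mer-m8` = 1L, `7mer-A1` = 0L, `6mer` = 0L),
    strong_lnc)
  list(lnc = lnc, utr = utr)
}

# Draw axis miRNAs by rejection so that (a) every miRNA core (reverse
# complement of positions 2-7) is unique, (b) no axis core occurs inside any
# other axis miRNA's planted window, and (c) no core occurs twice within its
# own windows. This guarantees planted site counts are exact after scrubbing.
draw_axis_mirnas <- function(n, len) {
  seqs <- character(0)
  windows <- list()
  cores <- character(0)
  tries <- 0L
  while (length(seqs) < n) {
    tries <- tries + 1L
    if (tries > 10000L) stop("failed to draw compatible axis miRNA sequences")
    cand <- random_seqs(1L, len)
    w <- site_windows(cand)
    core <- revcomp(substr(cand, 2L, 7L))
    ok <- !(core %in% cores)
    if (ok) # core appears exactly once in each of its own windows
      ok <- all(vapply(unlist(w), function(x) count_matches(core, x), 1L) == 1L)
    if (ok && length(seqs) > 0L) {
      old_windows <- unlist(windows)
      ok <- all(vapply(old_windows, function(x) count_matches(core, x), 1L) == 0L) &&
        all(vapply(cores, function(cc) {
          all(vapply(unlist(w), function(x) count_matches(cc, x), 1L) == 0L)
        }, TRUE))
    }
    if (ok) {
      seqs <- c(seqs, cand)
      cores <- c(cores, core)
      windows <- c(windows, list(w))
    }
  }
  list(seqs = seqs, cores = cores, windows = windows)
}

# Number of (possibly overlapping) occurrences of `pattern` in `x`.
count_matches <- function(pattern, x) {
  n <- nchar(x) - nchar(pattern) + 1L
  if (n < 1L) return(0L)
  sum(substring(x, seq_len(n), seq_len(n) + nchar(pattern) - 1L) == pattern)
}

# Place window strings at non-overlapping random positions in a random
# background; returns the sequence and the protected intervals.
plant_in_background <- function(len, windows) {
  if (length(windows) == 0L)
    return(list(seq = random_seqs(1L, len), intervals = NULL))
  wlen <- nchar(windows)
  k <- length(windows)
  for (attempt in seq_len(500L)) {
    starts <- sort(sample.int(len - max(wlen) + 1L, k))
    if (k == 1L || all(diff(starts) >= wlen[-k] + 2L)) break
    if (attempt == 500L) stop("could not place planted sites without overlap")
  }
  chars <- strsplit(random_seqs(1L, len), "", fixed = TRUE)[[1L]]
  for (i in seq_len(k)) {
    idx <- starts[i]:(starts[i] + wlen[i] - 1L)
    chars[idx] <- strsplit(windows[i], "", fixed = TRUE)[[1L]]
  }
  list(seq = paste(chars, collapse = ""),
       intervals = cbind(start = starts, end = starts + wlen - 1L))
}

# Mutate accidental core matches outside the protected intervals so the
# planted site counts are exact. One substring table per pass serves every
# core; deterministic base rotation; repeats because a mutation can itself
# create a new match (rare, converges in 2-3 passes).
scrub_sequence <- function(seq, cores, intervals = NULL) {
  cores <- unique(cores)
  if (length(cores) == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  protected <- rep(FALSE, length(chars))
  if (!is.null(intervals))
    for (i in seq_len(nrow(intervals)))
      protected[intervals[i, "start"]:intervals[i, "end"]] <- TRUE
  rotate <- c(A = "C", C = "G", G = "T", T = "A")
  width <- nchar(cores[1L])
  n <- length(chars) - width + 1L
  if (n < 1L) return(seq)
  for (pass in seq_len(50L)) {
    s <- paste(chars, collapse = "")
    tab <- substring(s, seq_len(n), seq_len(n) + width - 1L)
    hits <- which(tab %in% cores)
    mutated <- FALSE
    for (q in hits) {
      span <- q:(q + width - 1L)
      # re-check against the current characters: an earlier mutation in this
      # pass may already have destroyed this occurrence
      if (!paste(chars[span], collapse = "") %in% cores) next
      free <- span[!protected[span]]
      if (length(free) == 0L) next  # planted (or fully inside a window): keep
      chars[free[1L]] <- rotate[[chars[free[1L]]]]
      mutated <- TRUE
    }
    if (!mutated) return(paste(chars, collapse = ""))
  }
  paste(chars, collapse = "")
}

# ---- generator ---------------------------------------------------------------

#' Generate a planted-truth synthetic cohort
#'
#' Draws a gene-by-sample negative binomial count matrix, transcript/3'UTR and
#' mature miRNA sequences carrying planted seed sites, gene-set annotations
#' with two designated terms whose intersection holds the planted-axis mRNAs,
#' a clinical sample table (tissue, pairing, OLNM status, survival), and the
#' ground-truth table of planted axes.
#'
#' Planted differential expression and co-expression come from one latent
#' activity per sample, `a = 0` (normal), `1` (tumour OLNM-), `2` (tumour
#' OLNM+): each true-axis lncRNA and mRNA mean is multiplied by
#' `2^(effect_log2fc * a)`, which induces differential expression in both
#' contrasts and a positive lncRNA-mRNA correlation through one mechanism.
#' Decoy roles each violate exactly one screening filter (miRNA prevalence,
#' interaction score, lncRNA site count, correlation sign, or the DEG screen).
#'
#' @param config a [cohort_config()].
#' @return a `synthetic_cohort` list: `counts` (integer matrix), `gene_class`
#'   (named vector), `samples` (data frame), `sequences` (named lists
#'   `lncrna`, `utr3`, `mirna`), `gene_sets`, `truth`, `planted_effects`, and
#'   the originating `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_lncrna = 20, n_pcg = 60,
#'   n_mirna = 15, n_true_axes = 1, n_decoys_per_class = 0, seed = 7))
#' dim(coh$counts)
#' coh$truth
#' @export
generate_cohort <- function(config = cohort_config()) {
  config <- validate_cohort_config(config)
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n_axes <- cfg$n_true_axes + 5L * cfg$n_decoys_per_class
  roles <- c(rep("TRUE_AXIS", cfg$n_true_axes),
             rep(DECOY_ROLES, each = cfg$n_decoys_per_class))

  lnc_ids <- sprintf("LNC%04d", seq_len(cfg$n_lncrna))
  pcg_ids <- sprintf("PCG%04d", seq_len(cfg$n_pcg))
  mir_ids <- sprintf("MIR%04d", seq_len(cfg$n_mirna))

  tumor_ids <- sprintf("T%03d", seq_len(cfg$n_tumor))
  normal_ids <- sprintf("N%03d", seq_len(cfg$n_paired_normal))
  sample_ids <- c(tumor_ids, normal_ids)
  n_samples <- length(sample_ids)

  olnm_pos <- sort(sample.int(cfg$n_tumor, cfg$n_olnm_pos))
  olnm <- rep("neg", cfg$n_tumor); olnm[olnm_pos] <- "pos"
  activity <- c(ifelse(olnm == "pos", 2, 1), rep(0, cfg$n_paired_normal))

  lib <- rlnorm(n_samples, 0, cfg$lib_size_sigma)

  # baseline means; planted axis genes are pinned to a well-expressed level
  base <- c(rlnorm(cfg$n_lncrna, log(150), 1),
            rlnorm(cfg$n_pcg, log(150), 1),
            rlnorm(cfg$n_mirna, log(150), 1))
  gene_ids <- c(lnc_ids, pcg_ids, mir_ids)
  gene_class <- setNames(rep(c("lncRNA", "PCG", "miRNA"),
                             c(cfg$n_lncrna, cfg$n_pcg, cfg$n_mirna)), gene_ids)
  names(base) <- gene_ids

  beta <- setNames(rep(0, length(gene_ids)), gene_ids)  # log2FC per activity unit
  if (n_axes > 0L) {
    axis_lnc <- lnc_ids[seq_len(n_axes)]
    axis_mir <- mir_ids[seq_len(n_axes)]
    axis_mrna <- pcg_ids[seq_len(n_axes)]
    base[axis_lnc] <- 300; base[axis_mrna] <- 300; base[axis_mir] <- 120
    beta[axis_lnc] <- ifelse(roles == "DECOY_NOT_DE", 0, cfg$effect_log2fc)
    beta[axis_mrna] <- ifelse(roles == "DECOY_NEGATIVE_CORRELATION",
                              -cfg$effect_log2fc, cfg$effect_log2fc)
  } else {
    axis_lnc <- axis_mir <- axis_mrna <- character(0)
  }

  mu <- outer(base, lib) * 2^(outer(beta, activity))
  dimnames(mu) <- list(gene_ids, sample_ids)

  # low-prevalence decoy miRNAs: expressed in a fixed 30% subset of tumours
  low_prev_mask <- matrix(1, length(gene_ids), n_samples,
                          dimnames = list(gene_ids, sample_ids))
  for (i in which(roles == "DECOY_LOW_PREVALENCE")) {
    expressed_in <- sample.int(cfg$n_tumor, max(1L, floor(0.3 * cfg$n_tumor)))
    low_prev_mask[axis_mir[i], ] <- 0
    low_prev_mask[axis_mir[i], tumor_ids[expressed_in]] <- 1
  }
  mu <- mu * low_prev_mask

  counts <- matrix(rnbinom(length(mu), size = 1 / cfg$nb_dispersion,
                           mu = as.vector(mu)),
                   nrow = nrow(mu), ncol = ncol(mu), dimnames = dimnames(mu))
  storage.mode(counts) <- "integer"

  # ---- sequences -------------------------------------------------------------
  if (n_axes > 0L) {
    drawn <- draw_axis_mirnas(n_axes, cfg$mirna_len)
    mirna_seq <- c(drawn$seqs, random_seqs(cfg$n_mirna - n_axes, cfg$mirna_len))
    # background miRNA cores must not occur anywhere inside an axis planted
    # window (including shifted overlaps), or a background miRNA would pick
    # up one co-planted site per planted window and survive the lncRNA-side
    # filters by accident
    forbidden <- unique(unlist(lapply(unlist(drawn$windows), function(w) {
      substring(w, seq_len(nchar(w) - 5L), seq_len(nchar(w) - 5L) + 5L)
    })))
    forbidden <- union(forbidden, drawn$cores)
    for (j in seq((n_axes + 1L), length.out = cfg$n_mirna - n_axes)) {
      while (revcomp(substr(mirna_seq[j], 2L, 7L)) %in% forbidden)
        mirna_seq[j] <- random_seqs(1L, cfg$mirna_len)
    }
    # axis sequences are scrubbed against EVERY miRNA core: accidental matches
    # (including matches spanning a planted-window boundary) would otherwise
    # hand background miRNAs co-planted sites and corrupt the decoy design
    cores <- vapply(mirna_seq, function(m) revcomp(substr(m, 2L, 7L)),
                    character(1))
  } else {
    mirna_seq <- random_seqs(cfg$n_mirna, cfg$mirna_len)
    cores <- character(0)
    drawn <- NULL
  }
  names(mirna_seq) <- mir_ids

  lnc_seq <- setNames(random_seqs(cfg$n_lncrna, cfg$lncrna_len), lnc_ids)
  utr_seq <- setNames(random_seqs(cfg$n_pcg, cfg$utr_len), pcg_ids)

  truth_rows <- list()
  for (i in seq_len(n_axes)) {
    plan <- site_plan(roles[i])
    w <- drawn$windows[[i]]
    lnc_windows <- rep(unlist(w), plan$lnc[names(w)])
    utr_windows <- rep(unlist(w), plan$utr[names(w)])
    planted_lnc <- plant_in_background(cfg$lncrna_len, lnc_windows)
    planted_utr <- plant_in_background(cfg$utr_len, utr_windows)
    lnc_seq[axis_lnc[i]] <- scrub_sequence(planted_lnc$seq, cores,
                                           planted_lnc$intervals)
    utr_seq[axis_mrna[i]] <- scrub_sequence(planted_utr$seq, cores,
                                            planted_utr$intervals)
    truth_rows[[i]] <- data.frame(
      lncrna_id = axis_lnc[i], mirna_id = axis_mir[i], mrna_id = axis_mrna[i],
      role = roles[i],
      lnc_8mer = plan$lnc[["8mer"]], lnc_7mer_m8 = plan$lnc[["7mer-m8"]],
      lnc_7mer_a1 = plan$lnc[["7mer-A1"]], lnc_6mer = plan$lnc[["6mer"]],
      utr_8mer = plan$utr[["8mer"]], utr_7mer_m8 = plan$utr[["7mer-m8"]],
      utr_7mer_a1 = plan$utr[["7mer-A1"]], utr_6mer = plan$utr[["6mer"]],
      stringsAsFactors = FALSE)
  }
  truth <- if (n_axes > 0L) do.call(rbind, truth_rows) else empty_truth()

  # mature miRNAs are stored (and written) as RNA, the convention for miRNA
  # FASTA releases; all scanners accept U and T interchangeably.
  mirna_seq <- chartr("T", "U", mirna_seq)

  # ---- gene sets -------------------------------------------------------------
  gene_sets <- list()
  n_bg_terms <- 18L
  if (cfg$n_pcg > 0L) {
    for (t in seq_len(n_bg_terms))
      gene_sets[[sprintf("GS%02d", t)]] <-
        sample(pcg_ids, min(40L, cfg$n_pcg))
    non_axis <- setdiff(pcg_ids, axis_mrna)
    n_fill <- min(30L, 2L * (length(non_axis) %/% 2L))
    fillers <- if (n_fill > 0L) sample(non_axis, n_fill) else character(0)
    half <- length(fillers) %/% 2L
    gene_sets[["adhesion_like"]] <- c(axis_mrna, fillers[seq_len(half)])
    gene_sets[["epidermis_like"]] <- c(axis_mrna,
                                       fillers[seq((half + 1L), length.out = half)])
  }

  # ---- clinical table --------------------------------------------------------
  base_rate <- log(2) / 50  # median overall survival 50 months
  if (cfg$n_true_axes > 0L) {
    ref <- counts[axis_lnc[1L], tumor_ids]
    high <- ref > median(ref)
  } else high <- rep(FALSE, cfg$n_tumor)
  rate <- base_rate * ifelse(high, cfg$survival_hr, 1)
  t_raw <- rexp(cfg$n_tumor, rate)
  event <- as.integer(t_raw <= 60)
  time_months <- round(pmin(t_raw, 60), 3)

  samples <- data.frame(
    sample_id = sample_ids,
    tissue = rep(c("tumor", "normal"), c(cfg$n_tumor, cfg$n_paired_normal)),
    pair_id = c(ifelse(seq_len(cfg$n_tumor) <= cfg$n_paired_normal,
                       sprintf("P%03d", seq_len(cfg$n_tumor)), NA),
                sprintf("P%03d", seq_len(cfg$n_paired_normal))),
    olnm = c(olnm, rep(NA, cfg$n_paired_normal)),
    time_months = c(time_months, rep(NA, cfg$n_paired_normal)),
    event = c(event, rep(NA, cfg$n_paired_normal)),
    age_group = c(sample(c("<52", ">=52"), cfg$n_tumor, replace = TRUE),
                  rep(NA, cfg$n_paired_normal)),
    sex = c(sample(c("female", "male"), cfg$n_tumor, replace = TRUE,
                   prob = c(0.25, 0.75)), rep(NA, cfg$n_paired_normal)),
    smoking = c(sample(c("no", "yes"), cfg$n_tumor, replace = TRUE),
                rep(NA, cfg$n_paired_normal)),
    stringsAsFactors = FALSE)

  structure(list(counts = counts, gene_class = gene_class, samples = samples,
                 sequences = list(lncrna = lnc_seq, utr3 = utr_seq,
                                  mirna = mirna_seq),
                 gene_sets = gene_sets, truth = truth,
                 planted_effects = data.frame(gene_id = gene_ids,
                                              log2fc_per_activity = unname(beta),
                                              stringsAsFactors = FALSE),
                 config = cfg),
            class = "synthetic_cohort")
}

empty_truth <- function() {
  data.frame(lncrna_id = character(0), mirna_id = character(0),
             mrna_id = character(0), role = character(0),
             lnc_8mer = integer(0), lnc_7mer_m8 = integer(0),
             lnc_7mer_a1 = integer(0), lnc_6mer = integer(0),
             utr_8mer = integer(0), utr_7mer_m8 = integer(0),
             utr_7mer_a1 = integer(0), utr_6mer = integer(0),
             stringsAsFactors = FALSE)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d genes x %d samples (%d tumour / %d normal)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$samples$tissue == "tumor"),
              sum(x$samples$tissue == "normal")))
  cat(sprintf("  OLNM+: %d tumours; planted axes: %d (%d TRUE_AXIS)\n",
              sum(x$samples$olnm == "pos", na.rm = TRUE), nrow(x$truth),
              sum(x$truth$role == "TRUE_AXIS")))
  invisible(x)
}
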