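# Small planted cohort used across tests: one axis per role, desk-scale
# dimensions, full structure. ~0.5 s to generate and screen.
small_config <- function(seed = 1, ...) {
  args <- list(n_tumor = 24L, n_paired_normal = 8L, n_olnm_pos = 9L,
               n_lncrna = 40L, n_pcg = 120L, n_mirna = 25L,
               n_true_axes = 2L, n_decoys_per_class = 1L, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_config, args)
}

# Null cohort (no planted effects) for calibration tests.
null_config <- function(seed = 1, ...) {
  args <- list(n_tumor = 24L, n_paired_normal = 8L, n_olnm_pos = 9L,
               n_lncrna = 60L, n_pcg = 200L, n_mirna = 40L,
               n_true_axes = 0L, n_decoys_per_class = 0L,
               effect_log2fc = 0, survival_hr = 1, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_config, args)
}

axis_key <- function(df) paste(df[[1]], df[[2]], df[[3]])

true_axis_keys <- function(cohort) {
  tr <- cohort$truth
  axis_key(tr[tr$role == "TRUE_AXIS", c("lncrna_id", "mirna_id", "mrna_id")])
}

# Parse a filter_trace string into a named pass/fail logical vector.
parse_trace <- function(trace) {
  parts <- strsplit(trace, ";", fixed = TRUE)[[1]]
  nm <- sub("=.*$", "", parts)
  setNames(grepl(":pass$", parts), nm)
}

# Which filter is each decoy role designed to violate.
designed_filter <- c(
  DECOY_LOW_PREVALENCE = "mirna_prevalence",
  DECOY_LOW_SCORE = "lnc_score",
  DECOY_FEW_SITES = "lnc_sites",
  DECOY_NEGATIVE_CORRELATION = "positive_correlation")

# Brute-force seed-site oracle: walks every target position with an explicit
# loop and tests the four full site-pattern strings (built with paste) in
# strength order at each seed-core anchor. Deliberately a different code path
# from find_seed_sites, which classifies vectorised anchors by flanking
# characters.
oracle_seed_sites <- function(mirna_seq, target_seq) {
  norm <- function(x) chartr("U", "T", toupper(x))
  m <- norm(mirna_seq); t <- norm(target_seq)
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  core <- rc(substr(m, 2, 7))
  rc28 <- rc(substr(m, 2, 8))
  cm8 <- substr(rc28, 1, 1)
  L <- nchar(t)
  at <- function(p, w) p >= 1 && p + nchar(w) - 1 <= L &&
    substr(t, p, p + nchar(w) - 1) == w
  out <- list()
  for (q in seq_len(max(L - 5, 0))) {
    if (substr(t, q, q + 5) != core) next
    if (at(q - 1, paste0(rc28, "A"))) {
      rec <- list("8mer", q - 1)
    } else if (at(q - 1, rc28)) {
      rec <- list("7mer-m8", q - 1)
    } else if (at(q, paste0(core, "A"))) {
      rec <- list("7mer-A1", q)
    } else {
      rec <- list("6mer", q)
    }
    out[[length(out) + 1]] <- data.frame(site_type = rec[[1]],
                                         start = as.integer(rec[[2]]),
                                         stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(site_type = character(0), start = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

random_nt <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
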