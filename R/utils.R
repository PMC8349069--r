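`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, why) {
  stop(sprintf("configuration error: field '%s' %s", field, why), call. = FALSE)
}

assert_scalar_number <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_config(field, "must be a single non-missing number")
  invisible(x)
}

DNA_BASES <- c("A", "C", "G", "T")

# Normalise a nucleotide string to uppercase DNA (U -> T); errors on other
# characters. Used everywhere sequences enter the package.
normalize_seq <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  if (any(grepl("[^ACGT]", x)))
    stop(sprintf("invalid characters in %s: only A/C/G/T/U accepted", what),
         call. = FALSE)
  x
}

# Reverse complement on normalised DNA strings.
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

# Vector of n random sequences of the given length.
random_seqs <- function(n, len, alphabet = DNA_BASES) {
  if (n == 0L) return(character(0))
  draws <- sample(alphabet, n * len, replace = TRUE)
  apply(matrix(draws, nrow = n), 1L, paste, collapse = "")
}

# 32-bit FNV-1a hash of a string, reported as 8 hex digits. Small stable
# fingerprint for run manifests; not cryptographic. Arithmetic kept in doubles
# (exact below 2^53); the xor only ever touches the low byte.
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}
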