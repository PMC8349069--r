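#' Read a gene count table
#'
#' TSV dialect: first column `gene_id`, second `gene_class` (one of lncRNA,
#' PCG, miRNA), then one integer column per sample. Duplicate gene ids, ragged
#' rows, negative or non-integer counts are rejected with the offending
#' location.
#'
#' @param path file path.
#' @return list with `counts` (integer matrix, genes x samples) and
#'   `gene_class` (named character vector).
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("counts table must have gene_id, gene_class and >= 1 sample column")
  if (!identical(names(df)[1:2], c("gene_id", "gene_class")))
    stop("counts table must start with columns gene_id, gene_class")
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup) > 0L)
    stop("duplicate gene ids: ", paste(unique(dup), collapse = ", "))
  bad_class <- setdiff(unique(df$gene_class), c("lncRNA", "PCG", "miRNA"))
  if (length(bad_class) > 0L)
    stop("unknown gene_class value(s): ", paste(bad_class, collapse = ", "))
  mat <- as.matrix(df[, -(1:2), drop = FALSE])
  if (nrow(mat) == 0L) storage.mode(mat) <- "integer"
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(mat, 2L, as.numeric))),
                 arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric count at row %d, column '%s'",
                 bad[1L], colnames(mat)[bad[2L]]))
  }
  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L)
    stop(sprintf("negative count for gene '%s', sample '%s'",
                 df$gene_id[neg[1L, 1L]], colnames(mat)[neg[1L, 2L]]))
  storage.mode(mat) <- "integer"
  rownames(mat) <- df$gene_id
  list(counts = mat, gene_class = setNames(df$gene_class, df$gene_id))
}

#' Write a gene count table
#'
#' @param counts integer matrix with gene row names and sample column names.
#' @param gene_class named character vector of classes for the rows.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_counts <- function(counts, gene_class, path) {
  if (ncol(counts) == 0L) stop("counts must have at least one sample column")
  ids <- rownames(counts) %||% character(0)
  df <- data.frame(gene_id = ids, gene_class = unname(gene_class[ids]),
                   counts, check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased; U is preserved; the description after the first
#' whitespace in a header is dropped. Duplicate ids and empty records are
#' rejected.
#'
#' @param path FASTA file path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids) > 0L)
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L))
    stop("empty sequence record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  setNames(unname(seqs), ids)
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line: term id, description (dropped), then tab-separated gene ids,
#' deduplicated preserving order. Lines with fewer than 3 fields are rejected
#' with their line number.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need term, description, genes",
                   i, length(fields)))
    out[[fields[1L]]] <- unique(fields[-(1:2)])
  }
  out
}

#' Write gene sets in GMT format
#'
#' @param gene_sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional named descriptions (defaults to the term id).
#' @return the path, invisibly.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  lines <- vapply(names(gene_sets), function(tid) {
    desc <- descriptions[[tid]] %||% tid
    paste(c(tid, desc, gene_sets[[tid]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# TSV writer used for all tabular outputs: header row, no quoting surprises,
# NA as empty string on write.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Serialises counts (TSV), sample table (TSV), sequences (three FASTA
#' files), gene sets (GMT) and the planted-axis truth table (TSV). Reading
#' the files back with [read_cohort()] reproduces the in-memory cohort.
#'
#' @param cohort a [generate_cohort()] result.
#' @param directory output directory (created if missing).
#' @return named character vector of the file paths (the manifest).
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  paths <- c(counts = file.path(directory, "counts.tsv"),
             samples = file.path(directory, "samples.tsv"),
             transcripts = file.path(directory, "transcripts.fasta"),
             utr3 = file.path(directory, "utr3.fasta"),
             mirna = file.path(directory, "mirna.fasta"),
             genesets = file.path(directory, "genesets.gmt"),
             truth = file.path(directory, "truth.tsv"))
  write_counts(cohort$counts, cohort$gene_class, paths[["counts"]])
  write_tsv(cohort$samples, paths[["samples"]])
  write_fasta(cohort$sequences$lncrna, paths[["transcripts"]])
  write_fasta(cohort$sequences$utr3, paths[["utr3"]])
  write_fasta(cohort$sequences$mirna, paths[["mirna"]])
  write_gmt(cohort$gene_sets, paths[["genesets"]])
  write_tsv(cohort$truth, paths[["truth"]])
  paths
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param directory directory containing the cohort files.
#' @return a `synthetic_cohort`-shaped list (without `planted_effects` and
#'   `config`, which are generator-side metadata).
#' @export
read_cohort <- function(directory) {
  cts <- read_counts(file.path(directory, "counts.tsv"))
  samples <- read.delim(file.path(directory, "samples.tsv"),
                        stringsAsFactors = FALSE)
  samples$pair_id <- as.character(samples$pair_id)
  structure(list(counts = cts$counts, gene_class = cts$gene_class,
                 samples = samples,
                 sequences = list(
                   lncrna = read_fasta(file.path(directory, "transcripts.fasta")),
                   utr3 = read_fasta(file.path(directory, "utr3.fasta")),
                   mirna = read_fasta(file.path(directory, "mirna.fasta"))),
                 gene_sets = read_gmt(file.path(directory, "genesets.gmt")),
                 truth = load_truth(file.path(directory, "truth.tsv"))),
            class = "synthetic_cohort")
}

#' Load a planted-axis truth table
#'
#' @param path `truth.tsv` written by [write_cohort()].
#' @return data frame of planted-axis records; unknown role strings are
#'   rejected with their line number.
#' @export
load_truth <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("lncrna_id", "mirna_id", "mrna_id", "role")
  if (!all(need %in% names(df)))
    stop("truth table must have columns: ", paste(need, collapse = ", "))
  bad <- which(!df$role %in% AXIS_ROLES)
  if (length(bad) > 0L)
    stop(sprintf("unknown role '%s' in truth table at line %d",
                 df$role[bad[1L]], bad[1L] + 1L))
  df
}
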