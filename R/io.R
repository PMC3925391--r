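#' Construct a read set
#'
#' A read set is a plain `data.frame` with one row per read and columns
#' `read_id`, `sample_id`, `sequence`, `qual` (Sanger Phred+33 string) and
#' `mean_qv` (arithmetic mean of the per-base Phred scores). All pipeline
#' stages take and return this layout.
#'
#' @param read_id character vector of unique read identifiers.
#' @param sequence DNA strings over A/C/G/T.
#' @param qual Phred+33-encoded quality strings, same lengths as `sequence`.
#' @param sample_id sample assignment, `NA` when not yet demultiplexed.
#' @return data.frame with class `c("read_set", "data.frame")`.
#' @export
read_set <- function(read_id, sequence, qual, sample_id = NA_character_) {
  read_id <- as.character(read_id)
  sequence <- as.character(sequence)
  qual <- as.character(qual)
  if (length(sequence) != length(read_id) || length(qual) != length(read_id))
    stop("read_id, sequence and qual must have equal length")
  if (anyDuplicated(read_id)) stop("read ids must be unique")
  bad <- nchar(sequence) != nchar(qual)
  if (any(bad))
    stop(sum(bad), " reads have sequence/quality length mismatch")
  df <- data.frame(read_id = read_id,
                   sample_id = rep_len(as.character(sample_id), length(read_id)),
                   sequence = sequence,
                   qual = qual,
                   mean_qv = cpp_mean_phred(qual),
                   stringsAsFactors = FALSE)
  class(df) <- c("read_set", "data.frame")
  df
}

#' Read a FASTQ file into a read set
#'
#' @param path FASTQ file (Sanger/Phred+33 qualities).
#' @param sample_id optional sample label applied to all reads.
#' @return a [read_set()].
#' @export
read_fastq <- function(path, sample_id = NA_character_) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  read_set(read_id = sub("\\s.*$", "", names(x)),
           sequence = as.character(x),
           qual = as.character(S4Vectors::mcols(x)$qualities),
           sample_id = sample_id)
}

#' Write a read set to FASTQ (Sanger/Phred+33)
#'
#' @param reads a [read_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Write named sequences to FASTA
#' @param seqs named character vector of DNA strings.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a table as TSV with a seed header comment
#'
#' All tabular outputs carry a `# seed: <n>` comment line so a run can be
#' reproduced from its files alone.
#'
#' @param df data.frame to write.
#' @param path output file.
#' @param seed integer seed recorded in the header (optional).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()] (comment lines skipped)
#' @param path input file.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Reverse complement of DNA strings
#' @param x character vector of DNA strings.
#' @return character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
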