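# Read quality control: demultiplexing by exact barcode prefix, the primer
# presence check with the long-read (> 400 bp) exception, and the mean-quality
# (QV >= 25) filter. Counts of every disposition are reconciled in a QC report.

#' Demultiplex reads by exact barcode prefix match
#'
#' Reads whose prefix exactly matches a sample barcode are assigned to that
#' sample and the barcode (sequence and qualities) is stripped; all other
#' reads are marked unassigned. Barcodes must be unique and of one length.
#'
#' @param reads a [read_set()].
#' @param barcode_map data.frame with columns `sample_id` and `barcode`.
#' @return list: `reads` (assigned reads, barcode removed), `unassigned`
#'   (count), `n_input` (count).
#' @export
demultiplex <- function(reads, barcode_map) {
  bl <- unique(nchar(barcode_map$barcode))
  if (length(bl) != 1) stop("barcodes must share one length")
  if (anyDuplicated(barcode_map$barcode)) stop("duplicate barcode")
  prefix <- substr(reads$sequence, 1, bl)
  hit <- match(prefix, barcode_map$barcode)
  assigned <- !is.na(hit) & nchar(reads$sequence) > bl
  out <- reads[assigned, , drop = FALSE]
  out$sample_id <- barcode_map$sample_id[hit[assigned]]
  out$sequence <- substr(out$sequence, bl + 1, nchar(out$sequence))
  out$qual <- substr(out$qual, bl + 1, nchar(out$qual))
  out$mean_qv <- cpp_mean_phred(out$qual)
  class(out) <- c("read_set", "data.frame")
  list(reads = out, unassigned = sum(!assigned), n_input = nrow(reads))
}

#' Primer presence check with long-read exception
#'
#' A read is kept when the forward primer is found at its 5' end and the
#' reverse-complemented reverse primer at its 3' end (each within
#' `max_mismatch` substitutions), or -- regardless of primers -- when the read
#' (after barcode removal, before trimming) is longer than `length_exception`
#' bases. Found primer copies are trimmed from sequence and qualities.
#' Reads shorter than a primer count as primer failures.
#'
#' @param reads a [read_set()] (barcode already removed).
#' @param fwd_primer forward primer sequence (5' end of the read).
#' @param rev_primer reverse primer sequence; its reverse complement is sought
#'   at the 3' end.
#' @param max_mismatch maximum substitutions tolerated per primer (default 2;
#'   no indels).
#' @param length_exception reads longer than this many bases are kept even
#'   without primers (default 400; set to `Inf` to disable).
#' @param policy `"both"` (default) keeps reads only when both primers are
#'   found; `"either"` keeps reads when at least one is found (the literal
#'   reading of removing only reads that lack both).
#' @return list: `reads` (kept reads, primers trimmed), `primer_fail`
#'   (count removed), `length_exception_kept` (count kept only via the length
#'   exception).
#' @export
check_primers <- function(reads, fwd_primer, rev_primer, max_mismatch = 2,
                          length_exception = 400, policy = c("both", "either")) {
  policy <- match.arg(policy)
  if (!nzchar(fwd_primer) || !nzchar(rev_primer)) stop("primers must be non-empty")
  fwd <- toupper(fwd_primer)
  rcr <- revcomp(toupper(rev_primer))
  mm_f <- cpp_pattern_mismatch(reads$sequence, fwd, from_end = FALSE)
  mm_r <- cpp_pattern_mismatch(reads$sequence, rcr, from_end = TRUE)
  len <- nchar(reads$sequence)
  found_f <- mm_f >= 0 & mm_f <= max_mismatch
  found_r <- mm_r >= 0 & mm_r <= max_mismatch &
    (len - nchar(fwd) * found_f) >= nchar(rcr)
  primer_ok <- if (policy == "both") found_f & found_r else found_f | found_r
  long_ok <- len > length_exception
  keep <- primer_ok | long_ok
  out <- reads[keep, , drop = FALSE]
  ff <- found_f[keep]; fr <- found_r[keep]
  start <- ifelse(ff, nchar(fwd) + 1L, 1L)
  end <- ifelse(fr, nchar(out$sequence) - nchar(rcr), nchar(out$sequence))
  out$sequence <- substr(out$sequence, start, end)
  out$qual <- substr(out$qual, start, end)
  out$mean_qv <- cpp_mean_phred(out$qual)
  class(out) <- c("read_set", "data.frame")
  list(reads = out,
       primer_fail = sum(!keep),
       length_exception_kept = sum(keep & !primer_ok))
}

#' Mean-quality filter
#'
#' Keeps reads whose mean per-base Phred quality is at least `threshold`
#' (the removal rule is strict: mean QV `< 25` is removed, so a mean of
#' exactly 25 passes).
#'
#' @param reads a [read_set()].
#' @param threshold minimum mean QV (default 25).
#' @return list: `reads` (kept), `low_quality` (count removed).
#' @export
quality_filter <- function(reads, threshold = 25) {
  if (any(!nzchar(reads$qual)))
    stop("reads with empty quality strings")
  keep <- reads$mean_qv >= threshold
  out <- reads[keep, , drop = FALSE]
  class(out) <- c("read_set", "data.frame")
  list(reads = out, low_quality = sum(!keep))
}

#' Run the full read-QC stage
#'
#' Demultiplex, primer-check (with trimming and the > 400 bp exception), and
#' quality-filter a read set, returning the surviving reads and a stage-count
#' report whose categories reconcile exactly: `assigned = passed +
#' primer_fail_removed + low_quality_removed`.
#'
#' @param reads a [read_set()] of raw barcoded reads.
#' @param barcode_map data.frame `sample_id`, `barcode`.
#' @param fwd_primer,rev_primer see [check_primers()].
#' @param max_mismatch,length_exception,policy see [check_primers()].
#' @param qv_threshold see [quality_filter()].
#' @return list: `reads` (filter-passed, trimmed), `report` (data.frame
#'   `stage`, `count`, `fraction` -- fractions relative to assigned reads).
#' @export
run_read_qc <- function(reads, barcode_map, fwd_primer, rev_primer,
                        max_mismatch = 2, length_exception = 400,
                        policy = "both", qv_threshold = 25) {
  dm <- demultiplex(reads, barcode_map)
  pc <- check_primers(dm$reads, fwd_primer, rev_primer,
                      max_mismatch = max_mismatch,
                      length_exception = length_exception, policy = policy)
  qf <- quality_filter(pc$reads, threshold = qv_threshold)
  n_assigned <- nrow(dm$reads)
  counts <- c(input = dm$n_input,
              assigned = n_assigned,
              primer_fail_removed = pc$primer_fail,
              length_exception_kept = pc$length_exception_kept,
              low_quality_removed = qf$low_quality,
              passed = nrow(qf$reads))
  report <- data.frame(stage = names(counts), count = unname(counts),
                       fraction = unname(counts) / n_assigned,
                       stringsAsFactors = FALSE)
  list(reads = qf$reads, report = report)
}
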