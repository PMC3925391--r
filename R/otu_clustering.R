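# Rarefaction to a fixed per-sample depth, quality sorting, and greedy OTU
# clustering at 96% identity. Reads are pooled across samples and sorted by
# mean quality before clustering, so each OTU's representative is its
# highest-quality member.

#' Rarefy each sample to a fixed read depth
#'
#' Draws exactly `depth` reads per sample uniformly without replacement.
#' Samples with fewer than `depth` filter-passed reads are excluded with a
#' warning (never resampled with replacement).
#'
#' @param reads a [read_set()] with `sample_id` populated.
#' @param depth target depth (default 3000).
#' @param seed integer seed for the subsampling.
#' @return a [read_set()] in which every retained sample has exactly `depth`
#'   reads; excluded samples are recorded in attribute `"excluded_samples"`.
#' @export
rarefy_reads <- function(reads, depth = 3000, seed = 1L) {
  set.seed(seed)
  idx_by_sample <- split(seq_len(nrow(reads)), reads$sample_id)
  sizes <- lengths(idx_by_sample)
  excluded <- names(sizes)[sizes < depth]
  if (length(excluded))
    warning("excluding ", length(excluded), " sample(s) below depth ",
            depth, ": ", paste(excluded, collapse = ", "))
  keep <- unlist(lapply(idx_by_sample[sizes >= depth], function(i)
    sort(sample(i, depth))), use.names = FALSE)
  out <- reads[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("read_set", "data.frame")
  attr(out, "excluded_samples") <- excluded
  out
}

#' Sort reads by mean quality
#'
#' Descending mean QV; ties broken by longer sequence, then lexicographic
#' read id, so the order is a deterministic function of the read set and
#' invariant to input file order.
#'
#' @param reads a [read_set()].
#' @return the reads reordered.
#' @export
sort_by_quality <- function(reads) {
  o <- order(-reads$mean_qv, -nchar(reads$sequence), reads$read_id,
             method = "radix")
  out <- reads[o, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("read_set", "data.frame")
  out
}

#' Greedy OTU clustering of quality-sorted reads
#'
#' Each read (in the given order) is compared against existing OTU
#' representatives -- candidates ordered by shared k-mer count -- and joins
#' the first one reaching `identity_threshold`; otherwise it founds a new OTU
#' with itself as representative. Because input is sorted by quality,
#' representatives are the highest-quality members. A UCLUST-style reject cap
#' (`maxrejects`) bounds the candidates aligned per read.
#'
#' @param reads a quality-sorted [read_set()] (see [sort_by_quality()]).
#' @param identity_threshold minimum alignment identity to join an OTU
#'   (default 0.96).
#' @param k k-mer size for candidate ranking.
#' @param maxrejects failed alignments tolerated before founding a new OTU.
#' @return list of class `otu_clustering`: `assignment` (OTU id per read, in
#'   input order), `otus` (data.frame `otu_id`, `representative_read_id`,
#'   `representative_sequence`, `n_members`). OTU ids are `OTU_0001, ...` in
#'   founding order.
#' @export
greedy_cluster <- function(reads, identity_threshold = 0.96, k = 8,
                           maxrejects = 32) {
  if (nrow(reads) == 0)
    return(structure(list(assignment = character(0),
                          otus = data.frame(otu_id = character(0),
                                            representative_read_id = character(0),
                                            representative_sequence = character(0),
                                            n_members = integer(0))),
                     class = "otu_clustering"))
  ai <- cpp_greedy_cluster(reads$sequence, threshold = identity_threshold,
                           k = k, maxrejects = maxrejects)
  otu_id <- sprintf("OTU_%04d", ai)
  founders <- !duplicated(ai)
  otus <- data.frame(otu_id = otu_id[founders],
                     representative_read_id = reads$read_id[founders],
                     representative_sequence = reads$sequence[founders],
                     n_members = as.integer(table(ai)[as.character(ai[founders])]),
                     stringsAsFactors = FALSE)
  otus <- otus[order(otus$otu_id), , drop = FALSE]
  rownames(otus) <- NULL
  structure(list(assignment = otu_id, otus = otus), class = "otu_clustering")
}

#' Build the OTU count table
#'
#' Tabulates reads by (OTU, sample) and attaches each OTU's taxonomy from its
#' representative read's assignment.
#'
#' @param clustering a [greedy_cluster()] result.
#' @param reads the read set that was clustered (defines `sample_id` per read).
#' @param taxonomy optional per-read taxonomy (from [run_reference_search()]),
#'   matched to representative reads by `read_id`.
#' @return integer matrix (OTU x sample) of class `otu_table`, with
#'   attributes `taxonomy` (data.frame keyed by `otu_id`) and
#'   `representatives`.
#' @export
build_otu_table <- function(clustering, reads, taxonomy = NULL) {
  if (any(is.na(reads$sample_id))) stop("reads with unknown sample")
  tab <- table(clustering$assignment, reads$sample_id)
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  tax <- NULL
  if (!is.null(taxonomy)) {
    i <- match(clustering$otus$representative_read_id, taxonomy$read_id)
    tax <- cbind(otu_id = clustering$otus$otu_id,
                 taxonomy[i, c("assigned_rank", "taxon", "phylum", "genus",
                               "species", "best_identity"), drop = FALSE])
    tax <- tax[match(rownames(m), tax$otu_id), , drop = FALSE]
    rownames(tax) <- NULL
  }
  structure(m, class = c("otu_table", class(m)),
            taxonomy = tax, representatives = clustering$otus)
}

#' Collapse an OTU table to a taxonomic rank
#'
#' Sums counts over OTUs sharing a label at the requested rank; OTUs without a
#' label at that rank are pooled as `"unclassified"`.
#'
#' @param otu_table an [build_otu_table()] result.
#' @param rank `"genus"` or `"phylum"`.
#' @return taxon x sample count matrix.
#' @export
aggregate_taxa <- function(otu_table, rank = c("genus", "phylum")) {
  rank <- match.arg(rank)
  tax <- attr(otu_table, "taxonomy")
  if (is.null(tax)) stop("otu_table has no taxonomy attached")
  lab <- tax[[rank]]
  lab[is.na(lab)] <- "unclassified"
  rowsum(unclass(otu_table), group = lab)
}

#' Relative abundances of a count matrix
#' @param counts taxa x sample count matrix.
#' @return matrix of column proportions.
#' @export
relative_abundance <- function(counts) {
  sweep(unclass(counts), 2, colSums(counts), "/")
}
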