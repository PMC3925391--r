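# Similarity search of reads against the reference database: k-mer candidate
# ranking followed by banded local alignment (affine gaps). Drives both the
# match-length chimera rule (best-hit query coverage < 90%) and best-hit
# taxonomy assignment (species >= 97%, genus >= 95%, phylum >= 80% identity).

#' Align a query against a subject sequence
#'
#' Banded local alignment with affine gaps. Identity is matching columns over
#' aligned columns (gap columns count as non-matching; terminal gaps are
#' excluded); query coverage is the aligned query span over the query length;
#' `identity_global` additionally normalizes by at least the shorter sequence
#' length (`matches / max(cols, min(lengths))`), which penalizes short local
#' matches between otherwise unrelated sequences. A gap of length L costs
#' `gap_open + (L - 1) * gap_ext`.
#'
#' @param query,subject DNA strings.
#' @param match,mismatch,gap_open,gap_ext alignment scores (defaults
#'   +1/-2/-5/-2).
#' @param band maximum |i - j| explored; `NULL` uses
#'   `16 + abs(nchar(query) - nchar(subject))`, `-1` disables banding.
#' @return named numeric vector: `score`, `matches`, `cols`, `identity`,
#'   `identity_global`, `coverage`, `qstart`, `qend`, `sstart`, `send`
#'   (1-based).
#' @export
align_pair <- function(query, subject, match = 1, mismatch = -2,
                       gap_open = -5, gap_ext = -2, band = NULL) {
  if (is.null(band))
    band <- 16L + abs(nchar(query) - nchar(subject))
  cpp_align(query, subject, match, mismatch, gap_open, gap_ext, band)
}

#' Rank reference hits for a set of reads
#'
#' Candidate references are ordered by shared distinct k-mer count (default
#' k = 8) and the top `top_n` are aligned; ties are broken deterministically
#' by (score, database order). With `search_rc = TRUE` the reverse complement
#' of each read is also searched and the better orientation reported.
#'
#' @param sequences character vector of read sequences.
#' @param db a `reference_db` data.frame (`ref_id`, `sequence`, lineage).
#' @param k k-mer word size.
#' @param top_n candidates aligned per read.
#' @param search_rc also search the reverse complement.
#' @param ... alignment scores passed to the aligner.
#' @return data.frame: `query` (index into `sequences`), `ref_id`, `rank`,
#'   `score`, `identity`, `coverage`, `shared_kmers`. Reads shorter than `k`
#'   or sharing no k-mer with any reference have no rows.
#' @export
best_hits <- function(sequences, db, k = 8, top_n = 2, search_rc = FALSE,
                      ...) {
  if (nrow(db) == 0) stop("reference database is empty")
  hits <- cpp_search(sequences, db$sequence, k = k, top_n = top_n, ...)
  if (search_rc) {
    rc <- cpp_search(revcomp(sequences), db$sequence, k = k, top_n = top_n,
                     ...)
    both <- rbind(cbind(hits, rc = FALSE), cbind(rc, rc = TRUE))
    both <- both[order(both$query, -both$score, both$ref, both$rc), ]
    keep <- !duplicated(paste(both$query, both$ref))
    hits <- both[keep, , drop = FALSE]
    hits <- hits[order(hits$query, -hits$score, hits$ref), ]
    hits$rank <- ave(hits$score, hits$query,
                     FUN = function(x) seq_along(x))
    hits$rc <- NULL
  }
  hits$ref_id <- db$ref_id[hits$ref]
  hits$ref <- NULL
  hits
}

.best_per_query <- function(hits, n_queries) {
  top <- hits[hits$rank == 1, , drop = FALSE]
  i <- match(seq_len(n_queries), top$query)
  top[i, , drop = FALSE]
}

#' Flag chimeras by the best-hit match-length rule
#'
#' A read is flagged as chimeric when its best reference hit covers less than
#' `coverage_threshold` (default 0.90) of the read; reads with no hit at all
#' are a separate removal class.
#'
#' @param hits output of [best_hits()].
#' @param n_queries number of reads searched.
#' @param coverage_threshold minimum best-hit query coverage of a clean read.
#' @return character vector of length `n_queries`:
#'   `"ok"`, `"chimera"`, or `"no_hit"`.
#' @export
detect_chimeras <- function(hits, n_queries, coverage_threshold = 0.90) {
  top <- .best_per_query(hits, n_queries)
  status <- rep("no_hit", n_queries)
  has <- !is.na(top$query)
  status[has] <- ifelse(top$coverage[has] < coverage_threshold,
                        "chimera", "ok")
  status
}

#' Assign taxonomy from best hits
#'
#' Best-hit identity thresholds: identity at or above `species_id` assigns
#' the hit's species, above `genus_id` its genus, above `phylum_id` only its
#' phylum ("higher" rank); anything lower (or no hit) is unclassified.
#'
#' @param hits output of [best_hits()].
#' @param db the reference database searched.
#' @param n_queries number of reads searched.
#' @param species_id,genus_id,phylum_id identity thresholds
#'   (defaults 0.97, 0.95, 0.80).
#' @return data.frame: `ref_id`, `best_identity`, `coverage`,
#'   `assigned_rank` (species/genus/higher/unclassified), `taxon`, plus the
#'   full `phylum`/`genus`/`species` lineage of the best hit (NA where
#'   unclassified).
#' @export
assign_taxonomy <- function(hits, db, n_queries, species_id = 0.97,
                            genus_id = 0.95, phylum_id = 0.80) {
  top <- .best_per_query(hits, n_queries)
  ref_row <- match(top$ref_id, db$ref_id)
  id <- ifelse(is.na(top$query), 0, top$identity)
  rank <- ifelse(id >= species_id, "species",
          ifelse(id >= genus_id, "genus",
          ifelse(id >= phylum_id, "higher", "unclassified")))
  taxon <- rep(NA_character_, n_queries)
  taxon[rank == "species"] <- db$species[ref_row[rank == "species"]]
  taxon[rank == "genus"] <- db$genus[ref_row[rank == "genus"]]
  taxon[rank == "higher"] <- db$phylum[ref_row[rank == "higher"]]
  data.frame(ref_id = ifelse(rank == "unclassified", NA_character_,
                             db$ref_id[ref_row]),
             best_identity = id,
             coverage = ifelse(is.na(top$query), NA_real_, top$coverage),
             assigned_rank = rank,
             taxon = taxon,
             phylum = ifelse(rank == "unclassified", NA_character_,
                             db$phylum[ref_row]),
             genus = ifelse(rank %in% c("species", "genus"),
                            db$genus[ref_row], NA_character_),
             species = ifelse(rank == "species", db$species[ref_row],
                              NA_character_),
             stringsAsFactors = FALSE)
}

#' Run the reference-search stage on a read set
#'
#' Searches every read, flags chimeras (and no-hit reads), and assigns
#' taxonomy to the clean reads.
#'
#' @param reads a [read_set()] of filter-passed, primer-trimmed reads.
#' @param db the reference database.
#' @param coverage_threshold chimera rule threshold (default 0.90).
#' @param k,top_n,search_rc see [best_hits()].
#' @return list: `reads` (clean reads), `taxonomy` (per clean read, columns of
#'   [assign_taxonomy()] plus `read_id`), `status` (per input read), counts
#'   `chimera_removed` and `no_hit_removed`.
#' @export
run_reference_search <- function(reads, db, coverage_threshold = 0.90,
                                 k = 8, top_n = 2, search_rc = FALSE) {
  hits <- best_hits(reads$sequence, db, k = k, top_n = top_n,
                    search_rc = search_rc)
  status <- detect_chimeras(hits, nrow(reads), coverage_threshold)
  tax <- assign_taxonomy(hits, db, nrow(reads))
  ok <- status == "ok"
  out <- reads[ok, , drop = FALSE]
  class(out) <- c("read_set", "data.frame")
  tax_ok <- cbind(read_id = out$read_id, tax[ok, , drop = FALSE])
  rownames(tax_ok) <- NULL
  list(reads = out, taxonomy = tax_ok, status = status,
       chimera_removed = sum(status == "chimera"),
       no_hit_removed = sum(status == "no_hit"))
}
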