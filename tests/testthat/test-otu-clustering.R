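toy_reads <- function(seqs, qv, ids = sprintf("r%02d", seq_along(seqs)),
                      sample_id = "S1") {
  read_set(ids, seqs, vapply(seq_along(seqs), function(i)
    qstr(rep(qv[i], nchar(seqs[i]))), ""), sample_id = sample_id)
}

test_that("rarefaction draws the exact depth, reproducibly, excluding shallow samples", {
  set.seed(2)
  reads <- read_set(sprintf("r%04d", 1:1300),
                    replicate(1300, rdna(50)),
                    replicate(1300, qstr(rep(30, 50))),
                    sample_id = rep(c("A", "B", "C"), c(600, 500, 200)))
  expect_warning(rr <- rarefy_reads(reads, depth = 400, seed = 5), "C")
  expect_equal(unname(table(rr$sample_id)["A"]), 400, ignore_attr = TRUE)
  expect_equal(unname(table(rr$sample_id)["B"]), 400, ignore_attr = TRUE)
  expect_false("C" %in% rr$sample_id)
  expect_equal(attr(rr, "excluded_samples"), "C")
  rr2 <- suppressWarnings(rarefy_reads(reads, depth = 400, seed = 5))
  expect_identical(rr$read_id, rr2$read_id)
  rr3 <- suppressWarnings(rarefy_reads(reads, depth = 400, seed = 6))
  expect_false(identical(rr$read_id, rr3$read_id))
})

test_that("quality sort is descending with deterministic tie-breaks", {
  r <- toy_reads(c(rdna(50), rdna(50), rdna(50)), c(30, 35, 25))
  expect_equal(sort_by_quality(r)$mean_qv, c(35, 30, 25))
  # equal QVs: longer first, then lexicographic id; invariant to input order
  r2 <- toy_reads(c(rdna(60), rdna(50), rdna(60)), c(30, 30, 30),
                  ids = c("b", "c", "a"))
  s1 <- sort_by_quality(r2)
  # both 60-mers ("a", "b") precede the 50-mer ("c"); ties by id
  expect_equal(s1$read_id, c("a", "b", "c"))
  shuf <- r2[c(3, 1, 2), ]
  class(shuf) <- c("read_set", "data.frame")
  expect_identical(sort_by_quality(shuf)$read_id, s1$read_id)
})

test_that("greedy clustering groups identical reads and splits diverged ones", {
  s <- rdna(300)
  r <- toy_reads(c(s, s, s), c(35, 30, 25))
  cl <- greedy_cluster(r)
  expect_equal(nrow(cl$otus), 1)
  expect_equal(cl$otus$n_members, 3)
  # representative is the highest-quality member (first after sorting)
  expect_equal(cl$otus$representative_read_id, "r01")
  # two sequences at ~90% identity split at a 96% threshold
  s2 <- mutate_seq(s, 30)
  cl2 <- greedy_cluster(toy_reads(c(s, s2), c(35, 30)))
  expect_equal(nrow(cl2$otus), 2)
  # empty input
  cl0 <- greedy_cluster(toy_reads(character(0), numeric(0), ids = character(0)))
  expect_equal(nrow(cl0$otus), 0)
})

test_that("threshold monotonicity and member-representative identity hold", {
  cfg <- small_study_cfg(reads_per_sample = 120)
  db <- generate_reference_db(14, 3, seed = cfg$seed)
  rd <- generate_reads(generate_profiles(cfg, db), db, cfg)
  qc <- run_read_qc(rd$reads, rd$barcodes, cfg$fwd_primer, cfg$rev_primer)
  sorted <- sort_by_quality(qc$reads)
  counts <- vapply(c(0.90, 0.93, 0.96), function(th)
    nrow(greedy_cluster(sorted, identity_threshold = th)$otus), 0)
  expect_true(all(diff(counts) >= 0))
  cl <- greedy_cluster(sorted, identity_threshold = 0.96)
  # every member aligns to its representative at >= 0.96 identity
  reps <- setNames(cl$otus$representative_sequence, cl$otus$otu_id)
  idx <- sample(nrow(sorted), 150)
  ok <- vapply(idx, function(i) {
    align_pair(sorted$sequence[i],
               reps[[cl$assignment[i]]])[["identity"]] >= 0.96
  }, TRUE)
  expect_true(all(ok))
  # representatives carry the maximum mean quality of their members
  for (o in unique(cl$assignment)) {
    members <- sorted$mean_qv[cl$assignment == o]
    rep_qv <- sorted$mean_qv[sorted$read_id ==
                               cl$otus$representative_read_id[cl$otus$otu_id == o]]
    expect_gte(rep_qv, max(members) - 1e-9)
  }
  # deterministic given the sorted order
  cl2 <- greedy_cluster(sorted, identity_threshold = 0.96)
  expect_identical(cl$assignment, cl2$assignment)
})

test_that("OTU tables conserve counts and aggregate by taxonomy", {
  s1 <- rdna(300); s2 <- mutate_seq(s1, 40); s3 <- rdna(320)
  reads <- toy_reads(c(s1, s1, s2, s3, s3, s3), c(35, 30, 33, 31, 29, 28),
                     sample_id = c("A", "B", "A", "B", "B", "A"))
  sorted <- sort_by_quality(reads)
  cl <- greedy_cluster(sorted)
  tax <- data.frame(read_id = cl$otus$representative_read_id,
                    assigned_rank = "genus",
                    taxon = c("G1", "G2", "G3")[seq_len(nrow(cl$otus))],
                    phylum = "P1",
                    genus = c("G1", "G2", "G3")[seq_len(nrow(cl$otus))],
                    species = NA_character_, best_identity = 1)
  tab <- build_otu_table(cl, sorted, taxonomy = tax)
  expect_equal(sum(tab), nrow(reads))
  expect_equal(unname(colSums(tab)), c(3, 3))
  g <- aggregate_taxa(tab, "genus")
  expect_equal(sum(g), nrow(reads))
  ra <- relative_abundance(g)
  expect_equal(unname(colSums(ra)), c(1, 1))
  expect_error(build_otu_table(cl, within(sorted, sample_id <- NA), tax),
               "unknown sample")
})

test_that("clustering recovers the species count on a low-error study", {
  cfg <- small_study_cfg(reads_per_sample = 250)
  db <- generate_reference_db(14, 3, seed = cfg$seed)
  rd <- generate_reads(generate_profiles(cfg, db), db, cfg)
  qc <- run_read_qc(rd$reads, rd$barcodes, cfg$fwd_primer, cfg$rev_primer)
  rs <- run_reference_search(qc$reads, db)
  rare <- rarefy_reads(rs$reads, depth = 200, seed = cfg$seed)
  cl <- greedy_cluster(sort_by_quality(rare))
  # 42 species in the database; allow +/- 10%
  expect_gte(nrow(cl$otus), 38)
  expect_lte(nrow(cl$otus), 47)
  # count conservation at depth
  tab <- build_otu_table(cl, rare)
  expect_true(all(colSums(tab) == 200))
})
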