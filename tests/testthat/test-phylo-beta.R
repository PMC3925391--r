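test_that("trees over representatives are deterministic and genus-monophyletic", {
  db <- generate_reference_db(14, 3, seed = 19)
  seqs <- setNames(db$sequence, db$ref_id)
  tr <- build_tree(seqs)
  tr2 <- build_tree(seqs[sample(length(seqs))])
  expect_equal(ape::write.tree(tr), ape::write.tree(tr2))
  expect_true(all(tr$edge.length >= 0))
  mono <- vapply(unique(db$genus), function(g)
    ape::is.monophyletic(tr, db$ref_id[db$genus == g]), TRUE)
  expect_gte(mean(mono), 0.9)
  # identical sequences form a zero-length cherry
  s <- rdna(300)
  tr3 <- build_tree(c(x = s, y = s, z = mutate_seq(s, 60)))
  expect_equal(unname(ape::cophenetic.phylo(tr3)["x", "y"]), 0)
})

test_that("3-taxon neighbor joining reproduces pairwise distances exactly", {
  set.seed(23)
  base <- rdna(400)
  seqs <- c(A = base, B = mutate_seq(base, 12), C = mutate_seq(base, 40))
  d <- alignment_dist(seqs)
  tr <- build_tree(seqs)
  co <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(co, d, tolerance = 1e-10)
})

test_that("hand-computed star-tree UniFrac values are exact", {
  star <- ape::read.tree(text = "(L1:1,L2:1);")
  counts <- matrix(c(1, 0, 0, 1, 0.5, 0.5), 2, 3,
                   dimnames = list(c("L1", "L2"), c("A", "B", "C")))
  w <- unifrac(star, counts, weighted = TRUE, normalized = TRUE)
  expect_equal(w["A", "B"], 1.0)   # disjoint: raw 2 / D 2
  expect_equal(w["C", "A"], 0.5)   # (0.5,0.5) vs (1,0): raw 1 / D 2
  raw <- unifrac(star, counts, weighted = TRUE, normalized = FALSE)
  expect_equal(raw["A", "B"], 2.0)
  u <- unifrac(star, counts, weighted = FALSE)
  expect_equal(u["A", "B"], 1.0)
  expect_equal(u["A", "C"], 0.5)   # unique 1 / union 2
  expect_equal(unname(diag(w)), c(0, 0, 0))
})

test_that("traversal UniFrac equals brute force on random small trees", {
  set.seed(31)
  for (i in 1:20) {
    ntip <- sample(4:8, 1)
    tr <- ape::rtree(ntip, rooted = TRUE)
    for (j in 1:5) {
      counts <- matrix(rpois(2 * ntip, 5), ntip, 2,
                       dimnames = list(tr$tip.label, c("A", "B")))
      counts[counts == 0] <- ifelse(runif(sum(counts == 0)) < 0.5, 0, 1)
      if (any(colSums(counts) == 0)) next
      pA <- counts[, 1] / sum(counts[, 1]); pB <- counts[, 2] / sum(counts[, 2])
      w <- unifrac(tr, counts, weighted = TRUE, normalized = FALSE)
      expect_equal(w["A", "B"], brute_unifrac(tr, pA, pB, TRUE),
                   tolerance = 1e-12)
      u <- unifrac(tr, counts, weighted = FALSE)
      expect_equal(u["A", "B"], brute_unifrac(tr, pA, pB, FALSE),
                   tolerance = 1e-12)
    }
  }
})

test_that("UniFrac matches phyloseq and is scale-invariant", {
  set.seed(41)
  tr <- ape::rtree(12)
  counts <- matrix(rpois(12 * 4, 8) + 1, 12, 4,
                   dimnames = list(tr$tip.label, paste0("S", 1:4)))
  ours_w <- unifrac(tr, counts, weighted = TRUE, normalized = TRUE)
  ours_u <- unifrac(tr, counts, weighted = FALSE)
  ps <- phyloseq::phyloseq(phyloseq::otu_table(counts, taxa_are_rows = TRUE),
                           phyloseq::phy_tree(tr))
  ref_w <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE))
  ref_u <- as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))
  expect_equal(ours_w, ref_w[rownames(ours_w), colnames(ours_w)],
               tolerance = 1e-10)
  expect_equal(ours_u, ref_u[rownames(ours_u), colnames(ours_u)],
               tolerance = 1e-10)
  # multiplying one sample's counts by a constant changes nothing
  counts2 <- counts
  counts2[, 2] <- counts2[, 2] * 7
  expect_equal(unifrac(tr, counts2), ours_w, tolerance = 1e-12)
  # metric properties on random pairs
  expect_true(isSymmetric(ours_w))
  expect_true(all(diag(ours_w) == 0))
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    expect_lte(ours_u[i, j], ours_u[i, k] + ours_u[k, j] + 1e-12)
})

test_that("PCoA closed forms and planar round-trips hold", {
  # two samples at distance d: one positive eigenvalue d^2/2, coords +/- d/2
  d <- matrix(c(0, 0.8, 0.8, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  p <- pcoa(d, axes = 2)
  expect_equal(max(p$eigenvalues), 0.8^2 / 2, tolerance = 1e-12)
  expect_equal(sort(p$coordinates[, 1]), c(-0.4, 0.4), ignore_attr = TRUE)
  # planar points are recovered up to rotation/reflection
  set.seed(13)
  x <- matrix(rnorm(20), 10, 2)
  dm <- as.matrix(dist(x))
  co <- pcoa(dm, axes = 2)$coordinates
  xc <- scale(x, scale = FALSE); cc <- scale(co, scale = FALSE)
  sv <- svd(t(cc) %*% xc)
  rot <- sv$u %*% t(sv$v)
  expect_lt(sum((cc %*% rot - xc)^2), 1e-8)
  # degenerate all-zero matrix
  z <- matrix(0, 3, 3)
  expect_true(all(abs(pcoa(z)$eigenvalues) < 1e-12))
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("UPGMA merges closest samples first and reproduces ultrametric input", {
  d <- matrix(c(0, 0.1, 0.9,
                0.1, 0, 0.9,
                0.9, 0.9, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma_dendrogram(d)
  expect_true(ape::is.monophyletic(tr, c("A", "B")))
  # ultrametric (cophenetic) input is reproduced exactly
  set.seed(3)
  pts <- matrix(rnorm(24), 8, 3, dimnames = list(letters[1:8], NULL))
  hc <- hclust(dist(pts), method = "average")
  dd <- as.matrix(cophenetic(hc))
  tr2 <- upgma_dendrogram(dd)
  co <- ape::cophenetic.phylo(tr2)[rownames(dd), colnames(dd)]
  expect_equal(co, dd, tolerance = 1e-12)
})
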