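# Shared fixtures: a small seven-sample study configuration that exercises
# every pipeline stage quickly, and quality-string helpers.

small_biomarker_map <- data.frame(
  biomarker = c("lysozyme", "IL1b"),
  genus = c("Streptococcus", "Prevotella"),
  r = c(0.63, 0.58),
  mean = c(30, 80),
  sd = c(8, 20),
  stringsAsFactors = FALSE)

small_study_cfg <- function(seed = 7, reads_per_sample = 300, ...) {
  study_config(n_per_group = c(HC = 3, CD = 2, UC = 2),
               reads_per_sample = reads_per_sample,
               effect_sizes = c(Prevotella = 2.5, Streptococcus = 0.6),
               biomarker_map = small_biomarker_map,
               n_biomarker_subjects = c(HC = 3, CD = 2, UC = 2),
               qpcr_targets = "Prevotella melaninogenica",
               seed = seed, ...)
}

small_db <- function(seed = 7) generate_reference_db(6, 2, seed = seed)

# Phred+33 quality string from integer scores
qstr <- function(q) intToUtf8(33L + q)

# random DNA string
rdna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# substitute k bases of a sequence at given (or random) positions
mutate_seq <- function(seq, k, pos = NULL) {
  s <- strsplit(seq, "")[[1]]
  if (is.null(pos)) pos <- sample(length(s), k)
  for (p in pos) s[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1]
  paste(s, collapse = "")
}

# random abundance count vector with singletons and doubletons
rand_counts <- function(s = 30, lambda = 5) {
  v <- rpois(s, lambda) + 1L
  v[sample(s, min(3, s))] <- 1L
  v
}

# Independent brute-force formula evaluations (the oracle) for the estimator
# panel; written directly from the frequency-count definitions.
oracle_profile <- function(v) {
  v <- v[v > 0]
  n <- sum(v); s <- length(v); p <- v / n
  h <- -sum(p * log(p))
  lambda <- sum(p^2)
  f1 <- sum(v == 1); f2 <- sum(v == 2)
  chao <- s + f1 * (f1 - 1) / (2 * (f2 + 1))
  rare <- v[v <= 10]
  if (sum(rare) == 0 || (1 - f1 / sum(rare)) == 0 || sum(rare) < 2) {
    ace_o <- chao
  } else {
    c_ace <- 1 - f1 / sum(rare)
    fk <- tabulate(rare, 10)
    g2 <- max(length(rare) / c_ace * sum((1:10) * (0:9) * fk) /
                (sum(rare) * (sum(rare) - 1)) - 1, 0)
    ace_o <- sum(v > 10) + length(rare) / c_ace + f1 / c_ace * g2
  }
  alpha <- if (s < n) uniroot(function(a) a * log(1 + n / a) - s,
                              c(1e-8, 1e8), tol = 1e-14)$root else NA
  c(shannon = h, simpson = 1 - lambda, invsimpson = 1 / lambda,
    pielou = if (s > 1) h / log(s) else NA, chao1 = chao, ace = ace_o,
    fisher_alpha = alpha)
}

# independent brute-force UniFrac: per edge, recompute the descendant tip set
# naively and sum branch lengths over |pA - pB| (weighted) or set symmetric
# difference (unweighted)
brute_unifrac <- function(tree, pA, pB, weighted = TRUE) {
  ntip <- length(tree$tip.label)
  desc_tips <- function(node) {
    if (node <= ntip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  num <- 0; den_u <- 0
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tree$tip.label[desc_tips(tree$edge[e, 2])]
    a <- sum(pA[tips]); b <- sum(pB[tips])
    if (weighted) {
      num <- num + tree$edge.length[e] * abs(a - b)
    } else {
      num <- num + tree$edge.length[e] * as.numeric(xor(a > 0, b > 0))
      den_u <- den_u + tree$edge.length[e] * as.numeric(a > 0 || b > 0)
    }
  }
  if (weighted) num else num / den_u
}
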