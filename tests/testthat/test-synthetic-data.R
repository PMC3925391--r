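test_that("reference database generation is seeded and structurally sound", {
  db1 <- generate_reference_db(14, 3, seed = 1)
  db2 <- generate_reference_db(14, 3, seed = 1)
  expect_identical(db1, db2)
  expect_equal(nrow(db1), 42)
  expect_false(anyDuplicated(db1$ref_id) > 0)
  expect_true(all(grepl("^[ACGT]+$", db1$sequence)))
  # one record exceeds the 431 nt V1-V2 maximum (long-read exception bait)
  expect_true(any(nchar(db1$sequence) > 431))
  expect_error(generate_reference_db(1, 3), "n_genera")
})

test_that("genera are separated below 92% identity, species resolvable", {
  db <- generate_reference_db(5, 2, seed = 3)
  for (i in seq_len(nrow(db) - 1)) {
    for (j in (i + 1):nrow(db)) {
      a <- align_pair(db$sequence[i], db$sequence[j], band = -1)
      if (db$genus[i] != db$genus[j]) {
        expect_lt(a[["identity_global"]], 0.92)
      } else {
        # congeneric species: similar but distinct at the 96% OTU threshold
        expect_gt(a[["identity_global"]], 0.90)
        expect_lt(a[["identity_global"]], 0.96)
      }
    }
  }
})

test_that("profiles sum to one and respect fold-change directions", {
  cfg <- study_config(n_per_group = c(HC = 20, CD = 20, UC = 20),
                      effect_sizes = c(Prevotella = 3.0), seed = 11)
  db <- generate_reference_db(14, 3, seed = 11)
  pr <- generate_profiles(cfg, db)
  expect_equal(unname(colSums(pr$props)), rep(1, 60), tolerance = 1e-9)
  g <- true_genus_props(pr, db)
  grp <- pr$samples$group
  expect_gt(mean(g["Prevotella", grp == "CD"]), mean(g["Prevotella", grp == "HC"]))
  expect_gt(mean(g["Prevotella", grp == "UC"]), mean(g["Prevotella", grp == "HC"]))
  # null config: no systematic shift
  cfg0 <- study_config(n_per_group = c(HC = 20, CD = 20, UC = 20),
                       effect_sizes = c(Prevotella = 1.0), seed = 11)
  g0 <- true_genus_props(generate_profiles(cfg0, db), db)
  diff <- abs(mean(g0["Prevotella", grp == "CD"]) - mean(g0["Prevotella", grp == "HC"]))
  expect_lt(diff, 3 * sd(g0["Prevotella", ]) / sqrt(20) * 2)
  expect_error(generate_profiles(
    study_config(effect_sizes = c(NotAGenus = 2)), db), "absent")
})

test_that("effect size monotonicity: larger fold, larger realized difference", {
  db <- generate_reference_db(14, 3, seed = 5)
  diffs <- vapply(c(1, 2, 4), function(fc) {
    cfg <- study_config(n_per_group = c(HC = 25, CD = 25, UC = 25),
                        effect_sizes = c(Prevotella = fc), seed = 5)
    g <- true_genus_props(generate_profiles(cfg, db), db)
    grp <- rep(c("HC", "CD", "UC"), each = 25)
    mean(g["Prevotella", grp != "HC"]) - mean(g["Prevotella", grp == "HC"])
  }, 0)
  expect_true(all(diff(diffs) > 0))
})

test_that("read generation: determinism, manifest consistency, chimera and quality rates", {
  cfg <- study_config(n_per_group = c(HC = 4, CD = 3, UC = 3),
                      reads_per_sample = 4000, chimera_rate = 0.005,
                      effect_sizes = c(Prevotella = 2.5), seed = 13)
  db <- generate_reference_db(14, 3, seed = 13)
  pr <- generate_profiles(cfg, db)
  rd1 <- generate_reads(pr, db, cfg)
  rd2 <- generate_reads(pr, db, cfg)
  expect_identical(rd1$reads$sequence, rd2$reads$sequence)
  expect_identical(rd1$reads$qual, rd2$reads$qual)
  # one manifest row per read
  expect_setequal(rd1$reads$read_id, rd1$manifest$read_id)
  expect_equal(nrow(rd1$manifest), nrow(rd1$reads))
  n <- nrow(rd1$reads)
  # chimeric fraction inside the exact binomial 99% interval
  k <- sum(rd1$manifest$is_chimera)
  expect_gte(k, qbinom(0.005, n, 0.005))
  expect_lte(k, qbinom(0.995, n, 0.005))
  # chimera parents always differ and carry a middle breakpoint
  chi <- rd1$manifest[rd1$manifest$is_chimera, ]
  expect_true(all(chi$ref_id != chi$parent2))
  expect_true(all(chi$breakpoint >= 0.2 & chi$breakpoint <= 0.8))
  # low-quality fraction (mean QV < 25) matches the configured 0.75%
  low <- sum(rd1$reads$mean_qv < 25)
  expect_gte(low, qbinom(0.005, n, 0.0075))
  expect_lte(low, qbinom(0.995, n, 0.0075))
})

test_that("chimera_rate = 0 produces no chimeras", {
  cfg <- small_study_cfg(chimera_rate = 0, reads_per_sample = 50)
  db <- generate_reference_db(14, 3, seed = cfg$seed)
  rd <- generate_reads(generate_profiles(cfg, db), db, cfg)
  expect_false(any(rd$manifest$is_chimera))
})

test_that("biomarkers hit their anchored correlations", {
  cfg <- study_config(seed = 21) # default 59-sample design, 39 with biomarkers
  db <- generate_reference_db(14, 3, seed = 21)
  pr <- generate_profiles(cfg, db)
  bm <- generate_biomarkers(pr, db, cfg)
  expect_equal(nrow(bm), 39)
  g <- true_genus_props(pr, db)
  map <- cfg$biomarker_map
  for (i in seq_len(nrow(map))) {
    x <- g[map$genus[i], bm$sample_id]
    r <- cor(x, bm[[map$biomarker[i]]] / bm$total_protein)
    ci <- fisher_z_interval(map$r[i], nrow(bm))
    expect_gte(r, ci[1])
    expect_lte(r, ci[2])
  }
  # zero-noise panels are perfectly correlated
  bm0 <- generate_biomarkers(pr, db, cfg, noise = 0)
  r0 <- cor(g["Streptococcus", bm0$sample_id],
            bm0$lysozyme / bm0$total_protein)
  expect_equal(r0, 1, tolerance = 1e-12)
  # a null target correlation stays near zero at n = 39
  cfg_null <- study_config(
    biomarker_map = data.frame(biomarker = "lysozyme", genus = "Streptococcus",
                               r = 0, mean = 30, sd = 8), seed = 21)
  bmn <- generate_biomarkers(pr, db, cfg_null)
  rn <- cor(g["Streptococcus", bmn$sample_id],
            bmn$lysozyme / bmn$total_protein)
  expect_lt(abs(rn), 0.35)
  expect_error(study_config(biomarker_map = data.frame(
    biomarker = "x", genus = "Streptococcus", r = 1, mean = 1, sd = 1)),
    "correlations")
})

test_that("qPCR tables track true proportions", {
  cfg <- study_config(seed = 31)
  db <- generate_reference_db(14, 3, seed = 31)
  pr <- generate_profiles(cfg, db)
  # zero noise: asinh concordance with true proportions is exactly 1
  cfg0 <- study_config(qpcr_noise_sd = 0, seed = 31)
  qp0 <- generate_qpcr(pr, db, cfg0)
  prop <- colSums(pr$props[db$species == "Prevotella melaninogenica", ,
                           drop = FALSE])
  expect_equal(cor(asinh_transform(qp0[["Prevotella melaninogenica"]]),
                   asinh_transform(prop * 1e4)), 1, tolerance = 1e-12)
  # moderate-noise concordance envelopes (bands frozen from a 50-replicate
  # simulation of this construction): read-count scale asinh on both sides
  counts <- 3000 * prop
  rs5 <- vapply(1:50, function(s) {
    qp <- generate_qpcr(pr, db, study_config(qpcr_noise_sd = 0.5, seed = s))
    cor(asinh_transform(counts),
        asinh_transform(qp[["Prevotella melaninogenica"]]))
  }, 0)
  expect_true(all(rs5 > 0.5 & rs5 < 0.9))
  rs3 <- vapply(1:50, function(s) {
    qp <- generate_qpcr(pr, db, study_config(qpcr_noise_sd = 0.3, seed = s))
    cor(asinh_transform(counts),
        asinh_transform(qp[["Prevotella melaninogenica"]]))
  }, 0)
  expect_true(all(rs3 > 0.7 & rs3 < 0.99))
  # absent taxon quantifies to zero
  pr2 <- pr
  pr2$props[db$species == "Prevotella melaninogenica", 1] <- 0
  pr2$props[, 1] <- pr2$props[, 1] / sum(pr2$props[, 1])
  qp2 <- generate_qpcr(pr2, db, cfg)
  expect_identical(qp2[["Prevotella melaninogenica"]][1], 0)
  expect_error(study_config(qpcr_scale = 0), "positive")
})
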