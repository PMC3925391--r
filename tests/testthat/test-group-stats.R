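test_that("two-group comparisons match hand-evaluated statistics", {
  # Welch on {1,2,3} vs {4,5,6}: t = -3/sqrt(2/3) = -3.674, df = 4
  w <- compare_groups(c(1, 2, 3), c(4, 5, 6), mode = "welch")
  expect_equal(w$statistic, -3 / sqrt(2 / 3), tolerance = 1e-4)
  expect_equal(w$df, 4)
  expect_equal(w$test, "welch_t")
  # identical constant groups: statistic 0, p = 1
  z <- compare_groups(c(2, 2, 2), c(2, 2, 2), mode = "student")
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  zm <- compare_groups(c(2, 2, 2), c(2, 2, 2), mode = "mwu")
  expect_equal(zm$p_value, 1)
  # auto mode: heavy-tailed data routes to Mann-Whitney, normal data to t
  set.seed(1)
  skewed <- exp(rnorm(30, 0, 2))
  expect_equal(compare_groups(skewed, skewed + 1)$test, "mann_whitney")
  expect_equal(compare_groups(rnorm(30), rnorm(30))$test, "student_t")
  expect_error(compare_groups(1, c(1, 2)), "at least 2")
})

test_that("BH adjustment equals the stepwise-min oracle", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    # stepwise min: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1
    for (i in seq_len(m)) q[i] <- min(pmin(p[o][i:m] * m / (i:m), 1))
    q[order(o)]
  }
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.04)), c(0.01, 0.04))
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))^2
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12 & q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("Pearson matrix normalizes by total protein and evaluates exactly", {
  ga <- matrix(c(1, 2, 3, 1, 1, 1), 2, 3, byrow = TRUE,
               dimnames = list(c("g1", "gflat"), c("S1", "S2", "S3")))
  bm <- data.frame(sample_id = c("S1", "S2", "S3"),
                   m1 = c(1, 3, 2) * c(2, 4, 8),  # raw = normalized * protein
                   m2 = (2 * c(1, 2, 3) + 1) * c(2, 4, 8),
                   total_protein = c(2, 4, 8))
  pm <- pearson_matrix(ga, bm)
  expect_equal(pm$r[pm$genus == "g1" & pm$biomarker == "m1"], 0.5)
  expect_equal(pm$r[pm$genus == "g1" & pm$biomarker == "m2"], 1)
  expect_equal(pm$flag[pm$genus == "gflat"], c("zero_variance", "zero_variance"))
  expect_true(all(pm$q_value >= pm$p_value, na.rm = TRUE))
  # p-values match cor.test
  ct <- cor.test(ga["g1", ], bm$m1 / bm$total_protein)
  expect_equal(pm$p_value[pm$genus == "g1" & pm$biomarker == "m1"],
               ct$p.value, tolerance = 1e-12)
})

test_that("linear fits agree with the Pearson test and OLS geometry", {
  x <- c(1, 2, 3, 4)
  f <- suppressWarnings(linear_fit(x, 3 * x - 2))  # exact fit warns in summary.lm
  expect_equal(f[["slope"]], 3)
  expect_equal(f[["intercept"]], -2)
  set.seed(21)
  for (i in 1:100) {
    x <- rnorm(sample(5:30, 1))
    y <- rnorm(length(x))
    f <- linear_fit(x, y)
    expect_equal(f[["p_value"]], cor.test(x, y)$p.value, tolerance = 1e-12)
    res <- y - (f[["intercept"]] + f[["slope"]] * x)
    expect_lt(abs(sum(res * x)), 1e-9)
  }
  expect_error(linear_fit(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("asinh transform has its closed-form values and symmetry", {
  expect_equal(asinh_transform(0), 0)
  expect_equal(asinh_transform(1), log(1 + sqrt(2)))
  x <- seq(-5, 5, by = 0.25)
  expect_equal(asinh_transform(-x), -asinh_transform(x))
  expect_true(all(diff(asinh_transform(x)) > 0))
  expect_error(asinh_transform(c(1, Inf)), "finite")
})

test_that("qPCR concordance is exact without noise and robust to scaling", {
  counts <- c(0, 3, 10, 40, 120, 7, 0, 55)
  expect_equal(qpcr_concordance(counts, counts), 1)
  # asinh is only log-like, so a pure scale factor perturbs r slightly
  expect_gt(qpcr_concordance(counts, 100 * counts), 0.95)
  set.seed(5)
  copies <- counts * exp(rnorm(8, 0, 0.4)) * 50
  r1 <- qpcr_concordance(counts, copies)
  r2 <- qpcr_concordance(counts, copies * 10)
  expect_lt(abs(r1 - r2), 0.05)
})

test_that("group tests detect a fold-2.5 shift in most seeded replicates", {
  db <- generate_reference_db(14, 3, seed = 1)
  hit <- vapply(1:50, function(s) {
    cfg <- study_config(effect_sizes = c(Prevotella = 2.5), seed = s)
    g <- true_genus_props(generate_profiles(cfg, db), db)
    grp <- ifelse(rep(c("HC", "CD", "UC"), c(24, 21, 14)) == "HC", "HC", "IBD")
    tt <- taxon_group_tests(g, grp, "IBD", "HC", mode = "welch")
    tt$q_value[tt$taxon == "Prevotella"] < 0.05
  }, TRUE)
  expect_gte(mean(hit), 0.9)
})

test_that("distance group test separates structured groups", {
  set.seed(9)
  x <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 3), 10, 2))
  d <- as.matrix(dist(x))
  rownames(d) <- colnames(d) <- paste0("S", 1:20)
  res <- distance_group_test(d, rep(c("A", "B"), each = 10))
  expect_gt(res$mean_between, res$mean_within)
  expect_lt(res$p_value, 0.01)
})
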