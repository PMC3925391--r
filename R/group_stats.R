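# Group-comparison statistics (normality-dependent t / Mann-Whitney, Welch
# variant for taxon tables), Benjamini-Hochberg correction, biomarker
# correlation and regression, and the inverse-hyperbolic-sine qPCR concordance
# transform.

#' Two-group comparison with normality-dependent test choice
#'
#' `mode = "auto"` runs Shapiro-Wilk on each group at alpha = 0.05: if both
#' pass, a two-sample t-test (Student's); otherwise Mann-Whitney U with normal
#' approximation and tie correction. Explicit modes force Student's t, Welch's
#' t, or Mann-Whitney. Two identical constant groups return statistic 0 and
#' p = 1.
#'
#' @param x,y numeric observations of the two groups (>= 2 each).
#' @param mode `"auto"`, `"student"`, `"welch"`, or `"mwu"`.
#' @return data.frame (one row): `test`, `statistic`, `df` (NA for MWU),
#'   `p_value`.
#' @export
compare_groups <- function(x, y, mode = c("auto", "student", "welch", "mwu")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("need at least 2 observations per group")
  if (mode == "auto") {
    normal <- function(v) {
      if (length(unique(v)) < 3) return(FALSE)
      shapiro.test(v)$p.value >= 0.05
    }
    mode <- if (normal(x) && normal(y)) "student" else "mwu"
  }
  degenerate <- sd(x) == 0 && sd(y) == 0
  if (mode %in% c("student", "welch")) {
    test <- if (mode == "student") "student_t" else "welch_t"
    if (degenerate) {
      stat <- 0; df <- length(x) + length(y) - 2
      p <- if (mean(x) == mean(y)) 1 else 0
    } else {
      tt <- t.test(x, y, var.equal = (mode == "student"))
      stat <- unname(tt$statistic); df <- unname(tt$parameter)
      p <- tt$p.value
    }
    return(data.frame(test = test, statistic = stat, df = df, p_value = p,
                      stringsAsFactors = FALSE))
  }
  if (degenerate && mean(x) == mean(y)) {
    return(data.frame(test = "mann_whitney", statistic = length(x) * length(y) / 2,
                      df = NA_real_, p_value = 1, stringsAsFactors = FALSE))
  }
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  data.frame(test = "mann_whitney", statistic = unname(wt$statistic),
             df = NA_real_, p_value = wt$p.value, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1,
#' mapped back to the input order.
#'
#' @param p p-values in \[0, 1\] (NAs propagated).
#' @return q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-taxon group contrasts with BH correction
#'
#' Compares each taxon's relative abundance between two groups and adjusts the
#' p-values across taxa.
#'
#' @param abund taxa x sample relative-abundance matrix.
#' @param groups group label per sample (columns of `abund`).
#' @param g1,g2 the two group labels to contrast.
#' @param mode test mode (default `"welch"`, as used for taxon tables).
#' @return data.frame: `taxon`, `mean_g1`, `mean_g2`, `direction`, `test`,
#'   `statistic`, `p_value`, `q_value`.
#' @export
taxon_group_tests <- function(abund, groups, g1, g2, mode = "welch") {
  i1 <- which(groups == g1); i2 <- which(groups == g2)
  rows <- lapply(rownames(abund), function(tx) {
    x <- abund[tx, i1]; y <- abund[tx, i2]
    res <- tryCatch(compare_groups(x, y, mode = mode),
                    error = function(e) data.frame(test = mode, statistic = NA_real_,
                                                   df = NA_real_, p_value = NA_real_))
    data.frame(taxon = tx, mean_g1 = mean(x), mean_g2 = mean(y),
               direction = ifelse(mean(x) > mean(y), "higher_in_g1",
                                  "higher_in_g2"),
               test = res$test, statistic = res$statistic,
               p_value = res$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out
}

#' Pearson correlation matrix of genus abundances against biomarkers
#'
#' Biomarker values are divided by each subject's total protein before
#' correlation. Two-sided p-values from `t = r * sqrt((n - 2) / (1 - r^2))`;
#' BH adjustment across all genus x biomarker cells. Zero-variance pairs give
#' NA with a flag.
#'
#' @param genus_abund genus x sample relative-abundance matrix.
#' @param biomarkers data.frame with `sample_id`, biomarker columns and
#'   `total_protein`.
#' @param normalize divide biomarkers by `total_protein` (default TRUE).
#' @return data.frame (long): `genus`, `biomarker`, `n`, `r`, `p_value`,
#'   `q_value`, `flag` (`""` or `"zero_variance"`), plus attribute `"r_matrix"`
#'   (genus x biomarker).
#' @export
pearson_matrix <- function(genus_abund, biomarkers, normalize = TRUE) {
  ids <- intersect(colnames(genus_abund), biomarkers$sample_id)
  if (length(ids) < 3) stop("need at least 3 paired subjects")
  bm <- biomarkers[match(ids, biomarkers$sample_id), , drop = FALSE]
  cols <- setdiff(colnames(bm), c("sample_id", "group", "total_protein"))
  vals <- as.matrix(bm[, cols, drop = FALSE])
  if (normalize) {
    if (is.null(bm$total_protein)) stop("biomarkers lack a total_protein column")
    vals <- vals / bm$total_protein
  }
  ga <- genus_abund[, ids, drop = FALSE]
  n <- length(ids)
  rows <- list()
  k <- 0L
  rmat <- matrix(NA_real_, nrow(ga), length(cols),
                 dimnames = list(rownames(ga), cols))
  for (g in rownames(ga)) {
    for (b in cols) {
      k <- k + 1L
      x <- ga[g, ]; y <- vals[, b]
      if (sd(x) == 0 || sd(y) == 0) {
        rows[[k]] <- data.frame(genus = g, biomarker = b, n = n, r = NA_real_,
                                p_value = NA_real_, flag = "zero_variance",
                                stringsAsFactors = FALSE)
        next
      }
      r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
      p <- 2 * pt(-abs(tstat), df = n - 2)
      rmat[g, b] <- r
      rows[[k]] <- data.frame(genus = g, biomarker = b, n = n, r = r,
                              p_value = p, flag = "", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out <- out[, c("genus", "biomarker", "n", "r", "p_value", "q_value", "flag")]
  attr(out, "r_matrix") <- rmat
  out
}

#' Ordinary least-squares fit of y on x
#'
#' The slope's p-value is identical to the Pearson correlation p-value for the
#' same pair.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return named numeric: `slope`, `intercept`, `p_value`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) stop("need n >= 3 paired values")
  if (sd(x) == 0) stop("zero variance in x")
  fit <- lm(y ~ x)
  cf <- summary(fit)$coefficients
  c(slope = unname(cf["x", "Estimate"]),
    intercept = unname(cf["(Intercept)", "Estimate"]),
    p_value = unname(cf["x", "Pr(>|t|)"]))
}

#' Inverse hyperbolic sine transform
#'
#' `y = ln(x + sqrt(x^2 + 1))`: log-like but defined at zero, used for
#' read-count vs qPCR concordance.
#'
#' @param x finite numeric vector (zeros allowed).
#' @return transformed vector.
#' @export
asinh_transform <- function(x) {
  if (any(!is.finite(x))) stop("x must be finite")
  log(x + sqrt(x^2 + 1))
}

#' Concordance between sequencing read counts and qPCR copy numbers
#'
#' Pearson correlation of the inverse-hyperbolic-sine-transformed pairs.
#'
#' @param read_counts per-sample read counts of the target taxon.
#' @param copy_numbers per-sample qPCR copy numbers (paired).
#' @return Pearson r on the transformed scale.
#' @export
qpcr_concordance <- function(read_counts, copy_numbers) {
  if (length(read_counts) != length(copy_numbers))
    stop("unpaired samples")
  cor(asinh_transform(read_counts), asinh_transform(copy_numbers))
}

#' Compare UniFrac distances within vs between groups
#'
#' Treats pairwise distances as observations (Student's t), contrasting
#' within-group against between-group pairs; pair non-independence is a known
#' caveat of this convention.
#'
#' @param d sample x sample distance matrix.
#' @param groups group label per sample.
#' @return data.frame: `mean_within`, `mean_between`, `statistic`, `p_value`.
#' @export
distance_group_test <- function(d, groups) {
  n <- nrow(d)
  ut <- which(upper.tri(d), arr.ind = TRUE)
  same <- groups[ut[, 1]] == groups[ut[, 2]]
  within <- d[ut][same]
  between <- d[ut][!same]
  res <- compare_groups(within, between, mode = "student")
  data.frame(mean_within = mean(within), mean_between = mean(between),
             statistic = res$statistic, p_value = res$p_value)
}
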