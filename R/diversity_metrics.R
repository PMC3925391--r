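# Alpha-diversity estimator panel computed from a per-sample abundance vector
# (OTU counts). Natural logarithms throughout. Variants are pinned explicitly:
# bias-corrected Chao1 (classic form available by switch), ACE with rare
# cutoff 10 falling back to Chao1 when degenerate, Fisher's alpha by bisection.

.check_counts <- function(v) {
  v <- v[!is.na(v)]
  if (any(v < 0)) stop("abundance counts must be non-negative")
  v <- v[v > 0]
  if (length(v) == 0) stop("empty abundance vector")
  v
}

#' Shannon diversity (natural log)
#'
#' `H = -sum(p_i * ln(p_i))` over observed taxa.
#'
#' @param v non-negative abundance counts (zeros ignored).
#' @return H.
#' @export
shannon <- function(v) {
  v <- .check_counts(v)
  p <- v / sum(v)
  -sum(p * log(p))
}

#' Simpson and inverse Simpson diversity
#'
#' With `lambda = sum(p_i^2)`: Simpson diversity `1 - lambda` and inverse
#' Simpson `1 / lambda`.
#'
#' @param v non-negative abundance counts.
#' @return named numeric: `simpson`, `invsimpson`.
#' @export
simpson_family <- function(v) {
  v <- .check_counts(v)
  p <- v / sum(v)
  lambda <- sum(p^2)
  c(simpson = 1 - lambda, invsimpson = 1 / lambda)
}

#' Chao1 richness estimate
#'
#' Bias-corrected form `S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))` (default);
#' `bias_corrected = FALSE` gives the classic `S_obs + F1^2 / (2 * F2)`
#' (undefined without doubletons, where it falls back to the corrected form).
#'
#' @param v non-negative abundance counts.
#' @param bias_corrected use the bias-corrected estimator (default TRUE).
#' @return estimated richness, always `>= S_obs`.
#' @export
chao1 <- function(v, bias_corrected = TRUE) {
  v <- .check_counts(v)
  s_obs <- length(v)
  f1 <- sum(v == 1)
  f2 <- sum(v == 2)
  if (!bias_corrected && f2 > 0) return(s_obs + f1^2 / (2 * f2))
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' ACE richness estimate
#'
#' Abundance-based coverage estimator with rare cutoff `rare_cutoff`
#' (default 10). With `S_rare` rare taxa holding `N_rare` individuals,
#' coverage `C = 1 - F1 / N_rare` and
#' `gamma^2 = max((S_rare / C) * sum(k (k-1) F_k) / (N_rare (N_rare - 1)) - 1, 0)`,
#' `ACE = S_abund + S_rare / C + (F1 / C) * gamma^2`. Degenerate cases
#' (no rare individuals, zero coverage, or N_rare < 2) fall back to [chao1()].
#'
#' @param v non-negative abundance counts.
#' @param rare_cutoff rare-taxon threshold (counts `<= rare_cutoff`).
#' @return estimated richness.
#' @export
ace <- function(v, rare_cutoff = 10) {
  v <- .check_counts(v)
  rare <- v[v <= rare_cutoff]
  s_abund <- sum(v > rare_cutoff)
  s_rare <- length(rare)
  n_rare <- sum(rare)
  f1 <- sum(v == 1)
  if (n_rare == 0) return(chao1(v))
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0 || n_rare < 2) return(chao1(v))
  fk <- tabulate(rare, nbins = rare_cutoff)
  k <- seq_len(rare_cutoff)
  gamma2 <- max((s_rare / c_ace) * sum(k * (k - 1) * fk) /
                  (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + (f1 / c_ace) * gamma2
}

#' Fisher's log-series alpha
#'
#' Solves `S = alpha * ln(1 + N / alpha)` for `alpha` by bisection on
#' `(1e-8, 1e8)` to an `|S|` residual below `tol`.
#'
#' @param v non-negative abundance counts; requires `0 < S_obs < N`.
#' @param tol residual tolerance (default 1e-10).
#' @return alpha.
#' @export
fisher_alpha <- function(v, tol = 1e-10) {
  v <- .check_counts(v)
  s <- length(v)
  n <- sum(v)
  if (s >= n) stop("Fisher's alpha undefined when every taxon is a singleton")
  f <- function(a) a * log(1 + n / a) - s
  lo <- 1e-8
  hi <- 1e8
  if (f(lo) > 0 || f(hi) < 0) stop("Fisher's alpha outside search interval")
  repeat {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol || (hi - lo) < 1e-12 * mid) return(mid)
    if (fm > 0) hi <- mid else lo <- mid
  }
}

#' Pielou's evenness
#'
#' `J = H / ln(S_obs)`; undefined (NA) for a single observed taxon.
#'
#' @param v non-negative abundance counts.
#' @return J in \[0, 1\], or NA when `S_obs = 1`.
#' @export
pielou <- function(v) {
  v <- .check_counts(v)
  if (length(v) < 2) return(NA_real_)
  shannon(v) / log(length(v))
}

#' Full diversity profile of one abundance vector
#'
#' @param v non-negative abundance counts.
#' @return named numeric: `n_reads`, `s_obs`, `shannon`, `simpson`,
#'   `invsimpson`, `pielou`, `chao1`, `ace`, `fisher_alpha` (NA where
#'   undefined).
#' @export
diversity_profile <- function(v) {
  vv <- .check_counts(v)
  fa <- tryCatch(fisher_alpha(vv), error = function(e) NA_real_)
  sf <- simpson_family(vv)
  c(n_reads = sum(vv), s_obs = length(vv), shannon = shannon(vv),
    simpson = unname(sf["simpson"]), invsimpson = unname(sf["invsimpson"]),
    pielou = pielou(vv), chao1 = chao1(vv), ace = ace(vv), fisher_alpha = fa)
}

#' Per-sample diversity table of an OTU table
#'
#' @param otu_table OTU x sample count matrix.
#' @return data.frame with one row per sample and the columns of
#'   [diversity_profile()].
#' @export
sample_diversity <- function(otu_table) {
  m <- unclass(otu_table)
  prof <- t(apply(m, 2, diversity_profile))
  data.frame(sample_id = colnames(m), prof, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Group summary (mean +/- s.e.m.) of per-sample diversity
#'
#' @param diversity a [sample_diversity()] table.
#' @param groups group label per sample (aligned with `diversity$sample_id`).
#' @return data.frame: `group`, `index`, `mean`, `sem`, `n`.
#' @export
diversity_group_summary <- function(diversity, groups) {
  idx <- setdiff(colnames(diversity), "sample_id")
  out <- do.call(rbind, lapply(idx, function(ix) {
    vals <- split(diversity[[ix]], groups)
    data.frame(group = names(vals), index = ix,
               mean = vapply(vals, function(x) mean(x, na.rm = TRUE), 0),
               sem = vapply(vals, function(x)
                 sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))), 0),
               n = vapply(vals, function(x) sum(!is.na(x)), 0L),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
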