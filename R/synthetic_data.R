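# Synthetic-study generator: a seeded reference database, per-sample community
# profiles, barcoded error-bearing reads with a chimeric fraction, biomarker
# and qPCR panels, plus a per-read ground-truth manifest. Everything is fully
# determined by the configured seed so downstream stages can be tested against
# known truth.

.default_genera <- data.frame(
  genus = c("Streptococcus", "Prevotella", "Rothia", "Neisseria",
            "Granulicatella", "Actinomyces", "Haemophilus", "Veillonella",
            "Gemella", "Leptotrichia", "Fusobacterium", "Porphyromonas",
            "Lachnospiraceae", "Oribacterium"),
  phylum = c("Firmicutes", "Bacteroidetes", "Actinobacteria", "Proteobacteria",
             "Firmicutes", "Actinobacteria", "Proteobacteria", "Firmicutes",
             "Firmicutes", "Fusobacteria", "Fusobacteria", "Bacteroidetes",
             "Firmicutes", "Firmicutes"),
  base_prop = c(0.34, 0.10, 0.06, 0.08, 0.03, 0.05, 0.08, 0.06,
                0.04, 0.03, 0.04, 0.03, 0.03, 0.03),
  stringsAsFactors = FALSE)

# species epithets for the first species of selected genera, so qPCR targets
# have conventional names
.special_species <- c(Streptococcus = "Streptococcus mitis",
                      Prevotella = "Prevotella melaninogenica",
                      Haemophilus = "Haemophilus parainfluenzae",
                      Veillonella = "Veillonella sp. oral taxon 158",
                      Neisseria = "Neisseria mucosa",
                      Gemella = "Gemella sanguinis")

.default_effects <- c(Prevotella = 2.5, Veillonella = 2.0, Streptococcus = 0.6,
                      Haemophilus = 0.45, Neisseria = 0.5, Gemella = 0.5)

.default_biomarker_map <- data.frame(
  biomarker = c("lysozyme", "IL1b", "IL8", "LL37", "IL6", "TNFa", "MCP1",
                "IgA"),
  genus = c("Streptococcus", "Prevotella", "Streptococcus", "Haemophilus",
            "Prevotella", "Veillonella", "Prevotella", "Veillonella"),
  r = c(0.63, 0.58, -0.51, -0.54, 0.45, 0.40, 0.35, 0.45),
  mean = c(30, 80, 300, 4, 8, 6, 40, 200),
  sd = c(8, 20, 75, 1, 2, 1.5, 10, 50),
  stringsAsFactors = FALSE)

#' Study configuration for the synthetic-data generator
#'
#' Bundles every knob of the generator. Defaults emulate the study design the
#' pipeline was built around: 59 subjects (24 healthy controls, 21 Crohn's
#' disease, 14 ulcerative colitis), 5000 reads per sample, a 0.46% chimeric
#' fraction, a 0.75% low-mean-quality fraction, composition shifts in six key
#' oral genera, and biomarkers anchored to genus abundances at fixed Pearson
#' correlations.
#'
#' @param n_per_group named integer vector, subjects per group
#'   (`c(HC=,CD=,UC=)`).
#' @param reads_per_sample reads generated per sample; must be at least the
#'   rarefaction depth used downstream.
#' @param chimera_rate fraction of reads constructed as two-parent splices.
#' @param error_rate per-base substitution probability in the template.
#' @param homopolymer_indel_rate per-base indel probability inside homopolymer
#'   runs (454-style errors).
#' @param low_quality_rate fraction of reads drawn from the low-quality mean-QV
#'   mixture component (target removal fraction at the QV 25 filter).
#' @param effect_sizes named numeric vector, genus -> multiplicative fold
#'   change applied to both IBD groups before renormalization.
#' @param biomarker_map data.frame with columns `biomarker`, `genus`, `r`,
#'   `mean`, `sd`: each biomarker is anchored to one genus at population
#'   Pearson correlation `r` (on total-protein-normalized scale).
#' @param n_biomarker_subjects named integer vector, subjects per group with
#'   biomarker measurements (default `c(HC=15, CD=14, UC=10)`, n = 39).
#' @param dirichlet_conc concentration of the per-sample Dirichlet draw around
#'   the baseline genus proportions (larger = less sample-to-sample variation).
#' @param qpcr_targets species labels quantified by the synthetic qPCR assay.
#' @param qpcr_scale copies per unit proportion (> 0).
#' @param qpcr_noise_sd sdlog of the multiplicative lognormal qPCR noise.
#' @param fwd_primer,rev_primer amplification primer sequences flanking the
#'   insert (the reverse primer appears reverse-complemented at the 3' end).
#' @param barcode_length,barcode_min_dist barcode design: fixed length and
#'   minimum pairwise Hamming distance.
#' @param seed integer; fully determines all generator output.
#' @return list of class `study_config`.
#' @export
study_config <- function(n_per_group = c(HC = 24, CD = 21, UC = 14),
                         reads_per_sample = 5000,
                         chimera_rate = 0.0046,
                         error_rate = 0.002,
                         homopolymer_indel_rate = 0.0005,
                         low_quality_rate = 0.0075,
                         effect_sizes = .default_effects,
                         biomarker_map = .default_biomarker_map,
                         n_biomarker_subjects = c(HC = 15, CD = 14, UC = 10),
                         dirichlet_conc = 200,
                         qpcr_targets = c("Prevotella melaninogenica",
                                          "Haemophilus parainfluenzae"),
                         qpcr_scale = 1e4,
                         qpcr_noise_sd = 0.3,
                         fwd_primer = "AGAGTTTGATCCTGGCTCAG",
                         rev_primer = "TGCTGCCTCCCGTAGGAGT",
                         barcode_length = 8,
                         barcode_min_dist = 3,
                         seed = 1L) {
  rates <- c(chimera_rate = chimera_rate, error_rate = error_rate,
             homopolymer_indel_rate = homopolymer_indel_rate,
             low_quality_rate = low_quality_rate)
  if (any(rates < 0 | rates >= 1))
    stop("all rates must lie in [0, 1)")
  if (length(n_per_group) != 3 || is.null(names(n_per_group)))
    stop("n_per_group must be a named vector of three group sizes")
  if (any(n_per_group < 1)) stop("each group needs at least one subject")
  if (reads_per_sample < 1) stop("reads_per_sample must be positive")
  if (any(abs(biomarker_map$r) >= 1))
    stop("biomarker target correlations must lie in (-1, 1)")
  if (qpcr_scale <= 0) stop("qpcr_scale must be positive")
  cfg <- list(n_per_group = n_per_group,
              reads_per_sample = as.integer(reads_per_sample),
              chimera_rate = chimera_rate,
              error_rate = error_rate,
              homopolymer_indel_rate = homopolymer_indel_rate,
              low_quality_rate = low_quality_rate,
              effect_sizes = effect_sizes,
              biomarker_map = biomarker_map,
              n_biomarker_subjects = n_biomarker_subjects,
              dirichlet_conc = dirichlet_conc,
              qpcr_targets = qpcr_targets,
              qpcr_scale = qpcr_scale,
              qpcr_noise_sd = qpcr_noise_sd,
              fwd_primer = toupper(fwd_primer),
              rev_primer = toupper(rev_primer),
              barcode_length = as.integer(barcode_length),
              barcode_min_dist = as.integer(barcode_min_dist),
              seed = as.integer(seed))
  class(cfg) <- "study_config"
  cfg
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate_at_rate <- function(seq, rate) {
  bases <- c("A", "C", "G", "T")
  s <- strsplit(seq, "")[[1]]
  k <- max(1L, round(rate * length(s)))
  pos <- sample(length(s), k)
  for (p in pos) s[p] <- sample(setdiff(bases, s[p]), 1)
  paste(s, collapse = "")
}

#' Generate a synthetic 16S V1-V2 reference database
#'
#' Genus ancestors are independent random sequences (pairwise identity well
#' below the 92% genus separation floor); species diverge 2.5-4% from their
#' genus ancestor at randomly placed substitutions, so within-genus species
#' pairs sit ~5-8% apart -- resolvable at the 96% OTU threshold and
#' assignable at the 95% genus threshold. One record is extended beyond 431 nt
#' to exercise the long-read primer-check exception.
#'
#' @param n_genera number of genera (>= 2). Up to 14 genera reuse the built-in
#'   oral genus/phylum labels; extras are labelled `GenusNN`.
#' @param n_species_per_genus species per genus (>= 1).
#' @param seed integer seed.
#' @return data.frame of class `reference_db` with columns `ref_id`,
#'   `sequence`, `phylum`, `genus`, `species`.
#' @export
generate_reference_db <- function(n_genera = 14, n_species_per_genus = 3,
                                  seed = 1L) {
  if (n_genera < 2) stop("n_genera must be >= 2")
  if (n_species_per_genus < 1) stop("n_species_per_genus must be >= 1")
  set.seed(seed)
  ng <- n_genera
  gen <- .default_genera[seq_len(min(ng, nrow(.default_genera))), ]
  if (ng > nrow(.default_genera)) {
    extra <- ng - nrow(.default_genera)
    gen <- rbind(gen, data.frame(
      genus = sprintf("Genus%02d", seq_len(extra)),
      phylum = rep_len(unique(.default_genera$phylum), extra),
      base_prop = rep(0.02, extra)))
  }
  rows <- list()
  idx <- 0L
  for (g in seq_len(ng)) {
    len <- sample(300:431, 1)
    ancestor <- .random_dna(len)
    for (s in seq_len(n_species_per_genus)) {
      idx <- idx + 1L
      div <- runif(1, 0.025, 0.04)
      seqs <- .mutate_at_rate(ancestor, div)
      sp_name <- if (s == 1 && gen$genus[g] %in% names(.special_species)) {
        unname(.special_species[gen$genus[g]])
      } else {
        paste0(gen$genus[g], " sp", s)
      }
      rows[[idx]] <- data.frame(ref_id = sprintf("REF_%03d", idx),
                                sequence = seqs,
                                phylum = gen$phylum[g],
                                genus = gen$genus[g],
                                species = sp_name,
                                stringsAsFactors = FALSE)
    }
  }
  db <- do.call(rbind, rows)
  # one long record (> 431 nt) to exercise the length exception
  long_i <- nrow(db)
  tail_len <- 493 - nchar(db$sequence[long_i])
  if (tail_len > 0)
    db$sequence[long_i] <- paste0(db$sequence[long_i], .random_dna(tail_len))
  class(db) <- c("reference_db", "data.frame")
  db
}

#' Generate per-sample community profiles
#'
#' Healthy-control genus proportions are Dirichlet draws around a baseline
#' dominated by a Streptococcus-like genus; IBD (CD/UC) samples multiply the
#' configured genera by their fold change and renormalize. Genus mass is split
#' across its species by study-level species weights.
#'
#' @param config a [study_config()].
#' @param db a [generate_reference_db()] result.
#' @return list of class `community_profiles`: `samples` (data.frame
#'   `sample_id`, `group`) and `props` (reference x sample proportion matrix,
#'   columns summing to 1).
#' @export
generate_profiles <- function(config, db) {
  stopifnot(inherits(config, "study_config"))
  genera <- unique(db$genus)
  unknown <- setdiff(names(config$effect_sizes), genera)
  if (length(unknown))
    stop("effect_sizes reference genera absent from db: ",
         paste(unknown, collapse = ", "))
  set.seed(config$seed + 1L)
  base <- .default_genera$base_prop[match(genera, .default_genera$genus)]
  base[is.na(base)] <- 0.02
  base <- base / sum(base)
  names(base) <- genera
  # study-level species weights within each genus
  sp_w <- numeric(nrow(db))
  for (g in genera) {
    i <- which(db$genus == g)
    w <- rgamma(length(i), shape = 5)
    sp_w[i] <- w / sum(w)
  }
  groups <- rep(names(config$n_per_group), config$n_per_group)
  ids <- sprintf("S%02d", seq_along(groups))
  props <- matrix(0, nrow(db), length(ids),
                  dimnames = list(db$ref_id, ids))
  conc <- config$dirichlet_conc
  for (j in seq_along(ids)) {
    gp <- rgamma(length(base), shape = base * conc)
    gp <- gp / sum(gp)
    names(gp) <- genera
    if (groups[j] != "HC") {
      fc <- config$effect_sizes[names(config$effect_sizes) %in% genera]
      gp[names(fc)] <- gp[names(fc)] * fc
      gp <- gp / sum(gp)
    }
    props[, j] <- gp[db$genus] * sp_w
  }
  out <- list(samples = data.frame(sample_id = ids, group = groups,
                                   stringsAsFactors = FALSE),
              props = props)
  class(out) <- "community_profiles"
  out
}

#' True genus-level proportions of a profile set
#' @param profiles a [generate_profiles()] result.
#' @param db the matching reference database.
#' @return genus x sample matrix of proportions.
#' @export
true_genus_props <- function(profiles, db) {
  rowsum(profiles$props, group = db$genus[match(rownames(profiles$props),
                                                db$ref_id)])
}

#' Design sample barcodes
#'
#' Greedy selection of fixed-length barcodes with a minimum pairwise Hamming
#' distance, from a seeded random candidate stream.
#'
#' @param n number of barcodes.
#' @param length barcode length (nt).
#' @param min_dist minimum pairwise Hamming distance.
#' @param seed integer seed.
#' @return character vector of `n` barcodes; [generate_reads()] assigns them
#'   to samples in order.
#' @export
generate_barcodes <- function(n, length = 8, min_dist = 3, seed = 1L) {
  set.seed(seed)
  picked <- character(0)
  tries <- 0L
  while (base::length(picked) < n) {
    cand <- .random_dna(length)
    tries <- tries + 1L
    if (tries > 100000L) stop("barcode design space exhausted")
    ok <- TRUE
    for (b in picked) {
      d <- sum(strsplit(cand, "")[[1]] != strsplit(b, "")[[1]])
      if (d < min_dist) { ok <- FALSE; break }
    }
    if (ok) picked <- c(picked, cand)
  }
  picked
}

#' Generate barcoded amplicon reads with errors and chimeras
#'
#' Each read is `barcode + forward primer + template + revcomp(reverse
#' primer)`. Templates carry per-base substitution and homopolymer-indel
#' errors; a configured fraction are two-parent chimeras (parents from
#' different genera) spliced at a breakpoint uniform in the middle 60% of the
#' template. Per-read mean quality
#' is drawn from a two-component mixture (good ~ N(33, 2), low ~ N(19, 2) with
#' weight `low_quality_rate`) and per-base Phred values jitter around it, so
#' the fraction of reads with mean QV below 25 matches the configured rate.
#'
#' @param profiles a [generate_profiles()] result.
#' @param db the matching reference database.
#' @param config the [study_config()].
#' @return list: `reads` (a [read_set()] with `sample_id` unset -- reads are
#'   demultiplexed downstream), `manifest` (ground truth: `read_id`,
#'   `sample_id`, `ref_id`, `parent2`, `breakpoint`, `is_chimera`),
#'   `barcodes` (data.frame `sample_id`, `barcode`).
#' @export
generate_reads <- function(profiles, db, config) {
  stopifnot(inherits(config, "study_config"))
  ns <- nrow(profiles$samples)
  n <- config$reads_per_sample
  if (ns * n == 0) stop("no reads requested")
  set.seed(config$seed + 2L)
  barcodes <- generate_barcodes(ns, config$barcode_length,
                                config$barcode_min_dist,
                                seed = config$seed + 2L)
  bc_map <- data.frame(sample_id = profiles$samples$sample_id,
                       barcode = barcodes, stringsAsFactors = FALSE)
  rc_rev <- revcomp(config$rev_primer)
  seq_list <- vector("list", ns)
  man_list <- vector("list", ns)
  for (j in seq_len(ns)) {
    p <- profiles$props[, j]
    parent1 <- sample.int(nrow(db), n, replace = TRUE, prob = p)
    is_chi <- rbinom(n, 1, config$chimera_rate) == 1
    parent2 <- rep(NA_integer_, n)
    bp <- rep(NA_real_, n)
    templates <- db$sequence[parent1]
    if (any(is_chi)) {
      for (i in which(is_chi)) {
        # parents drawn from different genera so each parent covers < 90% of
        # the splice by construction (the match-length rule can detect it)
        other <- which(db$genus != db$genus[parent1[i]])
        p2 <- other[sample.int(length(other), 1, prob = p[other])]
        parent2[i] <- p2
        frac <- runif(1, 0.2, 0.8)
        t1 <- db$sequence[parent1[i]]
        t2 <- db$sequence[p2]
        b1 <- round(frac * nchar(t1))
        b2 <- round(frac * nchar(t2))
        templates[i] <- paste0(substr(t1, 1, b1),
                               substr(t2, b2 + 1, nchar(t2)))
        bp[i] <- frac
      }
    }
    templates <- cpp_mutate_seqs(templates, config$error_rate,
                                 config$homopolymer_indel_rate)
    full <- paste0(bc_map$barcode[j], config$fwd_primer, templates, rc_rev)
    low <- rbinom(n, 1, config$low_quality_rate) == 1
    mu <- ifelse(low, rnorm(n, 19, 2), rnorm(n, 33, 2))
    quals <- cpp_phred_strings(nchar(full), mu, sd = 2)
    ids <- sprintf("%s_R%05d", bc_map$sample_id[j], seq_len(n))
    seq_list[[j]] <- data.frame(read_id = ids, sequence = full, qual = quals,
                                stringsAsFactors = FALSE)
    man_list[[j]] <- data.frame(read_id = ids,
                                sample_id = bc_map$sample_id[j],
                                ref_id = db$ref_id[parent1],
                                parent2 = ifelse(is.na(parent2), NA_character_,
                                                 db$ref_id[parent2]),
                                breakpoint = bp,
                                is_chimera = is_chi,
                                stringsAsFactors = FALSE)
  }
  allr <- do.call(rbind, seq_list)
  reads <- read_set(allr$read_id, allr$sequence, allr$qual)
  list(reads = reads, manifest = do.call(rbind, man_list), barcodes = bc_map)
}

#' Generate the salivary biomarker panel
#'
#' Each biomarker is anchored to one genus: on the total-protein-normalized
#' scale, `value = mean + sd * (r * z(abundance) + sqrt(1 - r^2) * noise *
#' N(0,1))`, so the population Pearson correlation with the anchor genus
#' equals `r`. The emitted raw values are multiplied by a per-subject total
#' protein concentration; dividing by the `total_protein` column recovers the
#' normalized scale.
#'
#' @param profiles a [generate_profiles()] result.
#' @param db the matching reference database.
#' @param config the [study_config()].
#' @param noise scale factor on the residual term; `0` gives perfectly
#'   correlated (r = +/-1) panels.
#' @return data.frame: `sample_id`, `group`, one column per biomarker (raw
#'   values), `total_protein`.
#' @export
generate_biomarkers <- function(profiles, db, config, noise = 1) {
  stopifnot(inherits(config, "study_config"))
  map <- config$biomarker_map
  if (any(abs(map$r) >= 1)) stop("target correlations must lie in (-1, 1)")
  set.seed(config$seed + 3L)
  # subject subset with biomarker measurements
  keep <- unlist(lapply(names(config$n_biomarker_subjects), function(g) {
    i <- which(profiles$samples$group == g)
    head(i, config$n_biomarker_subjects[[g]])
  }))
  keep <- sort(keep)
  gprops <- true_genus_props(profiles, db)
  out <- profiles$samples[keep, , drop = FALSE]
  tp <- exp(rnorm(length(keep), 0, 0.2))
  for (b in seq_len(nrow(map))) {
    g <- map$genus[b]
    if (!g %in% rownames(gprops))
      stop("biomarker anchor genus absent from db: ", g)
    x <- gprops[g, keep]
    zx <- (x - mean(x)) / sd(x)
    # residuals orthogonalized against the anchor abundance so the sample
    # correlation with the true abundance equals the target exactly; any
    # deviation in recovered correlations then reflects pipeline measurement
    # error, not construction noise
    e <- rnorm(length(keep))
    e <- e - zx * sum(e * zx) / sum(zx^2)
    e <- (e - mean(e)) / sd(e)
    ystd <- map$r[b] * zx + sqrt(1 - map$r[b]^2) * noise * e
    out[[map$biomarker[b]]] <- (map$mean[b] + map$sd[b] * ystd) * tp
  }
  out$total_protein <- tp
  rownames(out) <- NULL
  out
}

#' Generate a synthetic qPCR quantification table
#'
#' Per-sample copy number = `qpcr_scale * true species proportion * lognormal
#' noise`; species absent from a profile yield exactly 0 copies.
#'
#' @param profiles a [generate_profiles()] result.
#' @param db the matching reference database.
#' @param config the [study_config()]; uses `qpcr_targets`, `qpcr_scale`,
#'   `qpcr_noise_sd`.
#' @return data.frame: `sample_id`, `group`, one column per target species.
#' @export
generate_qpcr <- function(profiles, db, config) {
  stopifnot(inherits(config, "study_config"))
  if (config$qpcr_scale <= 0) stop("qpcr_scale must be positive")
  targets <- config$qpcr_targets
  missing <- setdiff(targets, db$species)
  if (length(missing))
    stop("qPCR targets absent from db: ", paste(missing, collapse = ", "))
  set.seed(config$seed + 4L)
  out <- profiles$samples
  for (t in targets) {
    i <- which(db$species == t)
    prop <- colSums(profiles$props[i, , drop = FALSE])
    nz <- exp(rnorm(length(prop), 0, config$qpcr_noise_sd))
    out[[t]] <- ifelse(prop > 0, config$qpcr_scale * prop * nz, 0)
  }
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper calling [generate_reference_db()],
#' [generate_profiles()], [generate_reads()], [generate_biomarkers()] and
#' [generate_qpcr()] under one configuration.
#'
#' @param config a [study_config()].
#' @param n_genera,n_species_per_genus reference database size.
#' @return list: `config`, `db`, `profiles`, `reads`, `manifest`, `barcodes`,
#'   `biomarkers`, `qpcr`, `metadata` (sample_id, group).
#' @export
generate_study <- function(config = study_config(), n_genera = 14,
                           n_species_per_genus = 3) {
  db <- generate_reference_db(n_genera, n_species_per_genus,
                              seed = config$seed)
  profiles <- generate_profiles(config, db)
  rd <- generate_reads(profiles, db, config)
  biomarkers <- generate_biomarkers(profiles, db, config)
  qpcr <- generate_qpcr(profiles, db, config)
  list(config = config, db = db, profiles = profiles, reads = rd$reads,
       manifest = rd$manifest, barcodes = rd$barcodes,
       biomarkers = biomarkers, qpcr = qpcr, metadata = profiles$samples)
}
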