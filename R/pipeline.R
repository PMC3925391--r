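# End-to-end orchestration: QC -> chimera/taxonomy -> rarefaction ->
# quality-sorted clustering -> diversity -> UniFrac/PCoA/dendrogram ->
# group statistics -> biomarker correlations -> qPCR concordance, under one
# seeded configuration, with stage-count reconciliation.

#' Pipeline configuration
#'
#' @param depth rarefaction depth (reads/sample, default 3000).
#' @param identity OTU clustering identity threshold (default 0.96).
#' @param qv_threshold minimum mean quality value (default 25).
#' @param chimera_coverage best-hit query coverage below which a read is
#'   chimeric (default 0.90).
#' @param length_exception primer-check length exception in bases (default 400).
#' @param genus_identity genus-assignment identity threshold (default 0.95).
#' @param species_identity,phylum_identity remaining taxonomy thresholds.
#' @param max_mismatch substitutions tolerated per primer.
#' @param primer_policy `"both"` or `"either"` (see [check_primers()]).
#' @param k k-mer size for search and clustering.
#' @param top_n reference candidates aligned per read.
#' @param maxrejects clustering reject cap.
#' @param seed integer seed (rarefaction subsampling).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(depth = 3000, identity = 0.96, qv_threshold = 25,
                            chimera_coverage = 0.90, length_exception = 400,
                            genus_identity = 0.95, species_identity = 0.97,
                            phylum_identity = 0.80, max_mismatch = 2,
                            primer_policy = "both", k = 8, top_n = 2,
                            maxrejects = 32, seed = 1L) {
  stopifnot(depth >= 1, identity > 0, identity <= 1,
            chimera_coverage > 0, chimera_coverage <= 1,
            genus_identity <= species_identity)
  cfg <- list(depth = as.integer(depth), identity = identity,
              qv_threshold = qv_threshold,
              chimera_coverage = chimera_coverage,
              length_exception = length_exception,
              genus_identity = genus_identity,
              species_identity = species_identity,
              phylum_identity = phylum_identity,
              max_mismatch = max_mismatch, primer_policy = primer_policy,
              k = as.integer(k), top_n = as.integer(top_n),
              maxrejects = as.integer(maxrejects), seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path YAML file.
#' @return `path` (write) or the configuration (read).
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: demultiplexing + primer check + quality filter,
#' reference search (chimera removal, per-read taxonomy), rarefaction,
#' quality sorting, greedy OTU clustering, OTU table construction with genus
#' and phylum aggregates, alpha diversity, UniFrac (weighted and unweighted)
#' with PCoA and a UPGMA dendrogram, taxon group contrasts, biomarker
#' correlations, and qPCR concordance. Identical inputs + seed give identical
#' outputs.
#'
#' @param reads raw barcoded [read_set()].
#' @param barcode_map data.frame `sample_id`, `barcode`.
#' @param db reference database (`ref_id`, `sequence`, `phylum`, `genus`,
#'   `species`).
#' @param metadata data.frame `sample_id`, `group`.
#' @param fwd_primer,rev_primer amplification primers.
#' @param biomarkers optional biomarker table (see [generate_biomarkers()]).
#' @param qpcr optional qPCR table (see [generate_qpcr()]).
#' @param config a [pipeline_config()].
#' @param outdir optional output directory; when given, tables, FASTA and
#'   Newick files are written there.
#' @return list with elements `qc_report`, `search` (chimera/no-hit counts),
#'   `otu_table`, `genus_table`, `phylum_table`, `diversity`,
#'   `diversity_summary`, `tree`, `unifrac_weighted`, `unifrac_unweighted`,
#'   `pcoa`, `dendrogram`, `distance_tests`, `taxon_tests`, `correlations`,
#'   `qpcr_concordance`, `manifest` (stage counts, parameters, seed, timings).
#' @export
run_pipeline <- function(reads, barcode_map, db, metadata,
                         fwd_primer, rev_primer,
                         biomarkers = NULL, qpcr = NULL,
                         config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- t1 - t0
    t0 <<- t1
  }

  qc <- run_read_qc(reads, barcode_map, fwd_primer, rev_primer,
                    max_mismatch = config$max_mismatch,
                    length_exception = config$length_exception,
                    policy = config$primer_policy,
                    qv_threshold = config$qv_threshold)
  if (nrow(qc$reads) == 0) stop("qc: no reads survived")
  tick("qc")

  search <- run_reference_search(qc$reads, db,
                                 coverage_threshold = config$chimera_coverage,
                                 k = config$k, top_n = config$top_n)
  search$taxonomy$best_identity <- search$taxonomy$best_identity
  tick("search")

  rare <- rarefy_reads(search$reads, depth = config$depth, seed = config$seed)
  if (nrow(rare) == 0) stop("rarefy: no samples at depth")
  tick("rarefy")

  sorted <- sort_by_quality(rare)
  clust <- greedy_cluster(sorted, identity_threshold = config$identity,
                          k = config$k, maxrejects = config$maxrejects)
  otu_tab <- build_otu_table(clust, sorted, taxonomy = search$taxonomy)
  genus_tab <- aggregate_taxa(otu_tab, "genus")
  phylum_tab <- aggregate_taxa(otu_tab, "phylum")
  tick("cluster")

  div <- sample_diversity(otu_tab)
  groups <- metadata$group[match(div$sample_id, metadata$sample_id)]
  div_sum <- diversity_group_summary(div, groups)
  tick("diversity")

  reps <- setNames(attr(otu_tab, "representatives")$representative_sequence,
                   attr(otu_tab, "representatives")$otu_id)
  tree <- build_tree(reps)
  uf_w <- unifrac(tree, otu_tab, weighted = TRUE, normalized = TRUE)
  uf_u <- unifrac(tree, otu_tab, weighted = FALSE)
  ord <- pcoa(uf_w, axes = 3)
  dendro <- upgma_dendrogram(uf_w)
  sample_groups <- metadata$group[match(colnames(uf_w), metadata$sample_id)]
  dist_tests <- rbind(
    cbind(contrast = "HC_vs_IBD",
          distance_group_test(uf_w, ifelse(sample_groups == "HC", "HC", "IBD"))),
    cbind(contrast = "all_groups", distance_group_test(uf_w, sample_groups)))
  tick("beta")

  genus_rel <- relative_abundance(genus_tab)
  taxon_tests <- do.call(rbind, lapply(
    list(c("CD", "HC"), c("UC", "HC"), c("CD", "UC")),
    function(gg) {
      if (!all(gg %in% sample_groups)) return(NULL)
      cbind(contrast = paste(gg, collapse = "_vs_"),
            taxon_group_tests(genus_rel, sample_groups, gg[1], gg[2],
                              mode = "welch"))
    }))
  tick("stats")

  correlations <- NULL
  if (!is.null(biomarkers))
    correlations <- pearson_matrix(genus_rel, biomarkers)
  qpcr_res <- NULL
  if (!is.null(qpcr)) {
    tax <- attr(otu_tab, "taxonomy")
    targets <- setdiff(colnames(qpcr), c("sample_id", "group"))
    targets <- intersect(targets, unique(tax$species))
    qpcr_res <- do.call(rbind, lapply(targets, function(sp) {
      otus <- tax$otu_id[!is.na(tax$species) & tax$species == sp]
      counts <- colSums(unclass(otu_tab)[rownames(otu_tab) %in% otus, ,
                                         drop = FALSE])
      ids <- intersect(names(counts), qpcr$sample_id)
      r <- qpcr_concordance(counts[ids],
                            qpcr[[sp]][match(ids, qpcr$sample_id)])
      data.frame(species = sp, n = length(ids), r = r,
                 stringsAsFactors = FALSE)
    }))
  }
  tick("correlations")

  counts <- c(setNames(qc$report$count, qc$report$stage),
              chimera_removed = search$chimera_removed,
              no_hit_removed = search$no_hit_removed,
              clean = nrow(search$reads),
              rarefied = nrow(rare),
              n_samples = ncol(otu_tab),
              n_otus = nrow(otu_tab))
  manifest <- list(counts = counts, parameters = unclass(config),
                   seed = config$seed, timings = unlist(timings),
                   excluded_samples = attr(rare, "excluded_samples"))

  out <- list(qc_report = qc$report,
              search = list(chimera_removed = search$chimera_removed,
                            no_hit_removed = search$no_hit_removed,
                            status = search$status,
                            read_id = qc$reads$read_id),
              otu_table = otu_tab, genus_table = genus_tab,
              phylum_table = phylum_tab,
              diversity = div, diversity_summary = div_sum,
              tree = tree, unifrac_weighted = uf_w, unifrac_unweighted = uf_u,
              pcoa = ord, dendrogram = dendro,
              distance_tests = dist_tests, taxon_tests = taxon_tests,
              correlations = correlations, qpcr_concordance = qpcr_res,
              manifest = manifest)
  if (!is.null(outdir)) .write_pipeline_outputs(out, outdir, config$seed)
  out
}

.write_pipeline_outputs <- function(res, outdir, seed) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) write_tsv(df, file.path(outdir, name), seed = seed)
  w(res$qc_report, "qc_report.tsv")
  otu_df <- data.frame(otu_id = rownames(res$otu_table),
                       attr(res$otu_table, "taxonomy")[, -1, drop = FALSE],
                       unclass(res$otu_table), check.names = FALSE)
  w(otu_df, "otu_table.tsv")
  w(data.frame(genus = rownames(res$genus_table), res$genus_table,
               check.names = FALSE), "genus_table.tsv")
  w(res$diversity, "diversity.tsv")
  w(res$diversity_summary, "diversity_summary.tsv")
  w(data.frame(sample_id = rownames(res$unifrac_weighted),
               res$unifrac_weighted, check.names = FALSE),
    "unifrac_weighted.tsv")
  w(data.frame(sample_id = rownames(res$pcoa$coordinates),
               res$pcoa$coordinates, check.names = FALSE),
    "pcoa_coordinates.tsv")
  w(res$taxon_tests, "taxon_tests.tsv")
  if (!is.null(res$correlations)) w(res$correlations, "correlations.tsv")
  if (!is.null(res$qpcr_concordance))
    w(res$qpcr_concordance, "qpcr_concordance.tsv")
  reps <- attr(res$otu_table, "representatives")
  write_fasta(setNames(reps$representative_sequence, reps$otu_id),
              file.path(outdir, "otu_representatives.fasta"))
  ape::write.tree(res$tree, file.path(outdir, "otu_tree.nwk"))
  ape::write.tree(res$dendrogram, file.path(outdir, "sample_dendrogram.nwk"))
  invisible(outdir)
}

#' Fisher-z confidence interval for a correlation
#' @param r target correlation.
#' @param n sample size.
#' @param level confidence level (default 0.95).
#' @return c(lower, upper).
#' @export
fisher_z_interval <- function(r, n, level = 0.95) {
  z <- atanh(r)
  half <- qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(c(z - half, z + half))
}

#' Simulate a study and evaluate recovery against ground truth
#'
#' Generates a complete synthetic study, runs the pipeline on it, and compares
#' recovered quantities with the generator's truth: genus relative abundances,
#' chimera calls (recall/precision), OTU count vs species count, configured
#' fold-change directions (with BH-adjusted significance), anchored biomarker
#' correlations (Fisher-z interval check), and qPCR concordance.
#'
#' @param study_cfg a [study_config()].
#' @param pipe_cfg a [pipeline_config()] (its seed defaults to the study's).
#' @param outdir optional output directory passed to [run_pipeline()].
#' @return list: `pipeline` (full [run_pipeline()] result), `genus_recovery`,
#'   `chimera_eval`, `otu_count`, `effect_eval`, `biomarker_eval`,
#'   `qpcr_concordance`.
#' @export
simulate_and_run <- function(study_cfg = study_config(),
                             pipe_cfg = pipeline_config(seed = study_cfg$seed),
                             outdir = NULL) {
  study <- generate_study(study_cfg)
  res <- run_pipeline(study$reads, study$barcodes, study$db, study$metadata,
                      fwd_primer = study_cfg$fwd_primer,
                      rev_primer = study_cfg$rev_primer,
                      biomarkers = study$biomarkers, qpcr = study$qpcr,
                      config = pipe_cfg, outdir = outdir)

  # genus abundance recovery (percentage points), retained samples only
  truth <- true_genus_props(study$profiles, study$db)
  rec <- relative_abundance(res$genus_table)
  ids <- intersect(colnames(truth), colnames(rec))
  genera <- rownames(truth)
  err <- vapply(genera, function(g) {
    r <- if (g %in% rownames(rec)) rec[g, ids] else rep(0, length(ids))
    mean(abs(r - truth[g, ids])) * 100
  }, 0)
  genus_recovery <- data.frame(genus = genera,
                               true_mean_pct = rowMeans(truth[, ids]) * 100,
                               recovered_mean_pct = vapply(genera, function(g)
                                 if (g %in% rownames(rec))
                                   mean(rec[g, ids]) * 100 else 0, 0),
                               mean_abs_err_pct = err,
                               stringsAsFactors = FALSE)

  # chimera confusion among QC-passed reads
  man <- study$manifest[match(res$search$read_id, study$manifest$read_id), ]
  flagged <- res$search$status == "chimera"
  truechi <- man$is_chimera
  chimera_eval <- data.frame(
    n_true = sum(truechi), n_flagged = sum(flagged),
    recall = if (sum(truechi)) sum(flagged & truechi) / sum(truechi) else NA,
    precision = if (sum(flagged)) sum(flagged & truechi) / sum(flagged) else NA)

  # configured effect directions, HC vs each IBD group
  eff <- study_cfg$effect_sizes
  effect_eval <- do.call(rbind, lapply(c("CD", "UC"), function(g) {
    tt <- res$taxon_tests[res$taxon_tests$contrast ==
                            paste0(g, "_vs_HC"), , drop = FALSE]
    i <- match(names(eff), tt$taxon)
    data.frame(group = g, genus = names(eff), fold = unname(eff),
               expected = ifelse(eff > 1, "higher_in_g1", "higher_in_g2"),
               observed = tt$direction[i], q_value = tt$q_value[i],
               recovered = tt$direction[i] ==
                 ifelse(eff > 1, "higher_in_g1", "higher_in_g2") &
                 tt$q_value[i] < 0.05,
               stringsAsFactors = FALSE)
  }))

  # anchored biomarker correlations within Fisher-z intervals
  biomarker_eval <- NULL
  if (!is.null(res$correlations)) {
    map <- study_cfg$biomarker_map
    biomarker_eval <- do.call(rbind, lapply(seq_len(nrow(map)), function(i) {
      row <- res$correlations[res$correlations$genus == map$genus[i] &
                                res$correlations$biomarker == map$biomarker[i], ]
      ci <- fisher_z_interval(map$r[i], row$n[1])
      data.frame(biomarker = map$biomarker[i], genus = map$genus[i],
                 target_r = map$r[i], recovered_r = row$r[1], n = row$n[1],
                 ci_lo = ci[1], ci_hi = ci[2],
                 within_ci = row$r[1] >= ci[1] & row$r[1] <= ci[2],
                 stringsAsFactors = FALSE)
    }))
  }

  list(pipeline = res, genus_recovery = genus_recovery,
       chimera_eval = chimera_eval,
       otu_count = nrow(res$otu_table), n_species = nrow(study$db),
       effect_eval = effect_eval, biomarker_eval = biomarker_eval,
       qpcr_concordance = res$qpcr_concordance)
}
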