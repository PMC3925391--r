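---
title: "Methods: quality-sorted OTU analysis of 16S V1-V2 pyrosequencing surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quality-sorted OTU analysis of 16S V1-V2 pyrosequencing surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis

`amplipipe` implements a complete analysis chain for barcoded 454-style
16S rRNA V1--V2 amplicon surveys of the kind used to compare salivary
microbiota between healthy controls (HC) and inflammatory-bowel-disease
groups (Crohn's disease, CD; ulcerative colitis, UC):

1. **Read QC** -- exact-barcode demultiplexing; a primer-presence check
   requiring the forward primer at the 5' end and the reverse-complemented
   reverse primer at the 3' end (each within 2 substitutions), with the
   exception that reads longer than 400 bp are kept even without primers,
   because a few taxa carry V1--V2 regions longer than the usual 431 bp
   maximum and would otherwise be discarded; removal of reads with mean
   Phred quality below 25 (a mean of exactly 25 passes -- the rule is a
   strict `< 25`).
2. **Reference search** -- every read is compared against a 16S reference
   database by shared 8-mer candidate ranking followed by banded local
   alignment. Reads whose best hit covers less than 90% of the read are
   removed as chimeras (a spliced read matches each parent over roughly its
   breakpoint fraction only); best-hit identity assigns taxonomy at
   species (>= 97%), genus (>= 95%), or phylum (>= 80%) rank.
3. **Rarefaction and clustering** -- each sample is subsampled to 3000
   filter-passed reads without replacement (samples below depth are
   excluded, never resampled); the pooled reads are sorted by mean quality
   and clustered greedily at 96% identity, so every OTU's representative is
   its highest-quality member -- the property that motivates quality
   sorting, since representatives drive taxonomy.
4. **Diversity** -- per-sample Shannon, Simpson, inverse Simpson, Pielou
   evenness, Chao1, ACE and Fisher's alpha; group summaries as
   mean &plusmn; s.e.m.
5. **Beta diversity** -- a neighbor-joining tree over OTU representatives
   (distance `1 - identity`, midpoint-rooted), weighted and unweighted
   UniFrac, principal-coordinates analysis, and a UPGMA sample dendrogram.
6. **Statistics** -- Welch tests per genus with Benjamini--Hochberg
   correction across genera; normality-dependent Student-t/Mann--Whitney
   for general two-group comparisons; Pearson correlations between genus
   relative abundances and total-protein-normalized biomarkers with BH
   adjustment across all cells; ordinary least squares as the regression
   counterpart; and qPCR concordance as Pearson r on inverse-hyperbolic-
   sine-transformed read counts and copy numbers (asinh is log-like but
   defined at zero, which read counts and copy numbers regularly hit).

All stages are driven by `pipeline_config()` (depth 3000, identity 0.96,
QV threshold 25, chimera coverage 0.90, length exception 400 nt, genus
identity 0.95) and a single seed; identical inputs and seed give
byte-identical outputs.

## Alignment engine

The aligner is a banded Smith--Waterman with affine gaps (match +1,
mismatch -2, gap open -5 for the first gapped base, -2 per extension;
band `16 + |length difference|`, all configurable). Three quantities are
reported per alignment:

* `identity` -- matching columns over aligned columns, gap columns counted
  as mismatches, terminal gaps excluded;
* `coverage` -- aligned query span over query length;
* `identity_global` -- matches over `max(aligned columns, min(sequence
  lengths))`.

A *local* aligner was chosen deliberately: the chimera rule keys on the
best hit covering `< 90%` of the read, which requires an alignment that can
stop at the splice point. A query-global alignment would always cover 100%
of the read and the rule could never fire. The flip side of local
alignment is that two unrelated sequences sharing one short exact word
align with `identity = 1` over a tiny span; `identity_global` exists to
close that loophole and is the criterion used for OTU joins and for tree
distances. Because `identity_global <= identity`, every OTU member still
satisfies the documented `identity >= 0.96` invariant against its
representative. Candidate order is by shared distinct 8-mers; ties break
deterministically by (score, database order), and clustering stops probing
after 32 rejected candidates (a reject cap in the style of greedy
clustering tools; the exact heuristics of those tools are not reproduced).

Banding assumes bounded indel counts, which holds for amplicon data where
homopolymer indels are rare; the band widens automatically with the length
difference of the pair. The banded result is tested to equal the
exhaustive alignment, and scores are cross-checked against
`Biostrings::pairwiseAlignment(type = "local")` with the equivalent gap
parameterization.

## The synthetic-study generator

The generator produces complete studies with known truth, sized like the
survey the pipeline targets: 24 HC / 21 CD / 14 UC subjects, 5000 reads
per sample, and a 14-genus, 42-species oral reference panel dominated by a
*Streptococcus*-like genus.

* **Reference database.** Genus ancestors are independent random sequences
  of 300--431 nt (between-genus identity far below the 92% separation
  floor); species diverge 2.5--4% from their ancestor at randomly placed
  substitutions, so congeneric species sit ~5--8% apart -- separable at the
  96% OTU threshold and assignable at the 95% genus threshold. A literal
  2--4% *pairwise* species spacing would straddle the 96% cutoff and make
  species-level OTU recovery ill-posed, which is why divergence is defined
  from the ancestor. One record is extended to 493 nt to exercise the
  long-read primer-check exception.
* **Profiles.** Per-sample genus proportions are Dirichlet draws
  (concentration 200) around the baseline; CD/UC samples multiply six key
  genera by configured fold changes (*Prevotella* 2.5, *Veillonella* 2.0 up;
  *Streptococcus* 0.6, *Haemophilus* 0.45, *Neisseria* 0.5, *Gemella* 0.5
  down) and renormalize. Species weights within a genus are fixed per study
  so genus-level statistics are not diluted by species churn.
* **Reads.** `barcode + forward primer + template + revcomp(reverse
  primer)`, with per-base substitutions (0.2%) and homopolymer indels
  (0.05%) in the template. A 0.46% fraction are two-parent chimeras with a
  breakpoint uniform in the middle 60% of the template; parents are drawn
  from *different genera*, since a splice of two congeneric templates
  aligns full-length to either parent at ~97% identity and is invisible to
  any match-length criterion -- the generator only constructs chimeras the
  rule is defined to detect. Per-read mean quality comes from a
  two-component mixture, good ~ N(33, 2) and low ~ N(19, 2) with mixing
  weight 0.0075; the components are placed so that essentially all and only
  the low-component reads fall under the QV 25 threshold, making the
  removal fraction equal the configured rate. Per-base values jitter
  around the read mean (sd 2, clamped to [2, 40]).
* **Biomarkers.** Each of eight salivary markers (lysozyme, IgA, LL-37,
  IL-1b, IL-6, IL-8, TNF-a, MCP-1) is anchored to one genus at a target
  Pearson correlation on the total-protein-normalized scale (e.g.
  lysozyme ~ *Streptococcus* at 0.63, IL-1b ~ *Prevotella* at 0.58,
  LL-37 ~ *Haemophilus* at -0.54); 39 of the 59 subjects carry
  measurements (15/14/10 by group). One marker cannot be pinned to several
  compositionally correlated genera at once, so secondary correlations are
  emergent, not targets. The residual noise is orthogonalized against the
  anchor abundance, making the *sample* correlation with the true abundance
  exactly the target; recovered correlations then deviate only through
  pipeline measurement error, which is what the Fisher-z recovery checks
  are meant to measure.
* **qPCR.** Copy number = `1e4 x true species proportion x lognormal
  noise` for *P. melaninogenica*- and *H. parainfluenzae*-like species;
  absent species give exactly 0. The default noise (sdlog 0.3) was
  calibrated by simulation so the asinh-scale concordance with read counts
  sits around 0.8--0.9, the strength regime such validation experiments
  report; at sdlog 0.5 the simulated envelope is roughly 0.5--0.8.

What the generator does *not* emulate: flowgram-level 454 noise and
quality-error coupling (quality values are independent of the planted
errors), PCR amplification bias, barcode/primer synthesis errors (errors
are confined to the template, so the primer-check pass rate is ~100%
rather than the ~60% raw-run assignment rates seen in practice),
medication or disease-activity substructure, and real phylogenetic
sequence structure (random ancestors have no conserved/variable site
architecture). Passing tests therefore demonstrate the pipeline's
correctness and calibration under controlled truth, not its behaviour on
raw instrument output.

## Numerical choices

* **Estimator variants are pinned.** Chao1 is the bias-corrected form
  `S + F1(F1-1) / (2(F2+1))` (the classic `S + F1^2/(2F2)` is available by
  switch but undefined without doubletons). ACE uses rare cutoff 10 and
  falls back to Chao1 when the rare group is empty or coverage is zero.
  Fisher's alpha solves `S = alpha ln(1 + N/alpha)` by bisection on
  (1e-8, 1e8) to a residual below 1e-10; it is undefined when every taxon
  is a singleton. All logarithms are natural. Pielou is `NA` for a single
  observed taxon. Estimates are cross-checked in the tests against
  brute-force formula evaluation and against vegan.
* **UniFrac.** Branch proportions are accumulated in one postorder pass;
  the weighted metric defaults to the normalized variant (divide by
  `sum(depth_leaf * (pA + pB))`), which ranges 0--1. Proportions come from
  the rarefied OTU table. The unweighted denominator is the branch length
  spanned by either presence set; branches absent from both samples
  contribute to neither term.
* **PCoA.** Gower double-centering and symmetric eigendecomposition;
  negative eigenvalues are reported but excluded from variance fractions.
* **Trees.** Neighbor-joining on `1 - identity_global`, negative branch
  lengths clamped to zero, midpoint rooting, leaf order normalized before
  distance computation so the tree is a deterministic function of the set.
  The tree method is this package's choice -- the survey design it mirrors
  does not pin one -- and is the main reason ordination variance fractions
  are not exactly reproducible study-to-study.
* **Tests.** `compare_groups(mode = "auto")` runs Shapiro--Wilk per group
  at alpha 0.05 and uses Student's t only when both groups pass, otherwise
  Mann--Whitney with normal approximation and tie correction; `welch` is
  forced for the genus-table contrasts. Two identical constant groups
  return p = 1 explicitly rather than erroring. BH adjustment is the
  standard step-up procedure (`p.adjust(method = "BH")`), verified against
  a stepwise-min oracle. The UniFrac group comparison treats pairwise
  distances as observations with Student's t; pairs sharing a sample are
  not independent, so those p-values are descriptive rather than exact --
  a documented caveat of this convention.
* **Degenerate inputs.** Empty abundance vectors, empty quality strings,
  primers longer than the read, samples below rarefaction depth,
  zero-variance correlation inputs and no-hit reads all take explicit,
  tested paths (error, exclusion-with-warning, or flagged NA as
  appropriate).

## Problem sizes

The test suite runs the full default study (59 samples x 5000 reads,
~295k reads end-to-end; about two minutes on one core) once in its
acceptance block, and smaller seven-sample studies (120--300 reads/sample)
elsewhere; estimator and UniFrac oracles sweep 1000 random abundance
vectors and 100 random trees of up to 8 leaves. `scripts/acceptance.R`
re-runs the full default study from scratch at the seed the caller
provides.

## Limitations

* The primer-check pass rate on synthetic data is near 100% because
  errors are confined to inserts; the stage's removal accounting is
  exercised by construction rather than by realistic failure rates.
* Species-level richness estimators saturate on the 42-species synthetic
  panel (Chao1 ~ observed richness); richness *estimation* behaviour on
  long-tailed real communities is exercised only via the random-vector
  oracles.
* Chimera detection by match length is blind to splices of closely
  related parents; the generator honestly restricts itself to detectable
  (cross-genus) chimeras, and real data would contain the other kind.
* UniFrac distance group tests inherit the non-independence caveat above;
  no permutation test is provided because the analysis chain this package
  reproduces does not use one.
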