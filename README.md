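# amplipipe

Quality-sorted OTU analysis of barcoded 16S rRNA V1–V2 pyrosequencing
surveys, built for case–control microbiome studies (e.g. salivary
microbiota of inflammatory-bowel-disease patients vs healthy controls)
where composition shifts must be tied to clinical biomarkers.

The package implements the full analysis chain as testable R functions:

* **Read QC** — exact-barcode demultiplexing, a primer-presence check with
  a long-read (> 400 bp) exception, and removal of reads with mean Phred
  quality `< 25`.
* **Reference search** — shared *k*-mer candidate ranking plus banded
  local alignment (affine gaps, compiled in C++); reads whose best hit
  covers `< 90%` of the read are removed as chimeras; best-hit identity
  assigns taxonomy at species (≥ 97%), genus (≥ 95%) or phylum (≥ 80%)
  rank.
* **OTU clustering** — rarefaction to 3000 reads/sample, pooling, sorting
  by mean quality, and greedy clustering at 96% identity so each OTU's
  representative is its highest-quality member.
* **Diversity** — Shannon (natural log), Simpson `1 − Σp²`, inverse
  Simpson `1/Σp²`, Pielou `H/ln S`, bias-corrected Chao1
  `S + F₁(F₁−1)/(2(F₂+1))`, ACE (rare cutoff 10), and Fisher's alpha
  solving `S = α ln(1 + N/α)`.
* **Beta diversity** — neighbor-joining tree over OTU representatives,
  weighted UniFrac `Σ l_b |p_b^A − p_b^B|` (normalized to [0, 1]) and
  unweighted UniFrac, PCoA by Gower double-centering, UPGMA dendrogram.
* **Statistics** — Welch/Student/Mann–Whitney group contrasts with
  Benjamini–Hochberg correction, Pearson correlation of genus abundances
  against total-protein-normalized biomarkers, OLS regression, and qPCR
  concordance on inverse-hyperbolic-sine-transformed counts.
* **Synthetic-data generator** — seeded studies (reference database,
  community profiles, error- and chimera-bearing reads, biomarker and qPCR
  panels) with ground-truth manifests, so every stage is testable without
  external data.

See `vignettes/amplipipe-methods.Rmd` for the model, parameter and
numerical-design details.

## Worked example

Simulate the default study (59 samples: 24 HC / 21 CD / 14 UC; 5000 reads
per sample) and run the full pipeline on it:

```r
library(amplipipe)
rep <- simulate_and_run(study_config(seed = 1), pipeline_config(seed = 1))

rep$chimera_eval
#>   n_true n_flagged recall precision
#> 1   1334      1334      1         1

rep$otu_count
#> [1] 44            # 42 species in the generated database

head(rep$genus_recovery[order(-rep$genus_recovery$true_mean_pct), ], 3)
#>                       genus true_mean_pct recovered_mean_pct mean_abs_err_pct
#> Streptococcus Streptococcus     26.058825          25.867797        0.7164757
#> Prevotella       Prevotella     18.656531          18.648023        0.5437655
#> Veillonella     Veillonella      9.389099           9.436158        0.4056143

subset(rep$effect_eval, group == "CD")[, c("genus", "fold", "observed", "q_value")]
#>             genus fold     observed      q_value
#>        Prevotella 2.50 higher_in_g1 1.305873e-16
#>       Veillonella 2.00 higher_in_g1 3.257751e-05
#>     Streptococcus 0.60 higher_in_g2 2.890910e-15
#>       Haemophilus 0.45 higher_in_g2 1.775653e-09
#>         Neisseria 0.50 higher_in_g2 1.794519e-08
#>           Gemella 0.50 higher_in_g2 1.231612e-05

rep$biomarker_eval[1:2, c("biomarker", "genus", "target_r", "recovered_r")]
#>   biomarker         genus target_r recovered_r
#> 1  lysozyme Streptococcus     0.63   0.5939676
#> 2      IL1b    Prevotella     0.58   0.5771095

rep$qpcr_concordance
#>                      species  n         r
#> 1  Prevotella melaninogenica 59 0.8650416
#> 2 Haemophilus parainfluenzae 59 0.7527479
```

Reading: every planted chimera was caught with no false positives; the 42
reference species cluster into 44 OTUs at 96% identity; genus relative
abundances are recovered within a fraction of a percentage point; all six
configured group effects are significant after BH adjustment in the
expected direction; the biomarker correlations and qPCR concordance
recover the values the generator planted.

Real data enter through `read_fastq()`, a reference FASTA + lineage table,
and `run_pipeline()`; `inst/scripts/amplipipe.R` is a thin command-line
wrapper over the same functions.

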