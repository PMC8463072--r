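# tmtRuler

Absolute, per-cell protein copy numbers from multiplexed TMT SPS-MS3
proteomics — and the comparative analysis built on top of them.

## The problem

Isobaric-label (TMT) experiments quantify thousands of proteins across many
samples in one run, but reporter intensities are relative. For questions
like "how many granzyme molecules does a tissue-resident T cell carry
compared with a naive one?", intensities must be converted to an absolute
scale. The **histone proteomic ruler** does this without spike-ins: every
cell carries a known DNA mass, histone mass closely tracks DNA mass, so the
summed histone MS signal is an internal standard present in every sample.

`tmtRuler` implements the full pipeline for MaxQuant-style protein-group
tables from SPS-MS3 TMT designs (the motivating application is profiling
intestinal intraepithelial T-cell subsets against lymph-node CD8 T cells):

1. **Parse and filter** `proteinGroups.txt`-dialect tables (contaminant /
   reverse / only-by-site flags, < 2 razor + unique peptides).
2. **Allocate** each group's summed MS1 intensity across channels by its
   fractional MS3 reporter intensities:
   `I_pk = I_p · r_pk / Σ_j r_pj`.
3. **Copy numbers** via the ruler: for protein *p*, sample *s*,

   ```
   copies[p,s] = (I[p,s] / MW_p) · (m_DNA · N_A) / Σ_histones I[h,s]
   ```

   with `m_DNA = 5.52 pg` (diploid mouse) by default, and per-cell
   **protein content** `Σ_p copies · MW / N_A` in pg.
4. **Replicate QC**: flag replicates whose content deviates ≥ 15% from the
   leave-one-out median of their population.
5. **Differential expression**: empirical-Bayes moderated t-statistics
   (prior fitted by moment matching on log variances), Storey q-values,
   and the fold-change-distribution significance classes
   (`**`: p < 1e-3 and |log2fc − median| ≥ 1 sd;
   `***`: p < 1e-4 and ≥ 1.5 sd), with proteins detected in only one
   population reported as *exclusive* rather than as fold changes.
6. **Overrepresentation** of up/down candidate sets (p < 1e-3,
   |log2fc − median| ≥ 1.5 sd, unioned with exclusives) against
   user-supplied GMT collections, hypergeometric upper tail, background =
   proteins identified in either contrast population, BH FDR.
7. **Landscape summaries**: sample PCA, pairwise population Pearson
   correlations on log10 median copies, top-50%-of-proteome mass-fraction
   categories, and gene-set copy sums with Welch tests.

A first-class **synthetic-data generator** emulates the study design
(5 populations, 24 channels, ~8000 proteins, histone anchors, planted
fold-change categories, decoy rows, population-specific absence,
multiplicative reporter noise) with exact ground truth, so every stage is
testable without any deposited raw data.

## Worked example

```r
library(tmtRuler)

cfg <- SyntheticConfig(nProteins = 2000, nHistones = 20,
                       populations = c(LN_WT = 4L, IEL_ab = 4L),
                       reporterCV = 0.10,
                       plantedEffects = list(
                           list(name = "effector", members = 60,
                                populations = "IEL_ab", log2fc = 2)),
                       seed = 1)
fx  <- simulateFixture(cfg, "demo_fixture")
res <- runPipeline(fx$paths["protein_groups"], fx$paths["channel_design"],
                   "demo_out", contrasts = list(c("IEL_ab", "LN_WT")))

res$cne
#> class: CopyNumberExperiment
#> dim: 2000 8
#> assays(1): copies
#> rowData names(4): group_id gene_name mol_weight_da is_histone
#> colnames(8): LN_WT_1 LN_WT_2 ... IEL_ab_3 IEL_ab_4
#> dnaMassPg: 5.52 pg; 20 histone anchor rows

res$content$populations
#>   population  mean_pg    sd_pg n
#> 1     IEL_ab 569.3132 13.37735 4
#> 2      LN_WT 521.7372 11.03358 4

de <- res$differential$IEL_ab_vs_LN_WT
shared <- de[de$exclusive == "none", ]
head(as.data.frame(shared[order(shared$p_value),
     c("gene_name", "log2fc", "t", "p_value", "q_value", "star")]), 5)
#>         gene_name log2fc     t   p_value   q_value star
#> PG00129 Gene00109  2.173 22.65 1.159e-25 2.086e-24  ***
#> PG00536 Gene00516  2.198 22.61 1.243e-25 2.216e-24  ***
#> PG01090 Gene01070  2.201 22.53 1.444e-25 2.548e-24  ***
#> PG00696 Gene00676  2.138 22.16 2.779e-25 4.858e-24  ***
#> PG01409 Gene01389  2.047 21.47 9.855e-25 1.706e-23  ***

round(res$pca$varianceFraction[1:3], 3)
#>   PC1   PC2   PC3
#> 0.679 0.064 0.055
```

Reading the output: copy numbers for the 60 planted 4-fold-up proteins come
back with `log2fc ≈ 2` and `***` stars; the fold-change distribution of the
contrast (median ≈ 0, sd ≈ 0.36) sets the star thresholds; PC1 carries the
planted population separation (68% of variance here); the IEL population's
content is higher because the planted effect adds protein mass. Proteins
simulated as absent in one population appear in `de$exclusive`
(`a_only` / `b_only`), not as infinite fold changes. Every stage also
writes a TSV into `demo_out/`, with run metadata in `run_metadata.json`.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/tmt-ruler.R` (`simulate` and `run` subcommands).

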