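# thprof

Tissue expression profiling of CD4+ T helper (Th) subset regulators.

Human tissues differ in which Th lineages (Th1, Th2, Th9, Tfh, Th17,
Treg, Th22, Th25) they can host or suppress, and that difference is
visible in how strongly each lineage's regulators — master transcription
factors, cytokines, receptors — are transcribed per tissue. `thprof` is a
tidyverse-native toolkit for mining such gene-by-tissue transcript tables
and for classifying how knockouts or diseases shift regulator expression.
It is aimed at immunologists doing database-mining analyses of Th-subset
and Treg-plasticity biology.

## What it computes

**Trichotomous expression calling.** For gene *g* in tissue *t*, TPM
values are normalized to beta-actin arbitrary units,
AU(g,t) = TPM(g,t) / TPM(ACTB,t). A significance band is the mean + 2·SD
of the AU values of a fixed three-gene housekeeping panel. Each cell is
then called:

- `-` not expressed, when TPM < 1 (one transcript per million is the
  technical floor);
- `++` highly expressed, when AU exceeds the housekeeping band;
- `+` low expressed, otherwise.

**Subset aggregation.** Calls are joined to a packaged catalog of 61
Th-subset regulators (multi-lineage genes count toward every lineage they
carry) to yield per-tissue subset summaries, a "tissue pyramid" ranking
tissues by the variety of subsets with highly expressed regulators,
dominance scores, and immune-privilege flags for tissues with no high
calls at all.

**Differential regulation.** Case-vs-control replicate matrices get the
signed fold-change convention SFC = r if r ≥ 1 else −1/r (so −1.28 means
1.28-fold down), a Welch t-test, and an UP / DOWN / UNCHANGED call at
fc_min = 1.2, alpha = 0.05 by default — significant sub-2-fold shifts of
master regulators count. `geneset_regulation_counts()` tallies the calls
over panels such as the 14 mouse MHC class II genes.

**Exact Venn partitions** of 2–8 regulated gene/pathway sets, with
shared-vs-specific splits per focus set.

**Seeded simulators** generate synthetic tissue panels (negative-binomial
counts, planted high / silent genes) and case/control matrices (planted
fold effects) together with truth tables, so the whole pipeline is
testable with no database access.

## Worked example

The packaged call matrix is a transcription of a printed 32-tissue atlas
of the 61-regulator panel (see `thprof_example("CHANGELOG.md")` for
transcription notes).

```r
library(thprof)
library(dplyr)

calls <- read_call_matrix(thprof_example("tissue_calls_human.tsv"))
count_expression(calls, c("GATA3", "SPI1", "RORC", "STAT3"))
#> # A tibble: 4 × 3
#>   gene  n_expressed n_high
#>   <chr>       <int>  <int>
#> 1 GATA3          21      3
#> 2 SPI1           16     11
#> 3 RORC           18      7
#> 4 STAT3          31      2
```

The Th2 factor GATA3 is expressed in 21 of the 32 tissues, the Th9
factor SPI1 in 16 (11 of them at high level), the Th17 factor RORC in 18,
and the Th22 regulator STAT3 in 31.

```r
s <- summarize_subsets(calls, load_regulator_catalog("human"))
head(tissue_pyramid(s), 4)
#> # A tibble: 4 × 3
#>   tissue     n_subsets_high n_subsets_expressed
#>   <chr>               <int>               <int>
#> 1 Muscle                  7                   7
#> 2 Trachea                 7                   7
#> 3 Blood                   6                   7
#> 4 Lymph node              6                   7
```

Muscle, trachea, blood and lymph node top the tissue pyramid: they hold
highly expressed regulators from the widest variety of Th subsets.

```r
diff <- load_signed_table(thprof_example("mhc2_diff_mouse.tsv"))
geneset_regulation_counts(diff, load_gene_set("mhc2_mouse"))[, 1:6]
#> # A tibble: 3 × 6
#>   set        contrast  n_up n_down n_unchanged n_unmeasured
#>   <chr>      <chr>    <int>  <int>       <int>        <int>
#> 1 mhc2_mouse Gata3_KO     7      0           7            0
#> 2 mhc2_mouse Bcl6_KO      5      1           8            0
#> 3 mhc2_mouse Hdac6_KO     0      5           9            0
```

Seven of the 14 MHC class II genes are up in Gata3-knockout Treg and five
in Bcl6-knockout Treg, while five are down in Hdac6-knockout Treg —
GATA3 and BCL6 restrain, and HDAC6 promotes, the conversion of plastic
Treg toward an antigen-presenting-cell-like state.

Every result type has `autoplot()` (call heatmap, pyramid, volcano, Venn
region bars) plus `tidy()`/`glance()` methods.

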