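# tilescan

Analysis of CRISPR–Cas9 **tiling proliferation screens**: pooled screens
in which sgRNAs saturate a gene's coding sequence (one cut site every
~14 nt wherever an NGG PAM allows) so that guide dropout maps *which
parts of a protein* are required for cell proliferation, not just which
genes.

The package is written for functional genomicists analysing such screens:
it covers library design from CDS FASTA, count normalization and
Z-scoring, gene-level essentiality calls, deconvolution of per-gene
depletion profiles into essential regions, region annotation
(domains/literature/disorder, conservation), and a synthetic-screen
generator with ground truth for benchmarking and robustness analysis.

## The model

Cas9 cuts are repaired by error-prone end joining; ~80% of scars shift
the reading frame. With in-frame repair probability *p* = 0.2 per allele
and two alleles edited independently, a targeted diploid population
splits into

* (1 − p)² = **64%** of cells with biallelic frameshifts — these die
  wherever an *essential gene* is cut, and
* 1 − (1 − p)² = **36%** with at least one in-frame but locally
  mutagenized allele — these die only when the cut falls in an
  *essential region* of the protein.

Per-guide depletion along the CDS is therefore a step function; deep
steps mark essential regions. The deconvolution estimator is a **convex
fused lasso**: the fused-lasso objective

½‖y − x‖² + λ₀‖x‖₁ + λ₁ Σᵢ |xᵢ − xᵢ₋₁|

with both penalties passed through the saturating concave transform
f(t, a) = (1 − e^(−a·t))/a, which stops the ℓ₁ penalties from
over-shrinking the broad, deep blocks that functional domains produce.
Convexity (hence a global optimum) is guaranteed by the gate
**1 − a₀λ₀ − 4a₁λ₁ ≥ 0**, which the package enforces before fitting. The
solver is majorize–minimize over exactly solved weighted fused-lasso
subproblems (dynamic programming in C++), with the plain fused lasso
retained as the sharp-boundary baseline method.

## Worked example

Simulate the reference screen (40 genes, 6,365 guides including 601
nontargeting controls, 4 cell lines × 3 replicates, two planted
essential regions in each of the 30 frameshift-lethal genes), then run
the full analysis:

```r
library(tilescan)
library(dplyr)

genotype_fractions(p_inframe = 0.2, ploidy = 2)
#>   p_inframe ploidy all_frameshift at_least_one_inframe
#> 1       0.2      2           0.64                 0.36

sim    <- simulate_screen(sim_config(), seed = 0)
scores <- score_guides(sim$counts, sim$library)      # logFC -> median -> Z
mz     <- guide_mean_z(scores)                       # mean Z across lines
mzf    <- filter_guides(mz, sim$library)             # drop TTTT / Y-rich

fits    <- fit_profiles(mzf, sim$library, solver_config())
regions <- call_regions(fits, tau = 1,
                        ntc_sd = sd(mz$mean_z[mz$gene == "NTC"]))
head(regions, 3)
#>   gene  aa_start aa_end  score n_guides method
#> 1 G01        271    402 -0.389       19 tivex
#> 2 G02          5    972 -0.407      144 tivex
#> 3 G03          2    420 -0.518       63 tivex

precision_recall(regions, sim$truth$regions)
#>   precision recall n_called n_true precision_defined
#> 1     0.970   0.95       33     60 TRUE
```

The region table gives 1-based inclusive amino-acid intervals, the mean
fitted depletion over the region (Z units; more negative = stronger
dropout), and the guide support. Precision 0.97 / recall 0.95 say that
33 regions were called of which all but one overlap a planted region,
and 57 of the 60 planted regions were recovered. Gene-level calls
(`call_gene_essentiality()`, >9% of guides below Z = −1) recover all 30
lethal genes and none of the 10 neutral ones on this screen.

Plotting and broom-style accessors:

```r
autoplot(fits[["G01"]], regions = regions)   # profile + fit + regions
tidy(fits[["G01"]])                          # fitted segments
glance(fits[["G01"]])                        # objective, iterations, config
```

A thin CLI wraps the same functions
(`inst/cli/tilescan.R {design|score|fit|annotate|simulate|robustness|all}`),
and `run_pipeline()` drives everything from a YAML config, writing
scores, fits, regions (TSV + BED), gene calls, and a manifest with the
seed, parameters and convexity check.

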