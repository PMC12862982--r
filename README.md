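# SpaMeanImpute

Spatially aware dropout detection and imputation for spatially resolved
transcriptomics (SRT).

High-resolution SRT platforms (10x Genomics Visium, Stereo-seq, Slide-seqV2,
sci-Space) produce spot-by-gene count matrices that are 80–95% zeros. Some of
those zeros are *biological* (the gene is genuinely not expressed at that
spot); others are *technical dropouts* (the transcript was present but not
captured). Generic imputers fill in every zero, erasing real biological
sparsity; leaving all zeros in place degrades clustering and spatial-domain
detection. This package implements a neighborhood statistic that separates
the two cases using the one piece of information generic methods ignore —
the physical position of each spot — and imputes only the zeros it classifies
as dropouts.

## Method

For a log-normalized expression matrix **X′** (here stored genes x spots) and
spot coordinates **S** ∈ ℝ^(n x 2):

1. Genes with zero expression at every spot are removed; for each spot *i*
   the zero gene set 𝒵ᵢ = { j : X′ᵢⱼ = 0 } is indexed.
2. Each spot's k nearest neighbors 𝒩ᵢ (Euclidean distance, self excluded,
   ties by ascending index) are found.
3. For every zero entry (i, j), the **zero ratio** is the fraction of
   neighbors at which gene j is also zero:
   zero_ratioᵢⱼ = ( Σ_{m ∈ 𝒩ᵢ} 1[X′ₘⱼ = 0] ) / k.
4. If zero_ratioᵢⱼ ≤ δ (the dropout threshold) and at least one neighbor
   expresses gene j, the entry is imputed with the arithmetic mean of the
   non-zero neighbor values; if zero_ratioᵢⱼ > δ it is retained as a
   biological zero; if every neighbor is zero it is skipped.

A low zero ratio means the gene is expressed all around spot *i*, so its zero
is most likely technical; a high ratio means the neighborhood is genuinely
silent. Defaults are k = 6 (the contact number of a hexagonal Visium lattice)
and δ = 0.4. Non-zero entries are never modified, and by default every read
comes from a frozen snapshot of the input so the result does not depend on
spot visiting order.

Around the core algorithm the package provides the standard pipeline stages
(QC filtering, total-count/log1p normalization, highly-variable-gene
selection), clustering-agreement metrics implemented from their definitions
(ARI, NMI, AMI, homogeneity), zero-sparsity and dropout accounting,
masked-entry recovery validation, plain-text bundle IO (MatrixMarket + CSV +
JSON), Leiden clustering delegated to scran/igraph, and a synthetic SRT
generator with known spatial domains and a recorded dropout mask, so every
stage is testable without external downloads.

## Worked example

```r
library(SpaMeanImpute)

se <- simulateSpatialData(nSpots = 900, nGenes = 120, seed = 42)
se <- normalizeLog1p(se)
se <- spaMeanImpute(se, k = 6, delta = 0.4)
S4Vectors::metadata(se)$imputation_report
#> ImputationReport (k = 6 , delta = 0.4 )
#>   zero candidates      : 55942
#>   imputed dropouts     : 17133
#>   retained biological  : 38809
#>   skipped (all-zero NN): 0
#>   zero sparsity        : 51.798% -> 35.934% (dropout detected 15.864%)

cl   <- clusterSpots(se, "imputed",   seed = 42)
base <- clusterSpots(se, "logcounts", seed = 42)
round(rbind(imputed  = clusteringMetrics(domainLabels(se), cl),
            observed = clusteringMetrics(domainLabels(se), base)), 3)
#>            ari   nmi   ami  homo
#> imputed  0.973 0.957 0.957 0.957
#> observed 0.813 0.761 0.760 0.760
```

The report reads: of 55 942 zero entries, 17 133 had a neighborhood zero
ratio at most 0.4 and were imputed (zero sparsity drops from 51.8% to 35.9%;
the difference, 15.9 percentage points, is the detected-dropout share), while
38 809 zeros were classified as biological and kept. Clustering the imputed
matrix recovers the four simulated tissue domains almost perfectly
(ARI 0.97) versus 0.81 on the dropout-corrupted input.

A command-line wrapper with `simulate`, `impute`, `evaluate`, `recovery` and
`run` subcommands is installed at `inst/scripts/spamean.R`.

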