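# coigap

Threshold-based species delimitation and barcoding-gap analysis for COI
barcode data.

## The problem

DNA barcoding delimits putative species (molecular operational taxonomic
units, MOTUs) by clustering COI sequences at a genetic-distance
threshold. The approach only works where a *barcoding gap* exists — where
intraspecific distances stay below the threshold and interspecific
distances above it. In insects, intraspecific COI variation is often
large, so fixed empirical thresholds (1%, 2%, 2.2%, 3%) can oversplit
species and inflate diversity estimates. `coigap` implements the full
analysis a practitioner needs to measure this on BOLD-style specimen
data and to compare fixed thresholds with three flexible,
per-genus alternatives:

* **localMinima** — the first local minimum of a Gaussian kernel density
  fitted to all pairwise distances of a genus (no taxonomy needed);
* **Mininter** — the minimum congeneric interspecific distance, corrected
  by −1e−8 so the closest heterospecific pair stays separated under the
  strict `<` clustering comparison;
* **Opt** — a grid search (0.001–0.2, step 0.001) minimising the
  cumulative identification error (false positives + false negatives),
  averaging tied thresholds.

Distances are Kimura two-parameter (K2P) or p-distances with pairwise
deletion,

d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q),

with P and Q the transition and transversion proportions among compared
sites; non-positive logarithm arguments and empty site sets yield an
explicit *undefined* state that the quality filters act on. Clustering is
single linkage: records sharing any distance strictly below the
threshold join the same MOTU. Congruence with morphological species is
scored by the match ratio 2·Nmatch/(Ndelimited + Nmorph) and by
per-species MATCH/SPLIT/MERGE/MIXTURE outcomes.

The package also ships the full quality-filter cascade used for BOLD
extracts (identification level, ambiguous-name keywords, marker code,
minimum three sequences per species, subsampling at 100, alignment-gap
removal, internal stop codons under the invertebrate mitochondrial code,
undefined distances, 95th-quantile outliers, and the genus-level
preparation rules), plus a calibrated simulator of BOLD-like insect
barcode data with injectable defects, so every stage is testable without
any download.

## Worked example

```r
library(coigap)
library(dplyr)

sim <- simulate_barcodes(n_genera = 4, species_per_genus = 4,
                         seqs_per_species = 8, seed = 7)
g1  <- filter(sim$records, genus_name == "Genus001")
d   <- distance_matrix(g1, model = "K2P")

opt <- thresh_opt(d, g1)
opt
#> Threshold optimisation over 200 candidate thresholds
#>   records: 32  species: 4
#>   minimum cumulative error: 0 (at 31 thresholds)
#>   optimal threshold (mean of ties): 0.024
```

Zero cumulative error means some band of thresholds assigns every record
a purely conspecific neighbourhood; the optimum 0.024 is the mean of the
31 tied grid points. The other two flexible thresholds agree that the
gap sits between ~0.015 and ~0.04 for this genus:

```r
local_minima_thresholds(pairwise_values(d))
#> [1] 0.02653894 0.04834719
mininter_threshold(min_interspecific_congeneric(d, g1)$genus_min)
#> [1] 0.03950683
```

Clustering at the optimised threshold reproduces the true species
exactly — match ratio 1, all four species MATCH:

```r
part <- threshold_cluster(d, opt$optimum)
match_ratio(part, g1)
#> # A tibble: 1 × 4
#>   n_morph n_delimited n_match match_ratio
#>     <int>       <int>   <int>       <dbl>
#> 1       4           4       4           1
```

`run_genus_analysis()` repeats this for every genus and method and
aggregates:

```r
ga <- run_genus_analysis(sim$records, coigap_config())
ga$method_summary
#> # A tibble: 7 × 9
#>   method      n_genera mean_match_ratio n_morph n_delimited MATCH SPLIT MERGE MIXTURE
#> 1 localMinima        4            0.841      16          19    14     2     0       0
#> 2 mininter           4            1          16          16    16     0     0       0
#> 3 opt                4            1          16          16    16     0     0       0
#> 4 t_0.01             4            1          16          16    16     0     0       0
#> 5 t_0.02             4            1          16          16    16     0     0       0
#> 6 t_0.022            4            1          16          16    16     0     0       0
#> 7 t_0.03             4            1          16          16    16     0     0       0
```

Here the density-based method split two species in one genus (its first
KDE minimum fell inside the intraspecific mode), while the
error-minimising and minimum-interspecific thresholds were exact — the
kind of comparison the package is built to make. Real BOLD tables enter
through `read_bold_tsv()` / `read_barcode_fasta()`, are cleaned with
`run_filter_cascade()`, and `run_pipeline()` writes every report (TSV)
plus a JSON manifest for a fully reproducible run.

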