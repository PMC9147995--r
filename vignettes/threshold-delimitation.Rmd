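---
title: "Methods: distance-based MOTU delimitation and the barcoding gap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance-based MOTU delimitation and the barcoding gap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`coigap` treats species delimitation as single-linkage clustering of a
pairwise genetic distance matrix. Records are nodes; every pair at
distance strictly below a threshold *t* contributes an edge; the
connected components are the MOTUs. The method's central assumption is
the *barcoding gap*: within a genus, intraspecific distances should be
separated from interspecific ones, so that some band of thresholds
reproduces the species partition exactly. Everything in the package
either measures how well that assumption holds (distance summaries,
histograms, proportion of species with maximum intraspecific distance
above a cutoff) or picks thresholds that exploit it.

Distances follow the Kimura two-parameter model with pairwise deletion.
For a pair of aligned sequences, sites where either member carries a
gap, `N` or an ambiguity code are excluded; with transition proportion
*P* and transversion proportion *Q* among the compared sites,

$$d = -\tfrac{1}{2}\ln(1 - 2P - Q) - \tfrac{1}{4}\ln(1 - 2Q).$$

When no sites are comparable or a logarithm argument is non-positive
(saturation), the distance is *undefined* — represented as `NA`, a
first-class state rather than a sentinel value, because one quality
filter exists precisely to drop species containing such pairs. The
uncorrected p-distance is available as an alternative model; the K2P
correction always weakly exceeds it.

## Threshold selection

Three flexible per-genus methods complement the fixed empirical
thresholds (0.01, 0.02, 0.022, 0.03 substitutions/site):

* **localMinima.** A Gaussian kernel density is fitted to all pairwise
  distances of the genus; grid points strictly lower than both
  neighbours are candidate thresholds, and the first (smallest) is
  selected. A genuine barcoding gap shows up as the dip between the
  intra- and interspecific modes. A genus whose density is unimodal has
  no candidate and is reported NOT-EVALUABLE for this method — it is
  excluded from the method's averages rather than silently falling back
  to a fixed threshold.
* **Opt.** Every grid threshold (default 0.001–0.2, step 0.001) is
  scored by its cumulative identification error. Per record, the
  neighbourhood *M* is the set of other records at distance < *t*:
  empty *M* is a true negative for singleton species and a false
  negative otherwise; non-empty, purely conspecific *M* is a true
  positive; any heterospecific neighbour makes a false positive. The
  four categories are exhaustive and mutually exclusive, so they sum to
  the record count — a property the tests exercise at every grid point.
  The optimum is the arithmetic mean of all thresholds tying at the
  minimal error; averaging *all* tied grid points (not just a contiguous
  run) is the literal reading of mean-of-ties, and on clean-gap data the
  tied set is contiguous anyway, so both readings coincide exactly where
  they matter.
* **Mininter.** The minimum congeneric interspecific distance minus
  1e−8. The correction only makes sense together with the strict `<`
  edge comparison: subtracting 1e−8 guarantees the closest
  heterospecific pair sits on or above the threshold, so no MOTU can mix
  species (no MERGE or MIXTURE outcome is possible at this threshold —
  a property the tests verify on every fixture). The comparison operator
  is nevertheless exposed (`comparison = "le"`) for sensitivity
  analysis, and the test suite demonstrates that `<=` without the
  correction does violate purity.

Congruence with morphology uses the match ratio
$2 N_{match} / (N_{delimited} + N_{morph})$, where $N_{match}$ counts
MOTUs coinciding exactly with one species' full record set; it equals 1
iff the two partitions are identical. Per species, outcomes are MATCH
(one pure MOTU), SPLIT (several pure MOTUs), MERGE (one shared MOTU) or
MIXTURE (several MOTUs, at least one shared). Averages of match ratios
across genera are unweighted arithmetic means; outcome counts are
computed per species, so they sum to the species total.

## The filter cascade

Stages run in a fixed order, each independently callable and reported
with in/out counts and dropped identifiers: species-level identification
(empty, genus-only, or "sp."-style epithets with or without trailing
numerals), ambiguous-name keywords (`aff`, `cf`, `nr`, `spp` — matched
as whitespace- or period-delimited tokens, never substrings, so
legitimate epithets containing "nr" survive), exact marker code
(`COI-5P`), a minimum of three sequences per species, uniform
subsampling of species above 100 sequences, alignment-gap removal,
internal stop codons, undefined distances, and a 95th-quantile rule on
the per-species maximum intraspecific distance. Genus-level preparation
then removes both members of every congeneric species pair at zero
interspecific distance, genera with fewer than three species, and
families with a single genus.

Numerical and ordering choices worth knowing:

* The minimum-sequence rule is re-applied after gap removal, because
  deleting gap-bearing sequences can shrink a species below three; the
  re-check keeps the cascade's postcondition (every surviving species
  has ≥ 3 clean sequences) unconditionally true.
* Gap handling excises columns that are gaps in *every* sequence first,
  then removes any sequence still containing a gap, so the output
  alignment is entirely gap-free. Re-alignment after removal is out of
  scope; inputs are assumed pre-aligned (the simulator produces them
  that way).
* Stop codons are counted per forward reading frame under the
  invertebrate mitochondrial code (translation table 5 / `SGC4`, in
  which `TGA` encodes tryptophan), summed over all sequences of a
  species, ignoring each frame's final incomplete codon; the frame with
  the fewest stops is the species' frame, and any stop remaining there
  drops the whole species.
* The quantile cutoff uses linear interpolation between order statistics
  (type 7, the default of `stats::quantile()`), with species exactly at
  the cutoff retained; the algorithm is exposed because results are
  sensitive to the convention at small species counts. Note a
  consequence the tests account for: with distinct maxima, *some*
  species always exceeds the interpolated cutoff, so this stage is not a
  no-op even on clean data.
* The quantile rule runs after the undefined-distance rule, matching the
  listed filter order.
* Subsampling derives a per-species seed from the global seed and the
  species name, so the selection is invariant to row order of the input
  table.
* Zero-distance pairs remove *both* species: with an identical sequence
  shared between species, neither identification can be trusted more
  than the other.
* For the cutoff-subset report, per-species minimum congeneric distances
  are computed once on the full genus and reused across cutoffs;
  recomputing after each removal would change the retained species
  counts and make rows incomparable.

## The simulator

`simulate_barcodes()` emulates the statistical structure the analysis
assumes: per genus, a random in-frame coding sequence (no internal stop
codons under the invertebrate mitochondrial code) is evolved to species
ancestors and then to individuals under a two-rate substitution process
with transition:transversion odds κ:2 (default κ = 4, a typical
mitochondrial value). Mutations that would create an internal stop codon
in the coding frame are rejected and redrawn — simple, auditable, and
sufficient to keep all output translatable. Divergence targets are
expressed as expected pairwise K2P distance and inverted numerically
through the K2P expectation to per-site mutation probabilities, so
simulation targets and measured distances share a scale: individuals
branch at intra/2 from their species ancestor and species at
(inter − intra)/2 from the genus ancestor, giving expected pairwise
intraspecific distance ≈ intra (default 0.005) and congeneric
interspecific distance ≈ inter (default 0.06). Defaults of 600 bp,
three-plus species per genus, genera organised two per family: a small
BOLD-like extract. `inject_defects()` adds, on disjoint species so
defects never interact, exactly the defect classes the filters exist to
remove, with a manifest naming each defect's expected removal stage.

What the simulator does *not* model: coalescent genealogy (individuals
form a star around the species ancestor, so intraspecific distances are
exchangeable and slightly over-dispersed relative to a coalescent),
indel evolution (gaps exist only as injected defects), selection,
codon-usage bias, rate variation among sites, and mislabelled
specimens. Passing tests therefore demonstrate algorithmic correctness
and calibration on idealised data with a genuine gap — not that real
insect COI data have such a gap; measuring that on real data is the
package's purpose, not its test suite's.

## Known limitations

The localMinima method inherits the fragility of rule-of-thumb
bandwidths. When interspecific pairs dominate a genus' distance vector,
the interquartile range collapses and so does the `nrd0` bandwidth; the
intraspecific mode can then resolve into sub-bumps whose first dip lies
below the largest intraspecific distance. On calibrated simulations
(4 species × 8 sequences per genus) this places the first local minimum
outside the realized gap in roughly 4% of genera — though single-linkage
chaining usually still recovers the species exactly, because a single
large intraspecific distance does not disconnect a species. The KDE
settings (bandwidth rule, 512 evaluation points, 3-bandwidth range
extension) are exposed in `local_minima_thresholds()` for users who want
a more robust bandwidth; the defaults follow the standard density
routine. The identification-error taxonomy behind `thresh_opt()` is an
explicit reconstruction of the usual error-minimisation semantics; its
contract is stated precisely in the function documentation and enforced
by the tests.

Problem sizes: the test suite and the acceptance script run on
simulations of 2–20 genera (up to ~640 records), thousands of
constructed distance pairs and random matrices up to n = 30 — sizes at
which every oracle (closed forms, union-find, brute-force grid scans)
is exact and fast, and which already realise the distributional
features the methods depend on.
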