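---
title: "Pseudo-testcross mapping with a reciprocal translocation: models and methods"
author: "hazelmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-testcross mapping with a reciprocal translocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hazelmap)
```

# The problem

Highly heterozygous outcrossing species such as European hazelnut
(*Corylus avellana*) cannot be mapped through inbred-line designs.
The standard device is the double pseudo-testcross: an F1 full-sib
family of two heterozygous parents is treated as two superimposed
backcrosses. A SNP heterozygous in exactly one parent (the other parent
homozygous) segregates 1:1 in the progeny and is informative for that
parent's meiosis alone, so a separate linkage map is built per parent
from its own testcross markers.

Two complications drive this package's design:

* **Reciprocal translocations.** Some cultivars (here, the female
  parent) are heterozygous for an exchange of arms between two
  non-homologous chromosomes. At meiosis the four chromosomes form a
  quadrivalent; only alternate segregation yields balanced (viable)
  gametes, so the alleles flanking the two breakpoints are
  co-transmitted. In the progeny this produces *pseudo-linkage*: markers
  of the two chromosomes group together at any reasonable LOD threshold
  and no linear marker order exists for the merged group.
* **GBS-scale marker data.** Thousands of SNPs with appreciable
  missingness, redundancy (co-segregating tags) and chance segregation
  distortion must be screened before mapping.

`hazelmap` implements the full analysis: marker typing and QC,
two-point linkage mapping, detection and resolution of the
pseudo-linkage (breakpoint localisation, splitting the progeny by
transmitted arrangement, rebuilding the four arms), QTL scanning for a
quantitative trait, and a meiosis simulator that generates populations
with known truth so every stage is testable without external data.

# Data model

`TestcrossGenotypes` (extending `SummarizedExperiment`) holds a
markers-by-individuals matrix of calls in `{a, b, NA}`, where the call
is the transmitted allele of the informative parent, plus per-marker
metadata: scaffold of origin, physical position, SNP type and
segregating parent. The five parental-state SNP types are: I both
parents homozygous monomorphic; II both homozygous polymorphic; III
both heterozygous (1:2:1); IV female-only heterozygous (1:1); V
male-only heterozygous (1:1). Only types IV and V enter mapping: an
intercross (type III) marker's recombination estimate averages the two
parental meioses and conflicts with testcross orders.

# Marker QC

* **Segregation screen** (`segregationTest`): Pearson chi-square
  against 1:1 without continuity correction, classified by the 1-df
  quantiles 2.706 / 3.841 / 6.635 (alpha = 0.1 / 0.05 / 0.01): within
  the first bound "normal", then one and two asterisks (retained but
  annotated on the map), beyond the last bound excluded.
* **Redundancy screen** (`findRedundantMarkers`): markers whose calls
  agree on every pairwise-complete individual (similarity 1.000), with
  at least 30 shared non-missing calls, cluster transitively; one
  representative per cluster is kept (fewest missing calls, ties by
  lexicographic id). The minimum-overlap guard is our contract — with
  missing data, "identical on the observed overlap" is vacuous for tiny
  overlaps. Matching complemented columns (same locus in opposite
  phase) is available but off by default.
* **Framework selection** (`selectFramework`): one marker per genome
  scaffold (fewest missing calls, then lowest bp position, then
  lexicographic id); the rest are accessory. The funnel identity
  *input = retained + distorted + redundant + accessory* is asserted in
  the tests.

# Two-point linkage and map construction

For markers scored in the same parent, mismatch counting over
pairwise-complete individuals gives the phase-free recombinant count
`R = min(m, n - m)` and estimate `r = R/n`; phase is coupling when
`m <= n - m`. The LOD against independence is
`(n - R) log10(2(1 - r)) + R log10(2r)` (`n log10 2` at `r = 0`).
Grouping is single linkage over edges with `LOD >= 12` and
`r <= 0.40` — the stringent framework threshold; groups at a high
threshold always refine groups at a lower one.

Within a group, the order minimises SARF (sum of adjacent recombination
fractions): a greedy nearest-neighbour path grown from the tightest
pair, refined to a local optimum by best-improvement 2-opt segment
reversals alternating with Or-opt single-marker reinsertions, both
evaluated in vectorised form. On groups of up to six markers the result
is checked against exhaustive search in the tests. Orientation is
canonicalised (lexicographically smaller terminal first). Positions are
cumulative Kosambi distances, `d = 25 ln((1 + 2r)/(1 - 2r))` cM, over
adjacent pairs; map sizes are reported to 1 decimal, `r` to 3 decimals,
density as size/(count − 1) to 1 decimal, and gaps are adjacent
intervals strictly over 5 cM. Multipoint (regression or ML) ordering
and multipoint distances are deliberately out of scope: the
adjacent-pair construction is simple, fast and testable against closed
forms, at the cost of ignoring double-recombinant shrinkage that a
multipoint likelihood would model.

A per-marker phase annotation ("-r" for repulsion) is derived by
chaining adjacent-pair phases along the framework order. The same
chain-alignment (flip a marker when its codes anti-correlate with the
previous marker) orients marker codes before any QTL regression.

# The translocation module

**Detection.** Scaffolds carrying mapped markers in both parental maps
bridge the maps. A female group is flagged as entangled when its
scaffolds bridge to two distinct male groups with at least 5 bridges
each — single stray bridges (misassembled scaffolds) must not trigger
a flag.

**Visualisation.** `pcoMarkers` embeds the entangled markers by
principal coordinates of the pairwise `r` matrix (one minus the simple
matching similarity); the four-arm star of a translocation shows as
arms radiating from the breakpoint region.

**Breakpoint localisation.** Each entangled marker is assigned a
reference (male-map) group and position through its scaffold; the
cross-group pair with minimal `r` flanks the breakpoints (alternate
segregation forces co-transmission there). Ties break by larger
informative count, then lexicographic ids; if the minimum exceeds 0.35
no translocation is declared. The declaration cap is our choice — the
method needs a guard against declaring a breakpoint from noise, and
0.35 sits well above any plausible breakpoint `r` while below the 0.40
linkage cap.

**Splitting the progeny.** Each individual is labelled by the
arrangement allele transmitted at the two anchor markers; all markers
within 5 cM of either breakpoint (on the reference map) must support a
single arrangement, otherwise the individual is discarded with a
recorded reason (the window width follows the study design and is
configurable). The anchor coding is arbitrary in re-sequenced data, so
which label means "translocated" is supplied by the caller (from
parental phase knowledge, or simulation truth in the validation
studies); the split itself is label-symmetric.

**Rebuilding the four arms.** Inside one subpopulation the transmitted
arrangement is fixed, so the four arms segregate independently — but
segregation there is *distorted everywhere* (the minor-allele fraction
at distance d from a breakpoint is the recombination probability over
d). Two consequences shape the implementation:

* The classical testcross LOD assumes 1:1 and manufactures spurious
  linkage between independent, equally skewed markers. Within
  subpopulations we therefore group on a margin-conditioned association
  LOD, the 2x2 G-statistic divided by 2 ln 10, at the same threshold
  (default 4). Near-fixed markers (minor class below 5 calls) are
  excluded from grouping: they carry no linkage information and can
  bridge arms through chance co-occurrence of their few minor calls.
* One subpopulation alone can misjoin or fail to resolve an arm. The
  arm cores are therefore the intersection cells of the two
  subpopulation partitions: markers grouped in both subpopulations must
  agree in both; markers grouped in only one (the other silent) form
  one-sided cells that still count, with breakpoint-proximal stragglers
  absorbed into their parent arm by full-population mean `r`. If only
  three arms are supported — a short arm can lose most of its markers
  to a chance distortion cluster in QC — the missing arm is allocated
  from the reference map through scaffold anchors, mirroring the
  reference-map allocation step of the original strategy. Markers
  severely distorted within a subpopulation and not consistently
  assignable are dropped (these are the breakpoint-proximal markers);
  undistorted leftovers are rescued into the arm with the lowest mean
  `r`. Anything other than four arms mapping two-and-two onto the two
  reference groups is reported as a reconstruction failure with
  diagnostics.

Arms are named `<referenceGroup>a/b` with `a` the arm at lower
reference position, and finally re-ordered on the full population.

# The QTL module

Trait summaries use the adjusted Fisher–Pearson skewness and excess
kurtosis with the N-only standard errors
`SE_skew = sqrt(6N(N-1)/((N-2)(N+1)(N+3)))` and
`SE_kurt = sqrt(4(N^2-1) SE_skew^2 /((N-3)(N+5)))`. Marker-trait
association uses the tie-corrected Kruskal–Wallis test. Ordinal 1–9
phenology ratings are treated as quantitative throughout, as interval
mapping software conventionally does; no threshold model is fitted.

**Simple interval mapping** is Haley–Knott regression: at each grid
position (1 cM step, marker positions included) the expected testcross
code given the flanking markers is computed from Haldane transition
probabilities (one recombination event modelled per interval; missing
flanks degrade to single-marker conditioning), and the trait is
regressed on it: `LOD = (n/2) log10(RSS0/RSS1)`, `PV = 1 − RSS1/RSS0`,
additive effect = half the difference between the fitted class means.
At a fully informative marker this reduces exactly to single-marker
regression — the property that bounds the approximation and is asserted
to 1e-8 in the tests. Haley–Knott replaces the mixture-EM of
commercial interval mappers; the equivalence-at-markers property is the
guard. The additive sign is relative to the chain-aligned coding and
therefore arbitrary up to a global flip per group; the magnitude is the
meaningful quantity.

**MQM** augments the regression with cofactor marker codes (selected by
backward elimination from the interval-mapping peaks at p < 0.02;
aliased candidates are dropped later-entered-first). Cofactors on the
scanned group within 20 cM of the test position are omitted (no
self-fitting); LOD and PV are computed against the cofactor-reduced
residual. The 20 cM exclusion window is our default; it is configurable
and not derived from a published value.

**Genome-wide thresholds** come from permuting the trait across
individuals and recording the genome-wide maximum LOD (empirical
1 − alpha quantile, alpha = 0.05, 1000 permutations at study scale).
**QTL calls** are local maxima at or above the threshold; two maxima on
a group merge unless separated by a dip of more than 1 LOD below the
lower peak; each call carries the 1-LOD support interval, the nearest
locus, PV (as a percentage) and additive effect at the peak, and a
`lb_<map>_<LG>_<yy>` name.

# The simulator

`simulatePopulation` generates the full study design from a single
seed: phased parents, per-individual meioses, testcross calls, a trait
with planted QTL, genotyping noise, and a truth record (arrangement per
individual, transmitted QTL alleles, true breakpoints, phases, true
marker positions) filled before noise.

* **Crossovers** are a no-interference (Haldane) Poisson process per
  chromosome arm; this gives closed-form oracles
  (`r = (1 − exp(−2d/100))/2`) for every test. Kosambi is used only for
  distance reporting downstream, matching the analysis convention.
* **The quadrivalent is reduced to alternate segregation**: a fair coin
  transmits either both normal or both translocated chromosomes;
  unbalanced (adjacent-segregation) gametes are never emitted,
  mirroring the abortion of duplication/deficiency products. Interstitial
  crossovers between breakpoint and centromere are not modelled —
  breakpoints sit at the arm junctions. Segregation distortion near the
  breakpoints *within subpopulations* emerges from the arrangement coin
  rather than being injected separately.
* **Markers**: each position hosts one scaffold with one female- (type
  IV) and one male-informative (type V) SNP, giving both maps equal
  nominal density and abundant scaffold bridges; the overall SNP-type
  composition is shaped by filler loci of types I–III (defaults follow
  the study's observed type proportions). Phases are random per marker.
* **Trait**: `mean + sum(±a per QTL by transmitted allele) + N(0, sd²)`,
  optionally binned to the 1–9 phenology scale by equal-width bins over
  the population range (the rating procedure of the original study is
  not published; single-observation ratings are the default, with
  multi-year support as independent residual draws on shared genetic
  values). The default planted architecture (one major QTL with about
  45% of the variance plus minor QTL near 3%, total SD about 1.5 on a
  mean of 4.5) reproduces the published trait table's scale.
* **Noise**: calls are set missing, then flipped, independently at the
  configured rates; defaults are clean calls, with noise injected
  explicitly where a test needs it.

All draws flow from one generator stream in a documented order, so one
seed reproduces a population bit-for-bit.

What the simulator does *not* emulate: read-level errors (depth,
allelic dropout — noise is i.i.d. per call), real scaffold
misassembly, crossover interference, interstitial-segment meiosis,
environment-by-year structure beyond independent residuals, and
polygenic background beyond the planted QTL. Passing the recovery
studies therefore demonstrates correctness of the algorithms under the
stated meiosis model, not robustness to every artefact of real GBS
data.

# Validation studies and problem sizes

The packaged studies run the full stack at the study scale: 11
chromosomes of 100 cM (breakpoints at 47 and 23 cM on the two
translocated chromosomes), markers every 1 cM, 213 individuals, 100
seeds for the translocation recovery study; QTL recovery uses the same
1 cM markers, a 1 cM scan grid and 200 permutations per seed, 100 seeds,
with the planted major QTL at 45% PV. These sizes keep the full
validation within minutes while leaving every rate estimate with a
binomial standard error below 0.05.

Chance segregation-distortion clusters (binomial drift along a
chromosome, excluded at alpha = 0.01 exactly as in the QC rule) are the
dominant failure mode of the translocation recovery: when such a
cluster hits the reference anchors around a breakpoint, the minimum-r
pair lands away from the true junction and the short arm conditioned on
that anchor cannot be resolved. This is a property of the method under
the study design, not of the implementation; the recovery-rate
acceptance margin absorbs it.

# Numerical choices and degenerate inputs

* Chi-square tier bounds are computed from `qchisq`, not hard-coded.
* `kosambiCm` and `haldaneCm` reject `r >= 0.5`; adjacent `r` values
  are capped at 0.499 before conversion when building maps from noisy
  estimates.
* Pairs with no shared informative individuals get `r = NA`, LOD 0;
  ordering falls back to `r = rmax` for such pairs (logged).
* Constant traits give identically zero LOD profiles; monomorphic
  grid positions are skipped with a warning.
* Single-marker groups report size and density 0 with a warning.
* All representative/tie-break rules (redundancy representative,
  framework marker, breakpoint pair, orientation) are deterministic and
  documented so identical inputs give identical outputs.

# Limitations

Two-point ordering cannot exceed the information in pairwise counts:
at n = 213 some adjacent pairs are exactly tied and their local order
is arbitrary (the validation measures this directly). Distances are
additive Kosambi over adjacent pairs and inherit genotyping-error
inflation; no error-correcting multipoint HMM is fitted. The QTL module
assumes a single-QTL-per-interval regression model with homoscedastic
residuals. The translocation machinery assumes exactly one reciprocal
translocation heterozygous in one parent; inversions, complex
rearrangements and double translocations are out of scope.
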