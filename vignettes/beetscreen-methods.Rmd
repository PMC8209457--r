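---
title: "Methods and modelling choices in beetscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modelling choices in beetscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beetscreen)
```

`beetscreen` operationalises a community-analysis screen for plant
growth-promoting bacteria (PGPB): 16S rRNA gene sequences from tissue
clone libraries and root isolate collections are clustered into OTUs,
characterised by alpha/beta diversity and composition, filtered by a
rule-based candidate screen, and the screen's isolates are judged by
inoculation assays. This vignette records the conventions the package
adopts, why, and what its validation does and does not establish.

## Distances and clustering

Pairwise distances are computed on a fixed alignment with **pairwise
deletion**: a column is compared only when both sequences carry an
unambiguous base (A/C/G/T; U is read as T, N and gaps as missing). The
p-distance is the mismatch fraction over those columns; the Jukes–Cantor
distance is $d = -\tfrac{3}{4}\ln(1-\tfrac{4}{3}p)$. Pairwise deletion
keeps distances defined for ragged alignment ends, and treating N as
missing rather than mismatch is conservative for identity thresholds.
At $p \ge 0.75$ the Jukes–Cantor logarithm is undefined; the package
signals an error instead of clamping, because silently saturated
distances would corrupt downstream clustering.

OTUs are built by agglomerative clustering with **furthest-neighbour
(complete) linkage by default**: merging stops when the smallest
inter-cluster linkage distance exceeds the cutoff, so every OTU
satisfies a provable bound — no two members are further apart than the
threshold. That bound is what makes "97% identity" a checkable contract,
and it is asserted property-style in the tests. Nearest and average
linkage are available for sensitivity analysis. The linkage convention
is an assumption of this package (the era-typical default of the
classical clustering tools), not an established fact about any
particular historical analysis. Ties during merging are broken by
linkage distance, then by the lexicographically smallest member-id pair,
and OTU ids are assigned by decreasing size then smallest member id —
so results are reproducible across platforms.

The cutoff semantics deserve one note: a distance threshold of 0.03 on
**p-distances** corresponds directly to 97% identity; Jukes–Cantor
distances exceed p-distances, so the same numeric cutoff yields slightly
coarser OTUs. Both models are first-class; the pipeline and the
synthetic validation use p-distances for the threshold semantics.

## Alpha diversity conventions

The per-library statistics block names its indices without formulas in
most published tables, so the package adopts and documents the
conventions of the standard clustering tool chain:

| quantity | convention | default |
|---|---|---|
| Good's coverage | $C_x = 1 - n_1/N$ ($n_1$ singletons, $N$ library size) | — |
| Chao1 | bias-corrected, $S_{obs} + n_1(n_1-1)/(2(n_2+1))$ | — |
| ACE | rare/abundant split, $\gamma^2$ clamped at 0 | cutoff 10 |
| Shannon $H'$ | natural logarithm | — |
| inverse Simpson | unbiased $D = \sum n_i(n_i-1)/(N(N-1))$ | — |

ACE degenerates when every rare OTU is a singleton (its coverage term is
zero); the package then returns the observed richness with a warning
rather than failing. Printed-style tables round half away from zero to
one decimal (`round_half_up()`), since that matches how such tables are
typeset; internal computation is always full precision.

## Trees, UniFrac and ordination

Trees are neighbour-joining (via ape's reference implementation), with
negative branch-length estimates clamped to zero — standard practice,
and required because weighted UniFrac needs non-negative lengths; the
clamped deficit is kept as an attribute. Bootstrap support resamples
alignment columns and counts bipartitions of the point-estimate tree.

Weighted UniFrac is the branch sum $\sum_i b_i\,|A_i - B_i|$ with
$A_i, B_i$ the community fractions descending from branch $i$. The
branch-length-normalized variant (divide by $\sum_i b_i (A_i + B_i)$) is
available behind a flag but **off by default**: "abundance-weighted"
does not by itself determine the normalization, so both variants are
first-class and the validation suite exercises both. UniFrac needs a
root; unrooted trees are midpoint-rooted (documented, configurable by
rooting the tree yourself first).

PCoA is classical metric scaling: Gower double-centering of
$-D^2/2$, eigendecomposition, coordinates scaled by $\sqrt{\lambda_k}$.
Negative eigenvalues (UniFrac matrices are generally non-Euclidean) are
reported but excluded from coordinates and from the percent-variance
denominator; no Lingoes/Cailliez correction is applied — a documented
simplification. Eigenvector signs are fixed by making each axis's
largest-magnitude loading positive, for reproducible plots.

Published ordination percentages from any particular field data set
depend on that study's alignment and tree and are not reproducible from
summary tables; the package instead validates the *structural* claim on
synthetic data: on communities generated with above-/below-ground
affinity separation, the leading weighted-UniFrac PCoA axis cleanly
separates leaf/petiole libraries from taproot/lateral-root libraries in
20 of 20 seeds (both normalizations).

## Composition and the two-library test

Sequences are aggregated at a rank when the classifier confidence
reaches 0.8 (the classical classifier threshold); sub-threshold
sequences roll up to "unclassified *deepest confident parent*" rather
than being dropped, so every column still sums to 100%.

The two-library frequency comparison uses the exact tail of
$P(y\,|\,x) = (N_y/N_x)^y \frac{(x+y)!}{x!\,y!\,(1+N_y/N_x)^{x+y+1}}$
— the posterior predictive of a Poisson rate under a flat prior,
equivalently a negative binomial with size $x+1$. The reported p-value
doubles the smaller tail (capped at 1). Because that construction is
not perfectly symmetric in the two libraries, the package symmetrizes
by taking the minimum over the two orderings, which restores exact
swap-invariance; the exact statistic of the classical comparison
program is not published, so this is a documented stand-in with the
right exactness and symmetry properties. No multiple-testing correction
is applied across taxa — matching the practice the tables emulate — and
the report says so in an attached note.

## The selection engine

An OTU is selected when it has a cultured isolate, is not excluded by
the pathogen list, and satisfies at least one of: novelty
(best-hit identity **strictly** below 0.97), tissue specificity
(present only in taproot/lateral-root libraries or collections),
persistence (present in at least one below-ground tissue under **every**
fertilization condition observed for that tissue, pooling clones and
collections per condition), abundance (**strictly** above 1% in at least
one single below-ground library or collection), or a genus-level match
to the known-PGPB list. Decisions the package had to make where the
published rules leave room:

* **Presence** means raw count ≥ 1; no relative floor. The strictness
  of the identity and abundance inequalities follows the wording
  "less than" / "more than".
* **Persistence is evaluated per tissue** over conditions, not pooled
  across tissues; this honours "stable presence regardless of
  fertilizer application conditions" while keeping the below-ground
  focus. A pooled mode is a one-line config change
  (`target_tissues`).
* **The abundance criterion is restricted to below-ground
  libraries/collections** (the criterion's own sentence scopes it to
  taproots and lateral roots); configurable.
* The criteria combine as OR; isolate availability and pathogen
  exclusion are mandatory ANDs.
* The PGPB genus list ships as editable JSON seeded with the genera
  long reported as sugar-beet PGPB (*Acinetobacter*, *Bacillus*,
  *Burkholderia*, *Chryseobacterium*, *Pseudomonas*, *Paenibacillus*,
  *Rhodobacter*, *Stenotrophomonas*, *Variovorax*); the pathogen list
  is matched at species level by default so that pathogenic species do
  not disqualify beneficial congeners (genus-level matching is
  available).
* Missing best-hit identities make the novelty flag *undetermined*
  (`NA`, with a warning): the OTU is excluded from that criterion, not
  failed.

One isolate represents each selected OTU: by default the smallest-id
isolate from the collection where the OTU is most abundant —
deterministic, so candidate sets are reproducible.

## Inoculation statistics

Inoculation tests are repeated on different dates; each batch carries
its own control tray. Dry weights are divided by the mean control
weight of the same batch and tissue, which removes multiplicative batch
effects exactly (a two-batch fixture asserts this). The treated ratio
sample is then compared to the control ratio sample with Welch's
two-tailed *t*-test (Satterthwaite degrees of freedom, via
`stats::t.test`); a one-sample mode against ratio 1 and a batch-mean
mode are offered because the published procedure does not state which
granularity was used — per-seedling two-sample is the default. Effects
are promoting/inhibiting by the sign of (mean ratio − 1) at *p* < 0.05,
with a *p* < 0.01 tier. Two constant samples with equal means yield
*p* = 1 by convention. No correction across isolates is applied (again
matching the emulated practice; the results carry a note attribute).
Simulation shows the composite ratio + Welch procedure holds its nominal
size (type-I error 5% ± 1.5% over 1,000 null studies) and that power
increases monotonically in the true ratio.

## The synthetic-study generator

`simulate_study()` emulates the field design: 12 clone libraries (4
tissues × 3 fertilization plots) and 4 lateral-root isolate collections
(2 plots × 2 media), each 150–180 sequences deep (drawn once per
design from its seed). Base OTU abundances are log-normal (log-sd 1.5),
reproducing the long-tailed rank-abundance shape implied by high
singleton counts; tissue and condition multipliers structure the
communities; per-medium culturability biases the collections. Libraries
are multinomial draws — or, with `noiseless = TRUE`, deterministic
largest-remainder apportionments of the expected counts, the mode used
wherever exact recovery is asserted.

Planted roles make every selection criterion testable: per role
(novel, tissue-specific, persistent, abundant, known-PGPB,
pathogen-like) a configurable number of OTUs is constructed to satisfy
it, one OTU is unculturable on every medium yet present in clone
libraries (emulating taxa recalcitrant to isolation on standard media),
and background OTUs are constructed to satisfy *no* criterion. The
latter requires active enforcement on expected counts: background OTUs
are capped below one expected sequence in every below-ground
library/collection (hence under the 1% criterion at the designed
depths), every culturable background OTU loses one fertilization
condition (breaking persistence) and carries dominant above-ground
affinity with a guaranteed above-ground presence floor (breaking tissue
specificity); candidates get ≥ ~2 expected isolates per collection
(guaranteeing isolation). Enforcement is an iterative rescaling —
below-ground constraints act on base weights, above-ground floors on
above-ground affinities only, so the two cannot conflict — and the
generator verifies the final contracts. These guarantees hold when
library depth exceeds the reciprocal of the abundance threshold
(> 100 here); the defaults (150–180) satisfy that with margin.

Sequences are emitted on a fixed random template (default 800 columns,
minimum 500): one representative per OTU with enough random
substitutions that all inter-representative p-distances exceed 0.055
(re-drawn on collision), and per-read variants within 0.012 of their
representative. Intra-OTU read distances therefore stay below 0.025 and
inter-OTU distances above 0.03, so furthest-neighbour clustering at 0.03
provably recovers the planted partition — which the tests assert
exactly. Substitutions only, no indels: rows stay aligned, the distance
module stays exact, and no realignment step is needed.

Randomness is governed by one master seed expanded into fixed per-stage
substreams (`truth`, per-library draws, `sequences`, `taxonomy`,
`inoculation`, ...), so identical `(design, seed)` give byte-identical
studies and individual stages can be regenerated independently.

What passing on synthetic data does **not** show: real 16S data carry
chimeras, indels, alignment error, PCR/sequencing noise, compositional
classifier bias and rank-abundance shapes the generator does not model.
The synthetic studies validate the *logic* of every stage against known
truth; they cannot certify recovery rates on field data. Each clone
library is treated as one pooled sample (amplicons pooled across
plants), matching the one-row-per-library structure of the emulated
design; plot-level replication is not modelled.

## Problem sizes used in validation

The shipped tests and the acceptance script run scaled-down studies —
communities of 15–40 OTUs at the full per-library depths (150–180), and
a sequenced end-to-end study of ~700 reads — chosen so the whole suite
exercises every stage, including three full clustering runs, in about a
minute. The statistical checks use 1,000 null simulations (test size),
200 simulations (power), and 20 independent seeds (ordination
separation; planted-truth recovery). Depths stay above 100 because the
selection guarantees require it (see above); community size does not
enter any guarantee and is kept small for speed.

## Known limitations

* OptiClust-style and greedy centroid clustering are out of scope; the
  agglomerative path is quadratic in memory and suited to clone-library
  scales (thousands of sequences), not amplicon surveys.
* The two-library test is a documented stand-in for an unpublished
  statistic (see above).
* PCoA reports but does not correct negative eigenvalues.
* The taxonomy module consumes classifier output; it does not
  reimplement the classifier.
* Bootstrap support values on NJ trees are reported for completeness;
  no topology-dependent conclusion in the package relies on them.
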