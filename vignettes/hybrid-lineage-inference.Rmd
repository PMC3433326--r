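---
title: "Inferring hybrid lineage origins from dominant markers, plastid haplotypes and flow cytometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring hybrid lineage origins from dominant markers, plastid haplotypes and flow cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybriscope)
```

## The inference problem

Apomictic polyploid plant complexes pose a characteristic puzzle: putative
hybrid populations are morphologically intermediate between sympatric
congeners, ploidy varies within and between populations, and asexual seed
formation freezes genotypes into clones that can disperse. Three marker
systems triangulate the origin of such lineages:

* **Dominant multilocus fingerprints** (AFLP-type presence/absence bands)
  measure overall genomic similarity and carry taxon-specific bands.
* **Plastid haplotypes** are maternally inherited in most angiosperms, so
  an offspring's haplotype group names its seed parent.
* **Flow-cytometric DNA ploidy**, calibrated against chromosome-counted
  individuals, gives each sample an integer multiple of the base genome.

hybriscope combines these into a reproducible pipeline whose end point is a
verdict per hybrid lineage: can the lineage's (ploidy, haplotype,
composition) be produced by a *single* hybridisation event between the
candidate parents, or does it require a more complex history (multiple
origins, backcrossing, introgression)?

## Models and procedures

### Clonality

Two samples are considered the same clone when their band difference is at
most a threshold `t`. Because scoring is noisy, `t` is not zero:
`suggest_threshold()` derives it either from the largest difference
observed among replicate scorings of the same individuals, or from the
left edge of the first gap in the histogram of all pairwise differences
(within-clone noise and between-genotype differences form separated
modes). Clones are the connected components of the "≤ t" graph — single
linkage, the only convention under which a threshold relation is
transitively consistent. Ties between the two suggestions should be
resolved toward the larger threshold (conservative lumping). Per
population we report the sample count `Nb`, the genotype count `Nb_geno`,
and the bias-corrected Nei genotype diversity

$$D_g = \frac{n}{n-1}\Bigl(1 - \sum_i (s_i/n)^2\Bigr),$$

which is exactly 1 when every individual is its own genotype — the reason
the bias-corrected form is used; the uncorrected form cannot reach 1.

### Fragment accounting

A group's fragment set contains every locus present in at least one
non-excluded member (replicate re-scorings never contribute). This
"≥ 1 member" convention is what standard AFLP tabulations use; whether a
frequency threshold would be more appropriate is data-dependent, so the
grouping input of `fragment_sets()` is fully caller-controlled. Shared
fragments between groups are reported with the *focal* group's fragment
count as denominator (the convention of published shared-fragment tables);
percentages are rounded half-up to two decimals as printed tables do. A
locus is private to a group if no other compared group carries it, and
hybrids are screened for how many of each parent's private bands they
carry.

### Haplotype networks

After removing excluded alignment regions (typically poly-A stretches,
whose length variation is scoring noise), indels are coded: every distinct
gap run that is column-identical across the sequences carrying it becomes
one binary character, weighted like a substitution (one step). The network
joins haplotype pairs in order of increasing step distance; a k-step join
inserts k−1 inferred intermediates; joins above the connection limit are
refused, and the resulting components are the haplotype groups. Within one
step level, every join not already implied by shorter paths is made, so
equal-step alternatives are retained as cycles — a network, not a tree.

The classical statistical-parsimony limit ("the 95% rule") depends on a
recursion we deliberately did not hard-code; the `"auto"` limit instead
uses a transparent heuristic — the probability that j observed steps over
L characters involve no superimposed or parallel change,
$\prod_{i<j}(L-2i)/(L-i)$, kept above 0.95 — which for alignments of a few
hundred characters yields limits around 6–8: one-step links always join,
links beyond about a dozen steps never do. The limit is an explicit,
testable integer parameter everywhere.

### Distances, splits, ordination

Between-genotype distances on dominant markers use the Jaccard
coefficient, `d = 1 − a/(a+b+c)`: shared absences are uninformative for
dominant data and are ignored. The Neighbor-Net circular split system is
estimated by the published agglomeration-plus-NNLS algorithm (delegated to
phangorn's implementation behind this package's `split_system` surface);
splits with weight ≤ 1e−6 are dropped as numerical dust, a configurable
floor mirroring viewer-side cleanup. The NEXUS writer emits SplitsTree
dialect Taxa/Splits blocks including the CYCLE line.

Because hybrid/parent relationships are not hierarchical, the ordination
anchors predefined reference groups first: group centroids are embedded by
classical scaling of their Euclidean centroid distance matrix (maximally
separated, since all their variance is retained in two dimensions), then
every sample is placed at the planar point minimising the squared
deviation between its planar distances to the anchors and its
original-space distances to the centroids. The solver is a deterministic
multi-start (anchors, anchor midpoints, a coarse grid) refined by BFGS, so
results are reproducible without a random initialisation. The historical
two-stage method this emulates is described only verbally in the
literature; our centroid-anchored scheme is an interpretation that
reproduces its documented behaviour (reference groups at the outer limits,
hybrids intermediate) and is switchable to plain metric scaling
(`mode = "mds"`). The mapping error is likewise defined verbally in the
sources; we use the sum-ratio form
$\sum_{i<j}|d^{2D}_{ij} - d_{ij}| \big/ \sum_{i<j} d_{ij}$, which is
scale-free and rigid-motion invariant.

### Ploidy from flow cytometry

Fluorescence ratio is proportional to genome size, hence within a species
proportional to ploidy: per species we fit `ratio = β·ploidy` through the
origin on the chromosome-counted references and attribute each sample the
integer k minimising `|ratio − βk|`. Samples whose peak CV is ≥ 5% are
excluded (unreliable measurements); a best-k relative residual above 3%
flags a possible aneuploid — at 1% measurement noise, true euploids
essentially never exceed 3%, while a 6.3x anorthoploid sits 5% from the
nearest integer. Species without any reference cannot be attributed and
say so rather than borrowing another species' calibration silently.

### The single-event test

For a lineage of ploidy p and haplotype group g, `enumerate_crosses()`
lists every (mother, egg, father, pollen) combination with egg+pollen = p
and the mother transmitting g, drawn from a `gamete_model()`: per
taxon/cytotype, the set of pollen ploidies (meiotic, so half the somatic
count) and egg ploidies — which may include unreduced, apomeiotically
formed eggs; unknown gamete modes are encoded simply as additional female
ploidies, with no attempt to simulate the reproduction pathway itself.
Crosses within one taxon are excluded by default (the question is
interspecific hybridisation) and can be enabled.

Each hypothesis carries an expected maternal genome fraction
f = egg/(egg+pollen). The composition clause then asks whether the
lineage's fragment evidence *contradicts* f. Leaning is measured on
**retention fractions** — the share of each candidate parent's own
fragments found in the lineage — not on the table-style shared
percentages: shared percentages are confounded by parental fragment-count
asymmetry (a band-rich parent wins them regardless of dosage), whereas
retention fractions of an additive hybrid are symmetric around the same
baseline and shift only with actual genomic contribution. With f above
0.5 + dead band the father's retention must not exceed the mother's by
more than a tolerance; below 0.5 − dead band, the reverse; inside the dead
band (default ±0.05) either leaning passes. Only a wrong-direction
difference larger than the tolerance (default 0.10 retention units) fails
the clause: band-scoring noise moves retentions by a few points, and a
tied composition does not contradict a proposed cross. A lineage is
`single-event` iff at least one hypothesis survives both clauses; every
failure is reported with its reason.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes, with all parameters in `sim_config()`:

| parameter | default | meaning |
|---|---|---|
| `n_loci` | 241 | scored fragments |
| `epsilon` | 0.0124 | per-band scoring error (mean repeatability 98.76%) |
| `loss` | 0.17 | parental-union bands absent from a hybrid |
| `denovo` | 0.024 | non-parental bands appearing in a hybrid |
| `fcm_noise` | 0.01 | relative fluorescence-ratio noise |
| `between_steps` | 8 | minimum haplotype-group separation (groups in real data sit several to a dozen steps apart) |
| `pop_size` | 10 | samples per population (field samplings of this kind run 5–27) |

The packaged `"alpicola"` scenario plants: two cytotypes of a band-rich
parental species (2x with a small fragment complement, 6x with a large
one), a second 4x parental species with the largest complement, an
outgroup control taxon, and three clonal hybrid lineages — an F1
pentaploid (2x egg × 3x pollen, maternal haplotype of the 4x species), a
hexaploid of complex origin carrying the hexaploid parent's haplotype
(impossible as a single model cross — the hexaploid's eggs are unreduced),
and a pentaploid built by three rounds of recurrent backcrossing toward
the 4x species, whose retention profile contradicts the unique
haplotype-compatible cross. Within-taxon band frequencies use a mixture of
near-fixed core blocks (0.95) and private blocks (0.97); real frequency
spectra are unknown for such data, so this is a repository convention
recorded in `scenario_profiles()`. Haplotype sequences evolve by unit
steps along a star per group (group-private substitutions plus one private
substitution per non-ancestral haplotype); indels are single-column,
group-shared gaps; no coalescent or substitution-model realism is
attempted. Per-species FCM slopes differ, forcing the per-species
regression.

What passing tests on this generator do **not** show about real data:
band-size homoplasy, peak-calling artefacts correlated across samples,
fragment-frequency spectra, null-allele dosage effects (the generator's
hybrids are strict unions — band presence carries no dosage signal, which
is precisely why the composition clause uses retention fractions),
segregation in sexual descendants, and isolation-by-distance structure.

## Numerical choices and degenerate inputs

* Percentages and diversities are rounded half-away-from-zero to the
  printed precision (2 and 3 decimals); all internal arithmetic is double
  precision.
* Clone clustering at threshold 0 reproduces the strict identical-pattern
  rule; an all-excluded population is an error, a replicate-free dataset
  yields an explicit "no replicates" result.
* Identical haplotypes (0 steps) are joined directly in the network;
  inferred intermediates always have degree ≥ 2.
* Neighbor-Net agglomeration ties are resolved deterministically by the
  backend; the weight floor suppresses NNLS dust.
* The ordination solver's multi-start grid is fixed by the anchor
  geometry, so placements are deterministic; coincident reference
  centroids produce a warning, not an error.
* Marker matrices are strictly binary — missing data are not representable
  in this version; replicate mismatch is the error model instead.

## Problem sizes

The shipped tests run the scenario at its defaults (about 70 samples × 241
loci, eight haplotypes, three planted lineages), 20 seeded replicates for
lineage/verdict recovery and split recovery on 8-taxon additive trees, 100
seeded replicates of hybrid placement in ordination, and 10⁴ loci for
additivity-rate recovery — sizes at which every recovery property is
sharply testable while the whole suite runs in well under a minute.

## Known limitations

* The composition clause is a one-sided contradiction test on retention
  fractions; it cannot *confirm* dosage, only refute a proposed cross, and
  inherits the union-band model's blindness to dosage.
* Statistical-parsimony limits use the documented heuristic, not the
  original recursion; for published-data comparisons set the limit
  explicitly.
* Genotype-diversity reporting covers `D_g` only (no clonal richness R,
  Psex, or rarefaction).
* The Neighbor-Net stage scales as the backend does (tens of taxa in
  seconds, hundreds noticeably slower); subset or group samples first for
  large matrices.
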