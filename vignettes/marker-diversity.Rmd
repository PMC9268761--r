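---
title: "Dominant-marker diversity analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominant-marker diversity analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerdiv)
```

## The problem

RAPD, ISSR and SCoT are *dominant* PCR marker systems: a gel lane either
shows a band at a given mobility or it does not, so each locus is scored as
presence (1) or absence (0) per genotype and heterozygotes cannot be told
apart from dominant homozygotes. Diversity surveys built on these markers —
here, five kalanchoe (*Kalanchoe blossfeldiana*) flower-colour genotypes
genotyped with four informative primers per system — reduce to a small
number of standard computations over the resulting binary band matrix, plus
a parallel analysis of morphological traits. `markerdiv` implements that
pipeline as tested, reusable functions, with the `analysis/` scripts
providing the narrative drivers and `scripts/acceptance.R` the reproducible
summary; there is no separate command-line executable because the functions
and scripts are the interface.

## Band-matrix statistics

A locus is **monomorphic** if the band is present in every genotype,
**unique** if present in exactly one, and **polymorphic** otherwise; unique
loci are counted inside the polymorphic class, so per primer
`monomorphic + polymorphic = total` always balances. The polymorphism
percentage of a primer is `100 * polymorphic / total`.

Two printing conventions of published marker tables are reproduced
deliberately, because the package aims to regenerate such tables cell for
cell:

* per-primer percentages are **floored** to integers (2 polymorphic of 3
  loci prints as 66%, 7 of 11 as 63%);
* the per-system average polymorphism is the arithmetic mean of those
  floored values (giving e.g. 60.25% for the RAPD block), reported raw and
  rounded half-up to two decimals.

Both the raw and the printed values are returned so the convention is
auditable. With the fixture's ISSR block the mean of floored percentages is
14.5%; sources that print whole percentages would show 15%.

The **RAPD/SCoT percentage fidelity** contrasts unique-band yield with
total-locus yield between two systems A and B:
`100·u_A/u_B − 100·l_A/l_B`, each term rounded half-up to two decimals
*before* the subtraction — again matching how the printed intermediate
values (80.00 and 39.47 for counts 4, 5, 15, 38) combine to 40.53. The
index is undefined (an error, not infinity) when the reference system has
no unique bands or no loci.

## Similarity and clustering

Genetic similarity between genotypes uses the **Dice coefficient**
`2a / (2a + b + c)` (a = shared presences, b and c = presences exclusive to
either genotype): joint absences are ignored, which is the appropriate
choice for dominant markers where absence is uninformative. Jaccard
(`a / (a + b + c)`) and simple matching (`(a + d) / n`) are provided for
sensitivity analysis; Dice ≥ Jaccard holds pairwise by algebra. Monomorphic
loci are *retained* in the computation — all scored loci contribute, and
dropping them would change the values. Distance is the complement `1 − S`;
no transform beyond that is applied, since agglomerative clustering only
consumes the pair ranking.

Clustering is **WPGMA**: iteratively merge the closest pair at height
`d/2`, then set the new cluster's distance to every other cluster to the
unweighted mean `(d_ik + d_jk)/2` (UPGMA, which weights by cluster size, is
available as an option). Design choices worth stating:

* **Tie-breaking** is deterministic: among equally close pairs, the pair
  whose lexicographically smallest member label is smallest wins (then the
  larger label decides). Legacy GUI packages that popularized WPGMA do not
  document their internal order, so reproducibility requires fixing one.
* **Node height = merge distance / 2**, the standard ultrametric
  convention, so the cophenetic distance between two leaves (twice the
  height of their lowest common ancestor) reproduces the merge distance,
  and Newick branch lengths are parent height minus child height.
* **k-cluster extraction** removes the k − 1 highest merges (later merges
  first on ties) rather than cutting at a height, because published
  memberships are reported as "two groups", "three clusters" without axis
  values.

WPGMA's update is reducible, so merge heights never invert; this is
asserted on random matrices in the test suite, along with equality against
a brute-force re-implementation of the recurrence and against
`hclust(method = "mcquitty")`.

## Morphological arm

Six traits are analysed (`plant_height_cm`, `n_inflorescences`,
`n_flowers`, `flower_length_cm`, `flower_diameter_mm`, `n_petals`). For
each trait a one-way ANOVA across genotypes provides the pooled
within-group mean square; a pair of genotypes differs significantly when
its mean difference exceeds **Fisher's LSD**
`t(1 − α/2, df_within) · sqrt(MSE (1/n_i + 1/n_j))` at α = 0.05. The
method is the *unprotected* LSD with a common error term — that is what a
compact letter display over a single pooled analysis requires — with a
plain pairwise-t option for comparison. Where a source's methods text says
"Student t-tests" but its figures annotate Fisher's LSD letters, the letter
display fixes the interpretation, and that is what is implemented. The
familywise error of the unprotected procedure under a global null is
measured (not asserted tightly) in the test suite: with 5 equal groups it
sits between the per-test α and the 10-comparison upper envelope.

The **compact letter display** uses the insert-and-absorb algorithm: start
with one letter column containing all genotypes; for each significant pair
split every column containing both members into two columns (each missing
one member); absorb columns that became subsets of others. The resulting
invariant — two genotypes share a letter *iff* their comparison is
non-significant — is verified by reconstruction on random significance
patterns. Letters are assigned in group-appearance order by default (an
`order_by` argument letters the highest mean "a" instead).

The trait dendrogram uses **z-scored trait means** (across genotypes) under
Euclidean distance. Standardization is on by default because the traits mix
centimetres, millimetres and counts up to ~321 flowers; without it the
flower count dominates the geometry. A constant trait cannot be z-scored
and is dropped with a warning. Flower-level traits enter as per-plant means
(50 flowers per plant, 10 plants), so every trait has n = 10 replicates per
genotype; the generator also supports per-flower replication if one prefers
n = 500.

## The synthetic generator and the fixture

No gel-scored matrix or raw trait data are published for this study system,
so the generator is a first-class module rather than a test convenience.
`band_spec()` fixes, per primer block, the exact number of monomorphic,
unique and intermediate polymorphic columns; `generate_band_matrix()` emits
all-ones columns, single-carrier columns (owner uniform, or restricted to
an `unique_owner_pool`), and intermediate columns whose carrier count is
uniform on 2..n−1 with a uniform carrier set (or drawn from `carrier_sets`,
which plants group structure). Uniform carrier draws are the
least-informative choice consistent with the published counts, which say
nothing about the band-frequency spectrum. Classification of a generated
matrix recovers the spec's counts *exactly*, by construction — the
round-trip property the tests exercise over hundreds of random specs.

`kalanchoe_fixture()` encodes the published survey shape: five genotypes
(red, yellow, purple, orange, violet), twelve primer blocks totalling 70
loci (RAPD 15 = 5 + 10 with 4 unique; ISSR 17 = 14 + 3 with 0 unique; SCoT
38 = 16 + 22 with 5 unique), and a trait spec embedding the published
maxima (yellow 40 cm height; orange 9 inflorescences, 321 flowers, 2.1 cm
flower length; violet 40 petals). The remaining trait means are synthetic
values chosen once to echo the reported significance pattern (e.g. orange
and violet lead the flower traits; red, yellow and purple trail), with
standard deviations of 3 cm (height), 1 (inflorescences), 30 (flowers),
0.1 cm (length), 1.5 mm (diameter) and 1 (petals) as plausible
between-plant spreads; replicate noise is independent Gaussian, which is
all that mean ± SE reporting constrains. With noise-free means the
morphological WPGMA tree splits {orange, violet} from {red, yellow,
purple}, matching the published two-cluster reading; under replicate noise
that split is recovered in roughly 70% of draws (the acceptance script
measures the rate over 50 datasets).

What passing on synthetic data does and does not show: the fixture
guarantees the *counting*, *index* and *table* layers reproduce published
cells exactly, and that clustering recovers structure that is genuinely
planted; it cannot validate band calls from real gels, scoring errors,
co-migrating fragments, or the actual band patterns of the five genotypes,
which were never published. Similarity values and dendrograms on the
fixture are therefore self-consistent realizations, not historical values.

## Numerical conventions and degenerate inputs

* Percentages: flooring for per-primer prints; half-up rounding (not
  banker's) where two-decimal prints are matched.
* All-zero locus columns are rejected, not dropped — a scored band must be
  visible in at least one lane.
* A genotype with no bands makes Dice/Jaccard undefined and errors with the
  genotype named.
* Zero within-group variance with equal means yields one shared letter (the
  F-test is vacuous and its "perfect fit" warning suppressed); α = 1 warns
  and flags every non-zero difference.
* Problem sizes in the checks: random matrices up to 6 genotypes / 20 loci
  for coefficient oracles, 200 random distance matrices for the WPGMA
  oracle, 100 seeds for planted-structure recovery, 500 random specs for
  the generator round-trip — sizes at which brute-force oracles are exact
  and fast.

## Limitations

* WPGMA on a distance matrix is phenetic clustering; despite the word
  "phylogenetic" often attached to such dendrograms, no evolutionary model
  is involved.
* The fidelity index is reproduced as defined, including its rounding
  before subtraction; it is a descriptive contrast, not a statistic with
  sampling theory.
* The unprotected LSD does not control familywise error; the test suite
  quantifies this rather than hiding it.
* Fixture trait values other than the published maxima are synthetic; LSD
  letter patterns on the fixture resemble, but cannot replicate, the
  published figure annotations.
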