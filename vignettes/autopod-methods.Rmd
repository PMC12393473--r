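---
title: "Methods: surveying human-specific evolution in autopod regulatory elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying human-specific evolution in autopod regulatory elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autopodreg)
```

## The problem

The bones of the human hand and foot differ from those of chimpanzee
and gorilla in proportions — digit I robustness, shortened foot
phalanges — that are established while embryonic chondrocytes build the
growth plates of each skeletal element. The regulatory elements active
in those chondrocytes are therefore a natural place to look for the
genomic changes behind human autopod evolution. `autopodreg`
implements the analytical chain from a developmental chromatin
accessibility atlas to counts of human-lineage-specific sequence
change, entirely against synthetic data with planted truth, so every
stage can be verified end to end.

## The accessibility model

An atlas couples one master list of regulatory elements (a merged peak
universe shared by all samples) with a boolean matrix over conditions
labelled `limb.digit.region.timepoint` — 2 limbs × 5 digits × 2
proximal-distal regions (phalanges vs metapodial) × 2 timepoints = 40
conditions. Element identity across conditions is by identical merged
coordinates; all sharing statements are element-level, not
base-level.

Three classifications are built on this matrix:

* **brain filtering** removes any element overlapping an embryonic
  brain peak by ≥ 1 bp, whole elements rather than overlapping bases,
  because peak-level filtering is the right granularity for removing
  housekeeping regulatory activity from a peak universe;
* **specificity**: an element is *autopod-specific* when it overlaps no
  peak from any other developing skeletal tissue, and *tissue and
  timepoint specific* when it is accessible in exactly one tissue,
  where a tissue is a (limb, digit, region) combination and
  accessibility at one or both of that tissue's timepoints counts once
  — the two flags are independent;
* **axis partitions** split a set three ways along one axis (e.g. hand
  only / foot only / shared), a disjoint cover asserted on every run.

The sharing profile groups elements by their exact condition
combination, drops combinations with fewer than 5 elements (the default
reporting threshold), and tallies the rest by the number of distinct
tissues accessible early and late.

## The fixed-substitution survey

The survey estimates a lower bound on the number of single-base changes
fixed on a lineage inside a set of regulatory elements, using a
target/sister/outgroup genome trio (e.g. human/chimp/gorilla). The
pipeline order matters and is fixed:

1. **Standardise**: every element is re-centred on the floor of its
   midpoint and resized to exactly 500 bp, so element-length
   differences between sets cannot masquerade as rate differences.
   Windows that would leave the chromosome are rejected, not clamped —
   clamping would silently break the fixed length. The anchor
   (midpoint) is our choice; nothing downstream depends on it as long
   as it is deterministic.
2. **Mask**: every position polymorphic within any of the three species
   at minor-allele frequency strictly above 0.05, and every blacklisted
   base, is subtracted. Current allelic variation cannot explain fixed
   interspecific differences, so segregating sites are evidence of
   non-fixation and must not be counted; the strict inequality keeps
   sites at exactly 0.05. Subtraction may split an element into
   fragments; each fragment keeps its parent's identity.
3. **Map**: each fragment must lift to *both* non-target genomes along
   its entire length (`min_match = 1`) at a single locus; multiple
   candidate chains are an orthology ambiguity and a rejection, unlike
   the cross-species atlas comparison, where multiple matches and
   `min_match = 0.1` are appropriate because the question there is
   permissive sharing, not base-level orthology.
4. **Identity gate**: aligned fragments need ≥ 25% identity between
   the target sequence and each counterpart. 25% is the expected match
   of random equal-length nucleotide sequences, so anything below it
   indicates alignment failure rather than divergence. The gate is
   applied as AND across the two comparisons by default (the
   conservative reading); a config switch (`identity_mode = "or"`)
   exposes the alternative. The gate only excludes fragments — it
   never changes calls on fragments that pass, which is asserted by a
   dedicated test.
5. **Call**: position *i* is derived on the target lineage iff
   `target[i] != sister[i]` and `sister[i] == outgroup[i]`, with any N
   suppressing the call. Swapping the roles of target and sister
   counts the sister lineage's derived bases on the same surveyed
   fragments; because the two lineages have evolved for the same time
   since their common ancestor, the two counts are directly
   comparable.

Reported quantities per set and lineage: surveyed bp (accepted
fragments only), derived count, rate per bp, rejection tallies by
reason, and conservation scores at derived positions. Scores come from
a sparse track; positions without a score are excluded and counted,
never imputed as zero. The shift test is a two-sided Wilcoxon rank-sum
on the two score vectors.

## What the generator emulates, and what it does not

`simulate_trio()` draws a uniform-ACGT ancestor and plants: fixed
substitutions on the target and sister branches (each at a distinct
position, and disjoint between the branches — a position hit on both
branches would be parsimony-uninformative and would make the planted
truth unrecoverable by any method, so we exclude it by construction);
per-species polymorphic sites with MAF uniform on (0, 0.5), which may
coincide with planted fixed sites — the collision is the interesting
masking test case; and deletion blocks in sister and outgroup that
create chain gaps. Chains are emitted in both the UCSC and the TSV
dialect to exercise both readers. Variant catalogs are reported on
target coordinates, as real catalogs are after lifting.

Defaults state the world once: 1 Mb chromosome, 200 target / 150 sister
substitutions (per-bp rates of the order seen between human and chimp
in accessible regions), 100 polymorphic sites per species, 500 bp
elements so that standardisation is the identity in clean tests. The
generator does **not** model mutation-rate heterogeneity, CpG
hypermutability, context dependence, recombination or demography; a
green planted-truth test establishes that the bookkeeping (masking,
liftover, parsimony calls, aggregation) is exact, not that the
procedure is robust to alignment error or rate variation in real
genomes.

`simulate_atlas()` draws each element's condition combination from a
stated mixture; the default mixture (a broadly accessible core, limb-,
region- and timepoint-restricted blocks, two single-tissue-specific
blocks) reproduces the qualitative structure of developing-skeleton
atlases — most elements broadly accessible, a minority tissue- and
timepoint-specific. `simulate_score_track()` plants a mean shift at
constrained positions over Gaussian noise; `simulate_measurements()`
plants known interspecific scale factors.

## Numerical and design choices

* Coordinates are 0-based half-open throughout (BED convention); 1 bp
  suffices for overlap; abutting intervals do not overlap and are not
  merged unless a gap tolerance is configured (default 0).
* Differential-activity arithmetic rounds to the nearest integer, half
  away from zero — the only rule consistent with the published pairs
  (886 × 0.08 = 70.88 → 71 and 157 × 0.08 = 12.56 → 13).
* The gene-expression filter is inclusive (≥ 10 normalised units).
* Pairwise enrichment differences default to a two-sided Fisher exact
  test on base-level 2×2 tables (count vs covered-bp complement); the
  published analysis does not name its test, so the choice is ours,
  and a within-footprint permutation mode is exposed for sensitivity.
  Feature enrichment counts features per covered bp; splitting elements
  into abutting fragments cannot change a rate.
* Percent anatomical change pools raw proximal- and middle-phalanx
  measurements per digit before taking species means, and divides
  pooled means (not per-individual ratios, which are meaningless across
  unmatched skeletons); reciprocal changes multiply to 100² exactly.
* Overlap summary tables report both tallies — elements overlapped and
  distinct features hit — since summary counts of this kind are
  ambiguous between the two readings.
* Liftover rejections are never silent: `no_coverage`,
  `below_min_match`, `multiple_hits` at the mapping level;
  `standardize_out_of_bounds`, `unmappable_sister`,
  `unmappable_outgroup`, `low_identity` at the survey level.
* Configuration is JSON (not YAML) so the pipeline has no dependency
  outside core Bioconductor plus `jsonlite`; one config plus one seed
  determines every output byte.

## Limitations

Masked-fragment shortness is not penalised: fragments of any length
face the same full-length mappability rule, and no minimum surveyed
length is imposed. The survey counts substitutions only — structurally
divergent and unalignable regions are excluded by construction, so all
counts are lower bounds. The per-bp enrichment test treats bases as
independent trials, an approximation that is anticonservative for
strongly clustered features. Genome-scale performance was not a goal:
the per-base alignment path is linear in surveyed bases and comfortable
at the megabase scale of the test suite, not at whole-genome scale.
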