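---
title: "Dominant-marker diversity analysis with scotdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominant-marker diversity analysis with scotdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Dominant molecular markers — SCoT, ISSR, RAPD and relatives — score each
locus as band presence (1) or absence (0) on a gel. Heterozygotes cannot be
distinguished from band-carrying homozygotes, so the data are a binary
accessions × bands matrix, and everything downstream must be built on band
(phenotype) frequencies rather than genotypes. `scotdiv` implements the
complete analysis such a matrix supports: marker informativeness, genetic
similarity and clustering, ordination, isolation-by-distance testing,
diversity partitioning within/between groups, AMOVA with Φ~PT~, a
closed-form G~ST~ partition, and post-processing of Bayesian
admixture-clustering output.

The package was built around a germplasm survey of whipgrass (*Hemarthria
compressa*), a hexaploid forage grass from southwest China: 37 clones in
four unbalanced geographic groups (GZ 7, CQ 9, CDP 13, YL 8), fingerprinted
with 25 SCoT primers producing 368 bands of which 282 (76.6%) were
polymorphic. The accession metadata ships as
`whipgrass_accessions()`; the published per-primer and per-group summary
tables ship under `inst/extdata/` and the raw 0/1 matrix, which was never
deposited, is emulated by the simulator (see below).

# Marker informativeness

With `f` the presence frequency of a band across accessions, per-band
statistics are

* PIC (polymorphic information content) `= 2 f (1 − f)`, bounded by 0.5 —
  the dominant-marker ceiling, reached at `f = 0.5`;
* Shannon diversity `H = −[f ln f + (1 − f) ln(1 − f)]` in nats (two-state
  entropy: presence and absence terms both count), bounded by `ln 2`;
* band informativeness `Ib = 1 − 2|0.5 − f|`.

`primer_summary()` aggregates per primer: TNB and NPB (total and
polymorphic band counts; polymorphic means `0 < f < 1`, with no
minor-frequency threshold since none is standard), `PPB = 100·NPB/TNB`,
mean H and PIC **over the polymorphic bands only**, the marker index
`MI = NPB × mean PIC` (effective multiplex ratio times diversity index),
resolving power `Rp = Σ Ib` over all the primer's bands, and the genotype
index GI: the number of distinct banding profiles the primer alone induces,
divided by the number of accessions.

Averaging H and PIC over polymorphic bands only is a deliberate choice.
Including monomorphic bands (which contribute 0) would make a primer-level
mean PIC of, say, 0.386 at TNB 17 / NPB 9 imply a per-polymorphic-band mean
of about 0.73 — above the 0.5 ceiling — so published per-primer tables of
this kind are only internally consistent under the polymorphic-only
convention, and `MI = NPB × PIC` then holds within rounding.

Two collection-wide polymorphism rates are distinct and both reported by
`primer_summary()`: `100·ΣNPB/ΣTNB` (band-weighted; 76.63% for the survey
table) and the unweighted mean of per-primer PPB (77.21%). Published
abstracts often quote one while tables imply the other; keeping both avoids
the ambiguity.

`index_correlations()` gives pairwise Pearson r (with two-sided t-based
p-values) among PIC, Rp, MI, GI and H; zero-variance columns yield `NA`,
never 0.

# Similarity, clustering, ordination

`nei_li_similarity()` is the Dice-style coefficient `GS = 2a/(2a + b + c)`
on shared (`a`) and private (`b`, `c`) presences; `GD = 1 − GS`. Two
all-zero profiles get `GS = 1`: the formula is 0/0 there and identity is
its natural limit (the case is flagged with a warning at matrix level).

`upgma()` is written in the package rather than delegated to
`stats::hclust` because its contract pins down two things `hclust` leaves
open: merge heights equal to half the merge distance (so the tree is
ultrametric with leaf-to-node depth = d/2), and a deterministic tie-break
(the smallest pair of cluster indices in the current ordering). Agreement
with average-linkage `hclust` on tie-free inputs is verified in the test
suite. `bootstrap_supports()` resamples **bands** (columns) with
replacement — loci are the sampled characters in marker data — and reports
each original clade's replicate frequency as a percentage.

`pcoa()` wraps the classical Gower double-centering eigendecomposition
(`stats::cmdscale`). Nei–Li distances need not be Euclidean-embeddable, so
negative eigenvalues can and do occur; they are reported untouched and
excluded from the percent-variance denominator. No Lingoes/Cailliez
correction is applied — the low variance percentages typical of dominant
data (≈5–10% per axis) are a property of the data, not an artifact to be
corrected away.

# Isolation by distance

`geographic_distance_matrix()` computes haversine great-circle distances
(Earth radius 6371 km) and excludes — listing them — accessions without
coordinates (here the cultivars Guangyi and Chonggao, which have no wild
provenance). `mantel()` correlates the strict lower triangles and permutes
rows+columns of the second matrix jointly; the p-value is **one-sided,
upper tail**, `(#{r_perm ≥ r_obs} + 1)/(n_perm + 1)`, with an epsilon so
tied permutations (the identity among them) count in the tail. A p near 1
therefore means the observed correlation is *smaller* than almost all
permutations. The granularity of p is `1/n_perm`; with 10,000 permutations
the largest reportable value is 0.9999, which is how a "no IBD" verdict
prints at that setting.

# Diversity partitioning

`shannon_partition()` works on the globally polymorphic band set. Per
group, `H_zone` is the mean two-state entropy of within-group frequencies
(bands fixed inside a group contribute 0 — keeping the band set identical
across groups is what makes the pooling inequality `H_A ≤ H_W` hold);
`H_A` is the unweighted mean of `H_zone` over groups, `H_W` the entropy of
the pooled frequencies, and the intra-/inter-group components are
`H_A/H_W` and `(H_W − H_A)/H_W`.

`group_difference_test()` compares groups by treating per-band `H_zone`
values as replicates, with unpaired mean-difference permutation tests per
pair and a compact letter display at α = 0.05 and 0.01. A permutation test
was chosen over classical ANOVA because per-band entropies are bounded and
skewed; normality is not defensible at typical band counts.

`gst_partition()` provides a transparent closed-form Nei-style partition
in place of a Bayesian MCMC estimator: per band and group, the band-allele
frequency `p` is solved from the absence frequency under a diploid
dominant-phenotype model with optional inbreeding `f`
(`freq(absent) = (1−p)² + f·p(1−p)`; at `f = 0` this is the square-root
estimator `p = 1 − √freq(absent)`), `H = 2p(1−p)` per band, `H_S` per
group is the mean over bands, `H_T` comes from the unweighted group-mean
allele frequencies, and `G_ST = (H_T − H̄_S)/H_T`. `gst_summary()` exposes
the bare partition arithmetic for externally estimated heterozygosities.
The diploid model is applied although most whipgrass accessions are
hexaploid: no dosage model for aneu-polyploid dominant bands is
established, and the diploid form is the field's convention. This is a
documented limitation, not an oversight — absolute `p` estimates are
biased for polyploids, while the partition ratios are far less sensitive.

# AMOVA and Φ~PT~

For binary profiles the squared Euclidean distance is the mismatch count.
`amova_fit()` implements the two-level decomposition:
`SS_total = Σ_{i<j} d_ij / N`, within-group sums analogously,
`SS_between` by subtraction; `df = (k − 1, N − k)`;
`σ²_w = MS_within`, `σ²_a = (MS_between − MS_within)/n₀` with
`n₀ = (N − Σn_g²/N)/(k − 1)` for unbalanced designs; and
`Φ_PT = σ²_a/(σ²_a + σ²_w)`. Negative between-group components are
truncated to zero and flagged (the standard convention).
`amova_permutation()` shuffles whole-accession group labels — the only
exchangeable unit in a two-level design — with the same `+1` upper-tail
rule as the Mantel test. `pairwise_phipt()` repeats the two-group analysis
per pair; p-values are unadjusted by default with an optional sequential
Bonferroni (Holm) column, since pairwise Φ~PT~ tables are conventionally
reported raw.

The test suite checks `amova_fit` against a brute-force oracle that
computes sums of squares from explicit deviations-from-centroid in 0/1
coordinate space (valid precisely because the distances are squared
Euclidean), and calibrates the permutation test's type-I error at 5% over
200 seeded null simulations.

# Admixture-clustering post-processing

The clustering MCMC itself is out of scope; `scotdiv` consumes its
outputs. `evanno_delta_k()` computes
`ΔK = |L̄(K+1) − 2L̄(K) + L̄(K−1)| / sd(L(K))` with means over runs and the
sample (n−1) standard deviation; endpoints are `NA` by construction and a
zero run-to-run deviation makes ΔK undefined (flagged), not infinite.
`assign_memberships()` applies a membership threshold in (0.5, 1] — above
0.5 so at most one cluster can qualify — assigning each accession to the
cluster whose proportion strictly exceeds the threshold and labelling the
rest admixed. Raising the threshold is monotone: it can only move
accessions into the admixed class.

# The simulator

`simulate_band_matrix()` generates matrices with the statistical structure
the analysis assumes, so every stage is testable without the unpublished
raw matrix. Its defaults are the survey's design and are not tuned
per-analysis: groups of 7/9/13/8, 25 primers with 5–24 bands each,
ancestral presence frequencies uniform on [0.05, 0.95], differentiation
`F = 0.08` (inside the weak 0.05–0.15 Φ~PT~ band such surveys report), and
22% appended monomorphic (all-present) bands, matching a ~77% polymorphism
rate — random uniform-frequency columns at n = 37 go monomorphic by chance
with probability below 1%, so the appended fraction carries the rate.
Group frequencies follow the Balding–Nichols parameterisation: Beta with
mean equal to the ancestral frequency and variance `F·p(1−p)`, a point
mass at `F = 0`. The default "phenotype" mode draws band presence directly
from the group frequency — appropriate for a hexaploid where no dosage
model exists — while "diploid-dominant" mode draws two alleles and shows
the band unless homozygous null, exercising the allele-frequency
estimator's recovery.

`simulate_coordinates()` places group centroids uniformly in a box
spanning the collection region (lat 25–31, lon 101–108) and jitters
accessions around them (sd 0.35°). Isolation by distance is induced by
blending in a 2-axis metric embedding of a supplied genetic distance
matrix, with blend weight `ibd_strength`. One subtlety the tests document:
a Mantel "null" calibration needs structureless genetics (`F = 0`).
With `F > 0` and geographically clumped groups, the genetic and geographic
matrices share group structure even at `ibd_strength = 0`, and the Mantel
test correctly reports that confounding — a caution that applies equally
to real surveys whose groups are both genetically and spatially clustered.

What the simulator does **not** emulate: linkage between bands (bands are
independent given frequencies), gel-scoring error and co-migration, band
intensity, and polyploid allele dosage. Passing tests therefore show the
statistics are computed correctly under the stated model, not that the
model captures every feature of real gels.

# Numerical choices and problem sizes

Key conventions, gathered in one place: natural logarithms throughout;
polymorphism is `0 < f < 1`; UPGMA ties broken by smallest cluster index
pair; all-zero-profile similarity is 1; permutation p-values use the `+1`
correction and upper tail, with a 1e-12 epsilon for ties; negative AMOVA
components truncate to 0 with a flag; negative PCoA eigenvalues are
reported, never corrected; ΔK uses the sample standard deviation. Every
randomised routine takes an explicit seed and is bit-reproducible from it.

The shipped tests and the acceptance script use survey-sized problems
(37 × ~300–400 matrices), 999-permutation tests, tens of seeds for
calibration medians and 200 seeds for the type-I check — sizes chosen so
the whole suite re-runs in well under a minute per module while keeping
binomial error on calibrated rates a few percentage points.
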