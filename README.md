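# scotdiv

Genetic diversity analysis for **dominant molecular markers** — SCoT, ISSR,
RAPD and similar fingerprinting systems that score each locus as band
presence (1) or absence (0). Because heterozygotes are invisible in such
data, every statistic must be built on band frequencies; `scotdiv`
implements the full standard battery on a single binary band matrix:

* **Marker informativeness** per primer: TNB/NPB/PPB, Shannon diversity
  `H = −[f ln f + (1−f) ln(1−f)]`, `PIC = 2f(1−f)` (max 0.5 for dominant
  bands), marker index `MI = NPB × PIC`, resolving power
  `Rp = Σ(1 − 2|0.5 − f|)`, genotype index GI, and Pearson correlations
  among the indices.
* **Relatedness**: Nei–Li similarity `GS = 2a/(2a+b+c)`, UPGMA clustering
  with band-resampling bootstrap supports and Newick export, principal
  coordinate analysis, haversine geographic distances, and a one-sided
  permutation Mantel test of isolation by distance.
* **Diversity partitioning**: Shannon partition
  (`H_A/H_W` within, `(H_W − H_A)/H_W` between groups) with permutation
  letter-display group comparisons, and a closed-form Nei-style
  `G_ST = (H_T − H̄_S)/H_T` from square-root (or inbreeding-adjusted)
  allele-frequency estimates.
* **AMOVA** on squared Euclidean (mismatch) distances with unbalanced-design
  variance components, `Φ_PT = σ²_a/(σ²_a + σ²_w)`, label-permutation
  p-values and pairwise group Φ_PT.
* **Admixture post-processing**: Evanno
  `ΔK = |L̄(K+1) − 2L̄(K) + L̄(K−1)|/sd(L(K))` for choosing K, and Q-matrix
  membership assignment with a >0.6-type threshold.
* **A Balding–Nichols simulator** of band matrices (group frequencies Beta
  around an ancestral frequency with variance `F·p(1−p)`) plus coordinate
  simulation with tunable isolation-by-distance, for power and calibration
  studies.

The package grew around a 37-accession whipgrass (*Hemarthria compressa*)
germplasm survey from southwest China (4 geographic groups of 7/9/13/8,
25 SCoT primers, 368 bands); that collection's metadata ships as
`whipgrass_accessions()` and its published per-primer and per-group summary
tables ship under `inst/extdata/`.

## Worked example

```r
library(scotdiv)

sim    <- simulate_band_matrix(sim_config(seed = 42))  # survey-shaped data
m      <- sim$matrix
groups <- setNames(sim$records$group, sim$records$code)
m
#> band_matrix: 37 accessions x 342 bands (25 primers)
#> polymorphic bands: 252 (73.7%)

ps <- primer_summary(m)
head(as.data.frame(ps), 3)
#>   primer TNB NPB      PPB         H       PIC       MI       Rp        GI
#> 1    P01  21  17 80.95238 0.5445400 0.3660895 6.223521 9.243243 1.0000000
#> 2    P02   9   8 88.88889 0.5054054 0.3378378 2.702703 4.378378 0.6486486
#> 3    P03   5   4 80.00000 0.5287497 0.3593864 1.437546 2.432432 0.2702703

similarity_matrix(m)
#> similarity_matrix: 37 accessions; GS range 0.718-0.834, mean 0.773

amova_permutation(squared_euclidean_matrix(m), groups, n_perm = 999, seed = 42)
#>                df       SS     MS Est.Var     PVC
#> Between groups  3  260.310 86.770   4.583   9.20%
#> Within groups  33 1492.717 45.234  45.234  90.80%
#> Total          36 1753.027     NA  49.817 100.00%
#> Phi_PT = 0.092, p = 0.001 (999 permutations)

shannon_partition(m, groups)
#> Shannon diversity partition over 252 polymorphic bands
#>     H_zone
#> CDP 0.4913
#> CQ  0.4853
#> GZ  0.4503
#> YL  0.4551
#> H_A = 0.4705, H_W = 0.5549; within 84.80%, between 15.20%

pcoa(genetic_distance(similarity_matrix(m)))
#> pcoa_result: 37 points, 3 axes (9.61%, 7.94%, 7.00% of positive eigenvalue mass)
#> 3 negative eigenvalue(s) reported, not corrected
```

Reading the output: the simulated collection behaves like the survey it
emulates — three-quarters of bands polymorphic, per-primer mean PIC near
the 0.358 neighbourhood (below the 0.5 dominant-marker ceiling), weak
group differentiation (`Φ_PT ≈ 0.09`, significant because even small
structure is detectable with 342 bands), ~85% of Shannon diversity within
groups, and a flat ordination (first axis under 10% of variance) typical
of dominant fingerprints.

A thin command-line front end over the same functions lives at
`inst/cli/scotdiv.R` (subcommands `stats`, `tree`, `pcoa`, `mantel`,
`partition`, `amova`, `structure-post`, `simulate`).

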