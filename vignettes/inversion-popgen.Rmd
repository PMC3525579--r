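---
title: "Methods: inversion-partitioned population genetics along clines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inversion-partitioned population genetics along clines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Chromosomal inversions suppress recombination in heterokaryotypes: a single
crossover inside the inversion loop yields unbalanced gametes, so loci inside
an inverted segment exchange alleles between arrangements only through rare
double crossovers and gene conversion. When arrangement frequencies follow
latitudinal clines — as they famously do in *Drosophila subobscura* — the
natural analysis unit is not the population but the population × arrangement
group of phased chromosomes. `invclines` implements that analysis end to
end: gene diversity per group, haploid F~ST~ partitioned between and within
arrangements, marker–inversion and inter-locus linkage disequilibrium,
latitudinal cline and isolation-by-distance regressions, and an
fdist-style F~ST~-outlier scan, plus a synthetic-data generator that
emulates the sampling design so every stage is testable without field data.

Inputs are plain text: a haplotype table (one row per phased wild
chromosome, alleles as microsatellite fragment sizes in bp), a locus map
(chromosome, cytological order, inside/outside status per arrangement) and
population metadata (decimal latitude/longitude). `study_design()` ships the
nine-population, three-chromosome, 19-locus design used as the default
everywhere; its longitudes are gazetteer values for the nine towns, since
the survey it mirrors printed only latitudes, so geographic distances (and
hence IBD slopes) are approximate by construction.

## Estimators

**Gene diversity.** `gene_diversity()` is Nei's unbiased haploid estimator
He = n/(n−1)(1 − Σp̂²); the biased variant (no n/(n−1)) is kept for
frequency tables that come without sample sizes, and
`arrangement_diversity()` applies the same estimator to arrangement
frequencies treated as alleles of a pseudo-locus. The arcsin–square-root
transform (radians) is attached wherever a quantity feeds a latitude
regression, stabilising the variance of frequency-like responses.

**Haploid θ.** `fst_theta()` computes, per locus and allele indicator, the
one-way ANOVA sums of squares SSA = Σ n_k(p_ku − p̄_u)² (df r−1) and
SSW = Σ n_k p_ku(1 − p_ku) (df n−r), with n_c = (n − Σn_k²/n)/(r−1), and
forms σ²_a = (MSA − MSW)/n_c and σ²_w = MSW. Loci and alleles are combined
as a ratio of summed components (Weir–Cockerham convention), never a mean of
ratios. This is mathematically the haplotypic AMOVA F~ST~ with
allele-identity distance; we standardise on θ rather than re-implementing
AMOVA's SSD bookkeeping, and the test suite pins the estimator to a
brute-force ANOVA-on-indicators oracle over every small two-group biallelic
table. Negative estimates are retained in pairwise matrices (they are
information, not errors) and clamped only inside the PCoA, which treats θ as
a squared dissimilarity and Gower-centres −θ/2 before eigendecomposition.

One property worth knowing: when "between-arrangement" θ is computed over
all population × arrangement groups jointly (the convention of the original
haplotypic-AMOVA analyses, which we follow), the presence of several
populations per arrangement dilutes the among-group variance relative to the
arrangement-level divergence parameter. Recovering the generator's `F_arr`
as θ therefore requires comparing the arrangements themselves as units (one
pooled group per arrangement); the parameter-recovery tests do exactly that,
while the pipeline reports the conventional partition.

**Permutation tests.** `fst_permutation_test()` permutes haplotypes among
the compared groups (sizes preserved) and reports
p = (1 + #{θ\* ≥ θ})/(B+1); `partition_fst()` compares per-locus between-θ
against mean within-θ with an exact one-sided paired Wilcoxon signed-rank
test (pairing per locus; with m loci all concordant the exact p is 1/2^m).
The "between > within" contrast is one-sided by design: the scientific
question is whether inversions structure variation beyond geography.

**Linkage disequilibrium.** `dm_statistic()` implements the multiallelic
D′m = Σ_ij p_i q_j |D′_ij| (Hedrick's extension of Lewontin's D′, each cell
normalised by its sign-dependent bound); the inversion enters as a
pseudo-locus whose alleles are the frequent arrangements. Significance is a
Monte-Carlo Fisher exact test: the statistic is the table's conditional
hypergeometric log-probability and category labels are permuted, matching
the "exact test by permutation" practice of the classic software chain.
Interallelic patterns use 2×2 collapses per (allele, arrangement) cell with
Yates-corrected χ²; associations carried by fewer than `min_obs = 3` joint
observations are flagged unreliable regardless of p, a guard against
rare-cell artefacts. FDR control defaults to Benjamini–Yekutieli (the
conservative choice recommended for population-genetic scans), with
Benjamini–Hochberg optional; both delegate to `stats::p.adjust`.

**Ohta's decomposition.** For a locus pair over k subpopulations with
observed gametic tables, `ohta_components()` returns D²_IS, D²_ST, D′²_IS,
D′²_ST and D²_IT built from unweighted subpopulation means (a
sample-size-weighted mode exists but is non-default, following the LinkDos
convention). The identity D²_IT = D′²_IS + D′²_ST holds exactly by
construction and is asserted to 1e−12 in the tests. Reading the components:
drift scatters LD directions across populations (D′²_IS ≫ D′²_ST), while
systematic epistatic selection aligns them (D′²_ST large, D′²_IS near
sampling noise).

**Clines and geography.** Distances are haversine on a 6371-km sphere
(via `geosphere`). IBD regresses pairwise θ on log10 km — the base only
rescales the slope; R² and the Mantel p are base-invariant — with
significance from permuting population identities (rows and columns
together), one-sided on positive slope. Allele clines follow the MCA/SMCA
protocol: rank alleles by unweighted mean frequency across populations
(ties broken toward the smaller fragment size, a convention the source
material leaves open), regress asin(√freq) on latitude, and FDR-correct the
whole batch. Arrangement frequencies get degree-1 fits on the same scale;
the heterozygosity–latitude profile gets a degree-2 fit, since inverse
clines of standard and inverted arrangements put maximal arrangement
diversity at mid-latitudes. The quadratic is offered on raw and
arcsin-transformed He; the pipeline reports the transformed fit, consistent
with every other frequency-derived response.

**Outlier scan.** The neutral null is a symmetric island model (default
100 demes, 9 sampled at the study's ~30 haplotypes) simulated by a
structured coalescent written in C++: infinite-alleles mutation is applied
by the standard killing device (a mutation is the most recent on a lineage,
so it terminates the lineage and stamps a fresh allele on its sampled
descendants). The mutation parameter is drawn log-uniformly on the pooled
scale (default 0.05–20, spanning pooled He ≈ 0.05–0.95).
`calibrate_island_model()` bisects on log M until the median simulated
per-locus θ is within ±5% relative of the observed multi-locus θ, starting
from the M solving F~ST~ = 1/(1+2M). The envelope uses 50 equal-width He
bins with per-bin type-6 ((n+1)-rule) quantiles: with interpolated type-7
quantiles the exceedance probability of a fresh neutral locus beyond the
estimated 99.5th percentile of a ~100-locus bin is nearly triple the
nominal 0.5%, and the order-statistic rule restores the calibration
(measured false-positive rates 0.6–1.1% at nominal 1%). Binning rather than
LOESS smoothing is a deliberate simplification of the LOSITAN approach; one
optional refinement pass removes flagged loci, recalibrates and
re-classifies.

## The synthetic-data generator

The generator reproduces the *frequency-level consequences* of inversion
biology rather than its mechanism. Arrangement frequencies follow a
multinomial logit in latitude (softmax of a_k + b_k·lat); the default
coefficients give standard arrangements rising and inverted arrangements
falling over the 36–60° span with realistic mid-latitude polymorphism.
Recombination suppression appears as its consequence: loci inside
inversions carry arrangement-specific allele pools, drawn once per
arrangement from the base pool with a Dirichlet (Balding–Nichols)
divergence `F_arr`; outside loci share the base pool. Each population then
re-draws every pool with divergence `F_pop` (within-arrangement drift), so
E[θ] between a draw and its base equals the F parameter, with
Var(p_i) = F·p_i(1−p_i) — the moment the tests check. Defaults are the
study conditions: nine populations, ~30 haplotypes per arrangement ×
population group, 8 alleles per locus with biased gene diversity 0.84
(matching the observed microsatellite He range), `F_pop = 0.007` (the
reported within-arrangement differentiation) and `F_arr = 0.10` (chosen so
that inside-locus between-arrangement θ sits an order of magnitude above
the within-arrangement level, the reported contrast).

Two injection hooks exist for power studies: `clinal_allele` forces one
allele's frequency to sin²(c0 + c1·lat) (exactly invertible on the
arcsin–sqrt scale when unclipped), and `ld_pair` couples the modal alleles
of two loci at a target interallelic D′ via a 2×2 latent indicator draw.

What the generator does **not** emulate: coalescent ancestry (allele
frequencies, not genealogies, are the modelled objects), microsatellite
mutation dynamics, inversion breakpoints and the physical decay of LD with
distance from them, heterokaryotype recombination and gene flux, selection
dynamics, and temporal sampling structure. Passing parameter-recovery tests
therefore demonstrates that the estimators measure what they claim on data
with the assumed frequency structure — not that real data satisfy those
assumptions.

## Numerical choices and degenerate inputs

- Frequencies are validated to sum to 1 within 1e−8; allele frequencies
  from counts sum to 1 within 1e−12 by construction.
- θ is undefined (error) when every locus is monomorphic across groups;
  per-locus NaN components are dropped from multi-locus sums.
- `D'm` drops zero-margin rows/columns and errors if fewer than two
  categories survive; cells with D_max = 0 contribute D′ = 0.
- Monte-Carlo p-values use the add-one rule (1 + hits)/(B + 1), so the
  smallest attainable p is 1/(B+1) and p = 0 is impossible.
- Constant regression responses return R² = 0 with an NA p rather than the
  NaN that a raw `summary.lm` would produce.
- The group-size filter defaults to 7 haplotypes — the smallest group the
  motivating survey retained — and missing alleles are excluded locus-wise
  (pairwise deletion), so per-locus n varies within a group.
- Genepop export writes haploid data as homozygous diploids with 3-digit
  rank codes and a sidecar allele-size map; >999 alleles at a locus is an
  error.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen to
exercise every claim with comfortable Monte-Carlo margins: 20 replicates of
the 9-population × 30-haplotype × 8-locus design for the
differentiation-partition recovery; 200 replicates at B = 199 permutations
for each type-I calibration; 20 000-locus envelopes (50 bins, ~400 loci per
bin) with 2000–3000 null loci for the outlier-scan calibration; and
2000-locus pilot batches for island-model calibration. A production scan
would raise the envelope to the 100 000 loci of the original protocol via
`n_loci`; nothing else changes.

## Known limitations

- The fixture longitudes are gazetteer approximations, so IBD quantities on
  the default design carry a fixed geographic error.
- Individual-level Mantel permutation (as opposed to population-level) is
  not implemented; the population-level test is the one reported.
- The Ohta component labels follow the reading in which D′²_IS is the
  variance of LD among populations and D′²_ST the LD of the pooled
  averages; the implementation satisfies the exact decomposition identity,
  but users comparing against historical LinkDos output should verify the
  naming against the original derivation before equating columns.
- R_ST-style stepwise-mutation statistics, hierarchical three-level AMOVA,
  and Bayesian outlier alternatives are out of scope.
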