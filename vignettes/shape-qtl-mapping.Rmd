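---
title: "Mapping shape QTL with morphoqtl: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping shape QTL with morphoqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoqtl)
```

# The problem and the model

A backcross (N2) between two inbred strains segregates, at every
autosomal locus, two genotype classes: homozygous for the recurrent
parent or heterozygous. The phenotype of interest here is the *shape* of
a bilaterally symmetric 3D structure — the geometry left after removing
position, orientation, scale, and any departure from perfect bilateral
symmetry from a landmark configuration. Shape is intrinsically
multivariate: a locus acts as a q-dimensional vector of coordinated
landmark displacements, not as a set of independent univariate traits.

`morphoqtl` fits, at every position of a cM grid, the multivariate
Haley–Knott model

$$\mathbf{y}_i \mid \mathbf{M}_i \sim N_q\!\Big(\mu + \sum_c x_{ic}\beta_c
  + \sum_j p_{ij}\beta_j,\; S\Big)$$

where $\mathbf{y}_i$ are the specimen's scores on the non-zero principal
components of the symmetric shape component, $x_{ic}$ are covariates
(sex, direction of cross, log centroid size), and
$p_{ij} = \Pr(g_i = j \mid \mathbf{M}_i)$ is the posterior probability of
the QTL genotype given the flanking markers. In the backcross
parameterization a single regressor, $\Pr(\text{HET})$, carries the
additive effect.

# Morphometrics with object symmetry

`gpaObjectSymmetry()` doubles the sample with reflected-relabeled copies
(`reflectRelabel()`: negate x, swap each left/right pair), then iterates
full Procrustes superimposition — centering, scaling to unit centroid
size, optimal rotations, consensus re-estimation — until the consensus
changes by less than 1e-10 (at most 200 iterations), with a final
rotation pass against the fixed consensus. The consensus is symmetrized
every iteration, which pins the bilateral plane of the common frame at
x = 0; the frame is otherwise arbitrary up to a rotation about that
axis, and `alignmentRotation()` maps it onto any reference when effects
must be compared across analyses.

The symmetric component of a specimen is the average of its aligned
original and aligned reflected copy; the asymmetric component is half
their difference. Because the optimal rotation of the reflected copy is
the conjugate of the original's, the two components fall exactly in the
reflection-invariant subspace and its orthogonal complement — the test
suite checks their inner products vanish to machine precision.

Symmetric components are projected orthogonally onto the tangent space
at the consensus and decomposed by PCA. Aligned configurations satisfy
three exact linear constraints (centering), one radial constraint
(tangent projection) and the optimal-rotation constraint, so for generic
data with p bilateral pairs and l midline landmarks exactly
$3p + 2l - 4$ eigenvalues are non-zero; discarded directions sit at the
level of squared machine precision, about twelve orders of magnitude
below the retained ones. The relative eigenvalue tolerance is therefore
uncritical and fixed at 1e-9. With 22 pairs and 9 midline landmarks this
gives the 80-dimensional shape space used throughout.

`landmarkRepeatability()` screens replicate digitizations: a landmark is
flagged when its *median* replicate distance exceeds the cutoff (0.125 mm
by default). "Consistently exceeds" is not a precise statistic; the
median is the natural reading, and the quantile is an argument.

# Genotype probabilities

`calcGenotypeProbs()` runs the forward–backward algorithm on the
two-state chain along each chromosome, at every marker plus pseudomarkers
placed by uniform subdivision of each inter-marker interval into the
fewest segments with spacing at most `step` (1 cM by default). The
transition probability across d cM is the recombination fraction from the
Carter–Falconer map function, appropriate for the high crossover
interference of the mouse; the map function has no closed forward form
and is inverted by bracketed root search to 1e-10. Emissions flip the
observed genotype with probability `errorRate` (1e-4 by default);
missing genotypes are uninformative, so a fully untyped individual gets
flat posteriors rather than an error. The implementation is verified
against exhaustive enumeration of all hidden paths on small chromosomes.

# Scans, thresholds and their numerics

At each grid position the QTL term is tested against the covariate-only
model with Pillai's trace $V = \mathrm{tr}[H(H+E)^{-1}]$, preferred here
because shape variance is diffuse over many dimensions and determinant
based statistics are fragile when many eigenvalues are small. For a
single added regressor the approximate F is exact (it equals the
Hotelling $T^2$ test), and the scan computes it by
Frisch–Waugh–Lovell residualization: one matrix product gives the whole
genome, algebraically identical to position-wise `pillaiTest()` calls.
p-values are computed on the log scale so logP does not saturate at
large effects. Positions with a degenerate (monomorphic) regressor score
0 with a warning. Scans require error df at least q + 2 and direct the
user to truncate PCs otherwise.

Genome-wide significance uses permutations in which the phenotype rows
and covariate rows are reshuffled *jointly*, destroying only the
genotype–phenotype association; the threshold is the type-7 empirical
(1 − α) quantile of the stored genome-wide maxima. Under a joint
permutation the residualized phenotype stays orthogonal to the covariate
basis, which reduces each permutation to two thin cross-products; the
suite verifies this fast path equals directly permuted scans and that
un-permuted null scans exceed the threshold at the nominal ~5% rate.

# Multiple-QTL search and intervals

The model-comparison criterion is the penalized score
$\mathrm{logP} - T \cdot n_\mathrm{QTL}$, with T the genome-wide shape
threshold — the direct transcription of the penalized-LOD criterion to
logP, where logP is the *joint* Pillai logP of all QTL against the
covariate-only model (so the null model scores 0 exactly).
`forwardBackwardSearch()` adds, at each forward step, the argmax of the
conditional (added-QTL) logP profile, refines all positions, and repeats
to `maxQTL`; backward elimination then drops, at each step, the QTL whose
removal leaves the largest joint logP, refining after each drop, down to
the null model; the best penalized score over every visited model wins.
`refinePositions()` re-profiles each QTL over the whole genome (a QTL may
migrate between chromosomes) holding the others fixed, and accepts a move
only when the joint logP increases — making the refinement trace provably
monotone, which the tests assert. Ties break toward the lowest
chromosome then the lowest cM, via the grid ordering. The forward search
caps model size so the error df never falls below q + 2.
`stepwiseSignificanceSearch()` is the alternative stopping rule: add
while the best candidate's conditional logP reaches T, pruning any QTL
whose drop-one logP falls below T.

Credible intervals translate the familiar $10^{\mathrm{LOD}}$ Bayes
construction to logP: weights $\propto 10^{\mathrm{logP}(\theta)}$ are
normalized to unit mass over one chromosome's grid and accumulated in
decreasing order until the coverage level (0.95 by default — no level is
canonical) is reached; the interval is the position range of the
accumulated set, computed from the chromosome profile of each QTL
conditional on all other refined QTL. A flat all-zero profile returns
the whole chromosome with a warning. Endpoints are grid positions;
`cmToBp()` converts them to physical coordinates by piecewise-linear
anchor interpolation, flagging terminal extrapolation.

# Effects and their anatomy

Fitted effects are stacked per-dimension coefficients; their magnitude
is the Euclidean norm — a Procrustes distance, invariant to the
orthonormal choice of basis (PC-score space or tangent space). Variance
accounting uses drop-one sums of squares over all dimensions relative to
the total Procrustes sum of squares. Projection scores
$s = \mathbf{y}\beta^t(\beta\beta^t)^{-1/2}$ give the univariate shape
variable in the effect's own direction; the directional percentage is
defined as the conditional (drop-one) $R^2$ of the QTL term in a
regression of s on all model terms, the natural reading of "variance
accounted for in its specific direction".

`regionDecomposition()` sums per-landmark displacement magnitudes by
anatomical region, splitting a boundary landmark's magnitude equally
among its regions, and reports raw proportions plus proportions
normalized by the (fractional) landmark count. The null reference
(`randomVectorIntervals()`) draws isotropic standard-normal vectors in
the q-dimensional symmetric tangent subspace — the subspace QTL effects
are confined to — back-transforms them to displacements and decomposes
them identically. PC-angle statistics are offered in two modes, because
"angle to the PCs" is ambiguous: against PC1 alone, or against the span
of the leading PCs covering 90% of variance (the default); the isotropic
null satisfies $E[\cos^2\theta] = k/q$, which the tests use as the
analytic oracle.

# The synthetic generator

`simMap()`, `simulateBackcross()` and `simulateShapes()` emulate the
mapping panel the methods were designed for: 19 autosomes, ~882 evenly
spaced informative SNPs, n = 433 N2 mice in two directions of cross with
the panel's sex ratios, genotyping error 1e-4, and a 53-landmark skull
(22 bilateral pairs + 9 midline) of centroid size ~25 mm. Hidden
genotypes follow the marker-interval Markov chain with Carter–Falconer
transition probabilities, consistent with the inference HMM. Shape
phenotypes are built in the symmetric tangent subspace at the base
configuration: planted QTL effects (given in Procrustes units or as a
target percentage of the trace, converted with var(genotype) = 1/4),
covariate effects (sex, direction, allometry at the few-percent-variance
level reported for such panels), and residuals with a 10-factor
low-rank-plus-diagonal covariance so that variance is diffuse — no
single PC dominates, as in real skull data. Raw configurations then
receive isotropic asymmetric landmark noise and a random rotation,
translation and scale per specimen, with log centroid size carrying sex
and direction contributions.

What the generator does *not* emulate: imaging/segmentation artifacts,
observer placement error beyond an isotropic offset, landmark-specific
variance heterogeneity (the "Pinocchio" regime), linkage
disequilibrium structure beyond the map's interference model, and
X-linked or epistatic effects. Passing tests therefore demonstrate
correctness of the estimators under the stated model, not robustness to
those features of real data.

# Problem sizes and numerical notes

The test suite runs the calibration and recovery studies at deliberately
modest sizes chosen to keep the full suite under a few minutes: a
5-chromosome, 50-marker genome for scan studies; 200 permutation
replicates at n = 200 and q = 10 for threshold calibration; 50 seeds at
n = 400 with the full 53-landmark pipeline for single- and two-QTL
recovery; 200 replicates for interval coverage, with the planted effect
scaled so the peak logP is ~10, the weakest regime among mapped skull
loci, where interval widths (~5–6 cM) match the reported scale. The
interval-coverage band asserted (90–99%) reflects the known mild
liberality of profile-based intervals in multiple-QTL settings.

Other numerical choices: GPA convergence 1e-10 with a final rotation
pass; optimal rotations by SVD with the determinant sign constrained
(+1, no reflections); quantiles by linear interpolation (type 7);
position de-duplication at 1e-9 cM; effect vectors outside the symmetric
tangent subspace are rejected by construction (the generator only
produces vectors inside it). The hypergeometric enrichment test is
exact (`phyper` upper tail) and takes the background gene count N as an
argument, since any fixed genome count is annotation-version-bound.

# Known limitations

- Two-state backcross chains only; no intercross (F2) or X-chromosome
  support, no sex-specific maps.
- Additive QTL only; no epistatic penalties or interaction scans.
- Bayes credible intervals inherit the mild under-coverage of profile
  intervals when other QTL positions are uncertain.
- The logP-profile interval construction is sharper than a likelihood
  profile when q is large; at very strong signals intervals can collapse
  to a few grid points.
- No 3D rendering; displacement fields are exported as tables for
  external visualization.
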