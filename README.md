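# morphoqtl

Multivariate QTL mapping for 3D geometric morphometric shape in
experimental crosses.

Craniofacial shape is a high-dimensional, highly polygenic trait. Mapping
its genetic basis in an N2 backcross (e.g. C57BL/6J x A/J mice) requires
treating the whole landmark configuration as one multivariate phenotype
rather than mapping distances or principal components one at a time.
`morphoqtl` implements that workflow end to end for R users:

1. **Morphometrics.** Full generalized Procrustes analysis (GPA) with
   *object symmetry*: each configuration is superimposed together with its
   reflected, relabeled copy; the **symmetric component** (the average of
   the two) is the mapped phenotype, and centroid size the size proxy.
   After orthogonal projection onto the tangent space at the consensus,
   PCA yields the non-zero-eigenvalue basis: for p bilateral pairs and l
   midline landmarks, exactly 3p + 2l − 4 dimensions (80 for a 53-landmark
   skull with 22 pairs and 9 midline points).
2. **Genetics.** Hidden-Markov genotype probabilities
   p<sub>ij</sub> = Pr(g<sub>i</sub> = j | **M**<sub>i</sub>) on a 1-cM grid, with a
   genotyping error rate and the Carter–Falconer map function
   d = 12.5 log((1+2r)/(1−2r)) + 25 arctan(2r), which models the strong
   crossover interference of the mouse.
3. **Scanning.** Haley–Knott regression of the score matrix on the
   genotype probabilities,
   **y**<sub>i</sub> | **M**<sub>i</sub> ~ N<sub>q</sub>(μ + Σ<sub>c</sub> x<sub>ic</sub>β<sub>c</sub> + Σ<sub>j</sub> p<sub>ij</sub>β<sub>j</sub>, S),
   scored by Pillai's trace V = tr[**H**(**H**+**E**)<sup>−1</sup>] and reported as
   logP = −log10 p of its (here exact) F statistic; LOD scans for log
   centroid size; permutation genome-wide thresholds that reshuffle the
   phenotype jointly with its covariates.
4. **Multiple-QTL modelling.** Penalized forward/backward model search
   (criterion logP − T·n<sub>QTL</sub>, T the genome-wide threshold), iterative
   position refinement, Bayes credible intervals from the normalized
   10<sup>logP</sup> profile, and cM→bp interval conversion.
5. **Effects.** Procrustes magnitude ‖β‖, percent of total Procrustes
   variance, projection scores s = **y**β<sup>t</sup>(ββ<sup>t</sup>)<sup>−1/2</sup>, anatomical-region
   decomposition of displacement fields against random-vector nulls, and
   PC-angle statistics.
6. **Enrichment.** Interval-to-gene overlap (GenomicRanges) and an exact
   hypergeometric enrichment test for a training gene list.
7. **Synthetic data.** A full generator for backcross genotypes and raw
   3D landmark phenotypes with planted QTL, covariate effects and
   nuisance rotation/translation/scale, providing ground truth for every
   downstream test.

## Worked example

```r
library(morphoqtl)

## simulate a backcross panel: 5 autosomes, 50 markers, 300 mice
map   <- simMap(nChrom = 5, nMarkers = 50, lengths = rep(45, 5))
cross <- simulateBackcross(map, n = 300, seed = 1)

## 53 3D landmarks (22 bilateral pairs + 9 midline) with one planted
## shape QTL on chromosome 3 explaining ~2% of the Procrustes variance
base   <- makeSymmetricBaseConfig(p = 22, l = 9)
shapes <- simulateShapes(cross, base,
                         qtl = data.frame(chr = "3", pos = 20, pctTrace = 2),
                         seed = 2)

## morphometrics: GPA with object symmetry, symmetric component, PCA
shape <- gpaObjectSymmetry(shapes$coords, base$sym)
shape
#> ShapeSpace: 300 specimens, 53 landmarks, 80 non-zero PCs
#>   leading PC explains 5.1% of symmetric shape variance

## genotype probabilities and the multivariate Haley-Knott scan
probs <- calcGenotypeProbs(cross$cross, step = 1, errorRate = 1e-4)
scan  <- scanShape(probs, shape, shapes$covariates)
scan
#> ScanResult (shape): 230 positions on 5 chromosomes; max logP = 17.670 at chr 3, 21.0 cM

## genome-wide threshold (permutations) and credible interval
perm <- genomeWideThreshold(probs, shape, shapes$covariates,
                            nPerm = 300, alpha = 0.05, seed = 3)
perm
#> PermutationResult: 300 permutations, alpha = 0.05, threshold = 2.852
peak <- scan@table[which.max(scan@table$score), ]
qtlIntervals(probs, shape, shapes$covariates,
             peak[c("chr", "pos")], anchors = simAnchors(map))
#>   chr pos lower upper coverage lower_bp upper_bp
#> 1   3  21    20    23     0.95  4.3e+07  4.9e+07

## fitted effect: magnitude and variance accounting
fit  <- fitQTLModel(probs, shape, shapes$covariates, peak[c("chr", "pos")])
beta <- fit@effects[nrow(fit@effects), ]
effectMagnitude(beta)
#> effect magnitude ||beta|| = 0.0060 Procrustes units
varianceAccounting(probs, shape, shapes$covariates, peak[c("chr", "pos")])
#>              term      SS pctTotal
#> 1             sex 0.00182    0.897
#> 2 cross_direction 0.00175    0.861
#> 3           logCS 0.00279    1.373
#> 4        QTL_3@21 0.00263    1.297
```

The scan localizes the planted locus to within 1 cM (peak at 21 cM, truth
at 20 cM), far above the permutation threshold; the 95% credible interval
spans 20–23 cM; and the fitted effect accounts for ~1.3% of the total
Procrustes variance — the small-effect regime typical of skull-shape QTL,
where the variance attributable to a locus sits near the covariate
effects (sex, direction of cross, allometry) in magnitude.

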