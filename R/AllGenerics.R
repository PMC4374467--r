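#' @rdname GeneticMap-class
#' @param object,x an object.
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname GeneticMap-class
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))

#' @rdname Backcross-class
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' Number of retained principal components
#' @param x a [ShapeSpace-class].
#' @export
setGeneric("nPCs", function(x) standardGeneric("nPCs"))

#' @rdname ShapeSpace-class
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname ShapeSpace-class
#' @export
setGeneric("centroidSizes", function(x) standardGeneric("centroidSizes"))

#' @rdname ShapeSpace-class
#' @export
setGeneric("consensus", function(x) standardGeneric("consensus"))

#' Genome-wide significance threshold stored in a permutation result
#' @param x a [PermutationResult-class].
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))

setMethod("nMarkers", "GeneticMap", function(x) nrow(x@markers))
setMethod("chromosomes", "GeneticMap", function(x) unique(x@markers$chr))
setMethod("nMarkers", "Backcross", function(x) nMarkers(x@map))
setMethod("chromosomes", "Backcross", function(x) chromosomes(x@map))
setMethod("nIndividuals", "Backcross", function(x) nrow(x@geno))
setMethod("nIndividuals", "GenotypeProbs", function(x) nrow(x@pHet))
setMethod("nIndividuals", "ShapeSpace", function(x) nrow(x@scores))
setMethod("nPCs", "ShapeSpace", function(x) length(x@eigenvalues))
setMethod("scores", "ShapeSpace", function(x) x@scores)
setMethod("centroidSizes", "ShapeSpace", function(x) x@centroidSize)
setMethod("consensus", "ShapeSpace", function(x) x@consensus)
setMethod("threshold", "PermutationResult", function(x) x@threshold)

setMethod("show", "GeneticMap", function(object) {
  m <- object@markers
  cat(sprintf("GeneticMap: %d markers on %d chromosomes (%s bp positions)\n",
              nrow(m), length(unique(m$chr)),
              if (all(is.na(m$bp))) "no" else "with"))
})

setMethod("show", "Backcross", function(object) {
  cat(sprintf("Backcross (N2): %d individuals, %d markers on %d chromosomes\n",
              nrow(object@geno), nMarkers(object), length(chromosomes(object))))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * mean(is.na(object@geno))))
})

setMethod("show", "GenotypeProbs", function(object) {
  cat(sprintf("GenotypeProbs: %d individuals x %d grid positions (%d markers), step %g cM, error rate %g\n",
              nrow(object@pHet), nrow(object@grid), sum(!is.na(object@grid$marker)),
              object@step, object@errorRate))
})

setMethod("show", "ShapeSpace", function(object) {
  cat(sprintf("ShapeSpace: %d specimens, %d landmarks, %d non-zero PCs\n",
              nrow(object@scores), nrow(object@consensus), nPCs(object)))
  ev <- object@eigenvalues
  cat(sprintf("  leading PC explains %.1f%% of symmetric shape variance\n",
              100 * ev[1] / sum(ev)))
})

setMethod("show", "ScanResult", function(object) {
  t <- object@table
  i <- which.max(t$score)
  cat(sprintf("ScanResult (%s): %d positions on %d chromosomes; max %s = %.3f at chr %s, %.1f cM\n",
              object@type, nrow(t), length(unique(t$chr)),
              if (object@type == "shape") "logP" else "LOD",
              t$score[i], t$chr[i], t$pos[i]))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("PermutationResult: %d permutations, alpha = %g, threshold = %.3f\n",
              length(object@maxima), object@alpha, object@threshold))
})

setMethod("show", "QTLModel", function(object) {
  cat(sprintf("QTLModel: %d QTL, joint logP = %.2f, penalized = %.2f (T = %.2f)\n",
              nrow(object@loci), object@logP, object@penalized, object@threshold))
  if (nrow(object@loci)) print(object@loci)
})
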