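#' @rdname fitPLSDA
#' @export
setGeneric("fitPLSDA", function(x, labels, ncomp = 2, scale = TRUE, ...)
    standardGeneric("fitPLSDA"))

#' @rdname fitSPLSDA
#' @export
setGeneric("fitSPLSDA", function(x, labels, ncomp = 2, keepX,
                                 scale = TRUE, ...)
    standardGeneric("fitSPLSDA"))

#' @rdname runPCA
#' @export
setGeneric("runPCA", function(x, ncomp = 10, ...) standardGeneric("runPCA"))

#' Accessors for fitted latent-variable models
#'
#' `plsWeights()`, `plsLoadings()`, `plsScores()` return the gene weight,
#' gene loading and sample score matrices of a [PLSDAModel-class];
#' `classLabels()` the two class labels; `keepX()` and `selectedGenes()` the
#' sparsity level and per-component selected genes of a
#' [SparsePLSDAModel-class]; `cvError()` the (overall, balanced) error rates
#' of a [CVReport-class]; `chosenKeepX()` the tuned keepX values of a
#' [TuningResult-class]; `explainedVariance()` the per-component variance
#' proportions of a [PCAResult-class]; `normFactors()` and
#' `effectiveLibSizes()` the TMM factors and effective sizes of a
#' [NormFactors-class].
#'
#' @param object a fitted model or report object.
#' @return the matrix, vector or list documented above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("plsWeights", function(object) standardGeneric("plsWeights"))
#' @rdname accessors
#' @export
setGeneric("plsLoadings", function(object) standardGeneric("plsLoadings"))
#' @rdname accessors
#' @export
setGeneric("plsScores", function(object) standardGeneric("plsScores"))
#' @rdname accessors
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))
#' @rdname accessors
#' @export
setGeneric("keepX", function(object) standardGeneric("keepX"))
#' @rdname accessors
#' @export
setGeneric("selectedGenes", function(object) standardGeneric("selectedGenes"))
#' @rdname accessors
#' @export
setGeneric("cvError", function(object) standardGeneric("cvError"))
#' @rdname accessors
#' @export
setGeneric("chosenKeepX", function(object) standardGeneric("chosenKeepX"))
#' @rdname accessors
#' @export
setGeneric("explainedVariance", function(object)
    standardGeneric("explainedVariance"))
#' @rdname accessors
#' @export
setGeneric("normFactors", function(object) standardGeneric("normFactors"))
#' @rdname accessors
#' @export
setGeneric("effectiveLibSizes", function(object)
    standardGeneric("effectiveLibSizes"))

setMethod("plsWeights", "PLSDAModel", function(object) object@xWeights)
setMethod("plsLoadings", "PLSDAModel", function(object) object@xLoadings)
setMethod("plsScores", "PLSDAModel", function(object) object@scores)
setMethod("classLabels", "PLSDAModel", function(object) object@classLabels)
setMethod("keepX", "SparsePLSDAModel", function(object) object@keepX)
setMethod("selectedGenes", "SparsePLSDAModel", function(object)
    object@selected)
setMethod("cvError", "CVReport", function(object)
    c(oer = object@oer, ber = object@ber))
setMethod("chosenKeepX", "TuningResult", function(object) object@chosen)
setMethod("explainedVariance", "PCAResult", function(object)
    object@explained)
setMethod("normFactors", "NormFactors", function(object) object@factors)
setMethod("effectiveLibSizes", "NormFactors", function(object)
    object@effectiveSizes)

setMethod("show", "SimConfig", function(object) {
    cls <- c("CD_inflamed", "CD_normal", "UC_inflamed", "UC_normal")
    cat("SimConfig:", object@nGenes, "genes,",
        sum(object@nPerClass), "samples (",
        paste(sprintf("%s=%d", cls, object@nPerClass), collapse = ", "),
        ")\n")
    cat(sprintf(
        "  planted sets: %d inflammation (|lfc| %.2g), %d disease (|lfc| %.2g), %d segment (|lfc| %.2g)\n",
        object@nInflammationGenes, object@lfcInflammation,
        object@nDiseaseGenes, object@lfcDisease,
        object@nSegmentGenes, object@lfcSegment))
    cat(sprintf("  NB dispersion %.3g, seed %d\n",
                object@nbDispersion, object@seed))
})

setMethod("show", "NormFactors", function(object) {
    cat("NormFactors:", length(object@factors), "samples, TMM factors in [",
        sprintf("%.4f", min(object@factors)), ",",
        sprintf("%.4f", max(object@factors)), "], reference",
        object@refSample, "\n")
})

setMethod("show", "PCAResult", function(object) {
    cat("PCAResult:", ncol(object@scores), "components,",
        nrow(object@scores), "samples\n")
    cat("  explained:",
        paste(sprintf("%.1f%%", 100 * object@explained), collapse = " "),
        "\n")
})

setMethod("show", "PLSDAModel", function(object) {
    cat(class(object), ":", object@ncomp, "component(s),",
        length(object@geneIds), "genes,", nrow(object@scores), "samples\n")
    cat("  classes:", paste(object@classLabels, collapse = " vs "), "\n")
    if (is(object, "SparsePLSDAModel"))
        cat("  keepX:", paste(object@keepX, collapse = ", "), "\n")
})

setMethod("show", "CVReport", function(object) {
    cat(sprintf(
        "CVReport: %d-fold CV x %d repeat(s); overall error %.4f, balanced error %.4f\n",
        object@k, object@repeats, object@oer, object@ber))
})

setMethod("show", "TuningResult", function(object) {
    cat("TuningResult (criterion:", object@criterion, "): chosen keepX =",
        paste(object@chosen, collapse = ", "), "over grid of",
        length(object@grid), "values\n")
})

setMethod("show", "TwoStageReport", function(object) {
    cat("TwoStageReport\n")
    cat(sprintf("  genes: %d before filtering, %d after, %d kept for stage 2 (prune fraction %.2f)\n",
                object@preprocessing$genes_before,
                object@preprocessing$genes_after,
                length(object@keptGenes), object@pruneFraction))
    cat("  trench table (stage-1 / stage-2 CV error by prune fraction):\n")
    for (i in seq_len(nrow(object@trenchTable)))
        cat(sprintf("    %.2f: %.4f / %.4f\n",
                    object@trenchTable$fraction[i],
                    object@trenchTable$stage1_error[i],
                    object@trenchTable$stage2_error[i]))
    cat(sprintf("  stage 2: %d component(s), keepX = %s\n",
                object@stage2Ncomp,
                paste(object@finalModel@keepX, collapse = ", ")))
    cat(sprintf("  final CV: overall error %.4f, balanced error %.4f\n",
                object@finalCV@oer, object@finalCV@ber))
})
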