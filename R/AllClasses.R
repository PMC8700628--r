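#' @import methods
#' @importFrom stats predict rnbinom rnorm sd quantile prcomp setNames
#' @importFrom utils read.delim write.table head
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Simulation configuration for four-class IBD count matrices
#'
#' Parameters of the negative-binomial generator that emulates mucosal RNA-seq
#' counts from four sample classes: CD inflamed, CD normal, UC inflamed and
#' UC normal. Planted gene sets carry an inflammation effect (shared by both
#' inflamed classes), a disease effect (inflamed CD vs inflamed UC) and a
#' segment effect (normal CD vs normal UC, standing in for terminal ileum vs
#' rectum sampling). Construct with [simConfig()].
#'
#' @slot nPerClass integer(4), samples per class in the order CD_inflamed,
#'   CD_normal, UC_inflamed, UC_normal.
#' @slot nGenes number of simulated genes.
#' @slot nInflammationGenes,nDiseaseGenes,nSegmentGenes sizes of the disjoint
#'   planted sets.
#' @slot lfcInflammation,lfcDisease,lfcSegment planted absolute log2
#'   fold changes (>= 0).
#' @slot nbDispersion negative-binomial dispersion phi; variance mu + phi*mu^2.
#' @slot libsizeLogMean,libsizeLogSd natural-log mean/sd of the per-sample
#'   depth factor.
#' @slot baselineLogMean,baselineLogSd mean/sd of per-gene baseline log2
#'   expression.
#' @slot seed integer seed driving all randomness.
#' @export
setClass("SimConfig", representation(
    nPerClass = "integer",
    nGenes = "integer",
    nInflammationGenes = "integer",
    nDiseaseGenes = "integer",
    nSegmentGenes = "integer",
    lfcInflammation = "numeric",
    lfcDisease = "numeric",
    lfcSegment = "numeric",
    nbDispersion = "numeric",
    libsizeLogMean = "numeric",
    libsizeLogSd = "numeric",
    baselineLogMean = "numeric",
    baselineLogSd = "numeric",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character(0)
    if (length(object@nPerClass) != 4L || any(object@nPerClass < 2L))
        msg <- c(msg, "all four class sizes must be >= 2")
    nset <- object@nInflammationGenes + object@nDiseaseGenes +
        object@nSegmentGenes
    if (nset > object@nGenes)
        msg <- c(msg, "planted gene-set sizes must sum to <= nGenes")
    if (any(c(object@lfcInflammation, object@lfcDisease,
              object@lfcSegment) < 0))
        msg <- c(msg, "planted log2 fold changes must be >= 0")
    if (object@nbDispersion <= 0)
        msg <- c(msg, "nbDispersion must be > 0")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' TMM normalization factors and effective library sizes
#'
#' Result of [tmmFactors()]: raw library sizes (column sums), trimmed-mean-of-
#' M-values correction factors with geometric mean 1, and the effective
#' library sizes (raw size times factor) used for CPM computation.
#'
#' @slot libSizes raw per-sample library sizes.
#' @slot factors TMM factors, geometric mean 1.
#' @slot effectiveSizes libSizes * factors.
#' @slot refSample identifier of the reference column.
#' @export
setClass("NormFactors", representation(
    libSizes = "numeric",
    factors = "numeric",
    effectiveSizes = "numeric",
    refSample = "character"
))

setValidity("NormFactors", function(object) {
    msg <- character(0)
    if (abs(mean(log(object@factors))) > 1e-9)
        msg <- c(msg, "geometric mean of TMM factors must equal 1")
    if (any(object@effectiveSizes <= 0))
        msg <- c(msg, "effective library sizes must be strictly positive")
    if (length(object@libSizes) != length(object@factors))
        msg <- c(msg, "libSizes and factors must have equal length")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Principal component analysis of a log-expression matrix
#'
#' Scores (samples x components) and per-component explained-variance
#' proportions from an SVD of the column-centered sample-by-gene matrix.
#' Component signs are fixed so each component's largest-magnitude gene
#' loading is positive. Construct with [runPCA()].
#'
#' @slot scores sample x component score matrix.
#' @slot loadings gene x component loading (rotation) matrix.
#' @slot explained proportion of total variance per component.
#' @export
setClass("PCAResult", representation(
    scores = "matrix",
    loadings = "matrix",
    explained = "numeric"
))

setValidity("PCAResult", function(object) {
    e <- object@explained
    if (any(e < -1e-12 | e > 1 + 1e-9))
        return("explained proportions must lie in [0, 1]")
    if (any(diff(e) > 1e-9))
        return("explained proportions must be non-increasing")
    if (sum(e) > 1 + 1e-9)
        return("explained proportions must sum to <= 1")
    TRUE
})

#' Two-class PLS-DA model
#'
#' A fitted partial least-squares discriminant analysis model: per-component
#' gene weights (unit norm), regression loadings, sample scores, class
#' indicator loadings, the preprocessing (center/scale) vectors, and per-class
#' mean score vectors used for centroid prediction and for the pruning
#' statistic. Construct with [fitPLSDA()].
#'
#' @slot ncomp number of latent components H.
#' @slot xWeights gene x H weight matrix, unit-norm columns.
#' @slot xLoadings gene x H regression-loading matrix.
#' @slot yLoadings 2 x H class-indicator loading matrix.
#' @slot scores sample x H latent score matrix.
#' @slot rotations gene x H projection matrix W (P'W)^-1 mapping preprocessed
#'   data to scores.
#' @slot coefficients gene x 2 regression coefficient matrix for indicator
#'   prediction.
#' @slot centers,scales per-gene centering/scaling applied before fitting.
#' @slot scaled logical, whether genes were scaled to unit variance.
#' @slot yMeans means of the two indicator columns.
#' @slot classLabels the two class labels (levels order).
#' @slot classScoreMeans 2 x H per-class mean scores.
#' @slot geneIds gene identifiers (row order of the training matrix).
#' @export
setClass("PLSDAModel", representation(
    ncomp = "integer",
    xWeights = "matrix",
    xLoadings = "matrix",
    yLoadings = "matrix",
    scores = "matrix",
    rotations = "matrix",
    coefficients = "matrix",
    centers = "numeric",
    scales = "numeric",
    scaled = "logical",
    yMeans = "numeric",
    classLabels = "character",
    classScoreMeans = "matrix",
    geneIds = "character"
))

setValidity("PLSDAModel", function(object) {
    msg <- character(0)
    wn <- sqrt(colSums(object@xWeights^2))
    if (any(abs(wn - 1) > 1e-9))
        msg <- c(msg, "xWeights columns must have unit Euclidean norm")
    TT <- object@scores
    if (ncol(TT) > 1) {
        G <- crossprod(TT)
        off <- abs(G[upper.tri(G)])
        rel <- off / sqrt(tcrossprod(diag(G))[upper.tri(G)])
        if (any(rel > 1e-6))
            msg <- c(msg, "score columns must be mutually orthogonal")
    }
    if (length(object@classLabels) != 2L)
        msg <- c(msg, "exactly two class labels required")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Sparse two-class PLS-DA model
#'
#' A [PLSDAModel-class] whose per-component weight vectors are
#' soft-thresholded so exactly `keepX[h]` genes have nonzero weight in
#' component h. Reported loadings are masked to the component's support, so
#' unselected genes have exactly zero weight and loading. Construct with
#' [fitSPLSDA()].
#'
#' @slot keepX number of genes retained per component.
#' @slot selected list of per-component selected gene identifiers.
#' @export
setClass("SparsePLSDAModel", contains = "PLSDAModel", representation(
    keepX = "integer",
    selected = "list"
))

setValidity("SparsePLSDAModel", function(object) {
    msg <- character(0)
    for (h in seq_len(object@ncomp)) {
        nz <- sum(object@xWeights[, h] != 0)
        if (nz != object@keepX[h])
            msg <- c(msg, sprintf(
                "component %d has %d nonzero weights but keepX = %d",
                h, nz, object@keepX[h]))
        if (length(object@selected[[h]]) != object@keepX[h])
            msg <- c(msg, sprintf("component %d selected-gene list length != keepX", h))
        off <- setdiff(object@geneIds, object@selected[[h]])
        if (any(object@xLoadings[match(off, object@geneIds), h] != 0))
            msg <- c(msg, sprintf("component %d has nonzero loadings off support", h))
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Cross-validation report
#'
#' Fold assignments and error rates from repeated stratified k-fold
#' cross-validation. Within each repeat, held-out predictions are pooled
#' across folds before computing the overall error rate (OER, misclassified /
#' total) and balanced error rate (BER, mean of per-class error rates);
#' reported `oer` and `ber` average these over repeats. Construct with
#' [crossValidate()].
#'
#' @slot folds sample x repeat matrix of test-fold indices.
#' @slot perRepeat data.frame with one row per repeat (columns oer, ber).
#' @slot oer,ber mean error rates over repeats.
#' @slot k folds per repeat.
#' @slot repeats number of repeats.
#' @slot seed seed driving the fold splits.
#' @export
setClass("CVReport", representation(
    folds = "matrix",
    perRepeat = "data.frame",
    oer = "numeric",
    ber = "numeric",
    k = "integer",
    repeats = "integer",
    seed = "integer"
))

setValidity("CVReport", function(object) {
    msg <- character(0)
    if (object@oer < 0 || object@oer > 1 || object@ber < 0 || object@ber > 1)
        msg <- c(msg, "error rates must lie in [0, 1]")
    if (nrow(object@perRepeat) != object@repeats)
        msg <- c(msg, "perRepeat must have exactly `repeats` rows")
    bad <- apply(object@folds, 2, function(f)
        !all(sort(unique(f)) %in% seq_len(object@k)))
    if (any(bad))
        msg <- c(msg, "fold indices must lie in 1..k")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' keepX tuning result
#'
#' Per-component cross-validated error curves over a grid of candidate keepX
#' values, and the chosen value per component (sequential search; ties go to
#' the smaller keepX). Construct with [tuneKeepX()].
#'
#' @slot grid candidate keepX values.
#' @slot errorCurve data.frame: component, keepX, mean, sd of CV error.
#' @slot chosen chosen keepX per component.
#' @slot criterion "ber" or "oer".
#' @export
setClass("TuningResult", representation(
    grid = "integer",
    errorCurve = "data.frame",
    chosen = "integer",
    criterion = "character"
))

setValidity("TuningResult", function(object) {
    msg <- character(0)
    if (!all(object@chosen %in% object@grid))
        msg <- c(msg, "chosen keepX values must be members of the grid")
    ncomp <- length(object@chosen)
    if (nrow(object@errorCurve) != ncomp * length(object@grid))
        msg <- c(msg, "error curve must have one row per grid value per component")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Full two-stage analysis report
#'
#' Everything [runTwoStage()] computes: preprocessing summary, PCA, the
#' trench table of stage-1/stage-2 errors per prune fraction, the pruned and
#' kept gene sets, the stage-2 dense component scan, keepX tuning, the final
#' sparse model and its cross-validated error rates, and the fully resolved
#' configuration.
#'
#' @slot preprocessing list: genes before/after filtering, TMM factors.
#' @slot pca [PCAResult-class] of the full log-CPM matrix.
#' @slot trenchTable data.frame: fraction, stage1 and stage2 CV errors.
#' @slot pruneFraction fraction actually pruned before stage 2.
#' @slot pruneScores named per-gene pruning scores (stage-1 statistic).
#' @slot prunedGenes,keptGenes gene identifier vectors.
#' @slot stage1Model [PLSDAModel-class] fitted on normal samples.
#' @slot denseCV data.frame: stage-2 CV error per component count.
#' @slot stage2Ncomp chosen stage-2 component count.
#' @slot tuning [TuningResult-class].
#' @slot finalModel [SparsePLSDAModel-class].
#' @slot finalCV [CVReport-class] of the final model.
#' @slot config resolved analysis configuration (list).
#' @export
setClass("TwoStageReport", representation(
    preprocessing = "list",
    pca = "PCAResult",
    trenchTable = "data.frame",
    pruneFraction = "numeric",
    pruneScores = "numeric",
    prunedGenes = "character",
    keptGenes = "character",
    stage1Model = "PLSDAModel",
    denseCV = "data.frame",
    stage2Ncomp = "integer",
    tuning = "TuningResult",
    finalModel = "SparsePLSDAModel",
    finalCV = "CVReport",
    config = "list"
))
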