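.as_plsda_model <- function(fit, sparse = FALSE) {
    gn <- fit$gene_ids
    W <- fit$W; P <- fit$P
    dimnames(W) <- dimnames(P) <- list(gn, paste0("comp", seq_len(fit$ncomp)))
    if (sparse) {
        # reported loadings masked to the support; deflation used the full
        # regression loadings, so score orthogonality is untouched
        P <- P * (W != 0)
        sel <- lapply(seq_len(fit$ncomp), function(h) gn[W[, h] != 0])
    }
    TT <- fit$TT
    dimnames(TT) <- list(rownames(fit$TT), colnames(W))
    args <- list(
        ncomp = as.integer(fit$ncomp), xWeights = W, xLoadings = P,
        yLoadings = structure(fit$C,
                              dimnames = list(fit$lev, colnames(W))),
        scores = TT, rotations = fit$R, coefficients = fit$B,
        centers = fit$centers, scales = fit$scales, scaled = fit$scaled,
        yMeans = fit$ymeans, classLabels = fit$lev,
        classScoreMeans = fit$class_score_means, geneIds = gn)
    if (sparse)
        do.call(new, c(list("SparsePLSDAModel"), args,
                       list(keepX = as.integer(fit$keepx), selected = sel)))
    else
        do.call(new, c(list("PLSDAModel"), args))
}

.expr_and_labels <- function(x, labels) {
    if (is(x, "SummarizedExperiment")) {
        if (is.character(labels) && length(labels) == 1L)
            labels <- SummarizedExperiment::colData(x)[[labels]]
        x <- .get_expr(x)
    }
    x <- as.matrix(x)
    if (length(labels) != ncol(x))
        stop("`labels` must have one entry per sample")
    list(X = t(x), y = factor(labels))
}

#' Fit a two-class PLS-DA model
#'
#' Partial least-squares discriminant analysis: class labels are encoded as a
#' centered two-column indicator matrix; each latent component's gene weight
#' vector maximizes the covariance between the projected (centered, by
#' default unit-variance-scaled) expression matrix and the projected
#' indicator; after each component both matrices are deflated by their
#' regression on the component score. Deterministic for fixed input.
#'
#' @param x a genes x samples log-expression matrix, or a
#'   SummarizedExperiment with a `"logcpm"` assay.
#' @param labels a two-class label per sample; for a SummarizedExperiment,
#'   optionally the name of a `colData` column.
#' @param ncomp number of latent components.
#' @param scale scale genes to unit variance before fitting.
#' @param ... unused.
#' @return a [PLSDAModel-class].
#' @examples
#' se <- logCPM(filterLowCounts(simulateCounts(simConfig(nGenes = 300))))
#' normals <- se[, se$status == "normal"]
#' fit <- fitPLSDA(normals, "disease", ncomp = 2)
#' fit
#' @rdname fitPLSDA
#' @export
setMethod("fitPLSDA", "ANY", function(x, labels, ncomp = 2, scale = TRUE,
                                      ...) {
    el <- .expr_and_labels(x, labels)
    .as_plsda_model(.pls_engine(el$X, el$y, ncomp, keepx = NULL,
                                do_scale = scale))
})

.model_to_core <- function(object) {
    list(W = object@xWeights, P = object@xLoadings, C = t(object@yLoadings),
         TT = object@scores, R = object@rotations, B = object@coefficients,
         centers = object@centers, scales = object@scales,
         scaled = object@scaled, ymeans = object@yMeans,
         lev = object@classLabels, gene_ids = object@geneIds,
         class_score_means = object@classScoreMeans, ncomp = object@ncomp)
}

#' Predict class labels from a fitted (sparse) PLS-DA model
#'
#' `"max_score"` assigns the class whose predicted indicator value is
#' largest; `"centroid"` assigns the class whose mean training score vector
#' is nearest in Euclidean distance in latent space. Exact ties go to the
#' alphabetically first class label.
#'
#' @param object a [PLSDAModel-class] or [SparsePLSDAModel-class].
#' @param newdata a genes x samples matrix or SummarizedExperiment covering
#'   the model's genes (extra genes are ignored).
#' @param distance `"max_score"` or `"centroid"`.
#' @param ... unused.
#' @return a factor of predicted labels, one per sample.
#' @export
setMethod("predict", "PLSDAModel",
          function(object, newdata, distance = c("max_score", "centroid"),
                   ...) {
    expr <- .get_expr(newdata)
    missing <- setdiff(object@geneIds, rownames(expr))
    if (length(missing))
        stop("newdata is missing model gene(s), first: ", missing[1L])
    Xnew <- t(expr[object@geneIds, , drop = FALSE])
    .pls_predict(.model_to_core(object), Xnew, match.arg(distance))
})

#' Per-gene alignment with the inter-class direction (pruning statistic)
#'
#' For a fitted two-class model, forms the unit vector d connecting the two
#' class mean score vectors in latent space and scores every gene by the
#' absolute projection of its loading vector onto d:
#' score_g = | sum_h loadings\[g, h\] d_h |. Genes that strongly discriminate
#' the two classes get large scores; in the two-stage workflow this is
#' computed on the normal-tissue model and large scores flag gut-segment
#' confounders to prune.
#'
#' @param model a fitted [PLSDAModel-class].
#' @return a named non-negative numeric vector, one score per gene.
#' @examples
#' se <- logCPM(filterLowCounts(simulateCounts(simConfig(nGenes = 300))))
#' normals <- se[, se$status == "normal"]
#' sc <- classDirectionScores(fitPLSDA(normals, "disease", ncomp = 2))
#' head(sort(sc, decreasing = TRUE))
#' @export
classDirectionScores <- function(model) {
    stopifnot(is(model, "PLSDAModel"))
    d <- model@classScoreMeans[1L, ] - model@classScoreMeans[2L, ]
    nd <- sqrt(sum(d^2))
    if (nd < .Machine$double.eps)
        stop("degenerate class-mean direction: the class centroids coincide")
    d <- d / nd
    setNames(abs(as.numeric(model@xLoadings %*% d)), model@geneIds)
}
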