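#' Principal component analysis of log expression
#'
#' Samples are observations, genes variables; the matrix is column-centered
#' (not scaled — log-CPM is already on a common scale) and decomposed by SVD.
#' Explained variance per component is sigma_h^2 / sum(sigma^2) over all
#' components, so the reported proportions are fractions of total variance
#' even when `ncomp` is small. Component signs are fixed so each component's
#' largest-magnitude gene loading is positive, making output reproducible
#' across linear-algebra backends.
#'
#' @param x a genes x samples log-expression matrix or SummarizedExperiment
#'   with a `"logcpm"` assay.
#' @param ncomp number of components to return; must be at most
#'   min(samples - 1, genes).
#' @param ... unused.
#' @return a [PCAResult-class].
#' @examples
#' se <- logCPM(filterLowCounts(simulateCounts(simConfig(nGenes = 300))))
#' runPCA(se, ncomp = 4)
#' @rdname runPCA
#' @export
setMethod("runPCA", "ANY", function(x, ncomp = 10, ...) {
    expr <- .get_expr(x)
    X <- t(expr)                                   # samples x genes
    n <- nrow(X); p <- ncol(X)
    if (ncomp < 1 || ncomp > min(n - 1, p))
        stop("ncomp must lie in 1..min(samples - 1, genes) = ",
             min(n - 1, p))
    pc <- prcomp(X, center = TRUE, scale. = FALSE)
    explained_all <- pc$sdev^2 / sum(pc$sdev^2)
    keep <- seq_len(ncomp)
    rot <- pc$rotation[, keep, drop = FALSE]
    sc <- pc$x[, keep, drop = FALSE]
    flip <- vapply(keep, function(h) {
        v <- rot[, h]
        sign(v[which.max(abs(v))]) < 0
    }, logical(1))
    rot[, flip] <- -rot[, flip]
    sc[, flip] <- -sc[, flip]
    new("PCAResult", scores = sc, loadings = rot,
        explained = explained_all[keep])
})
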