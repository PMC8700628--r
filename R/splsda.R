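#' Fit a sparse two-class PLS-DA model
#'
#' As [fitPLSDA()], but each component's dense weight vector is
#' soft-thresholded at the magnitude of its (keepX\[h\] + 1)-largest absolute
#' entry so that exactly keepX\[h\] genes keep nonzero weight (ties at the
#' cut broken by gene identifier), then renormalized to unit length.
#' Deflation proceeds as in the dense fit. With keepX = number of genes the
#' fit reduces exactly to the dense model.
#'
#' @inheritParams fitPLSDA
#' @param keepX number of genes to retain per component; recycled to
#'   `ncomp` values.
#' @return a [SparsePLSDAModel-class].
#' @examples
#' se <- logCPM(filterLowCounts(simulateCounts(simConfig(nGenes = 300))))
#' inflamed <- se[, se$status == "inflamed"]
#' fit <- fitSPLSDA(inflamed, "disease", ncomp = 2, keepX = c(10, 20))
#' lengths(selectedGenes(fit))
#' @rdname fitSPLSDA
#' @export
setMethod("fitSPLSDA", "ANY", function(x, labels, ncomp = 2, keepX,
                                       scale = TRUE, ...) {
    el <- .expr_and_labels(x, labels)
    keepX <- as.integer(rep_len(keepX, ncomp))
    p <- ncol(el$X)
    if (any(keepX < 1L | keepX > p))
        stop("keepX values must lie in 1..", p)
    .as_plsda_model(.pls_engine(el$X, el$y, ncomp, keepx = keepX,
                                do_scale = scale),
                    sparse = TRUE)
})

#' Tune the number of genes per sparse component
#'
#' Sequential (greedy) per-component grid search: component 1's keepX is
#' chosen by minimizing the mean cross-validated error over the grid, then
#' held fixed while component 2's grid is searched, and so on. Folds are
#' stratified by class and driven solely by `seed`; the same splits are
#' reused across grid values, so candidates are compared on identical folds.
#' The tuning criterion defaults to balanced error (mean per-class error),
#' appropriate for the mildly imbalanced cohort classes; ties go to the
#' smaller keepX (parsimony).
#'
#' @inheritParams fitPLSDA
#' @param ncomp number of components to tune.
#' @param grid candidate keepX values (defaults to 1..300, capped at the
#'   number of genes).
#' @param folds folds per cross-validation.
#' @param repeats number of repeated random splits.
#' @param seed integer seed for the fold splits.
#' @param distance prediction rule, see [predict,PLSDAModel-method].
#' @param criterion `"ber"` (balanced) or `"oer"` (overall) error.
#' @return a [TuningResult-class].
#' @examples
#' se <- logCPM(filterLowCounts(simulateCounts(simConfig(nGenes = 300))))
#' inflamed <- se[, se$status == "inflamed"]
#' tuneKeepX(inflamed, "disease", ncomp = 2, grid = c(5, 10, 25),
#'           repeats = 3, seed = 1)
#' @export
tuneKeepX <- function(x, labels, ncomp = 2, grid = 1:300, folds = 5,
                      repeats = 100, seed = 1, scale = TRUE,
                      distance = c("max_score", "centroid"),
                      criterion = c("ber", "oer")) {
    distance <- match.arg(distance)
    criterion <- match.arg(criterion)
    el <- .expr_and_labels(x, labels)
    X <- el$X; y <- el$y
    p <- ncol(X)
    grid <- sort(unique(as.integer(grid)))
    grid <- grid[grid >= 1L & grid <= p]
    if (!length(grid)) stop("`grid` is empty after capping at 1..", p)
    if (folds < 2) stop("`folds` must be >= 2")
    if (any(table(y) < folds))
        stop("every class must have at least `folds` members")

    lev <- levels(y)
    chosen <- integer(0)
    curves <- vector("list", ncomp)
    for (h in seq_len(ncomp)) {
        # err[r, g]: criterion error of repeat r at grid value g
        err <- matrix(NA_real_, repeats, length(grid))
        for (r in seq_len(repeats)) {
            fold_id <- stratifiedFolds(y, folds, seed + r - 1L)
            pred <- matrix(NA_character_, length(y), length(grid))
            for (f in seq_len(folds)) {
                test <- fold_id == f
                st <- .pls_init(X[!test, , drop = FALSE], y[!test], scale)
                for (hh in seq_len(h - 1L))
                    st <- .pls_step(st, chosen[hh])
                Xte <- X[test, , drop = FALSE]
                for (g in seq_along(grid)) {
                    fit <- .pls_finalize(.pls_step(st, grid[g]))
                    pred[test, g] <- as.character(
                        .pls_predict(fit, Xte, distance))
                }
            }
            for (g in seq_along(grid)) {
                pr <- factor(pred[, g], levels = lev)
                err[r, g] <- .error_rates(y, pr)[[criterion]]
            }
        }
        m <- colMeans(err)
        s <- apply(err, 2, sd)
        best <- grid[which.min(m)]      # which.min takes the first (smallest)
        chosen <- c(chosen, best)
        curves[[h]] <- data.frame(component = h, keepX = grid,
                                  mean = m, sd = s)
    }
    new("TuningResult", grid = grid,
        errorCurve = do.call(rbind, curves),
        chosen = chosen, criterion = criterion)
}
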