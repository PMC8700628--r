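#' Stratified fold assignment
#'
#' Within each class, samples are permuted by the seeded generator and dealt
#' round-robin into k folds, so per-class fold sizes differ by at most one
#' and every fold contains every class (required for balanced error with a
#' 13-sample class under 5-fold splits).
#'
#' @param labels class label per sample.
#' @param k number of folds.
#' @param seed integer seed.
#' @return an integer fold index (1..k) per sample.
#' @examples
#' table(stratifiedFolds(rep(c("a", "b"), c(65, 13)), 5, 1),
#'       rep(c("a", "b"), c(65, 13)))
#' @export
stratifiedFolds <- function(labels, k, seed) {
    y <- factor(labels)
    if (k < 2) stop("`k` must be >= 2")
    small <- table(y) < k
    if (any(small))
        stop("class(es) smaller than k folds: ",
             paste(names(small)[small], collapse = ", "))
    set.seed(as.integer(seed))
    out <- integer(length(y))
    for (cl in levels(y)) {
        idx <- which(y == cl)
        out[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
    out
}

# overall and balanced error rates from true/predicted factors on the same
# levels; NA predictions count as errors
.error_rates <- function(truth, pred) {
    wrong <- is.na(pred) | as.character(pred) != as.character(truth)
    per_class <- vapply(levels(factor(truth)),
                        function(cl) mean(wrong[truth == cl]), numeric(1))
    list(oer = mean(wrong), ber = mean(per_class))
}

#' Fitter constructors for cross-validation
#'
#' Build the model-fitting closures [crossValidate()] consumes. A fitter is
#' called with a training matrix (samples x genes) and training labels and
#' must return a prediction function over a test matrix with the same gene
#' columns. `plsdaFitter()` wraps the dense fit, `splsdaFitter()` the sparse
#' fit at fixed keepX, and `prunedPlsdaFitter()` performs the stage-1
#' prune-within-fold procedure: fit dense, score genes against the
#' inter-class direction, prune the top `fraction`, refit on the survivors.
#'
#' @param ncomp components to fit.
#' @param scale scale genes to unit variance.
#' @param distance prediction rule.
#' @param keepX genes kept per component (sparse fitter).
#' @param fraction fraction of top-scoring genes pruned inside each training
#'   fold (pruned fitter).
#' @return a function `(X, y) -> function(Xnew) -> factor`.
#' @name fitters
NULL

#' @rdname fitters
#' @export
plsdaFitter <- function(ncomp = 2, scale = TRUE, distance = "max_score") {
    force(ncomp); force(scale); force(distance)
    function(X, y) {
        fit <- .pls_engine(X, y, ncomp, keepx = NULL, do_scale = scale)
        function(Xnew) .pls_predict(fit, Xnew, distance)
    }
}

#' @rdname fitters
#' @export
splsdaFitter <- function(ncomp = 2, keepX, scale = TRUE,
                         distance = "max_score") {
    force(ncomp); force(keepX); force(scale); force(distance)
    function(X, y) {
        kx <- as.integer(rep_len(keepX, ncomp))
        kx <- pmin(kx, ncol(X))
        fit <- .pls_engine(X, y, ncomp, keepx = kx, do_scale = scale)
        function(Xnew) .pls_predict(fit, Xnew, distance)
    }
}

#' @rdname fitters
#' @export
prunedPlsdaFitter <- function(ncomp = 2, fraction = 0.5, scale = TRUE,
                              distance = "max_score") {
    force(ncomp); force(fraction); force(scale); force(distance)
    function(X, y) {
        dense <- .pls_engine(X, y, ncomp, keepx = NULL, do_scale = scale)
        sc <- classDirectionScores(.as_plsda_model(dense))
        keep <- pruneTopFraction(sc, fraction)
        fit <- .pls_engine(X[, keep, drop = FALSE], y, ncomp,
                           keepx = NULL, do_scale = scale)
        function(Xnew) .pls_predict(fit, Xnew[, keep, drop = FALSE],
                                    distance)
    }
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repeat, samples are split into k stratified folds; the fitter is
#' trained on k-1 folds and predicts the held-out fold; held-out predictions
#' are pooled within the repeat before computing the overall error rate
#' (misclassified / total — so unequal fold sizes are weighted by sample)
#' and the balanced error rate (mean per-class error). Any feature selection
#' done by the fitter happens inside each training fold, so no information
#' leaks from test samples.
#'
#' @param fitter a closure from [plsdaFitter()], [splsdaFitter()] or
#'   [prunedPlsdaFitter()] (or any function with the same contract).
#' @param x a genes x samples expression matrix or SummarizedExperiment with
#'   a `"logcpm"` assay.
#' @param labels class label per sample (or a colData column name).
#' @param k folds per repeat.
#' @param repeats number of independent re-randomized splits.
#' @param seed integer seed; repeat r uses seed + r - 1.
#' @return a [CVReport-class].
#' @examples
#' se <- logCPM(filterLowCounts(simulateCounts(simConfig(nGenes = 300))))
#' inflamed <- se[, se$status == "inflamed"]
#' crossValidate(plsdaFitter(ncomp = 2), inflamed, "disease",
#'               repeats = 2, seed = 1)
#' @export
crossValidate <- function(fitter, x, labels, k = 5, repeats = 10, seed = 1) {
    el <- .expr_and_labels(x, labels)
    X <- el$X; y <- el$y
    n <- length(y)
    lev <- levels(y)
    folds <- matrix(NA_integer_, n, repeats)
    per <- data.frame(oer = numeric(repeats), ber = numeric(repeats))
    for (r in seq_len(repeats)) {
        fold_id <- stratifiedFolds(y, k, as.integer(seed) + r - 1L)
        folds[, r] <- fold_id
        pred <- rep(NA_character_, n)
        for (f in seq_len(k)) {
            test <- fold_id == f
            predictor <- tryCatch(
                fitter(X[!test, , drop = FALSE], y[!test]),
                error = function(e) stop(
                    "fitter failed on repeat ", r, ", fold ", f, ": ",
                    conditionMessage(e)))
            pred[test] <- as.character(predictor(X[test, , drop = FALSE]))
        }
        e <- .error_rates(y, factor(pred, levels = lev))
        per$oer[r] <- e$oer
        per$ber[r] <- e$ber
    }
    rownames(folds) <- rownames(X)
    new("CVReport", folds = folds, perRepeat = per,
        oer = mean(per$oer), ber = mean(per$ber),
        k = as.integer(k), repeats = as.integer(repeats),
        seed = as.integer(seed))
}
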