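.get_counts <- function(x) {
    if (is(x, "SummarizedExperiment")) {
        m <- SummarizedExperiment::assay(x, "counts")
    } else {
        m <- x
    }
    m <- as.matrix(m)
    if (any(m < 0)) stop("count matrix has negative entries")
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
        stop("count matrix must have unique gene identifiers as rownames")
    if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
        stop("count matrix must have unique sample identifiers as colnames")
    if (ncol(m) < 2) stop("count matrix must have at least 2 samples")
    m
}

#' Filter genes with very low counts across all samples
#'
#' Keeps genes that clear both of two hurdles: CPM above the cutoff implied
#' by `minCount` at the median library size in at least k samples, where k is
#' the size of the smallest group, and a total count of at least `minTotal`.
#' Row order of survivors is preserved. The rule is idempotent.
#'
#' @param x a SummarizedExperiment with a `"counts"` assay, or a genes x
#'   samples count matrix with dimnames.
#' @param groups optional per-sample group labels used for the smallest-group
#'   size k; for a SummarizedExperiment the `class` column of `colData` is
#'   used when present. With no groups, all samples form one group.
#' @param minCount required count at the median library size.
#' @param minTotal required total count across samples.
#' @return the input with filtered rows (same class as `x`).
#' @examples
#' se <- simulateCounts(simConfig(nGenes = 300, seed = 1))
#' dim(filterLowCounts(se))
#' @importFrom edgeR cpm
#' @export
filterLowCounts <- function(x, groups = NULL, minCount = 10, minTotal = 15) {
    m <- .get_counts(x)
    if (is.null(groups) && is(x, "SummarizedExperiment") &&
        "class" %in% colnames(SummarizedExperiment::colData(x)))
        groups <- x$class
    if (is.null(groups)) groups <- rep("all", ncol(m))
    if (length(groups) != ncol(m))
        stop("`groups` must have one label per sample")
    k <- min(table(groups))
    lib <- colSums(m)
    cutoff <- minCount / stats::median(lib) * 1e6
    cpms <- edgeR::cpm(m, lib.size = lib)
    keep <- rowSums(cpms >= cutoff) >= k & rowSums(m) >= minTotal
    if (!any(keep))
        stop("all genes were removed by the low-count filter; ",
             "lower `minCount`/`minTotal` or check the input")
    if (is(x, "SummarizedExperiment")) x[keep, ] else m[keep, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Computes trimmed-mean-of-M-values factors: per sample, a weighted trimmed
#' mean of gene-wise log2 expression ratios against a reference sample (the
#' one whose upper-quartile CPM is closest to the mean upper-quartile CPM),
#' with genes zero in either sample excluded, double trimming by M-value
#' (`trimM`) and average abundance (`trimA`), and precision weights from the
#' asymptotic binomial variance. Factors are rescaled to geometric mean 1.
#'
#' @param x counts as in [filterLowCounts()]; every column sum must be
#'   positive.
#' @param trimM,trimA two-sided trim fractions for M and A values.
#' @return a [NormFactors-class] object.
#' @examples
#' se <- simulateCounts(simConfig(nGenes = 300, seed = 1))
#' tmmFactors(se)
#' @importFrom edgeR calcNormFactors
#' @export
tmmFactors <- function(x, trimM = 0.30, trimA = 0.05) {
    m <- .get_counts(x)
    lib <- colSums(m)
    if (any(lib == 0))
        stop("sample(s) with all-zero counts: ",
             paste(colnames(m)[lib == 0], collapse = ", "))
    f <- edgeR::calcNormFactors(m, lib.size = lib, method = "TMM",
                                logratioTrim = trimM, sumTrim = trimA)
    # reference column as chosen by the TMM procedure (upper-quartile rule)
    f75 <- apply(m, 2, function(cc) quantile(cc, 0.75)) / lib
    ref <- colnames(m)[which.min(abs(f75 - mean(f75)))]
    new("NormFactors", libSizes = lib, factors = as.numeric(f),
        effectiveSizes = as.numeric(lib * f), refSample = ref)
}

#' Log2 counts per million on effective library sizes
#'
#' value(g, s) = log2( (count + prior_s) / (effectiveSize_s + 2 * prior_s)
#' * 1e6 ), where prior_s is `priorCount` rescaled per sample in proportion
#' to its effective size, so equal-count genes in equal-depth samples agree.
#' Always finite: the prior prevents log of zero.
#'
#' @param x counts as in [filterLowCounts()].
#' @param norm a [NormFactors-class] computed from the same samples; computed
#'   on the fly when missing.
#' @param priorCount average prior count added before the log.
#' @return for a matrix input, the genes x samples log2-CPM matrix; for a
#'   SummarizedExperiment, the same object with an added `"logcpm"` assay.
#' @examples
#' se <- simulateCounts(simConfig(nGenes = 300, seed = 1))
#' se <- logCPM(se)
#' SummarizedExperiment::assay(se, "logcpm")[1:3, 1:3]
#' @importFrom edgeR cpm
#' @export
logCPM <- function(x, norm = tmmFactors(x), priorCount = 2) {
    m <- .get_counts(x)
    if (length(norm@libSizes) != ncol(m) ||
        !isTRUE(all.equal(unname(norm@libSizes), unname(colSums(m)))))
        stop("normalization result does not match the sample set of `x`")
    lc <- edgeR::cpm(m, lib.size = norm@effectiveSizes, log = TRUE,
                     prior.count = priorCount)
    dimnames(lc) <- dimnames(m)
    if (is(x, "SummarizedExperiment")) {
        SummarizedExperiment::assay(x, "logcpm") <- lc
        x
    } else lc
}

# pull the log-expression matrix (genes x samples) out of whatever the user
# handed us
.get_expr <- function(x) {
    if (is(x, "SummarizedExperiment")) {
        if (!"logcpm" %in% SummarizedExperiment::assayNames(x))
            stop("no 'logcpm' assay; run logCPM() first")
        return(SummarizedExperiment::assay(x, "logcpm"))
    }
    as.matrix(x)
}
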