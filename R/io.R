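.check_count_matrix <- function(m) {
    if (anyDuplicated(rownames(m)))
        stop("duplicate gene identifiers in count matrix")
    if (anyDuplicated(colnames(m)))
        stop("duplicate sample identifiers in count matrix")
    if (any(m < 0)) stop("negative counts in count matrix")
    storage.mode(m) <- "integer"
    m
}

#' Read a count matrix
#'
#' TSV layout: header row of sample identifiers, first column gene
#' identifiers. MTX layout: a MatrixMarket sparse matrix plus sidecar
#' one-identifier-per-line text files for genes (rows) and samples
#' (columns). Both readers produce the identical dense integer matrix for
#' equivalent content.
#'
#' @param path path to the TSV or MTX file.
#' @param format `"tsv"` or `"mtx"` (default guessed from the extension).
#' @param genesFile,samplesFile sidecar identifier files, required for MTX
#'   (default: `path` with `.mtx` replaced by `_genes.txt` /
#'   `_samples.txt`).
#' @return a genes x samples integer matrix with dimnames.
#' @importFrom Matrix readMM
#' @export
readCounts <- function(path, format = c("auto", "tsv", "mtx"),
                       genesFile = NULL, samplesFile = NULL) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "tsv") {
        df <- read.delim(path, check.names = FALSE)
        m <- as.matrix(df[, -1, drop = FALSE])
        rownames(m) <- as.character(df[[1]])
    } else {
        if (is.null(genesFile)) genesFile <- sub("\\.mtx$", "_genes.txt", path)
        if (is.null(samplesFile))
            samplesFile <- sub("\\.mtx$", "_samples.txt", path)
        m <- as.matrix(Matrix::readMM(path))
        rownames(m) <- readLines(genesFile)
        colnames(m) <- readLines(samplesFile)
    }
    .check_count_matrix(m)
}

#' Write a count matrix as TSV
#'
#' @param counts genes x samples matrix, or a SummarizedExperiment with a
#'   `"counts"` assay.
#' @param path output path.
#' @export
writeCounts <- function(counts, path) {
    m <- .get_counts(counts)
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

.meta_vocab <- list(disease = c("CD", "UC"), status = c("inflamed", "normal"))

#' Read and validate a sample metadata table
#'
#' Expects a TSV with columns `sample_id`, `disease` (CD or UC) and `status`
#' (inflamed or normal); any other vocabulary is rejected with the offending
#' row named.
#'
#' @param path path to the metadata TSV.
#' @return a data.frame with factor columns `disease`, `status` and `class`
#'   (their cross), rownames = sample ids.
#' @export
readMetadata <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- read.delim(path, colClasses = "character")
    need <- c("sample_id", "disease", "status")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample identifiers in metadata")
    for (col in c("disease", "status")) {
        bad <- which(!df[[col]] %in% .meta_vocab[[col]])
        if (length(bad))
            stop("metadata row ", bad[1L], " (sample '",
                 df$sample_id[bad[1L]], "') has ", col, " = '",
                 df[[col]][bad[1L]], "'; allowed values: ",
                 paste(.meta_vocab[[col]], collapse = ", "))
    }
    out <- data.frame(
        sample_id = df$sample_id,
        disease = factor(df$disease, levels = .meta_vocab$disease),
        status = factor(df$status, levels = .meta_vocab$status),
        row.names = df$sample_id)
    out$class <- factor(paste(out$disease, out$status, sep = "_"),
                        levels = .sim_classes)
    out
}

#' Write sample metadata as TSV
#'
#' @param meta a data.frame with `sample_id`, `disease`, `status` columns or
#'   a SummarizedExperiment with those colData columns.
#' @param path output path.
#' @export
writeMetadata <- function(meta, path) {
    if (is(meta, "SummarizedExperiment"))
        meta <- as.data.frame(SummarizedExperiment::colData(meta))
    write.table(meta[, c("sample_id", "disease", "status")], path,
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Assemble counts and metadata into a SummarizedExperiment
#'
#' Validates that the sample sets of the count matrix and metadata match
#' exactly, then builds the container the pipeline operates on.
#'
#' @param counts genes x samples integer matrix (see [readCounts()]).
#' @param meta validated metadata (see [readMetadata()]).
#' @return a SummarizedExperiment with assay `"counts"`.
#' @export
buildExperiment <- function(counts, meta) {
    counts <- .check_count_matrix(as.matrix(counts))
    extra <- setdiff(colnames(counts), meta$sample_id)
    absent <- setdiff(meta$sample_id, colnames(counts))
    if (length(extra) || length(absent))
        stop("sample sets of counts and metadata differ",
             if (length(extra)) paste0("; counts-only: ",
                                       paste(head(extra, 3), collapse = ", ")),
             if (length(absent)) paste0("; metadata-only: ",
                                        paste(head(absent, 3), collapse = ", ")))
    meta <- meta[colnames(counts), , drop = FALSE]
    SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(meta))
}
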