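#' Build a simulation configuration
#'
#' Defaults mirror the study cohort: 29 inflamed and 65 normal CD samples,
#' 20 inflamed and 13 normal UC samples, on a reduced universe of 2000 genes
#' (the cohort's protein-coding universe was 19,596; reduce or raise with
#' `nGenes`). Three disjoint gene sets are planted: inflammation genes shift
#' both inflamed classes identically (the dominant axis of variation),
#' disease genes separate inflamed CD from inflamed UC (the stage-2 signal),
#' and segment genes separate normal CD from normal UC, emulating the
#' terminal-ileum vs rectum origin of normal biopsies (the confound stage 1
#' prunes). Within each set, half of the genes go up and half down.
#'
#' @param nCDInflamed,nCDNormal,nUCInflamed,nUCNormal class sizes.
#' @param nGenes number of genes.
#' @param nInflammationGenes,nDiseaseGenes,nSegmentGenes planted set sizes.
#' @param lfcInflammation,lfcDisease,lfcSegment absolute log2 fold changes
#'   (>= 0; 0 disables the effect).
#' @param nbDispersion negative-binomial dispersion phi
#'   (variance = mu + phi mu^2).
#' @param libsizeLogMean,libsizeLogSd log-normal depth-factor parameters
#'   (natural log scale).
#' @param baselineLogMean,baselineLogSd per-gene baseline log2 expression
#'   distribution.
#' @param seed integer seed; identical configs give bit-identical counts.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nGenes = 500, seed = 7)
#' cfg
#' @export
simConfig <- function(nCDInflamed = 29, nCDNormal = 65,
                      nUCInflamed = 20, nUCNormal = 13,
                      nGenes = 2000,
                      nInflammationGenes = 200,
                      nDiseaseGenes = 20,
                      nSegmentGenes = 100,
                      lfcInflammation = 2,
                      lfcDisease = 1.5,
                      lfcSegment = 2,
                      nbDispersion = 0.1,
                      libsizeLogMean = 0, libsizeLogSd = 0.3,
                      baselineLogMean = 4, baselineLogSd = 2,
                      seed = 1L) {
    new("SimConfig",
        nPerClass = as.integer(c(nCDInflamed, nCDNormal,
                                 nUCInflamed, nUCNormal)),
        nGenes = as.integer(nGenes),
        nInflammationGenes = as.integer(nInflammationGenes),
        nDiseaseGenes = as.integer(nDiseaseGenes),
        nSegmentGenes = as.integer(nSegmentGenes),
        lfcInflammation = as.numeric(lfcInflammation),
        lfcDisease = as.numeric(lfcDisease),
        lfcSegment = as.numeric(lfcSegment),
        nbDispersion = as.numeric(nbDispersion),
        libsizeLogMean = as.numeric(libsizeLogMean),
        libsizeLogSd = as.numeric(libsizeLogSd),
        baselineLogMean = as.numeric(baselineLogMean),
        baselineLogSd = as.numeric(baselineLogSd),
        seed = as.integer(seed))
}

.sim_classes <- c("CD_inflamed", "CD_normal", "UC_inflamed", "UC_normal")

#' Simulate a four-class RNA-seq count matrix
#'
#' Draws counts from a Gamma-Poisson (negative-binomial) model. Each gene g
#' has a baseline log2 mean b_g ~ N(baselineLogMean, baselineLogSd); planted
#' effects add a signed log2 shift e_gc per class c; each sample j carries a
#' log-normal depth factor s_j; the count is NB with mean
#' mu_gcj = s_j * 2^(b_g + e_gc) and dispersion phi.
#'
#' @param config a [SimConfig-class] from [simConfig()].
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"counts"` (genes x samples), `colData` columns `disease`
#'   (CD/UC), `status` (inflamed/normal), `class` and `depth_factor`,
#'   `rowData` columns `role` (inflammation/disease/segment/null) and
#'   `direction`, and `metadata()$groundTruth` holding the planted gene sets
#'   and the gene x class matrix of expected log2 means.
#' @examples
#' se <- simulateCounts(simConfig(nGenes = 200, seed = 1))
#' table(se$class)
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata
#' @export
simulateCounts <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    set.seed(config@seed)

    p <- config@nGenes
    ncls <- config@nPerClass
    n <- sum(ncls)
    gene_ids <- sprintf("g%04d", seq_len(p))
    cls <- factor(rep(.sim_classes, ncls), levels = .sim_classes)
    sample_ids <- paste0(substr(as.character(cls), 1, 2),
                         ifelse(grepl("inflamed", cls), "i", "n"),
                         unlist(lapply(ncls, seq_len)))

    baseline <- rnorm(p, config@baselineLogMean, config@baselineLogSd)

    idx <- sample.int(p, config@nInflammationGenes + config@nDiseaseGenes +
                          config@nSegmentGenes)
    infl <- idx[seq_len(config@nInflammationGenes)]
    dis <- idx[config@nInflammationGenes + seq_len(config@nDiseaseGenes)]
    seg <- idx[config@nInflammationGenes + config@nDiseaseGenes +
                   seq_len(config@nSegmentGenes)]

    # signed shifts: first half of each set up, second half down; "down" for
    # the disease/segment pairs means up in the opposing class instead, so the
    # between-class |log2FC| equals the configured value in both directions
    half_dir <- function(k) rep(c(1, -1), length.out = k)
    E <- matrix(0, p, 4, dimnames = list(gene_ids, .sim_classes))
    if (length(infl)) {
        d <- half_dir(length(infl)) * config@lfcInflammation
        E[infl, "CD_inflamed"] <- E[infl, "CD_inflamed"] + d
        E[infl, "UC_inflamed"] <- E[infl, "UC_inflamed"] + d
    }
    if (length(dis)) {
        d <- half_dir(length(dis))
        up_cd <- d > 0
        E[dis[up_cd], "CD_inflamed"] <- E[dis[up_cd], "CD_inflamed"] +
            config@lfcDisease
        E[dis[!up_cd], "UC_inflamed"] <- E[dis[!up_cd], "UC_inflamed"] +
            config@lfcDisease
    }
    if (length(seg)) {
        d <- half_dir(length(seg))
        up_cd <- d > 0
        E[seg[up_cd], "CD_normal"] <- E[seg[up_cd], "CD_normal"] +
            config@lfcSegment
        E[seg[!up_cd], "UC_normal"] <- E[seg[!up_cd], "UC_normal"] +
            config@lfcSegment
    }

    depth <- exp(rnorm(n, config@libsizeLogMean, config@libsizeLogSd))
    log2mu <- baseline + E[, as.integer(cls), drop = FALSE]
    mu <- sweep(2^log2mu, 2, depth, "*")
    counts <- matrix(rnbinom(p * n, size = 1 / config@nbDispersion, mu = mu),
                     nrow = p, dimnames = list(gene_ids, sample_ids))
    storage.mode(counts) <- "integer"

    role <- rep("null", p)
    role[infl] <- "inflammation"
    role[dis] <- "disease"
    role[seg] <- "segment"
    direction <- rep(0L, p)
    direction[infl] <- as.integer(half_dir(length(infl)))
    direction[dis] <- as.integer(half_dir(length(dis)))
    direction[seg] <- as.integer(half_dir(length(seg)))

    truth <- list(
        inflammation_genes = gene_ids[infl],
        disease_genes = gene_ids[dis],
        segment_genes = gene_ids[seg],
        expected_log2_mean = baseline + E)

    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(gene_id = gene_ids, role = role,
                            direction = direction),
        colData = DataFrame(
            sample_id = sample_ids,
            disease = factor(sub("_.*", "", cls), levels = c("CD", "UC")),
            status = factor(sub(".*_", "", cls),
                            levels = c("inflamed", "normal")),
            class = cls,
            depth_factor = depth,
            row.names = sample_ids))
    S4Vectors::metadata(se)$groundTruth <- truth
    S4Vectors::metadata(se)$simConfig <- config
    se
}

#' Planted ground truth of a simulated experiment
#'
#' @param se a SummarizedExperiment produced by [simulateCounts()].
#' @return the ground-truth list stored at simulation time (planted gene sets
#'   and expected log2 means).
#' @export
groundTruth <- function(se) {
    gt <- S4Vectors::metadata(se)$groundTruth
    if (is.null(gt))
        stop("no ground truth: object was not produced by simulateCounts()")
    gt
}
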