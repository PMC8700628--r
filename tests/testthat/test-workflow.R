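test_that("count TSV and MTX round trips reproduce the matrix exactly", {
    m <- rand_counts(25, 6, seed = 111)
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeCounts(m, tsv)
    expect_identical(readCounts(tsv), m)

    mtx <- withr::local_tempfile(fileext = ".mtx")
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), mtx)
    writeLines(rownames(m), sub("\\.mtx$", "_genes.txt", mtx))
    writeLines(colnames(m), sub("\\.mtx$", "_samples.txt", mtx))
    expect_identical(readCounts(mtx), m)
})

test_that("metadata validation names the offending row and vocabulary", {
    meta <- data.frame(sample_id = c("s1", "s2", "s3"),
                       disease = c("CD", "UC", "CD"),
                       status = c("inflamed", "normal", "inflammed"))
    path <- withr::local_tempfile(fileext = ".tsv")
    write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readMetadata(path), "row 3.*inflammed.*inflamed, normal")

    meta$status[3] <- "normal"
    write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
    md <- readMetadata(path)
    expect_equal(levels(md$disease), c("CD", "UC"))
    expect_equal(as.character(md$class[1]), "CD_inflamed")
})

test_that("experiment assembly rejects mismatched samples, duplicates and negatives", {
    m <- rand_counts(10, 4, seed = 112)
    meta <- data.frame(sample_id = colnames(m),
                       disease = rep(c("CD", "UC"), 2),
                       status = rep(c("inflamed", "normal"), each = 2))
    rownames(meta) <- meta$sample_id
    se <- buildExperiment(m, meta)
    expect_s4_class(se, "SummarizedExperiment")

    expect_error(buildExperiment(m[, 1:3], meta), "sample sets")
    m_dup <- m; colnames(m_dup)[2] <- colnames(m_dup)[1]
    expect_error(buildExperiment(m_dup, meta), "duplicate sample")
    m_neg <- m; m_neg[1, 1] <- -1L
    expect_error(buildExperiment(m_neg, meta), "negative")
})

test_that("the two-stage run is deterministic and keeps its stages separate", {
    se <- simulateCounts(simConfig(nGenes = 400, seed = 9))
    cfg <- analysisConfig(keepXGrid = c(5, 20, 50), stageRepeats = 2,
                          tuneRepeats = 2, finalEvalRepeats = 3, seed = 11)
    rep1 <- runTwoStage(se, cfg)
    rep2 <- runTwoStage(se, cfg)

    # stage separation: the stage-2 universe is exactly the pruned survivors
    expect_identical(rep1@keptGenes,
                     pruneTopFraction(rep1@pruneScores,
                                      rep1@pruneFraction))
    expect_identical(sort(c(rep1@keptGenes, rep1@prunedGenes)),
                     sort(names(rep1@pruneScores)))
    expect_setequal(rep1@finalModel@geneIds, rep1@keptGenes)

    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    writeReport(rep1, d1)
    writeReport(rep2, d2)
    for (f in c("signatures.tsv", "trench_table.tsv", "tuning_curve.tsv",
                "pruned_genes.tsv", "pca_scores.tsv"))
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))),
                         label = f)
    expect_true(file.exists(file.path(d1, "report.json")))

    js <- jsonlite::read_json(file.path(d1, "report.json"),
                              simplifyVector = TRUE)
    expect_equal(js$config$pruneFraction, cfg$pruneFraction)
    expect_equal(js$config$seed, cfg$seed)
    expect_equal(js$config$folds, 5)
    expect_equal(js$config$distance, "max_score")
    expect_equal(sort(js$tuning$chosen), sort(chosenKeepX(rep1@tuning)))
})

test_that("the default configuration echoes the documented protocol", {
    cfg <- analysisConfig()
    expect_equal(cfg$pruneFraction, 0.5)
    expect_equal(cfg$trenchFractions, c(0.25, 0.5, 0.75))
    expect_equal(cfg$keepXGrid, 1:300)
    expect_equal(cfg$folds, 5L)
    expect_equal(cfg$stageRepeats, 10L)
    expect_equal(cfg$tuneRepeats, 100L)
    expect_equal(cfg$finalEvalRepeats, 100L)
    expect_error(analysisConfig(pruneFraction = 1), "\\[0, 1\\)")
})

test_that("stage 1 never sees inflamed labels; stage 2 is a function of inflamed samples and kept genes", {
    se <- simulateCounts(simConfig(nGenes = 400, seed = 13))
    cfg <- analysisConfig(keepXGrid = c(5, 20), stageRepeats = 2,
                          tuneRepeats = 2, finalEvalRepeats = 2, seed = 13)
    rep1 <- runTwoStage(se, cfg)

    # permuting disease labels within the inflamed samples must leave every
    # stage-1 quantity untouched
    se2 <- se
    infl <- which(se$status == "inflamed")
    set.seed(99)
    se2$disease[infl] <- se$disease[sample(infl)]
    rep2 <- runTwoStage(se2, cfg)
    expect_identical(rep2@pruneScores, rep1@pruneScores)
    expect_identical(rep2@keptGenes, rep1@keptGenes)
    expect_identical(rep2@trenchTable$stage1_error,
                     rep1@trenchTable$stage1_error)
    expect_identical(plsWeights(rep2@stage1Model),
                     plsWeights(rep1@stage1Model))

    # the final sparse model is reproducible from the inflamed samples
    # restricted to the kept genes alone: no normal sample enters the fit
    expr <- logCPM(filterLowCounts(
        SummarizedExperiment::assay(se, "counts"),
        groups = paste(se$disease, se$status)))
    infl_expr <- expr[rep1@keptGenes, se$status == "inflamed"]
    refit <- fitSPLSDA(infl_expr, droplevels(se$disease[infl]),
                       ncomp = rep1@stage2Ncomp,
                       keepX = chosenKeepX(rep1@tuning))
    expect_equal(plsWeights(refit), plsWeights(rep1@finalModel),
                 tolerance = 1e-12)
})

test_that("a missing class is rejected before any computation", {
    se <- simulateCounts(simConfig(nGenes = 120, nInflammationGenes = 12,
                                   nDiseaseGenes = 6, nSegmentGenes = 6,
                                   seed = 10))
    sub <- se[, se$class != "UC_normal"]
    expect_error(runTwoStage(sub, analysisConfig()), "every class needs")
})
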