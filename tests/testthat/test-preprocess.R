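test_that("low-count filter removes zeros, keeps abundant genes, matches a brute-force rule", {
    m <- rand_counts(50, 6, seed = 2, lambda = 500)
    m["g001", ] <- 0L
    kept <- filterLowCounts(m)
    expect_false("g001" %in% rownames(kept))
    expect_equal(rownames(kept), setdiff(rownames(m), "g001"))

    big <- rand_counts(20, 4, seed = 3, lambda = 2000)
    big[big < 1000L] <- 1000L
    expect_identical(filterLowCounts(big), big)

    # 4-gene x 4-sample toy, two groups of two -> k = 2; scalar rule applied
    # gene by gene, independently of the vectorized implementation
    toy <- matrix(c(  0L,  1L,  0L,  2L,
                     30L, 40L,  2L,  1L,
                      5L,  6L,  7L,  8L,
                    400L, 350L, 500L, 450L), 4, 4, byrow = TRUE,
                  dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
    groups <- c("a", "a", "b", "b")
    lib <- colSums(toy)
    cutoff <- 10 / median(lib) * 1e6
    keep_brute <- vapply(seq_len(4), function(g) {
        n_pass <- 0
        for (j in seq_len(4))
            if (toy[g, j] / lib[j] * 1e6 >= cutoff) n_pass <- n_pass + 1
        n_pass >= 2 && sum(toy[g, ]) >= 15
    }, logical(1))
    expect_identical(rownames(filterLowCounts(toy, groups)),
                     rownames(toy)[keep_brute])
})

test_that("low-count filter is idempotent and errors when nothing survives", {
    m <- rand_counts(80, 5, seed = 4, lambda = 12)
    once <- filterLowCounts(m)
    expect_lt(nrow(once), nrow(m))
    expect_identical(filterLowCounts(once), once)
    tiny <- matrix(1L, 3, 3, dimnames = list(paste0("g", 1:3),
                                             paste0("s", 1:3)))
    expect_error(filterLowCounts(tiny), "all genes were removed")
})

test_that("TMM factors: identical columns and pure depth changes give factor 1", {
    one <- rand_counts(30, 1, seed = 5, lambda = 200)[, 1]
    same <- cbind(s1 = one, s2 = one, s3 = one)
    rownames(same) <- sprintf("g%03d", seq_along(one))
    expect_equal(normFactors(tmmFactors(same)), rep(1, 3))

    depth <- cbind(s1 = one, s2 = 2L * one, s3 = 4L * one)
    rownames(depth) <- rownames(same)
    expect_equal(normFactors(tmmFactors(depth)), rep(1, 3))
})

test_that("TMM matches the manual trimmed-mean oracle and normalizes its geometric mean", {
    toy <- tmm_toy()
    expect_equal(normFactors(tmmFactors(toy)), manual_tmm(toy),
                 tolerance = 1e-9)
    for (s in 1:5) {
        m <- rand_counts(60, 4, seed = 100 + s, lambda = 80)
        f <- normFactors(tmmFactors(m))
        expect_lt(abs(mean(log(f))), 1e-9)
        expect_equal(f, manual_tmm(m), tolerance = 1e-9)
    }
    zero <- rand_counts(10, 3, seed = 6)
    zero[, 2] <- 0L
    expect_error(tmmFactors(zero), "all-zero")
})

test_that("TMM factors are invariant to column order", {
    m <- rand_counts(60, 5, seed = 7, lambda = 120)
    f <- normFactors(tmmFactors(m))
    perm <- c(3, 1, 5, 2, 4)
    f_perm <- normFactors(tmmFactors(m[, perm]))
    expect_equal(f_perm, f[perm], tolerance = 1e-12)
})

test_that("log-CPM matches the formula, stays finite, and respects CPM scale invariance", {
    cnt <- matrix(c(100L, 100L, 999900L, 999900L), 2, 2, byrow = TRUE,
                  dimnames = list(c("g1", "g2"), c("s1", "s2")))
    norm <- new("NormFactors", libSizes = colSums(cnt), factors = c(1, 1),
                effectiveSizes = as.numeric(colSums(cnt)),
                refSample = "s1")
    lc <- logCPM(cnt, norm, priorCount = 2)
    # value frozen from the formula log2((100 + 2) / (1e6 + 4) * 1e6)
    expect_equal(lc["g1", "s1"], 6.67241957120287, tolerance = 1e-12)
    expect_equal(lc["g1", "s1"], log2((100 + 2) / (1e6 + 4) * 1e6),
                 tolerance = 1e-12)

    # a zero-count gene at equal effective sizes: constant finite row
    cnt0 <- rbind(cnt, g3 = c(0L, 0L))
    norm0 <- new("NormFactors", libSizes = colSums(cnt0),
                 factors = c(1, 1),
                 effectiveSizes = as.numeric(colSums(cnt0)),
                 refSample = "s1")
    lc0 <- logCPM(cnt0, norm0)
    expect_true(all(is.finite(lc0)))
    expect_equal(lc0["g3", "s1"], lc0["g3", "s2"])

    # doubling counts and depths is exactly invariant without the prior,
    # and invariant up to the prior's vanishing contribution with it
    m <- rand_counts(40, 3, seed = 8, lambda = 500)
    f1 <- tmmFactors(m); f2 <- tmmFactors(2L * m)
    expect_equal(logCPM(m, f1, priorCount = 0),
                 logCPM(2L * m, f2, priorCount = 0), tolerance = 1e-12)
    expect_equal(logCPM(m, f1), logCPM(2L * m, f2), tolerance = 0.02)
})

test_that("log-CPM is strictly increasing in the count entry", {
    m <- rand_counts(20, 3, seed = 9, lambda = 100)
    ks <- c(0L, 1L, 10L, 100L, 1000L)
    # gene 2 absorbs the difference so library sizes (and hence the
    # normalization) stay fixed while only the entry of interest moves
    vals <- vapply(ks, function(k) {
        m2 <- m
        m2[1, 1] <- k
        m2[2, 1] <- m[2, 1] + (max(ks) - k)
        norm <- new("NormFactors", libSizes = colSums(m2),
                    factors = rep(1, 3),
                    effectiveSizes = as.numeric(colSums(m2)),
                    refSample = "s001")
        logCPM(m2, norm)[1, 1]
    }, numeric(1))
    expect_true(all(diff(vals) > 0))
})
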