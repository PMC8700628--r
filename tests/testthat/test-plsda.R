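test_that("first-component weights equal the closed-form cross-covariance direction", {
    set.seed(31)
    X <- rand_expr(10, 12, seed = 31)
    y <- factor(rep(c("A", "B"), each = 6))
    X[1:3, y == "A"] <- X[1:3, y == "A"] + 2
    fit <- fitPLSDA(X, y, ncomp = 1, scale = TRUE)
    Xs <- scale(t(X), center = TRUE, scale = TRUE)
    z <- as.numeric(y == "A"); z <- z - mean(z)
    w_oracle <- as.numeric(crossprod(Xs, z))
    w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
    w <- plsWeights(fit)[, 1]
    expect_gt(abs(sum(w * w_oracle)), 1 - 1e-8)
})

test_that("two-component scores match the indicator-deflation oracle and mixOmics", {
    X <- rand_expr(10, 12, seed = 32)
    y <- factor(rep(c("A", "B"), each = 6))
    X[1:2, y == "A"] <- X[1:2, y == "A"] + 1.5
    fit <- fitPLSDA(X, y, ncomp = 2)
    TT <- indicator_pls_scores(t(X), y, ncomp = 2)
    for (h in 1:2)
        expect_same_up_to_sign(plsScores(fit)[, h], TT[, h], 1e-6)
    skip_if_not_installed("mixOmics")
    mo <- mixOmics::plsda(t(X), y, ncomp = 2, scale = TRUE)
    for (h in 1:2) {
        expect_same_up_to_sign(plsScores(fit)[, h], mo$variates$X[, h], 1e-6)
        expect_same_up_to_sign(plsWeights(fit)[, h], mo$loadings$X[, h],
                               1e-6)
    }
})

test_that("well-separated clouds give zero training error and duplication leaves weights unchanged", {
    sc <- sep_clouds(p = 15, n_per = 5, gap = 40, seed = 33)
    fit <- fitPLSDA(sc$expr, sc$y, ncomp = 1)
    expect_equal(as.character(predict(fit, sc$expr)), as.character(sc$y))

    X <- rand_expr(12, 10, seed = 34)
    y <- factor(rep(c("A", "B"), each = 5))
    f1 <- fitPLSDA(X, y, ncomp = 2)
    f2 <- fitPLSDA(cbind(X, X + 0), factor(c(y, y)), ncomp = 2)
    expect_equal(unname(plsWeights(f1)), unname(plsWeights(f2)),
                 tolerance = 1e-8)
})

test_that("prediction distances follow the contract, ties break alphabetically", {
    X <- rand_expr(8, 20, seed = 35)
    y <- factor(rep(c("A", "B"), each = 10))
    X[1:4, y == "A"] <- X[1:4, y == "A"] + 3
    fit <- fitPLSDA(X, y, ncomp = 2)

    # brute-force centroid assignment over latent scores
    TT <- plsScores(fit)
    cm <- rbind(colMeans(TT[y == "A", ]), colMeans(TT[y == "B", ]))
    brute <- apply(TT, 1, function(t)
        c("A", "B")[which.min(c(sum((t - cm[1, ])^2),
                                sum((t - cm[2, ])^2)))])
    expect_equal(as.character(predict(fit, X, distance = "centroid")),
                 unname(brute))

    # a sample constructed to sit exactly at the class-A score centroid
    Xs <- scale(t(X), center = fit@centers, scale = fit@scales)
    target <- fit@classScoreMeans["A", ]
    # invert (minimal-norm) back to preprocessed space, then undo scaling
    R <- fit@rotations
    xa <- R %*% solve(crossprod(R), target)
    xnew <- matrix(xa * fit@scales + fit@centers, ncol = 1,
                   dimnames = list(rownames(X), "new"))
    expect_equal(as.character(predict(fit, xnew, distance = "centroid")),
                 "A")

    # the grand mean of balanced classes has an exactly zero indicator
    # margin: the tie goes to the alphabetically first label
    xc <- matrix(fit@centers, ncol = 1,
                 dimnames = list(rownames(X), "ctr"))
    expect_equal(as.character(predict(fit, xc, distance = "max_score")),
                 "A")

    expect_error(predict(fit, X[-1, , drop = FALSE]), "missing model gene")
})

test_that("degenerate and invalid inputs are rejected", {
    X <- rand_expr(6, 9, seed = 36)
    expect_error(fitPLSDA(X, factor(rep(c("A", "B", "C"), each = 3))),
                 "two distinct class")
    expect_error(fitPLSDA(X, factor(rep(c("A", "B"), c(8, 1)))),
                 "at least 2 samples")
    expect_error(fitPLSDA(X, factor(rep(c("A", "B"), c(4, 5))), ncomp = 9),
                 "rank")
})

test_that("score columns are orthogonal for every fitted model", {
    for (s in 1:5) {
        X <- rand_expr(25, 14, seed = 40 + s)
        y <- factor(rep(c("A", "B"), each = 7))
        fit <- fitPLSDA(X, y, ncomp = 3)
        G <- crossprod(plsScores(fit))
        off <- abs(G[upper.tri(G)]) /
            sqrt(tcrossprod(diag(G))[upper.tri(G)])
        expect_lt(max(off), 1e-6)
        expect_true(validObject(fit))
    }
})

test_that("class-direction scores find a planted single discriminator", {
    hits <- 0L
    for (s in 1:20) {
        X <- rand_expr(30, 16, seed = 50 + s)
        y <- factor(rep(c("A", "B"), each = 8))
        X[7, y == "A"] <- X[7, y == "A"] + 4      # lone true discriminator
        fit <- fitPLSDA(X, y, ncomp = 2)
        sc <- classDirectionScores(fit)
        if (names(which.max(sc)) == rownames(X)[7]) hits <- hits + 1L
    }
    expect_gte(hits, 19L)
})

test_that("class-direction scores: one component reduces to |loading|, label swap and gene order are immaterial", {
    X <- rand_expr(12, 10, seed = 61)
    y <- factor(rep(c("A", "B"), each = 5))
    X[1:2, y == "A"] <- X[1:2, y == "A"] + 2
    f1 <- fitPLSDA(X, y, ncomp = 1)
    expect_equal(unname(classDirectionScores(f1)),
                 unname(abs(plsLoadings(f1)[, 1])))

    f2 <- fitPLSDA(X, y, ncomp = 2)
    y_swapped <- factor(as.character(y), levels = c("B", "A"))
    f2s <- fitPLSDA(X, y_swapped, ncomp = 2)
    expect_equal(classDirectionScores(f2), classDirectionScores(f2s),
                 tolerance = 1e-9)

    perm <- sample(nrow(X))
    f2p <- fitPLSDA(X[perm, ], y, ncomp = 2)
    expect_equal(classDirectionScores(f2p),
                 classDirectionScores(f2)[rownames(X)[perm]],
                 tolerance = 1e-9)
})
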