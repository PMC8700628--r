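# Fixtures are generated in code; seeds fixed per call site.

# random expression matrix, genes x samples, with dimnames
rand_expr <- function(p, n, seed = 1, mean = 5, sd = 1) {
    set.seed(seed)
    matrix(rnorm(p * n, mean, sd), p, n,
           dimnames = list(sprintf("g%03d", seq_len(p)),
                           sprintf("s%03d", seq_len(n))))
}

# random count matrix with positive library sizes
rand_counts <- function(p, n, seed = 1, lambda = 50) {
    set.seed(seed)
    m <- matrix(rpois(p * n, lambda), p, n,
                dimnames = list(sprintf("g%03d", seq_len(p)),
                                sprintf("s%03d", seq_len(n))))
    storage.mode(m) <- "integer"
    m
}

# two well-separated Gaussian clouds; returns list(expr genes x samples, y)
sep_clouds <- function(p = 20, n_per = 6, gap = 50, seed = 1) {
    set.seed(seed)
    X <- matrix(rnorm(2 * n_per * p), 2 * n_per, p)
    X[seq_len(n_per), ] <- X[seq_len(n_per), ] + gap
    dimnames(X) <- list(sprintf("s%02d", seq_len(2 * n_per)),
                        sprintf("g%03d", seq_len(p)))
    list(expr = t(X),
         y = factor(rep(c("A", "B"), each = n_per)))
}

# independent step-by-step TMM oracle (manual trimmed-mean walk-through)
manual_tmm <- function(x, trimM = 0.3, trimA = 0.05) {
    lib <- colSums(x)
    f75 <- vapply(seq_len(ncol(x)), function(j)
        quantile(x[, j], 0.75, names = FALSE), numeric(1)) / lib
    ref <- which.min(abs(f75 - mean(f75)))
    f <- vapply(seq_len(ncol(x)), function(j) {
        obs <- x[, j]; rf <- x[, ref]; nO <- lib[j]; nR <- lib[ref]
        M <- log2((obs / nO) / (rf / nR))
        A <- (log2(obs / nO) + log2(rf / nR)) / 2
        v <- (nO - obs) / nO / obs + (nR - rf) / nR / rf
        fin <- is.finite(M) & is.finite(A)
        M <- M[fin]; A <- A[fin]; v <- v[fin]
        if (max(abs(M)) < 1e-6) return(1)
        n <- length(M)
        loL <- floor(n * trimM) + 1; hiL <- n + 1 - loL
        loS <- floor(n * trimA) + 1; hiS <- n + 1 - loS
        keep <- rank(M) >= loL & rank(M) <= hiL &
            rank(A) >= loS & rank(A) <= hiS
        2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
    }, numeric(1))
    f / exp(mean(log(f)))
}

# hand-worked 6-gene x 3-sample TMM toy: one sample-specific high expressor
tmm_toy <- function() {
    matrix(c(1000, 1200,  900,
              500,  450,  520,
              200,  220,  210,
              100,   90,  110,
               50,   60,   55,
               80,   70, 5000), nrow = 6, byrow = TRUE,
           dimnames = list(paste0("g", 1:6), paste0("s", 1:3)))
}

# independent sequential PLS oracle for two classes: every component weight
# is proportional to the deflated cross-covariance with the centered
# class-1 indicator column (no SVD involved)
indicator_pls_scores <- function(X, y, ncomp, scale = TRUE) {
    Xc <- scale(X, center = TRUE, scale = FALSE)
    if (scale) {
        s <- apply(Xc, 2, sd)
        s[s < .Machine$double.eps] <- 1
        Xc <- sweep(Xc, 2, s, "/")
    }
    z <- as.numeric(y == levels(factor(y))[1])
    z <- z - mean(z)
    TT <- matrix(0, nrow(X), ncomp)
    for (h in seq_len(ncomp)) {
        w <- crossprod(Xc, z)
        w <- w / sqrt(sum(w^2))
        tt <- Xc %*% w
        tss <- sum(tt^2)
        p_load <- crossprod(Xc, tt) / tss
        c_load <- sum(z * tt) / tss
        Xc <- Xc - tcrossprod(tt, p_load)
        z <- z - as.numeric(tt) * c_load
        TT[, h] <- tt
    }
    TT
}

# simulated, preprocessed experiment ready for model fitting
sim_expr <- function(cfg) {
    se <- simulateCounts(cfg)
    logCPM(filterLowCounts(se))
}

expect_same_up_to_sign <- function(a, b, tol) {
    d <- min(max(abs(a - b)), max(abs(a + b)))
    expect_lt(d, tol)
}
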