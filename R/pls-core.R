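# Internal PLS-DA engine. X is samples x genes throughout; user-facing
# wrappers transpose from the Bioconductor genes x samples orientation.
# Two-class only: Y is the centered 2-column class indicator matrix and each
# component's weight vector is the leading left singular vector of X'Y
# (equivalently, for two classes, the direction of the scaled between-class
# mean difference of the deflated matrix). Deflation is regression-mode: both
# X and Y are regressed out on the score, which makes score columns exactly
# orthogonal.

.col_center_scale <- function(X, do_scale) {
    centers <- colMeans(X)
    Xc <- sweep(X, 2, centers, "-", check.margin = FALSE)
    if (do_scale) {
        scales <- sqrt(colSums(Xc^2) / (nrow(X) - 1))
        scales[scales < .Machine$double.eps] <- 1   # constant genes untouched
        Xc <- sweep(Xc, 2, scales, "/", check.margin = FALSE)
    } else {
        scales <- rep(1, ncol(X))
    }
    list(X = Xc, centers = centers, scales = scales)
}

.pls_init <- function(X, y, do_scale = TRUE) {
    if (!is.factor(y)) y <- factor(y)
    y <- droplevels(y)
    lev <- levels(y)
    if (length(lev) != 2L)
        stop("exactly two distinct class labels required, got ",
             length(lev))
    if (any(table(y) < 2L))
        stop("each class needs at least 2 samples")
    cs <- .col_center_scale(X, do_scale)
    Y <- cbind(as.numeric(y == lev[1L]), as.numeric(y == lev[2L]))
    ymeans <- colMeans(Y)
    list(Xd = cs$X, Yd = sweep(Y, 2, ymeans, check.margin = FALSE),
         centers = cs$centers, scales = cs$scales, scaled = do_scale,
         ymeans = ymeans, lev = lev, y = y,
         gene_ids = colnames(X),
         W = NULL, P = NULL, C = NULL, TT = NULL, keepx = integer(0))
}

# soft-threshold w to exactly `keep` nonzero entries; lambda is the largest
# magnitude outside the selected set; ties at the cut broken by gene id
.soft_threshold <- function(w, keep, ids) {
    p <- length(w)
    if (keep >= p) return(w)
    aw <- abs(w)
    ord <- order(-aw, ids)
    sel <- ord[seq_len(keep)]
    lambda <- aw[ord[keep + 1L]]
    out <- numeric(p)
    out[sel] <- sign(w[sel]) * (aw[sel] - lambda)
    # exact magnitude ties at the cut would otherwise shrink to zero and
    # break the exact-support contract; retain an infinitesimal weight
    zero_sel <- sel[out[sel] == 0]
    if (length(zero_sel))
        out[zero_sel] <- sign(w[zero_sel]) * .Machine$double.xmin
    out
}

# add one component; keep = NULL means dense
.pls_step <- function(st, keep = NULL) {
    M <- crossprod(st$Xd, st$Yd)                   # p x 2 cross-covariance
    sv <- svd(M, nu = 1L, nv = 1L)
    w <- sv$u[, 1L]
    q <- sv$v[, 1L]
    if (q[1L] < 0 || (q[1L] == 0 && sum(w) < 0)) { w <- -w; q <- -q }
    if (!is.null(keep)) {
        w <- .soft_threshold(w, keep, st$gene_ids)
        nw <- sqrt(sum(w^2))
        if (nw == 0) stop("degenerate sparse weight vector")
        w <- w / nw
    }
    tt <- st$Xd %*% w
    tss <- sum(tt^2)
    if (tss < .Machine$double.eps)
        stop("degenerate component: no covariance left to model ",
             "(ncomp may exceed the rank of the data)")
    p_load <- crossprod(st$Xd, tt) / tss
    c_load <- crossprod(st$Yd, tt) / tss
    st$Xd <- st$Xd - tcrossprod(tt, p_load)
    st$Yd <- st$Yd - tcrossprod(tt, c_load)
    st$W <- cbind(st$W, as.numeric(w))
    st$P <- cbind(st$P, as.numeric(p_load))
    st$C <- cbind(st$C, as.numeric(c_load))
    st$TT <- cbind(st$TT, as.numeric(tt))
    st$keepx <- c(st$keepx, if (is.null(keep)) ncol(st$Xd) else keep)
    st
}

.pls_finalize <- function(st) {
    H <- ncol(st$W)
    R <- st$W %*% solve(crossprod(st$P, st$W))     # rotations: T = Xc R
    B <- R %*% t(st$C)                             # indicator coefficients
    cm <- rbind(colMeans(st$TT[st$y == st$lev[1L], , drop = FALSE]),
                colMeans(st$TT[st$y == st$lev[2L], , drop = FALSE]))
    rownames(cm) <- st$lev
    list(W = st$W, P = st$P, C = st$C, TT = st$TT, R = R, B = B,
         centers = st$centers, scales = st$scales, scaled = st$scaled,
         ymeans = st$ymeans, lev = st$lev, gene_ids = st$gene_ids,
         class_score_means = cm, ncomp = H, keepx = st$keepx)
}

.pls_engine <- function(X, y, ncomp, keepx = NULL, do_scale = TRUE) {
    st <- .pls_init(X, y, do_scale)
    if (ncomp < 1L) stop("ncomp must be >= 1")
    if (ncomp > min(nrow(X) - 1L, ncol(X)))
        stop("ncomp (", ncomp, ") exceeds the rank of the data")
    for (h in seq_len(ncomp))
        st <- .pls_step(st, if (is.null(keepx)) NULL else keepx[h])
    .pls_finalize(st)
}

.pls_preprocess_new <- function(fit, Xnew) {
    Xs <- sweep(Xnew, 2, fit$centers, "-", check.margin = FALSE)
    if (fit$scaled)
        Xs <- sweep(Xs, 2, fit$scales, "/", check.margin = FALSE)
    Xs
}

# predict class labels; Xnew is samples x genes in the training gene order
.pls_predict <- function(fit, Xnew,
                         distance = c("max_score", "centroid")) {
    distance <- match.arg(distance)
    Xs <- .pls_preprocess_new(fit, Xnew)
    first <- fit$lev[order(fit$lev)][1L]            # alphabetical tie-break
    if (distance == "max_score") {
        Yhat <- Xs %*% fit$B
        Yhat <- sweep(Yhat, 2, fit$ymeans, "+", check.margin = FALSE)
        d <- Yhat[, 1L] - Yhat[, 2L]
        pred <- ifelse(d > 0, fit$lev[1L],
                       ifelse(d < 0, fit$lev[2L], first))
    } else {
        Tn <- Xs %*% fit$R
        d1 <- rowSums(sweep(Tn, 2, fit$class_score_means[1L, ],
                            check.margin = FALSE)^2)
        d2 <- rowSums(sweep(Tn, 2, fit$class_score_means[2L, ],
                            check.margin = FALSE)^2)
        pred <- ifelse(d1 < d2, fit$lev[1L],
                       ifelse(d2 < d1, fit$lev[2L], first))
    }
    factor(pred, levels = fit$lev)
}
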