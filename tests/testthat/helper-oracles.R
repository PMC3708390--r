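# Independent brute-force oracles, kept deliberately naive: double loops,
# explicit sorting and textbook closed forms that the implementation under
# test must reproduce.

# Elementwise kernel matrix via the scalar kernel, double loop.
oracleKernelMatrix <- function(spec, X, Y) {
    out <- matrix(NA_real_, nrow(X), nrow(Y))
    for (i in seq_len(nrow(X)))
        for (j in seq_len(nrow(Y)))
            out[i, j] <- kernelEval(spec, X[i, ], Y[j, ])
    out
}

# Explicit double centering H K H with H = I - (1/n) 11'.
oracleCenter <- function(K) {
    n <- nrow(K)
    H <- diag(n) - matrix(1 / n, n, n)
    H %*% K %*% H
}

# Classical PCA scores by eigendecomposition of the covariance matrix.
oraclePCAScores <- function(X, k) {
    Xc <- scale(X, center = TRUE, scale = FALSE)
    ev <- eigen(crossprod(Xc) / nrow(X), symmetric = TRUE)
    Xc %*% ev$vectors[, seq_len(k), drop = FALSE]
}

# Two-class Fisher LDA direction w = Sw^-1 (m1 - m2).
oracleLDADirection <- function(X, labels) {
    cl <- sort(unique(labels))
    stopifnot(length(cl) == 2L)
    X1 <- X[labels == cl[1], , drop = FALSE]
    X2 <- X[labels == cl[2], , drop = FALSE]
    Sw <- crossprod(scale(X1, scale = FALSE)) +
        crossprod(scale(X2, scale = FALSE))
    solve(Sw, colMeans(X1) - colMeans(X2))
}

# KNN by exhaustive distance sort with the same deterministic tie-breaking
# contract (majority, then smallest summed distance, then lowest class).
oracleKNN <- function(points, labels, query, K) {
    d <- apply(points, 1L, function(p) sqrt(sum((p - query)^2)))
    nb <- sort.list(d, method = "radix")[seq_len(K)]
    counts <- table(labels[nb])
    cand <- as.integer(names(counts)[counts == max(counts)])
    if (length(cand) > 1L) {
        sums <- sapply(cand, function(cl) sum(d[nb][labels[nb] == cl]))
        cand <- cand[sums == min(sums)]
    }
    min(cand)
}

# IEFP by explicit per-point summation of EQPC / r^2.
oracleIEFP <- function(points, labels, query, cl) {
    idx <- which(labels == cl)
    eqpc <- 1 / length(idx)
    total <- 0
    for (i in idx)
        total <- total + eqpc / sum((points[i, ] - query)^2)
    total
}

oracleIntensityPredict <- function(points, labels, query) {
    classes <- sort(unique(labels))
    vals <- sapply(classes, function(cl)
        oracleIEFP(points, labels, query, cl))
    min(classes[vals == max(vals)])
}
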