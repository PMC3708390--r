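test_that("linear-kernel KPCA with centering equals classical PCA scores", {
    for (seed in 1:8) {
        set.seed(seed)
        n <- sample(6:20, 1); p <- sample(2:6, 1)
        X <- matrix(rnorm(n * p), n, p)
        k <- min(3, p, n - 1)
        m <- fitKPCA(X, kernelSpec("linear"), k = k)
        ref <- oraclePCAScores(X, k)
        for (j in seq_len(k))
            expect_equal(abs(unname(m@trainScores[, j])), abs(ref[, j]),
                         tolerance = 1e-8)
    }
})

test_that("two centered points project to unit scores of opposite sign", {
    m <- fitKPCA(matrix(c(0, 2), 2, 1), kernelSpec("linear"), k = 1)
    expect_equal(abs(unname(drop(m@trainScores))), c(1, 1), tolerance = 1e-12)
    expect_equal(sum(m@trainScores), 0, tolerance = 1e-12)
})

test_that("duplicate samples receive identical scores", {
    X <- rbind(randomMatrix(5, 3, 2), randomMatrix(5, 3, 2)[2, , drop = FALSE])
    m <- fitKPCA(X, kernelSpec("rbf", sigma = 1), k = 2)
    expect_equal(unname(m@trainScores[2, ]), unname(m@trainScores[6, ]),
                 tolerance = 1e-10)
})

test_that("projection transform is self-consistent and batch-independent", {
    X <- randomMatrix(12, 4, 6)
    for (m in list(fitKPCA(X, kernelSpec("rbf", sigma = 1.5), k = 3),
                   fitKPCA(X, kernelSpec("polynomial", degree = 2,
                                         theta = 0.5), k = 3, center = FALSE),
                   fitGDA(X, rep(1:3, each = 4), kernelSpec("rbf", sigma = 2),
                          k = 2))) {
        # transforming the training data reproduces the stored scores
        expect_equal(unname(projectedCoords(projectSamples(m, X))),
                     unname(m@trainScores), tolerance = 1e-8)
        # a new sample equal to training row j scores like row j
        pr <- projectSamples(m, X[c(4, 7), , drop = FALSE])
        expect_equal(unname(projectedCoords(pr)[1, ]),
                     unname(m@trainScores[4, ]), tolerance = 1e-8)
        # single query vs batch containing it
        single <- projectedCoords(projectSamples(m, X[7, , drop = FALSE]))
        expect_equal(unname(single[1, ]), unname(projectedCoords(pr)[2, ]),
                     tolerance = 1e-12)
    }
    expect_error(projectSamples(fitKPCA(X, kernelSpec("linear"), k = 2),
                                randomMatrix(3, 5, 1)), "mismatch")
})

test_that("KPCA training scores are mutually uncorrelated", {
    X <- randomMatrix(15, 6, 8)
    m <- fitKPCA(X, kernelSpec("rbf", sigma = 2), k = 4)
    cp <- crossprod(m@trainScores)
    off <- abs(cp[upper.tri(cp)])
    expect_lt(max(off), 1e-8 * max(diag(cp)))
})

test_that("KPCA refuses more components than positive eigenvalues", {
    X <- matrix(rep(c(0, 1), each = 3), 6, 1)  # rank-1 centered Gram
    expect_error(fitKPCA(X, kernelSpec("linear"), k = 3), "rank")
    expect_error(fitKPCA(randomMatrix(3, 2, 1), kernelSpec("linear"), k = 3),
                 "at least")
})

test_that("KPCA agrees with an independent kernel PCA implementation", {
    X <- randomMatrix(14, 5, 12)
    sigma <- 1.7
    m <- fitKPCA(X, kernelSpec("rbf", sigma = sigma), k = 3)
    ref <- kernlab::kpca(X, kernel = "rbfdot",
                         kpar = list(sigma = 1 / sigma^2), features = 3)
    rot <- kernlab::rotated(ref)
    for (j in 1:3) {
        r <- abs(cor(m@trainScores[, j], rot[, j]))
        expect_gt(r, 1 - 1e-8)
    }
})

test_that("two-class linear GDA induces the Fisher LDA ordering", {
    for (seed in 1:5) {
        blobs <- twoBlobs(nPerClass = 12, sep = 6, p = 3, seed = seed)
        g <- fitGDA(blobs$X, blobs$labels, kernelSpec("linear"), k = 1)
        w <- oracleLDADirection(blobs$X, blobs$labels)
        o.gda <- order(g@trainScores[, 1])
        o.lda <- order(blobs$X %*% w)
        expect_true(identical(o.gda, o.lda) || identical(o.gda, rev(o.lda)))
    }
})

test_that("GDA Fisher ratios are monotone and bounded by one", {
    set.seed(20)
    X <- do.call(rbind, lapply(1:4, function(cl)
        matrix(rnorm(16, mean = 3 * cl), 8, 2)))
    g <- fitGDA(X, rep(1:4, each = 8), kernelSpec("rbf", sigma = 4), k = 3)
    expect_true(all(diff(g@eigenvalues) <= 1e-12))
    expect_true(all(g@eigenvalues > 0 & g@eigenvalues <= 1 + 1e-10))
})

test_that("GDA projected geometry is invariant to sample order", {
    set.seed(21)
    X <- do.call(rbind, lapply(1:3, function(cl)
        matrix(rnorm(12, mean = 4 * cl), 6, 2)))
    labels <- rep(1:3, each = 6)
    g1 <- fitGDA(X, labels, kernelSpec("linear"), k = 2)
    perm <- sample(nrow(X))
    g2 <- fitGDA(X[perm, ], labels[perm], kernelSpec("linear"), k = 2)
    expect_equal(unname(g2@trainScores), unname(g1@trainScores[perm, ]),
                 tolerance = 1e-6)
})

test_that("projection fits are deterministic", {
    X <- randomMatrix(12, 4, 30)
    labels <- rep(1:2, each = 6)
    expect_identical(fitKPCA(X, kernelSpec("rbf", sigma = 1), k = 3),
                     fitKPCA(X, kernelSpec("rbf", sigma = 1), k = 3))
    expect_identical(fitGDA(X, labels, kernelSpec("polynomial", degree = 2),
                            k = 1),
                     fitGDA(X, labels, kernelSpec("polynomial", degree = 2),
                            k = 1))
})

test_that("GDA rejects singleton classes and too many discriminants", {
    X <- randomMatrix(7, 2, 2)
    expect_error(fitGDA(X, c(1, 1, 1, 2, 2, 2, 3), kernelSpec("linear"),
                        k = 1), "singleton.*3")
    expect_error(fitGDA(X[1:6, ], rep(1:2, each = 3), kernelSpec("linear"),
                        k = 2), "C - 1")
    expect_error(fitGDA(X[1:6, ], rep(1, 6), kernelSpec("linear"), k = 1),
                 "2 classes")
})
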