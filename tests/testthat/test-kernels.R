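test_that("kernel functions evaluate to their closed forms", {
    # zero distance and hand-computed values
    expect_equal(kernelEval(kernelSpec("rbf", sigma = 1), c(1, 2), c(1, 2)), 1)
    expect_equal(kernelEval(kernelSpec("polynomial", degree = 2, theta = 0),
                            c(1, 1), c(1, 1)), 4)
    expect_equal(kernelEval(kernelSpec("rbf", sigma = 0.5), c(0, 0), c(1, 0)),
                 exp(-4), tolerance = 1e-12)
    expect_equal(kernelEval(kernelSpec("linear", theta = 2), c(1, 2), c(3, 4)),
                 13)
    expect_equal(kernelEval(kernelSpec("sigmoid", v = 0.5, r = -1),
                            c(1, 0), c(2, 5)), tanh(0))
})

test_that("kernel evaluation rejects malformed input", {
    spec <- kernelSpec("linear")
    expect_error(kernelEval(spec, c(1, 2), c(1, 2, 3)), "2.*3")
    expect_error(kernelEval(spec, c(1, NA), c(1, 2)), "finite")
    expect_error(kernelEval(spec, c(1, Inf), c(1, 2)), "finite")
    expect_error(kernelMatrix(spec, matrix(numeric(), 0, 2)), "non-empty")
    expect_error(kernelSpec("rbf", sigma = 0), "sigma")
    expect_error(kernelSpec("polynomial", degree = 0), "degree")
})

test_that("kernel matrices equal the elementwise kernel_eval loop", {
    specs <- list(kernelSpec("linear", theta = 0.3),
                  kernelSpec("polynomial", degree = 3, theta = 1),
                  kernelSpec("rbf", sigma = 2),
                  kernelSpec("sigmoid", v = 0.2, r = 0.1))
    for (seed in 1:6) {
        for (spec in specs) {
            set.seed(seed)
            n <- sample(2:10, 1); m <- sample(2:10, 1); p <- sample(1:6, 1)
            X <- matrix(rnorm(n * p), n, p)
            Y <- matrix(rnorm(m * p), m, p)
            expect_equal(unname(kernelValues(kernelMatrix(spec, X, Y))),
                         oracleKernelMatrix(spec, X, Y), tolerance = 1e-12)
        }
    }
})

test_that("identity rows under a linear kernel give the identity matrix", {
    K <- kernelMatrix(kernelSpec("linear"), diag(2))
    expect_equal(unname(kernelValues(K)), diag(2))
})

test_that("self-kernels are symmetric and rbf/linear self-kernels are PSD", {
    for (seed in 1:5) {
        X <- randomMatrix(8, 3, seed)
        for (spec in list(kernelSpec("linear", theta = 1),
                          kernelSpec("polynomial", degree = 2, theta = 0.5),
                          kernelSpec("rbf", sigma = 1.5))) {
            K <- kernelValues(kernelMatrix(spec, X))
            expect_equal(K, t(K), tolerance = 1e-10)
        }
        for (spec in list(kernelSpec("rbf", sigma = 1),
                          kernelSpec("linear", theta = 0.2))) {
            ev <- eigen(kernelValues(kernelMatrix(spec, X)),
                        symmetric = TRUE, only.values = TRUE)$values
            expect_gte(min(ev), -1e-8 * max(ev))
        }
    }
})

test_that("rbf self-kernel entries lie in (0, 1] with unit diagonal", {
    K <- kernelValues(kernelMatrix(kernelSpec("rbf", sigma = 0.7),
                                   randomMatrix(6, 4, 3)))
    expect_true(all(K > 0 & K <= 1))
    expect_equal(unname(diag(K)), rep(1, 6))
})

test_that("non-PSD sigmoid self-kernels warn but are allowed through", {
    set.seed(4)
    X <- matrix(rnorm(40, sd = 3), 10, 4)
    expect_warning(kernelMatrix(kernelSpec("sigmoid", v = 1, r = -2), X),
                   "positive semi-definite")
})

test_that("kernel centering matches the explicit H K H oracle", {
    for (seed in 1:4) {
        X <- randomMatrix(4 + seed, 3, seed)
        K <- kernelMatrix(kernelSpec("rbf", sigma = 1), X)
        Kc <- kernelValues(centerKernel(K))
        expect_equal(Kc, unname(oracleCenter(kernelValues(K))),
                     tolerance = 1e-12, ignore_attr = TRUE)
        # centering identity: zero row and column sums
        expect_lt(max(abs(rowSums(Kc))), 1e-9)
        expect_lt(max(abs(colSums(Kc))), 1e-9)
    }
})

test_that("centering all-equal samples yields the zero matrix", {
    X <- matrix(1, 5, 3)
    Kc <- centerKernel(kernelMatrix(kernelSpec("linear"), X))
    expect_equal(max(abs(kernelValues(Kc))), 0)
})

test_that("re-centering a centered kernel matrix is an error", {
    K <- kernelMatrix(kernelSpec("rbf"), randomMatrix(4, 2, 1))
    Kc <- centerKernel(K)
    expect_error(centerKernel(Kc), "already centered")
})

test_that("test-kernel centering agrees with centering inside the big Gram", {
    # centering an (n+m) joint Gram and reading off the test block must match
    # the rectangular test-centering formula against train statistics
    Xtr <- randomMatrix(6, 3, 10)
    rownames(Xtr) <- paste0("s", 1:6)
    Xte <- randomMatrix(3, 3, 11)
    spec <- kernelSpec("rbf", sigma = 1.3)
    Ktr <- kernelMatrix(spec, Xtr)
    Kte <- kernelMatrix(spec, Xte, Xtr)
    got <- kernelValues(centerKernel(Ktr, Kte))
    n <- 6
    Ktr.v <- kernelValues(Ktr); Kte.v <- kernelValues(Kte)
    expected <- Kte.v -
        matrix(rowMeans(Kte.v), 3, n) -
        matrix(colMeans(Ktr.v), 3, n, byrow = TRUE) + mean(Ktr.v)
    expect_equal(got, expected, tolerance = 1e-12)
})
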