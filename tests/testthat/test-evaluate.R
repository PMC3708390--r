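test_that("LOOCV on well-separated Gaussian classes is perfect", {
    blobs <- twoBlobs(nPerClass = 10, sep = 10, p = 2, seed = 3)
    data <- labeledDataset(blobs$X, blobs$labels)
    cfg <- pipelineConfig("kpca", kernelSpec("linear"), k = 2,
                         rule = decisionRule("knn", K = 1))
    rep <- loocv(data, cfg)
    expect_equal(overallRate(rep), 1.0)
    expect_equal(unname(perClassRates(rep)), c(1, 1))
})

test_that("confusion bookkeeping identities hold", {
    set.seed(40)
    X <- matrix(rnorm(60), 30, 2)
    data <- labeledDataset(X, rep(1:3, c(12, 10, 8)))
    rep <- loocv(data, pipelineConfig("kpca", kernelSpec("rbf", sigma = 2),
                                      k = 2, rule = decisionRule("knn", K = 3)))
    conf <- confusionMatrix(rep)
    expect_equal(unname(rowSums(conf)), c(12, 10, 8))
    expect_equal(sum(conf), 30)
    expect_equal(overallRate(rep), sum(diag(conf)) / 30)
    expect_equal(unname(perClassRates(rep)),
                 unname(diag(conf) / rowSums(conf)))
})

test_that("identical samples with differing labels resolve by tie-breaking", {
    # four identical points labelled (1, 1, 2, 3); K = 3 neighbours all at
    # distance zero, so the vote is traced entirely by the tie-break rules:
    # held-out class-1 samples win the three-way tie (lowest class index),
    # held-out 2 and 3 lose to the class-1 majority -> overall 2/4
    X <- matrix(1, 4, 2)
    data <- labeledDataset(X, c(1, 1, 2, 3))
    cfg <- pipelineConfig("kpca", kernelSpec("linear"), k = 1, scale = FALSE,
                          center = FALSE, rule = decisionRule("knn", K = 3))
    rep <- loocv(data, cfg)
    expect_equal(overallRate(rep), 0.5)
    expect_equal(predictions(rep)$predicted, c("1", "1", "1", "1"))
})

test_that("K = n-1 KNN reproduces majority-class accuracy exactly", {
    set.seed(41)
    X <- matrix(rnorm(40), 20, 2)
    data <- labeledDataset(X, rep(1:3, c(12, 5, 3)))
    cfg <- pipelineConfig("kpca", kernelSpec("linear"), k = 2,
                          rule = decisionRule("knn", K = 19))
    expect_equal(overallRate(loocv(data, cfg)), 12 / 20)
})

test_that("LOOCV re-runs are bit-identical", {
    set.seed(42)
    X <- matrix(rnorm(48), 24, 2)
    data <- labeledDataset(X, rep(1:2, each = 12))
    for (cfg in list(
        pipelineConfig("kpca", kernelSpec("rbf", sigma = 1), k = 2,
                       rule = decisionRule("knn", K = 3)),
        pipelineConfig("gda", kernelSpec("rbf", sigma = 2), k = 1,
                       rule = decisionRule("intensity")))) {
        expect_identical(loocv(data, cfg), loocv(data, cfg))
    }
})

test_that("paper-literal no-refit mode holds samples out of the vote only", {
    blobs <- twoBlobs(nPerClass = 8, sep = 8, p = 2, seed = 5)
    data <- labeledDataset(blobs$X, blobs$labels)
    cfg <- pipelineConfig("kpca", kernelSpec("rbf", sigma = 3), k = 2,
                          rule = decisionRule("knn", K = 1), refit = FALSE)
    rep <- loocv(data, cfg)
    expect_equal(overallRate(rep), 1.0)
    cfg2 <- pipelineConfig("gda", kernelSpec("linear"), k = 1,
                           rule = decisionRule("intensity"), refit = FALSE)
    expect_equal(overallRate(loocv(data, cfg2)), 1.0)
})

test_that("adding a duplicate of a correct sample barely moves its class", {
    set.seed(43)
    X <- matrix(rnorm(40), 20, 2)
    data <- labeledDataset(X, rep(1:2, each = 10))
    cfg <- pipelineConfig("kpca", kernelSpec("rbf", sigma = 2), k = 2,
                          rule = decisionRule("knn", K = 3))
    rep1 <- loocv(data, cfg)
    ok <- which(predictions(rep1)$true == predictions(rep1)$predicted &
                predictions(rep1)$true == "1")[1]
    X2 <- rbind(X, X[ok, ])
    data2 <- labeledDataset(X2, c(rep(1:2, each = 10), 1),
                            ids = c(sampleIds(data), "dup"))
    rep2 <- loocv(data2, cfg)
    expect_gte(confusionMatrix(rep2)["1", "1"],
               confusionMatrix(rep1)["1", "1"] - 1)
})

test_that("LOOCV preconditions are checked before starting", {
    X <- matrix(rnorm(12), 6, 2)
    expect_error(loocv(labeledDataset(X, c(1, 1, 2, 2, 3, 3)),
                       pipelineConfig("gda", kernelSpec("linear"), k = 1,
                                      rule = decisionRule("knn", K = 1))),
                 ">= 3")
    expect_error(loocv(labeledDataset(X[1:3, ], c(1, 2, 3)),
                       pipelineConfig("kpca", kernelSpec("linear"), k = 1)),
                 "at least")
})

test_that("grid search ranks candidates deterministically", {
    blobs <- twoBlobs(nPerClass = 6, sep = 8, p = 2, seed = 6)
    data <- labeledDataset(blobs$X, blobs$labels)
    cfg <- pipelineConfig("kpca", kernelSpec("rbf", sigma = 2), k = 2,
                          rule = decisionRule("knn", K = 1))
    # single candidate -> rank 1
    g1 <- gridSearch(data, list(cfg))
    expect_equal(g1$candidate, 1L)
    # duplicate candidates -> identical scores, stable order
    g2 <- gridSearch(data, list(cfg, cfg))
    expect_equal(g2$candidate, c(1L, 2L))
    expect_equal(g2$overall[1], g2$overall[2])
    # failing candidate is reported, not fatal
    bad <- pipelineConfig("gda", kernelSpec("linear"), k = 1,
                          rule = decisionRule("knn", K = 1))
    gm <- loocv(data, cfg) # reference still works
    g3 <- gridSearch(labeledDataset(blobs$X, c(rep(1, 11), 2)),
                     list(bad))
    expect_true(!is.na(g3$error[1]))
    expect_equal(overallRate(gm), 1.0)
})

test_that("only the rbf candidate separates concentric shells", {
    sh <- makeConcentricShells(12, radii = c(1, 3), noise = 0.1, seed = 50)
    rule <- decisionRule("knn", K = 3)
    cands <- list(
        pipelineConfig("kpca", kernelSpec("linear"), k = 3, scale = FALSE,
                       rule = rule),
        pipelineConfig("kpca", kernelSpec("rbf", sigma = 1), k = 3,
                       scale = FALSE, rule = rule),
        pipelineConfig("kpca", kernelSpec("polynomial", degree = 2,
                                          theta = 1), k = 3, scale = FALSE,
                       rule = rule))
    g <- gridSearch(sh, cands)
    expect_equal(g$candidate[1], 2L)
})

test_that("shipped presets encode the published model settings", {
    a <- presetConfig("datasetA")
    expect_equal(a@kernel@name, "rbf")
    expect_equal(a@kernel@sigma, 0.5)
    expect_equal(a@rule@K, 3L)
    b <- presetConfig("datasetB")
    expect_equal(b@method, "gda")
    expect_equal(b@kernel@degree, 4L)
    expect_equal(b@kernel@theta, 1.5)
    expect_equal(b@rule@method, "intensity")
    s1 <- presetConfig("membrane-stage1")
    expect_equal(s1@kernel@degree, 2L)
    expect_equal(s1@kernel@theta, 0.1)
    expect_equal(s1@rule@K, 5L)
    s2 <- presetConfig("membrane-stage2")
    expect_equal(s2@method, "gda")
    expect_equal(s2@kernel@sigma, 5)
    expect_error(presetConfig("nope"), "datasetA")
})
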