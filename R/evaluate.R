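# Pipeline assembly, LOOCV harness, grid search and reporting.

#' Construct a pipeline configuration
#'
#' @param method projection method, `"kpca"` or `"gda"`.
#' @param kernel a [KernelSpec-class].
#' @param k projection dimension (default 3).
#' @param scale range-scale features to \[0, 1\] (default `TRUE`); the scaler
#'   is fitted on the training fold only, never on held-out samples.
#' @param center center the kernel matrix (KPCA only; GDA always centers).
#' @param rule a [DecisionRule-class].
#' @param refit refit the whole pipeline in every leave-one-out fold
#'   (default `TRUE`, leakage-free). `refit = FALSE` fits once on all
#'   samples and only holds the test sample out of the vote/field.
#' @return a [PipelineConfig-class].
#' @examples
#' pipelineConfig("kpca", kernelSpec("rbf", sigma = 0.5),
#'                rule = decisionRule("knn", K = 3))
#' @export
pipelineConfig <- function(method = c("kpca", "gda"),
                           kernel = kernelSpec("linear"),
                           k = 3L, scale = TRUE, center = TRUE,
                           rule = decisionRule("knn", K = 3L),
                           refit = TRUE) {
    method <- match.arg(method)
    new("PipelineConfig", method = method, kernel = kernel,
        k = as.integer(k), scale = isTRUE(scale), center = isTRUE(center),
        rule = rule, refit = isTRUE(refit))
}

#' Named model presets
#'
#' Shipped configurations for the four published model settings:
#' \describe{
#'   \item{`datasetA`}{KPCA, rbf kernel `sigma = 0.5`, KNN `K = 3` — the
#'     structural-class model for the 277-domain set.}
#'   \item{`datasetB`}{GDA, polynomial kernel `d = 4`, `theta = 1.5`,
#'     class-intensity rule — the structural-class model for the 498-domain
#'     set.}
#'   \item{`membrane-stage1`}{KPCA, polynomial `d = 2`, `theta = 0.1`,
#'     KNN `K = 5` — multipass-vs-rest stage of the membrane pipeline.}
#'   \item{`membrane-stage2`}{GDA, rbf `sigma = 5`, class-intensity rule —
#'     second stage over the remaining membrane types.}
#' }
#'
#' @param name preset name.
#' @return a [PipelineConfig-class].
#' @export
presetConfig <- function(name) {
    switch(name,
        "datasetA" = pipelineConfig("kpca", kernelSpec("rbf", sigma = 0.5),
                                    k = 3L, rule = decisionRule("knn", K = 3L)),
        "datasetB" = pipelineConfig("gda",
                                    kernelSpec("polynomial", degree = 4L,
                                               theta = 1.5),
                                    k = 3L, rule = decisionRule("intensity")),
        "membrane-stage1" = pipelineConfig("kpca",
                                    kernelSpec("polynomial", degree = 2L,
                                               theta = 0.1),
                                    k = 3L, rule = decisionRule("knn", K = 5L)),
        "membrane-stage2" = pipelineConfig("gda", kernelSpec("rbf", sigma = 5),
                                    k = 3L, rule = decisionRule("intensity")),
        stop("unknown preset '", name, "'; available presets: ",
             "datasetA, datasetB, membrane-stage1, membrane-stage2"))
}

#' Fit a full classification pipeline
#'
#' Fits (optionally) the range scaler, then the kernel projection, then
#' builds the charge field over the projected training samples. The fitted
#' pipeline predicts new samples with [predict()].
#'
#' @param X training feature matrix.
#' @param labels class labels.
#' @param config a [PipelineConfig-class].
#' @param classLevels optional class level names.
#' @return a [FittedPipeline-class].
#' @export
fitPipeline <- function(X, labels, config, classLevels = NULL) {
    stopifnot(is(config, "PipelineConfig"))
    X <- .asFeatureMatrix(X)
    if (is.factor(labels)) {
        if (is.null(classLevels)) classLevels <- levels(labels)
        labels <- as.integer(labels)
    }
    labels <- as.integer(labels)
    if (is.null(classLevels))
        classLevels <- as.character(seq_len(max(labels)))
    scaler <- NULL
    if (config@scale) {
        scaler <- fitScaler(X)
        X <- applyScaler(scaler, X)
    }
    model <- if (config@method == "kpca")
        fitKPCA(X, config@kernel, k = config@k, center = config@center)
    else
        fitGDA(X, labels, config@kernel, k = config@k)
    field <- buildChargeField(model@trainScores, labels)
    new("FittedPipeline", scaler = scaler, model = model, field = field,
        config = config, classLevels = classLevels)
}

#' Predict classes for new samples
#'
#' @param object a [FittedPipeline-class].
#' @param newdata feature matrix of samples to classify.
#' @param ... unused.
#' @return integer vector of predicted class codes.
#' @export
setMethod("predict", "FittedPipeline", function(object, newdata, ...) {
    newdata <- .asFeatureMatrix(newdata)
    if (!is.null(object@scaler))
        newdata <- applyScaler(object@scaler, newdata)
    proj <- projectSamples(object@model, newdata)
    .classifyProjected(object@field, proj@coords, object@config@rule)
})

.classifyProjected <- function(field, coords, rule) {
    if (rule@method == "knn")
        knnPredict(field@points, field@labels, coords, K = rule@K)
    else
        intensityPredict(field, coords, epsilon = rule@epsilonCoincide)
}

.makeReport <- function(true, pred, classLevels, ids, config,
                        stage = NULL) {
    lv <- seq_along(classLevels)
    conf <- table(factor(true, levels = lv), factor(pred, levels = lv))
    conf <- unclass(conf)
    dimnames(conf) <- list(true = classLevels, predicted = classLevels)
    rs <- rowSums(conf)
    perClass <- ifelse(rs > 0, diag(conf) / rs, NA_real_)
    names(perClass) <- classLevels
    preds <- data.frame(id = ids, true = classLevels[true],
                        predicted = classLevels[pred],
                        stringsAsFactors = FALSE)
    if (!is.null(stage)) preds$stage <- stage
    new("EvalReport", confusion = conf, perClass = perClass,
        overall = sum(diag(conf)) / sum(conf), predictions = preds,
        config = config)
}

#' @rdname loocv
#' @param verbose log fold progress via `message()`.
#' @export
setMethod("loocv", signature("LabeledDataset", "PipelineConfig"),
          function(data, config, verbose = FALSE, ...) {
    n <- length(data)
    labels <- data@labels
    C <- length(unique(labels))
    if (n < C + 1L)
        stop(sprintf("need at least %d samples for %d classes, got %d",
                     C + 1L, C, n))
    if (config@method == "gda") {
        sizes <- table(labels)
        if (any(sizes < 3L))
            stop("GDA leave-one-out requires every class to have >= 3 ",
                 "members; too small: ",
                 paste(data@classLevels[as.integer(names(sizes)[sizes < 3L])],
                       collapse = ", "))
    }
    X <- data@features
    pred <- integer(n)
    if (config@refit) {
        for (i in seq_len(n)) {
            if (verbose && i %% 25L == 1L)
                message("LOOCV fold ", i, "/", n)
            fp <- fitPipeline(X[-i, , drop = FALSE], labels[-i], config,
                              classLevels = data@classLevels)
            pred[i] <- predict(fp, X[i, , drop = FALSE])
        }
    } else {
        # Paper-literal mode: fit scaler + projection + field once on all
        # samples; hold each sample out of the vote/field only.
        fp <- fitPipeline(X, labels, config, classLevels = data@classLevels)
        scores <- fp@model@trainScores
        for (i in seq_len(n)) {
            restField <- buildChargeField(scores[-i, , drop = FALSE],
                                          labels[-i])
            pred[i] <- .classifyProjected(restField, scores[i, , drop = FALSE],
                                          config@rule)
        }
    }
    .makeReport(labels, pred, data@classLevels, data@ids, config)
})

#' Rank candidate configurations by LOOCV accuracy
#'
#' Runs [loocv()] for every candidate and ranks by overall success rate;
#' ties are broken by fewer hyperparameters, then by candidate order.
#' Candidates that fail are reported with their error message rather than
#' aborting the search.
#'
#' @param data a [LabeledDataset-class].
#' @param configs list of [PipelineConfig-class] candidates.
#' @return data.frame with columns `rank`, `candidate`, `overall`,
#'   `nParams`, `error`, plus the reports as attribute `"reports"`.
#' @export
gridSearch <- function(data, configs) {
    if (length(configs) < 1L)
        stop("at least one candidate configuration is required")
    reports <- vector("list", length(configs))
    overall <- rep(NA_real_, length(configs))
    err <- rep(NA_character_, length(configs))
    for (i in seq_along(configs)) {
        res <- tryCatch(loocv(data, configs[[i]]), error = function(e)
            conditionMessage(e))
        if (is.character(res)) err[i] <- res
        else {
            reports[[i]] <- res
            overall[i] <- res@overall
        }
    }
    np <- vapply(configs, .nParams, numeric(1))
    ord <- order(-ifelse(is.na(overall), -Inf, overall), np,
                 seq_along(configs))
    out <- data.frame(rank = seq_along(configs), candidate = ord,
                      overall = overall[ord], nParams = np[ord],
                      error = err[ord], stringsAsFactors = FALSE)
    attr(out, "reports") <- reports
    out
}

.nParams <- function(config) {
    kp <- switch(config@kernel@name, linear = 1, polynomial = 2,
                 rbf = 1, sigmoid = 2)
    kp + if (config@rule@method == "knn") 1 else 0
}

#' @rdname EvalReport-class
#' @export
setMethod("overallRate", "EvalReport", function(x) x@overall)

#' @rdname EvalReport-class
#' @export
setMethod("perClassRates", "EvalReport", function(x) x@perClass)

#' @rdname EvalReport-class
#' @export
setMethod("confusionMatrix", "EvalReport", function(x) x@confusion)

#' @rdname EvalReport-class
#' @export
predictions <- function(x) {
    stopifnot(is(x, "EvalReport"))
    x@predictions
}

setMethod("show", "EvalReport", function(object) {
    cat("LOOCV evaluation report\n")
    cat(sprintf("  overall success rate: %.4f (%d/%d)\n", object@overall,
                sum(diag(object@confusion)), sum(object@confusion)))
    for (cl in names(object@perClass))
        cat(sprintf("  %-12s %.4f (%d/%d)\n", cl,
                    object@perClass[[cl]],
                    object@confusion[cl, cl], sum(object@confusion[cl, ])))
})

#' Write an evaluation report
#'
#' Writes `<prefix>_report.tsv` (per-class rates and overall, mirroring the
#' published table layout) and `<prefix>_report.json` (confusion matrix,
#' rates and per-sample predictions).
#'
#' @param report an [EvalReport-class].
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
writeReport <- function(report, prefix) {
    stopifnot(is(report, "EvalReport"))
    tsv <- paste0(prefix, "_report.tsv")
    json <- paste0(prefix, "_report.json")
    df <- data.frame(class = c(names(report@perClass), "overall"),
                     rate = c(unname(report@perClass), report@overall))
    .atomicWrite(tsv, function(tmp)
        utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                           row.names = FALSE))
    payload <- list(overall = report@overall,
                    perClass = as.list(report@perClass),
                    confusion = report@confusion,
                    predictions = report@predictions)
    .atomicWrite(json, function(tmp)
        jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA))
    invisible(c(tsv, json))
}
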