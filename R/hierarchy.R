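# Two-stage hierarchical pipeline: a binary target-vs-rest stage followed by
# a second-stage classifier over the remaining classes.

#' Construct a hierarchical configuration
#'
#' @param stage1 [PipelineConfig-class] for the binary target-vs-rest stage.
#' @param stage2 [PipelineConfig-class] for the remaining classes.
#' @param targetClass the stage-1 target class (level name, or integer code).
#' @return a [HierarchicalConfig-class].
#' @examples
#' hierarchicalConfig(presetConfig("membrane-stage1"),
#'                    presetConfig("membrane-stage2"), targetClass = "C")
#' @export
hierarchicalConfig <- function(stage1, stage2, targetClass) {
    new("HierarchicalConfig", stage1 = stage1, stage2 = stage2,
        targetClass = as.character(targetClass))
}

.resolveTarget <- function(targetClass, classLevels) {
    if (targetClass %in% classLevels)
        return(match(targetClass, classLevels))
    code <- suppressWarnings(as.integer(targetClass))
    if (!is.na(code) && code >= 1L && code <= length(classLevels))
        return(code)
    stop("target class '", targetClass, "' not among class levels: ",
         paste(classLevels, collapse = ", "))
}

#' Two-stage hierarchical prediction
#'
#' Stage 1 is trained on binarised labels (target class vs rest) and decides
#' which samples are the target; only the samples routed to "rest" are then
#' classified by stage 2, trained on the non-target training samples with
#' their original labels. A sample predicted as the target in stage 1 never
#' reaches stage 2, and stage 2 is not even fitted when nothing is routed to
#' it.
#'
#' @param train a [LabeledDataset-class] of training samples.
#' @param newdata feature matrix of samples to classify.
#' @param config a [HierarchicalConfig-class].
#' @return data.frame with columns `id`, `predicted` (class level) and
#'   `stage` (1 or 2, the stage that produced the label).
#' @export
hierarchicalPredict <- function(train, newdata, config) {
    stopifnot(is(train, "LabeledDataset"), is(config, "HierarchicalConfig"))
    newdata <- .asFeatureMatrix(newdata)
    target <- .resolveTarget(config@targetClass, train@classLevels)
    binLabels <- ifelse(train@labels == target, 1L, 2L)
    fp1 <- fitPipeline(train@features, binLabels, config@stage1,
                       classLevels = c("target", "rest"))
    s1 <- predict(fp1, newdata)
    pred <- integer(nrow(newdata))
    stage <- integer(nrow(newdata))
    pred[s1 == 1L] <- target
    stage[s1 == 1L] <- 1L
    routed <- which(s1 == 2L)
    if (length(routed)) {
        restIdx <- train@labels != target
        restLabels <- train@labels[restIdx]
        missing <- setdiff(seq_along(train@classLevels),
                           c(target, unique(restLabels)))
        if (length(missing))
            stop("stage-2 training set is missing class(es): ",
                 paste(train@classLevels[missing], collapse = ", "))
        fp2 <- fitPipeline(train@features[restIdx, , drop = FALSE],
                           restLabels, config@stage2,
                           classLevels = train@classLevels)
        pred[routed] <- predict(fp2, newdata[routed, , drop = FALSE])
        stage[routed] <- 2L
    }
    ids <- rownames(newdata)
    data.frame(id = if (is.null(ids)) .defaultIds(nrow(newdata)) else ids,
               predicted = train@classLevels[pred], stage = stage,
               stringsAsFactors = FALSE)
}

#' @rdname loocv
#' @export
setMethod("loocv", signature("LabeledDataset", "HierarchicalConfig"),
          function(data, config, verbose = FALSE, ...) {
    n <- length(data)
    target <- .resolveTarget(config@targetClass, data@classLevels)
    restSizes <- table(data@labels[data@labels != target])
    if (config@stage2@method == "gda" && any(restSizes < 3L))
        stop("GDA stage 2 requires every non-target class to have >= 3 ",
             "members")
    pred <- integer(n)
    stage <- integer(n)
    for (i in seq_len(n)) {
        if (verbose && i %% 25L == 1L)
            message("hierarchical LOOCV fold ", i, "/", n)
        out <- hierarchicalPredict(data[-i], data@features[i, , drop = FALSE],
                                   config)
        pred[i] <- match(out$predicted, data@classLevels)
        stage[i] <- out$stage
    }
    .makeReport(data@labels, pred, data@classLevels, data@ids, config,
                stage = stage)
})
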