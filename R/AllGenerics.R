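#' Project new samples with a fitted kernel model
#'
#' Projects rows of `newdata` into the k-dimensional kernel space of a fitted
#' [ProjectionModel-class], applying the same kernel and the same centering
#' treatment as at fit time.
#'
#' @param object a fitted [ProjectionModel-class].
#' @param newdata numeric matrix with the same number of columns as the
#'   training matrix.
#' @param ... unused.
#' @return a [ProjectedPoints-class] object.
#' @export
setGeneric("projectSamples",
           function(object, newdata, ...) standardGeneric("projectSamples"))

#' Leave-one-out cross-validation
#'
#' For every sample, fits the configured pipeline (scaler, projection,
#' classifier) on the remaining samples and predicts the held-out one, then
#' aggregates the predictions into an [EvalReport-class]. Fully deterministic
#' given the data and configuration.
#'
#' @param data a [LabeledDataset-class].
#' @param config a [PipelineConfig-class] or [HierarchicalConfig-class].
#' @param ... passed to methods (`verbose = TRUE` logs fold progress).
#' @return an [EvalReport-class].
#' @export
setGeneric("loocv", function(data, config, ...) standardGeneric("loocv"))

#' @rdname LabeledDataset-class
#' @param object,x a `LabeledDataset`.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname LabeledDataset-class
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname LabeledDataset-class
#' @export
setGeneric("classLevels", function(x) standardGeneric("classLevels"))

#' @rdname LabeledDataset-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname EvalReport-class
#' @param x an `EvalReport`.
#' @export
setGeneric("overallRate", function(x) standardGeneric("overallRate"))

#' @rdname EvalReport-class
#' @export
setGeneric("perClassRates", function(x) standardGeneric("perClassRates"))

#' @rdname EvalReport-class
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))
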