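#' @import methods
NULL

.KERNEL_NAMES <- c("linear", "polynomial", "rbf", "sigmoid")

#' Kernel specification
#'
#' Holds the name of a kernel function and its hyperparameters. Only the
#' hyperparameters relevant to the chosen kernel are ever read:
#' `theta` (offset) for the linear and polynomial kernels, `degree` for the
#' polynomial kernel, `sigma` (width) for the Gaussian (rbf) kernel, and
#' `v`/`r` (slope/offset) for the sigmoid kernel.
#'
#' The rbf kernel is `exp(-||x - y||^2 / sigma^2)`; note the denominator is
#' `sigma^2`, not the `2 sigma^2` of some other conventions.
#'
#' @slot name character, one of `"linear"`, `"polynomial"`, `"rbf"`, `"sigmoid"`.
#' @slot theta numeric offset for linear/polynomial kernels.
#' @slot degree integer degree (>= 1) for the polynomial kernel.
#' @slot sigma positive numeric width for the rbf kernel.
#' @slot v,r numeric slope and offset for the sigmoid kernel.
#' @seealso [kernelSpec()], [kernelEval()], [kernelMatrix()]
#' @exportClass KernelSpec
setClass("KernelSpec",
    representation(name = "character", theta = "numeric", degree = "integer",
                   sigma = "numeric", v = "numeric", r = "numeric"),
    prototype(name = "linear", theta = 0, degree = 2L, sigma = 1, v = 1, r = 0))

setValidity("KernelSpec", function(object) {
    msg <- character()
    if (length(object@name) != 1L || !object@name %in% .KERNEL_NAMES)
        msg <- c(msg, sprintf("'name' must be one of: %s",
                              paste(.KERNEL_NAMES, collapse = ", ")))
    for (s in c("theta", "degree", "sigma", "v", "r")) {
        val <- slot(object, s)
        if (length(val) != 1L || !is.finite(val))
            msg <- c(msg, sprintf("'%s' must be a single finite number", s))
    }
    if (length(object@sigma) == 1L && is.finite(object@sigma) &&
        object@sigma <= 0)
        msg <- c(msg, "'sigma' must be > 0")
    if (length(object@degree) == 1L && !is.na(object@degree) &&
        object@degree < 1L)
        msg <- c(msg, "'degree' must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Kernel matrix with identity metadata
#'
#' An n x m matrix of pairwise kernel evaluations between two sample sets,
#' together with the sample identifiers along each margin and a flag stating
#' whether the matrix has been centered in feature space.
#'
#' @slot values numeric matrix of kernel values.
#' @slot rowIds,colIds character identifiers of the row/column samples.
#' @slot centered logical, `TRUE` after [centerKernel()].
#' @seealso [kernelMatrix()], [centerKernel()]
#' @exportClass KernelMatrix
setClass("KernelMatrix",
    representation(values = "matrix", rowIds = "character",
                   colIds = "character", centered = "logical"))

setValidity("KernelMatrix", function(object) {
    msg <- character()
    if (nrow(object@values) != length(object@rowIds))
        msg <- c(msg, "length(rowIds) must equal nrow(values)")
    if (ncol(object@values) != length(object@colIds))
        msg <- c(msg, "length(colIds) must equal ncol(values)")
    if (length(object@centered) != 1L)
        msg <- c(msg, "'centered' must be a single logical")
    if (!object@centered &&
        nrow(object@values) == ncol(object@values) &&
        identical(object@rowIds, object@colIds) &&
        max(abs(object@values - t(object@values))) > 1e-10)
        msg <- c(msg, "uncentered self-kernel matrix must be symmetric")
    if (length(msg)) msg else TRUE
})

#' Per-feature range scaler
#'
#' Learned per-feature minima and maxima mapping training features onto
#' \[0, 1\] via `(x - min) / (max - min)`. Constant features are flagged and
#' map to 0; transformed test values are clipped into \[0, 1\].
#'
#' @slot mins,maxs numeric per-feature training minima/maxima.
#' @slot constant logical flags for zero-range features.
#' @seealso [fitScaler()], [applyScaler()]
#' @exportClass RangeScaler
setClass("RangeScaler",
    representation(mins = "numeric", maxs = "numeric", constant = "logical"))

setValidity("RangeScaler", function(object) {
    if (length(object@mins) != length(object@maxs) ||
        length(object@mins) != length(object@constant))
        return("mins, maxs and constant must have equal length")
    if (any(object@maxs < object@mins))
        return("per-feature max must be >= min")
    TRUE
})

#' Labeled feature dataset
#'
#' A numeric feature matrix (samples in rows) together with integer class
#' labels, the class level names, and sample identifiers.
#'
#' @slot features numeric matrix, samples x features.
#' @slot labels integer codes into `classLevels`.
#' @slot classLevels character names of the classes.
#' @slot ids character sample identifiers.
#' @seealso [labeledDataset()], [featureMatrix()], [classLabels()]
#' @exportClass LabeledDataset
setClass("LabeledDataset",
    representation(features = "matrix", labels = "integer",
                   classLevels = "character", ids = "character"))

setValidity("LabeledDataset", function(object) {
    msg <- character()
    n <- nrow(object@features)
    if (length(object@labels) != n)
        msg <- c(msg, "length(labels) must equal nrow(features)")
    if (length(object@ids) != n)
        msg <- c(msg, "length(ids) must equal nrow(features)")
    if (anyDuplicated(object@ids))
        msg <- c(msg, "sample ids must be unique")
    if (any(!is.finite(object@features)))
        msg <- c(msg, "features must be finite")
    if (length(object@labels) &&
        (anyNA(object@labels) || min(object@labels) < 1L ||
         max(object@labels) > length(object@classLevels)))
        msg <- c(msg, "labels must index classLevels")
    if (length(msg)) msg else TRUE
})

#' Fitted kernel projection models
#'
#' `ProjectionModel` is the virtual parent of `KPCAModel` (kernel principal
#' component analysis) and `GDAModel` (kernel generalized discriminant
#' analysis). Both retain the scaled training matrix, the dual coefficients
#' alpha (one column per retained component, normalised to unit feature-space
#' norm `alpha' K alpha = 1`), the component eigenvalues, and the kernel-matrix
#' statistics needed to center new samples consistently with the fit.
#'
#' For `KPCAModel` the eigenvalues are those of `K/n`; for `GDAModel` they are
#' the Fisher ratios of Eq-style criterion `(a' K D K a) / (a' K K a)`, which
#' lie in \[0, 1\].
#'
#' @slot spec the [KernelSpec-class] used.
#' @slot Xtrain retained training matrix (already scaled if scaling is used).
#' @slot dualCoef n x k matrix of dual coefficients.
#' @slot eigenvalues k component eigenvalues, descending.
#' @slot k integer number of retained components.
#' @slot center logical, whether the kernel matrix was centered.
#' @slot kColMeans,kMean column means and grand mean of the uncentered
#'   training kernel matrix (used to center test kernels).
#' @slot trainScores n x k matrix of projected training samples.
#' @slot ids character training sample ids.
#' @seealso [fitKPCA()], [fitGDA()], [projectSamples()]
#' @aliases KPCAModel-class GDAModel-class
#' @exportClass ProjectionModel
setClass("ProjectionModel",
    representation("VIRTUAL",
                   spec = "KernelSpec", Xtrain = "matrix",
                   dualCoef = "matrix", eigenvalues = "numeric",
                   k = "integer", center = "logical",
                   kColMeans = "numeric", kMean = "numeric",
                   trainScores = "matrix", ids = "character"))

setValidity("ProjectionModel", function(object) {
    msg <- character()
    if (ncol(object@dualCoef) != object@k)
        msg <- c(msg, "dualCoef must have k columns")
    if (length(object@eigenvalues) != object@k)
        msg <- c(msg, "eigenvalues must have length k")
    if (object@k > 1L && any(diff(object@eigenvalues) > 1e-12))
        msg <- c(msg, "eigenvalues must be sorted descending")
    if (any(object@eigenvalues <= 0))
        msg <- c(msg, "retained eigenvalues must be > 0")
    if (length(msg)) msg else TRUE
})

#' @exportClass KPCAModel
setClass("KPCAModel", contains = "ProjectionModel")

#' @exportClass GDAModel
setClass("GDAModel", contains = "ProjectionModel",
    representation(labels = "integer", classSizes = "integer"))

#' Projected sample coordinates
#'
#' Coordinates of samples in the k-dimensional kernel space, with sample ids
#' and (optionally) integer class labels (`NA` when unknown).
#'
#' @slot coords m x k numeric matrix of projected coordinates.
#' @slot ids character sample identifiers.
#' @slot labels integer labels or `NA`.
#' @seealso [projectSamples()]
#' @exportClass ProjectedPoints
setClass("ProjectedPoints",
    representation(coords = "matrix", ids = "character", labels = "integer"))

setValidity("ProjectedPoints", function(object) {
    msg <- character()
    if (length(object@ids) != nrow(object@coords))
        msg <- c(msg, "length(ids) must equal nrow(coords)")
    if (length(object@labels) != nrow(object@coords))
        msg <- c(msg, "length(labels) must equal nrow(coords)")
    if (any(!is.finite(object@coords)))
        msg <- c(msg, "coordinates must be finite")
    if (length(msg)) msg else TRUE
})

#' Class charge field
#'
#' The state of the class-intensity classifier: projected training points,
#' their labels, and the per-class point charge EQPC_C = 1/n_C (so that
#' `EQPC_C * n_C = 1` exactly for every class).
#'
#' @slot points n x k coordinates of projected training samples.
#' @slot labels integer class labels.
#' @slot eqpcByClass named numeric, charge per class.
#' @slot nByClass named integer, class sizes.
#' @seealso [buildChargeField()], [iefp()], [intensityPredict()]
#' @exportClass ChargeField
setClass("ChargeField",
    representation(points = "matrix", labels = "integer",
                   eqpcByClass = "numeric", nByClass = "integer"))

setValidity("ChargeField", function(object) {
    msg <- character()
    if (length(object@labels) != nrow(object@points))
        msg <- c(msg, "length(labels) must equal nrow(points)")
    if (!all(as.character(unique(object@labels)) %in%
             names(object@nByClass)))
        msg <- c(msg, "every label must be present in nByClass")
    if (!isTRUE(all.equal(unname(object@eqpcByClass[names(object@nByClass)] *
                                 object@nByClass),
                          rep(1, length(object@nByClass)),
                          tolerance = 1e-12)))
        msg <- c(msg, "EQPC_C * n_C must equal 1 for every class")
    if (length(msg)) msg else TRUE
})

#' Decision rule
#'
#' How a projected query is assigned a class: `"knn"` (majority vote among the
#' K nearest projected training samples) or `"intensity"` (argmax of the
#' inverse-square class field intensity). `epsilonCoincide` is the distance
#' below which a query is treated as coinciding with a training point, in
#' which case that point's class is returned directly.
#'
#' @slot method `"knn"` or `"intensity"`.
#' @slot K integer neighbourhood size (knn only).
#' @slot epsilonCoincide coincidence radius (intensity only).
#' @seealso [decisionRule()], [knnPredict()], [intensityPredict()]
#' @exportClass DecisionRule
setClass("DecisionRule",
    representation(method = "character", K = "integer",
                   epsilonCoincide = "numeric"),
    prototype(method = "knn", K = 3L, epsilonCoincide = 1e-12))

setValidity("DecisionRule", function(object) {
    msg <- character()
    if (length(object@method) != 1L ||
        !object@method %in% c("knn", "intensity"))
        msg <- c(msg, "'method' must be \"knn\" or \"intensity\"")
    if (length(object@K) != 1L || is.na(object@K) || object@K < 1L)
        msg <- c(msg, "'K' must be a positive integer")
    if (length(object@epsilonCoincide) != 1L || object@epsilonCoincide < 0)
        msg <- c(msg, "'epsilonCoincide' must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Pipeline configuration
#'
#' A complete model configuration: projection method (`"kpca"` or `"gda"`),
#' kernel, projection dimension `k`, whether inputs are range-scaled to
#' \[0, 1\], whether the KPCA kernel matrix is centered, the decision rule,
#' and whether leave-one-out folds refit the whole pipeline (`refit = TRUE`,
#' the leakage-free default) or fit once on all samples and only hold the
#' test sample out of the vote (`refit = FALSE`).
#'
#' @slot method `"kpca"` or `"gda"`.
#' @slot kernel a [KernelSpec-class].
#' @slot k integer projection dimension (default 3).
#' @slot scale logical, range-scale features to \[0, 1\].
#' @slot center logical, center the kernel matrix (KPCA only; GDA always
#'   centers).
#' @slot rule a [DecisionRule-class].
#' @slot refit logical, refit per leave-one-out fold.
#' @seealso [pipelineConfig()], [presetConfig()], [loocv()]
#' @exportClass PipelineConfig
setClass("PipelineConfig",
    representation(method = "character", kernel = "KernelSpec",
                   k = "integer", scale = "logical", center = "logical",
                   rule = "DecisionRule", refit = "logical"))

setValidity("PipelineConfig", function(object) {
    msg <- character()
    if (length(object@method) != 1L || !object@method %in% c("kpca", "gda"))
        msg <- c(msg, "'method' must be \"kpca\" or \"gda\"")
    if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
        msg <- c(msg, "'k' must be a positive integer")
    for (s in c("scale", "center", "refit"))
        if (length(slot(object, s)) != 1L || is.na(slot(object, s)))
            msg <- c(msg, sprintf("'%s' must be TRUE or FALSE", s))
    if (length(msg)) msg else TRUE
})

#' Two-stage hierarchical configuration
#'
#' Stage 1 is a binary classifier (target class vs the rest); samples
#' predicted as "rest" are passed to the stage-2 classifier trained on the
#' remaining classes. A sample predicted as the target in stage 1 never
#' reaches stage 2.
#'
#' @slot stage1,stage2 [PipelineConfig-class] objects.
#' @slot targetClass the stage-1 target class (integer code or level name).
#' @seealso [hierarchicalConfig()], [hierarchicalPredict()]
#' @exportClass HierarchicalConfig
setClass("HierarchicalConfig",
    representation(stage1 = "PipelineConfig", stage2 = "PipelineConfig",
                   targetClass = "character"))

#' Fitted classification pipeline
#'
#' The result of [fitPipeline()]: the fitted scaler (if any), the fitted
#' projection model, and the charge field over the projected training set.
#'
#' @slot scaler a [RangeScaler-class] or `NULL`.
#' @slot model a [ProjectionModel-class].
#' @slot field a [ChargeField-class] over the projected training samples.
#' @slot config the [PipelineConfig-class] used.
#' @slot classLevels character class level names.
#' @exportClass FittedPipeline
setClass("FittedPipeline",
    representation(scaler = "ANY", model = "ProjectionModel",
                   field = "ChargeField", config = "PipelineConfig",
                   classLevels = "character"))

#' Leave-one-out evaluation report
#'
#' Confusion matrix (true class in rows, predicted in columns), per-class and
#' overall success rates, the per-sample predictions, and an echo of the
#' configuration. Row sums of the confusion matrix equal the class sizes;
#' the overall rate is trace/total.
#'
#' @slot confusion integer matrix of true x predicted counts.
#' @slot perClass named numeric per-class success rates.
#' @slot overall numeric overall success rate.
#' @slot predictions data.frame with columns `id`, `true`, `predicted` and,
#'   for hierarchical runs, `stage`.
#' @slot config the configuration evaluated.
#' @seealso [loocv()], [overallRate()], [perClassRates()], [confusionMatrix()]
#' @exportClass EvalReport
setClass("EvalReport",
    representation(confusion = "matrix", perClass = "numeric",
                   overall = "numeric", predictions = "data.frame",
                   config = "ANY"))

setValidity("EvalReport", function(object) {
    msg <- character()
    if (nrow(object@confusion) != ncol(object@confusion))
        msg <- c(msg, "confusion matrix must be square")
    tot <- sum(object@confusion)
    if (tot > 0 &&
        abs(object@overall - sum(diag(object@confusion)) / tot) > 1e-12)
        msg <- c(msg, "overall rate must equal trace/total")
    if (length(msg)) msg else TRUE
})
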