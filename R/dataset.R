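#' Construct a labeled dataset
#'
#' @param features numeric matrix, samples in rows.
#' @param labels class labels (factor, character or integer codes).
#' @param ids sample identifiers; defaults to the feature row names.
#' @param classLevels class level names when `labels` are integer codes.
#' @return a [LabeledDataset-class].
#' @examples
#' labeledDataset(matrix(rnorm(12), 6), rep(c("a", "b"), each = 3))
#' @export
labeledDataset <- function(features, labels, ids = NULL, classLevels = NULL) {
    features <- .asFeatureMatrix(features)
    if (is.null(ids)) ids <- rownames(features)
    if (is.numeric(labels) && is.null(classLevels))
        labels <- factor(labels)
    if (!is.factor(labels) && !is.integer(labels))
        labels <- factor(labels)
    if (is.factor(labels)) {
        classLevels <- levels(labels)
        labels <- as.integer(labels)
    }
    rownames(features) <- ids
    new("LabeledDataset", features = features, labels = as.integer(labels),
        classLevels = as.character(classLevels), ids = as.character(ids))
}

#' @rdname LabeledDataset-class
#' @export
setMethod("featureMatrix", "LabeledDataset", function(x) x@features)

#' @rdname LabeledDataset-class
#' @export
setMethod("classLabels", "LabeledDataset", function(x) x@labels)

#' @rdname LabeledDataset-class
#' @export
setMethod("classLevels", "LabeledDataset", function(x) x@classLevels)

#' @rdname LabeledDataset-class
#' @export
setMethod("sampleIds", "LabeledDataset", function(x) x@ids)

#' @rdname LabeledDataset-class
#' @export
setMethod("length", "LabeledDataset", function(x) nrow(x@features))

#' @rdname LabeledDataset-class
#' @param i integer or logical index of samples to keep.
#' @param j,drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "LabeledDataset", function(x, i, j, ..., drop = FALSE) {
    new("LabeledDataset", features = x@features[i, , drop = FALSE],
        labels = x@labels[i], classLevels = x@classLevels,
        ids = x@ids[i])
})

setMethod("show", "LabeledDataset", function(object) {
    cat(sprintf("LabeledDataset: %d samples x %d features, %d classes\n",
                nrow(object@features), ncol(object@features),
                length(object@classLevels)))
    tab <- table(factor(object@classLevels[object@labels],
                        levels = object@classLevels))
    cat("  class sizes:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

#' Read a label table
#'
#' Tab-separated file with header `id<TAB>label`.
#'
#' @param path path to the TSV file.
#' @return data.frame with character columns `id` and `label`.
#' @export
readLabelTable <- function(path) {
    if (!file.exists(path)) stop("label table not found: ", path)
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = "character", quote = "")
    if (!all(c("id", "label") %in% names(df)))
        stop("label table must have header columns 'id' and 'label'")
    if (anyDuplicated(df$id))
        stop("duplicate ids in label table: ",
             paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
    df[, c("id", "label")]
}

#' Read / write a feature table
#'
#' CSV with an `id` column (optional; first column named `id`), numeric
#' feature columns, and a final `label` column.
#'
#' @param path path to the CSV file.
#' @return `readFeatureTable()`: a [LabeledDataset-class].
#' @export
readFeatureTable <- function(path) {
    if (!file.exists(path)) stop("feature table not found: ", path)
    df <- utils::read.csv(path, check.names = FALSE)
    if (!"label" %in% names(df))
        stop("feature table must contain a 'label' column")
    ids <- if ("id" %in% names(df)) as.character(df$id)
           else .defaultIds(nrow(df))
    feat <- df[, setdiff(names(df), c("id", "label")), drop = FALSE]
    if (!all(vapply(feat, is.numeric, logical(1))))
        stop("feature columns must be numeric")
    labeledDataset(as.matrix(feat), as.character(df$label), ids = ids)
}

#' @rdname readFeatureTable
#' @param data a [LabeledDataset-class].
#' @export
writeFeatureTable <- function(data, path) {
    stopifnot(is(data, "LabeledDataset"))
    df <- data.frame(id = data@ids, data@features,
                     label = data@classLevels[data@labels],
                     check.names = FALSE)
    .atomicWrite(path, function(tmp)
        utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE))
}
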