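# Class decision in the projected kernel space: K-nearest-neighbour vote or
# the Coulomb-style class-intensity model (EQPC / IEFP).

#' Construct a decision rule
#'
#' @param method `"knn"` or `"intensity"`.
#' @param K neighbourhood size for knn (default 3).
#' @param epsilonCoincide coincidence radius for the intensity model
#'   (default `1e-12`): a query within this distance of a training point is
#'   assigned that point's class directly, which is the limit of the
#'   diverging inverse-square field and keeps leave-one-out evaluation
#'   well defined.
#' @return a [DecisionRule-class].
#' @export
decisionRule <- function(method = c("knn", "intensity"), K = 3L,
                         epsilonCoincide = 1e-12) {
    method <- match.arg(method)
    new("DecisionRule", method = method, K = as.integer(K),
        epsilonCoincide = as.numeric(epsilonCoincide))
}

.pointsAndLabels <- function(train, labels) {
    if (is(train, "ProjectedPoints")) {
        pts <- train@coords
        if (is.null(labels)) labels <- train@labels
    } else {
        pts <- as.matrix(train)
    }
    if (is.factor(labels)) labels <- as.integer(labels)
    list(points = pts, labels = as.integer(labels))
}

#' K-nearest-neighbour prediction in projected space
#'
#' Euclidean distances in the projected space; majority class among the K
#' nearest training samples. Vote ties are broken by the smallest summed
#' distance among the tied classes' neighbours, then by the lowest class
#' index — both deterministic.
#'
#' @param train projected training coordinates ([ProjectedPoints-class] or
#'   matrix).
#' @param labels integer class labels of the training samples.
#' @param query a single coordinate vector or a matrix of query rows.
#' @param K neighbourhood size, `1 <= K <= n`.
#' @return integer predicted class, one per query row.
#' @export
knnPredict <- function(train, labels, query, K) {
    tl <- .pointsAndLabels(train, labels)
    pts <- tl$points; labels <- tl$labels
    if (nrow(pts) == 0L)
        stop("empty training set")
    K <- as.integer(K)
    if (K < 1L || K > nrow(pts))
        stop(sprintf("K = %d must be in 1..%d", K, nrow(pts)))
    if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
    query <- as.matrix(query)
    if (ncol(query) != ncol(pts))
        stop("query dimension must match training coordinates")
    apply(query, 1L, function(q) {
        d <- sqrt(colSums((t(pts) - q)^2))
        nb <- order(d)[seq_len(K)]
        votes <- table(labels[nb])
        cand <- as.integer(names(votes)[votes == max(votes)])
        if (length(cand) > 1L) {
            sums <- vapply(cand, function(cl)
                sum(d[nb][labels[nb] == cl]), numeric(1))
            cand <- cand[sums == min(sums)]
        }
        min(cand)
    })
}

#' Build the class charge field
#'
#' Every projected training sample becomes a point charge whose magnitude is
#' its class's EQPC (Electric Quantity of Point Charge), `EQPC_C = 1/n_C`,
#' so that a class's total charge is always 1 regardless of its size.
#'
#' @param train projected training coordinates ([ProjectedPoints-class] or
#'   matrix).
#' @param labels integer class labels; every class needs at least 1 member.
#' @return a [ChargeField-class].
#' @export
buildChargeField <- function(train, labels = NULL) {
    tl <- .pointsAndLabels(train, labels)
    if (nrow(tl$points) == 0L)
        stop("empty training set")
    if (anyNA(tl$labels))
        stop("labels are required to build a charge field")
    classes <- sort(unique(tl$labels))
    nBy <- vapply(classes, function(cl) sum(tl$labels == cl), integer(1))
    names(nBy) <- classes
    new("ChargeField", points = tl$points, labels = tl$labels,
        eqpcByClass = stats::setNames(1 / nBy, classes), nByClass = nBy)
}

#' Intensity of the electric field of one point (IEFP)
#'
#' The inverse-square field intensity of class `cl` at `query`:
#' `IEFP_C = sum_i EQPC_C / r_i^2` over the class's training points, with
#' `r_i` the Euclidean distance in projected space. If the query lies within
#' `epsilon` of a class-`cl` training point the field diverges and `Inf` is
#' returned (the coincidence signal; [intensityPredict()] resolves it by
#' returning the touching point's class).
#'
#' @param field a [ChargeField-class].
#' @param query coordinate vector in the projected space.
#' @param cl class present in the field.
#' @param epsilon coincidence radius.
#' @return field intensity (possibly `Inf`).
#' @examples
#' f <- buildChargeField(matrix(c(1, 0), 1), labels = 1L)
#' iefp(f, c(0, 0), 1L)  # 1/1^2 = 1
#' iefp(f, c(-1, 0), 1L) # 1/2^2 = 0.25
#' @export
iefp <- function(field, query, cl, epsilon = 1e-12) {
    stopifnot(is(field, "ChargeField"))
    key <- as.character(as.integer(cl))
    if (!key %in% names(field@nByClass))
        stop("unknown class: ", cl)
    pts <- field@points[field@labels == as.integer(cl), , drop = FALSE]
    d2 <- colSums((t(pts) - as.numeric(query))^2)
    if (any(sqrt(d2) < epsilon))
        return(Inf)
    sum(field@eqpcByClass[[key]] / d2)
}

#' Predict by maximal class field intensity
#'
#' Returns the class with the largest IEFP at each query. A query that
#' coincides with a training point (distance below `epsilon`) is assigned
#' that point's class directly. Exact intensity ties are broken by the
#' lowest class index and reported via `message()`.
#'
#' @param field a [ChargeField-class].
#' @param query a coordinate vector or matrix of query rows.
#' @param epsilon coincidence radius (default `1e-12`).
#' @return integer predicted class, one per query row.
#' @export
intensityPredict <- function(field, query, epsilon = 1e-12) {
    stopifnot(is(field, "ChargeField"))
    if (is.null(dim(query))) query <- matrix(query, nrow = 1L)
    query <- as.matrix(query)
    if (ncol(query) != ncol(field@points))
        stop("query dimension must match field coordinates")
    classes <- as.integer(names(field@nByClass))
    apply(query, 1L, function(q) {
        d <- sqrt(colSums((t(field@points) - q)^2))
        if (min(d) < epsilon)
            return(field@labels[which.min(d)])
        vals <- vapply(classes, function(cl) iefp(field, q, cl, epsilon),
                       numeric(1))
        top <- classes[vals == max(vals)]
        if (length(top) > 1L)
            message("IEFP tie between classes ",
                    paste(top, collapse = ", "),
                    "; choosing lowest class index")
        min(top)
    })
}

setMethod("show", "ChargeField", function(object) {
    cat(sprintf("ChargeField: %d points in %d dimensions, %d classes\n",
                nrow(object@points), ncol(object@points),
                length(object@nByClass)))
    cat("  EQPC:",
        paste(sprintf("class %s = 1/%d", names(object@nByClass),
                      object@nByClass), collapse = ", "), "\n")
})

setMethod("show", "DecisionRule", function(object) {
    if (object@method == "knn")
        cat(sprintf("DecisionRule: knn (K = %d)\n", object@K))
    else
        cat(sprintf("DecisionRule: intensity (epsilon = %g)\n",
                    object@epsilonCoincide))
})
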