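#' Construct a kernel specification
#'
#' The four supported kernels are
#' \describe{
#'   \item{linear}{`K(x, y) = <x, y> + theta`}
#'   \item{polynomial}{`K(x, y) = (<x, y> + theta)^degree`}
#'   \item{rbf}{`K(x, y) = exp(-||x - y||^2 / sigma^2)` — the denominator is
#'     `sigma^2`, without the factor 2 used by some other conventions}
#'   \item{sigmoid}{`K(x, y) = tanh(v <x, y> + r)`; not positive
#'     semi-definite for all parameter choices, see [kernelMatrix()]}
#' }
#' Irrelevant hyperparameters are ignored.
#'
#' @param name kernel name.
#' @param theta offset (linear, polynomial).
#' @param degree polynomial degree, integer >= 1.
#' @param sigma rbf width, > 0.
#' @param v,r sigmoid slope and offset.
#' @return a [KernelSpec-class] object.
#' @examples
#' kernelSpec("rbf", sigma = 0.5)
#' kernelSpec("polynomial", degree = 4, theta = 1.5)
#' @export
kernelSpec <- function(name = c("linear", "polynomial", "rbf", "sigmoid"),
                       theta = 0, degree = 2L, sigma = 1, v = 1, r = 0) {
    name <- match.arg(name)
    new("KernelSpec", name = name, theta = as.numeric(theta),
        degree = as.integer(degree), sigma = as.numeric(sigma),
        v = as.numeric(v), r = as.numeric(r))
}

#' Evaluate a kernel on a pair of vectors
#'
#' @param spec a [KernelSpec-class].
#' @param x,y numeric vectors of equal length.
#' @return a single kernel value.
#' @examples
#' kernelEval(kernelSpec("rbf", sigma = 0.5), c(0, 0), c(1, 0)) # exp(-4)
#' @export
kernelEval <- function(spec, x, y) {
    stopifnot(is(spec, "KernelSpec"))
    x <- as.numeric(x); y <- as.numeric(y)
    if (length(x) != length(y))
        stop(sprintf("dimension mismatch: length(x) = %d but length(y) = %d",
                     length(x), length(y)))
    if (!all(is.finite(x)) || !all(is.finite(y)))
        stop("kernel inputs must be finite")
    switch(spec@name,
        linear     = sum(x * y) + spec@theta,
        polynomial = (sum(x * y) + spec@theta)^spec@degree,
        rbf        = exp(-sum((x - y)^2) / spec@sigma^2),
        sigmoid    = tanh(spec@v * sum(x * y) + spec@r))
}

# Plain-matrix kernel evaluation, the workhorse behind kernelMatrix() and the
# projection fits. X: n x p, Y: m x p; returns n x m.
.kmat <- function(spec, X, Y) {
    if (ncol(X) != ncol(Y))
        stop(sprintf("dimension mismatch: X has %d columns but Y has %d",
                     ncol(X), ncol(Y)))
    if (!all(is.finite(X)) || !all(is.finite(Y)))
        stop("kernel inputs must be finite")
    G <- tcrossprod(X, Y)
    switch(spec@name,
        linear     = G + spec@theta,
        polynomial = (G + spec@theta)^spec@degree,
        rbf        = {
            d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * G
            d2[d2 < 0] <- 0   # guard tiny negative round-off
            exp(-d2 / spec@sigma^2)
        },
        sigmoid    = tanh(spec@v * G + spec@r))
}

#' Build a kernel matrix between two sample sets
#'
#' Entry (i, j) equals `kernelEval(spec, X[i, ], Y[j, ])`. When `Y` is
#' omitted the self-kernel of `X` is returned; for the sigmoid kernel a
#' warning is emitted if that self-kernel is not positive semi-definite
#' (sigmoid kernels do not satisfy Mercer's condition for all parameters,
#' but are allowed through).
#'
#' @param spec a [KernelSpec-class].
#' @param X,Y numeric matrices with samples in rows and the same number of
#'   columns. `Y` defaults to `X`.
#' @return a [KernelMatrix-class] with `centered = FALSE`.
#' @examples
#' K <- kernelMatrix(kernelSpec("rbf", sigma = 2), matrix(rnorm(10), 5))
#' @export
kernelMatrix <- function(spec, X, Y) {
    stopifnot(is(spec, "KernelSpec"))
    selfK <- missing(Y)
    X <- .asFeatureMatrix(X)
    if (selfK) {
        Y <- X
    } else {
        anon <- is.null(rownames(Y))
        Y <- .asFeatureMatrix(Y)
        if (anon) rownames(Y) <- .defaultIds(nrow(Y), "y")
    }
    if (nrow(X) == 0L || nrow(Y) == 0L)
        stop("kernel matrix requires non-empty X and Y")
    V <- .kmat(spec, X, Y)
    if (selfK && spec@name == "sigmoid") {
        ev <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
        if (min(ev) < -1e-8 * max(abs(ev)))
            warning("sigmoid kernel matrix is not positive semi-definite ",
                    sprintf("(min eigenvalue %.3g)", min(ev)))
    }
    new("KernelMatrix", values = V, rowIds = rownames(X),
        colIds = rownames(Y), centered = FALSE)
}

# Double-center a square kernel matrix; returns the centered matrix plus the
# training statistics needed to center test kernels consistently.
.centerTrain <- function(K) {
    cm <- colMeans(K)
    mu <- mean(K)
    Kc <- K - outer(rowMeans(K), rep(1, ncol(K))) -
        outer(rep(1, nrow(K)), cm) + mu
    list(Kc = Kc, colMeans = cm, mean = mu)
}

# Center an m x n test kernel against training statistics.
.centerTest <- function(Kt, trainColMeans, trainMean) {
    Kt - outer(rowMeans(Kt), rep(1, ncol(Kt))) -
        outer(rep(1, nrow(Kt)), trainColMeans) + trainMean
}

#' Center kernel matrices in feature space
#'
#' Double-centers a square training kernel matrix,
#' `K - 1K - K1 + 1K1` with `1 = (1/n) 11'`, which corresponds to
#' translating the mapped data to zero mean in feature space. When `Ktest`
#' is supplied (a rectangular test-vs-train kernel whose columns are the
#' training samples), the corresponding test-centering formula is applied
#' and the centered test matrix is returned instead.
#'
#' @param Ktrain an uncentered square self-[KernelMatrix-class].
#' @param Ktest optional uncentered test [KernelMatrix-class] whose
#'   `colIds` equal `Ktrain`'s ids.
#' @return a centered [KernelMatrix-class] (the training matrix, or the test
#'   matrix when `Ktest` is given).
#' @export
centerKernel <- function(Ktrain, Ktest = NULL) {
    stopifnot(is(Ktrain, "KernelMatrix"))
    if (Ktrain@centered)
        stop("kernel matrix is already centered")
    if (nrow(Ktrain@values) != ncol(Ktrain@values))
        stop("Ktrain must be square")
    ctr <- .centerTrain(Ktrain@values)
    if (is.null(Ktest))
        return(new("KernelMatrix", values = ctr$Kc, rowIds = Ktrain@rowIds,
                   colIds = Ktrain@colIds, centered = TRUE))
    stopifnot(is(Ktest, "KernelMatrix"))
    if (Ktest@centered)
        stop("test kernel matrix is already centered")
    if (!identical(Ktest@colIds, Ktrain@colIds))
        stop("Ktest column ids must match Ktrain sample ids")
    new("KernelMatrix",
        values = .centerTest(Ktest@values, ctr$colMeans, ctr$mean),
        rowIds = Ktest@rowIds, colIds = Ktest@colIds, centered = TRUE)
}

#' @describeIn KernelMatrix-class numeric matrix of kernel values.
#' @param object a `KernelMatrix`.
#' @export
kernelValues <- function(object) {
    stopifnot(is(object, "KernelMatrix"))
    object@values
}

setMethod("show", "KernelSpec", function(object) {
    pars <- switch(object@name,
        linear     = sprintf("theta = %g", object@theta),
        polynomial = sprintf("degree = %d, theta = %g",
                             object@degree, object@theta),
        rbf        = sprintf("sigma = %g", object@sigma),
        sigmoid    = sprintf("v = %g, r = %g", object@v, object@r))
    cat(sprintf("KernelSpec: %s (%s)\n", object@name, pars))
})

setMethod("show", "KernelMatrix", function(object) {
    cat(sprintf("KernelMatrix: %d x %d, %s\n",
                nrow(object@values), ncol(object@values),
                if (object@centered) "centered" else "uncentered"))
})
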