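# Kernel PCA and kernel generalized discriminant analysis.
#
# Both fits reduce to symmetric eigenproblems on the (centered) kernel
# matrix; dual coefficient vectors are normalised to unit feature-space norm
# (alpha' K alpha = 1) and their sign is fixed deterministically so repeated
# fits are bit-identical.

# Flip each column so its largest-magnitude entry is positive (first index
# wins on ties). Returns the sign vector.
.fixSigns <- function(A) {
    vapply(seq_len(ncol(A)), function(j) {
        i <- which.max(abs(A[, j]))
        if (A[i, j] < 0) -1 else 1
    }, numeric(1))
}

#' Fit kernel principal component analysis
#'
#' Builds the kernel matrix of the training samples, centers it in feature
#' space (by default), and solves the dual eigenproblem
#' `lambda alpha = (1/n) K alpha`, keeping the top `k` eigenpairs. Dual
#' coefficients are normalised so each feature-space principal direction has
#' unit norm (`alpha' K alpha = 1`); with a linear kernel (`theta = 0`) and
#' centering the training scores then equal classical PCA scores up to
#' per-component sign. Eigenvector signs are fixed so the largest-magnitude
#' dual coefficient of each component is positive.
#'
#' @param X numeric training matrix (samples x features), `n >= k + 1`.
#' @param spec a [KernelSpec-class].
#' @param k number of kernel principal components (default 3).
#' @param center logical; center the kernel matrix in feature space
#'   (default `TRUE`). `center = FALSE` runs on the raw kernel matrix.
#' @return a [KPCAModel-class].
#' @seealso [projectSamples()], [fitGDA()]
#' @examples
#' m <- fitKPCA(matrix(rnorm(40), 10), kernelSpec("rbf", sigma = 2), k = 3)
#' @export
fitKPCA <- function(X, spec, k = 3L, center = TRUE) {
    stopifnot(is(spec, "KernelSpec"))
    X <- .asFeatureMatrix(X)
    k <- as.integer(k)
    n <- nrow(X)
    if (n < k + 1L)
        stop(sprintf("need at least k + 1 = %d samples, got %d", k + 1L, n))
    K <- .kmat(spec, X, X)
    if (center) {
        ctr <- .centerTrain(K)
        Ku <- ctr$Kc
        kColMeans <- ctr$colMeans
        kMean <- ctr$mean
    } else {
        Ku <- K
        kColMeans <- numeric()
        kMean <- NA_real_
    }
    eig <- eigen(Ku / n, symmetric = TRUE)
    lam <- eig$values
    npos <- sum(lam > max(lam, 0) * 1e-10)
    if (k > npos)
        stop(sprintf(
            "k = %d exceeds the number of positive eigenvalues (rank %d)",
            k, npos))
    idx <- seq_len(k)
    mu <- n * lam[idx]                       # eigenvalues of K itself
    alpha <- sweep(eig$vectors[, idx, drop = FALSE], 2L, sqrt(mu), "/")
    alpha <- sweep(alpha, 2L, .fixSigns(alpha), "*")
    scores <- Ku %*% alpha
    dimnames(scores) <- list(rownames(X), paste0("KPC", idx))
    new("KPCAModel", spec = spec, Xtrain = X, dualCoef = alpha,
        eigenvalues = lam[idx], k = k, center = center,
        kColMeans = kColMeans, kMean = kMean, trainScores = scores,
        ids = rownames(X))
}

#' Fit kernel generalized discriminant analysis
#'
#' Kernelised Fisher discriminant analysis: finds up to `C - 1` feature-space
#' directions maximising the ratio of between-class to total scatter of the
#' mapped data, via the dual criterion
#' `lambda = (alpha' K D K alpha) / (alpha' K K alpha)` with `D` the
#' block-diagonal matrix of `1/n_c` blocks. The kernel matrix is centered in
#' feature space and the problem is solved in its reduced eigenbasis:
#' eigenvalues below `1e-10` times the largest are discarded, the reduced
#' symmetric problem is solved there, and the solution is mapped back to dual
#' coefficients (the standard numerically stable route; the printed criterion
#' divides by `alpha' K K alpha`, which is singular for rank-deficient `K`).
#' Discriminant directions are normalised to unit feature-space norm and
#' ordered by descending Fisher ratio (each ratio lies in \[0, 1\]).
#'
#' With a linear kernel and two classes the single discriminant direction
#' induces the same 1D ordering as classical Fisher LDA.
#'
#' @param X numeric training matrix (samples x features).
#' @param labels integer or factor class labels; every class needs at least
#'   2 members.
#' @param spec a [KernelSpec-class].
#' @param k number of discriminant directions, `k <= C - 1` (default
#'   `min(3, C - 1)`).
#' @return a [GDAModel-class].
#' @seealso [projectSamples()], [fitKPCA()]
#' @export
fitGDA <- function(X, labels, spec, k = 3L) {
    stopifnot(is(spec, "KernelSpec"))
    X <- .asFeatureMatrix(X)
    if (is.factor(labels)) labels <- as.integer(labels)
    labels <- as.integer(labels)
    if (length(labels) != nrow(X))
        stop("length(labels) must equal nrow(X)")
    classes <- sort(unique(labels))
    C <- length(classes)
    if (C < 2L)
        stop("GDA needs at least 2 classes")
    sizes <- vapply(classes, function(cl) sum(labels == cl), integer(1))
    if (any(sizes < 2L))
        stop("singleton (or near-singleton) class: ",
             paste(classes[sizes < 2L], collapse = ", "),
             " — every class needs at least 2 members")
    k <- as.integer(k)
    if (k > C - 1L)
        stop(sprintf("k = %d exceeds C - 1 = %d nonzero discriminants",
                     k, C - 1L))
    n <- nrow(X)
    K <- .kmat(spec, X, X)
    ctr <- .centerTrain(K)
    eigK <- eigen(ctr$Kc, symmetric = TRUE)
    keep <- eigK$values > 1e-10 * max(eigK$values)
    P <- eigK$vectors[, keep, drop = FALSE]
    gam <- eigK$values[keep]
    # Reduced numerator matrix P' D P, built class by class.
    A <- matrix(0, ncol(P), ncol(P))
    for (i in seq_along(classes)) {
        pc <- colSums(P[labels == classes[i], , drop = FALSE])
        A <- A + tcrossprod(pc) / sizes[i]
    }
    eigA <- eigen(A, symmetric = TRUE)
    ratios <- eigA$values[seq_len(k)]
    if (any(ratios <= 0))
        stop(sprintf("only %d positive discriminants available, k = %d",
                     sum(eigA$values > 1e-12), k))
    Y <- eigA$vectors[, seq_len(k), drop = FALSE]
    # Unit feature-space norm: alpha' K alpha = y' Gamma^-1 y = 1.
    nrm <- sqrt(colSums(Y^2 / gam))
    Y <- sweep(Y, 2L, nrm, "/")
    alpha <- P %*% (Y / gam)
    sgn <- .fixSigns(alpha)
    alpha <- sweep(alpha, 2L, sgn, "*")
    scores <- sweep(P %*% Y, 2L, sgn, "*")   # = Kc alpha
    dimnames(scores) <- list(rownames(X), paste0("GD", seq_len(k)))
    new("GDAModel", spec = spec, Xtrain = X, dualCoef = alpha,
        eigenvalues = ratios, k = k, center = TRUE,
        kColMeans = ctr$colMeans, kMean = ctr$mean, trainScores = scores,
        ids = rownames(X), labels = labels, classSizes = sizes)
}

#' @rdname projectSamples
#' @export
setMethod("projectSamples", "ProjectionModel", function(object, newdata, ...) {
    newdata <- .asFeatureMatrix(newdata)
    if (ncol(newdata) != ncol(object@Xtrain))
        stop(sprintf("feature count mismatch: model has %d, newdata has %d",
                     ncol(object@Xtrain), ncol(newdata)))
    Kt <- .kmat(object@spec, newdata, object@Xtrain)
    if (object@center)
        Kt <- .centerTest(Kt, object@kColMeans, object@kMean)
    scores <- Kt %*% object@dualCoef
    dimnames(scores) <- list(rownames(newdata),
                             colnames(object@trainScores))
    new("ProjectedPoints", coords = scores, ids = rownames(newdata),
        labels = rep(NA_integer_, nrow(scores)))
})

#' @describeIn ProjectedPoints-class coordinate matrix.
#' @param object a `ProjectedPoints`.
#' @export
projectedCoords <- function(object) {
    stopifnot(is(object, "ProjectedPoints"))
    object@coords
}

#' Export projected coordinates as TSV
#'
#' Writes `id, dim1, ..., dimk, label` so the 3D class distributions can be
#' rendered in any plotting tool.
#'
#' @param points a [ProjectedPoints-class] (or a fitted
#'   [ProjectionModel-class], whose training scores are exported).
#' @param path output TSV path.
#' @param labels optional class labels to include.
#' @export
writeCoords <- function(points, path, labels = NULL) {
    if (is(points, "ProjectionModel")) {
        coords <- points@trainScores
        ids <- points@ids
    } else {
        stopifnot(is(points, "ProjectedPoints"))
        coords <- points@coords
        ids <- points@ids
    }
    df <- data.frame(id = ids, coords, check.names = FALSE)
    colnames(df)[-1] <- paste0("dim", seq_len(ncol(coords)))
    if (!is.null(labels)) df$label <- labels
    .atomicWrite(path, function(tmp)
        utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                           row.names = FALSE))
}

setMethod("show", "KPCAModel", function(object) {
    cat(sprintf("KPCAModel: %d components, %d training samples, %s kernel%s\n",
                object@k, nrow(object@Xtrain), object@spec@name,
                if (object@center) ", centered" else ", uncentered"))
    cat("  eigenvalues (of K/n):",
        paste(signif(object@eigenvalues, 4), collapse = ", "), "\n")
})

setMethod("show", "GDAModel", function(object) {
    cat(sprintf("GDAModel: %d discriminants, %d training samples (%d classes), %s kernel\n",
                object@k, nrow(object@Xtrain), length(object@classSizes),
                object@spec@name))
    cat("  Fisher ratios:",
        paste(signif(object@eigenvalues, 4), collapse = ", "), "\n")
})

setMethod("show", "ProjectedPoints", function(object) {
    cat(sprintf("ProjectedPoints: %d samples in %d dimensions\n",
                nrow(object@coords), ncol(object@coords)))
})
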