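# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
    if (missing(seed) || is.null(seed) || !is.finite(seed))
        stop("a finite integer 'seed' is required")
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

# Write a file atomically: write to a temporary sibling, then rename.
.atomicWrite <- function(path, writer) {
    tmp <- paste0(path, ".tmp", Sys.getpid())
    ok <- FALSE
    on.exit(if (!ok && file.exists(tmp)) unlink(tmp), add = TRUE)
    writer(tmp)
    if (!file.rename(tmp, path))
        stop("could not move temporary file onto ", path)
    ok <- TRUE
    invisible(path)
}

.defaultIds <- function(n, prefix = "s") sprintf("%s%d", prefix, seq_len(n))

# Coerce to a numeric matrix, inventing row ids when absent.
.asFeatureMatrix <- function(X) {
    X <- as.matrix(X)
    storage.mode(X) <- "double"
    if (is.null(rownames(X))) rownames(X) <- .defaultIds(nrow(X))
    X
}
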