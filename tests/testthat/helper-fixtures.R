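# Small deterministic fixtures built in code at test time.

randomMatrix <- function(n, p, seed) {
    set.seed(seed)
    matrix(rnorm(n * p), n, p)
}

# Two well-separated isotropic Gaussian classes.
twoBlobs <- function(nPerClass = 10, sep = 8, p = 2, seed = 1) {
    set.seed(seed)
    X <- rbind(matrix(rnorm(nPerClass * p), nPerClass, p),
               matrix(rnorm(nPerClass * p, mean = sep), nPerClass, p))
    list(X = X, labels = rep(1:2, each = nPerClass))
}

writeTempFasta <- function(lines) {
    path <- tempfile(fileext = ".fasta")
    writeLines(lines, path)
    path
}
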