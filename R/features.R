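#' The 20 standard amino acids in alphabetical one-letter order
#'
#' Fixed column order of every composition matrix produced by
#' [aaComposition()], so feature columns are reproducible across runs.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and whitespace-stripped; ids are the first
#' whitespace-delimited token of each header. Empty files, records with
#' empty sequences and duplicated ids are errors.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::AAStringSet] named by sequence id.
#' @export
readFasta <- function(path) {
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    if (file.size(path) == 0)
        stop("empty FASTA file: ", path)
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) == 0L)
        stop("no FASTA records in ", path)
    ids <- sub("\\s.*$", "", names(raw))
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop("duplicate FASTA ids: ", paste(unique(dup), collapse = ", "))
    seqs <- toupper(gsub("[[:space:]]", "", as.character(raw)))
    empty <- ids[nchar(seqs) == 0L]
    if (length(empty))
        stop("FASTA record with empty sequence: ",
             paste(empty, collapse = ", "))
    out <- Biostrings::AAStringSet(seqs)
    names(out) <- ids
    out
}

#' Amino-acid composition of protein sequences
#'
#' Computes, for each sequence, the 20-vector of standard-residue fractions
#' in the fixed alphabetical order of [AA20]. Non-standard letters
#' (B, J, O, U, X, Z and anything else outside the 20) are excluded from both
#' numerator and denominator; their count is reported in the `"nSkipped"`
#' attribute and a warning is emitted when any are present. Fractions sum to
#' 1 for every sequence with at least one standard residue; a sequence with
#' none is an error.
#'
#' @param x an [Biostrings::AAStringSet] (e.g. from [readFasta()]) or a
#'   character vector of sequences.
#' @return a numeric matrix (sequences x 20) with attributes `"nCounted"`
#'   and `"nSkipped"` (integer vectors per sequence).
#' @examples
#' aaComposition(c(s1 = "AAC"))[1, c("A", "C")] # 2/3, 1/3
#' @export
aaComposition <- function(x) {
    if (is.character(x)) {
        ids <- names(x)
        x <- Biostrings::AAStringSet(toupper(gsub("[[:space:]]", "", x)))
        names(x) <- if (is.null(ids)) .defaultIds(length(x)) else ids
    }
    stopifnot(is(x, "AAStringSet"))
    if (length(x) == 0L)
        stop("no sequences given")
    if (any(BiocGenerics::width(x) == 0L))
        stop("empty sequence: ",
             paste(names(x)[BiocGenerics::width(x) == 0L], collapse = ", "))
    counts <- Biostrings::letterFrequency(x, letters = AA20)
    nCounted <- as.integer(rowSums(counts))
    nSkipped <- as.integer(BiocGenerics::width(x)) - nCounted
    if (any(nCounted == 0L))
        stop("sequence with no standard residues: ",
             paste(names(x)[nCounted == 0L], collapse = ", "))
    if (any(nSkipped > 0L))
        warning(sum(nSkipped), " non-standard residue(s) skipped in ",
                sum(nSkipped > 0L), " sequence(s)")
    frac <- counts / nCounted
    dimnames(frac) <- list(names(x), AA20)
    structure(frac, nCounted = nCounted, nSkipped = nSkipped)
}

#' Range scaling to [0, 1]
#'
#' `fitScaler()` learns per-feature minima and maxima from a training matrix;
#' `applyScaler()` maps features through `(x - min) / (max - min)`, sends
#' constant training features to 0, and clips transformed values into
#' \[0, 1\] (so out-of-range test features are clipped, not extrapolated,
#' keeping kernel arguments bounded).
#'
#' @param X numeric matrix, samples in rows (`n >= 2` for fitting).
#' @return `fitScaler()`: a [RangeScaler-class]; `applyScaler()`: the scaled
#'   matrix.
#' @examples
#' s <- fitScaler(cbind(c(2, 4, 6)))
#' applyScaler(s, cbind(c(2, 4, 6)))   # 0, 0.5, 1
#' @export
fitScaler <- function(X) {
    X <- .asFeatureMatrix(X)
    if (nrow(X) < 2L)
        stop("need at least 2 samples to fit a range scaler")
    mins <- apply(X, 2L, min)
    maxs <- apply(X, 2L, max)
    new("RangeScaler", mins = unname(mins), maxs = unname(maxs),
        constant = unname(maxs == mins))
}

#' @rdname fitScaler
#' @param scaler a fitted [RangeScaler-class].
#' @export
applyScaler <- function(scaler, X) {
    stopifnot(is(scaler, "RangeScaler"))
    X <- .asFeatureMatrix(X)
    if (ncol(X) != length(scaler@mins))
        stop(sprintf("feature count mismatch: scaler has %d, data has %d",
                     length(scaler@mins), ncol(X)))
    rng <- scaler@maxs - scaler@mins
    rng[scaler@constant] <- 1   # avoid 0/0; constant columns become 0 below
    out <- sweep(sweep(X, 2L, scaler@mins), 2L, rng, "/")
    out[, scaler@constant] <- 0
    pmin(pmax(out, 0), 1)
}

setMethod("show", "RangeScaler", function(object) {
    cat(sprintf("RangeScaler: %d features (%d constant)\n",
                length(object@mins), sum(object@constant)))
})
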