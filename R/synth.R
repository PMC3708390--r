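# Seeded synthetic-data generators. Every generator is a pure function of
# its parameters and the mandatory seed, so fixtures are reproducible and no
# external downloads are needed to exercise the full pipeline.

#' Gaussian blob classes
#'
#' Isotropic Gaussian clusters with configurable centre separation. Class
#' centres are placed `separation` apart along the coordinate axes (cycling
#' with a growing multiplier when there are more classes than dimensions),
#' so `separation = 0` collapses all classes onto one distribution.
#'
#' @param nPerClass samples per class (scalar or one value per class).
#' @param nClasses number of classes (default `length(nPerClass)` when that
#'   is a vector, else 2).
#' @param dim ambient dimension (default 3).
#' @param separation centre separation (default 5).
#' @param sd within-class standard deviation (default 1).
#' @param seed mandatory RNG seed.
#' @return a [LabeledDataset-class].
#' @export
makeGaussianBlobs <- function(nPerClass, nClasses = NULL, dim = 3L,
                              separation = 5, sd = 1, seed) {
    if (is.null(nClasses))
        nClasses <- if (length(nPerClass) > 1L) length(nPerClass) else 2L
    if (nClasses < 2L)
        stop("need at least 2 classes")
    nPerClass <- rep_len(as.integer(nPerClass), nClasses)
    if (any(nPerClass < 1L))
        stop("nPerClass must be positive")
    centers <- t(vapply(seq_len(nClasses), function(cl) {
        v <- numeric(dim)
        v[((cl - 1L) %% dim) + 1L] <- separation * ceiling(cl / dim)
        v
    }, numeric(dim)))
    .withSeed(seed, {
        X <- do.call(rbind, lapply(seq_len(nClasses), function(cl) {
            matrix(stats::rnorm(nPerClass[cl] * dim, sd = sd),
                   nPerClass[cl], dim) +
                matrix(centers[cl, ], nPerClass[cl], dim, byrow = TRUE)
        }))
        labels <- rep(seq_len(nClasses), nPerClass)
        rownames(X) <- .defaultIds(nrow(X), "b")
        labeledDataset(X, labels,
                       classLevels = paste0("C", seq_len(nClasses)))
    })
}

#' Concentric shell classes
#'
#' Points on noisy hyperspheres of distinct radii: linearly inseparable but
#' radially separable, the structure nonlinear kernel projection exists to
#' recover. The default ambient dimension (25) is deliberately much larger
#' than the 3 projected dimensions: with a few dozen samples per shell, the
#' within-shell nearest-neighbour distance on the outer sphere then exceeds
#' the gap to the inner sphere (extreme-value statistics of the largest
#' pairwise cosine, roughly `sqrt(2 log n / d)`, put the within-shell
#' nearest neighbour at `r * sqrt(2 (1 - c))` against a between-shell
#' distance of about `sqrt(r1^2 + r2^2 - 2 r1 r2 c)`), so plain
#' nearest-neighbour geometry in the input space mixes the shells while an
#' rbf projection that encodes the radius separates them.
#'
#' @param nPerClass samples per class.
#' @param radii distinct shell radius per class.
#' @param noise radial noise standard deviation (default 0.1). A warning is
#'   emitted when shells overlap within the noise.
#' @param dim ambient dimension (default 25).
#' @param seed mandatory RNG seed.
#' @return a [LabeledDataset-class].
#' @export
makeConcentricShells <- function(nPerClass, radii = c(1, 3), noise = 0.1,
                                 dim = 25L, seed) {
    radii <- as.numeric(radii)
    if (anyDuplicated(radii))
        stop("shell radii must be distinct")
    nClasses <- length(radii)
    nPerClass <- rep_len(as.integer(nPerClass), nClasses)
    if (any(nPerClass < 1L))
        stop("nPerClass must be positive")
    if (min(abs(diff(sort(radii)))) < 4 * noise)
        warning("shell radii overlap within the radial noise")
    .withSeed(seed, {
        X <- do.call(rbind, lapply(seq_len(nClasses), function(cl) {
            n <- nPerClass[cl]
            dirs <- matrix(stats::rnorm(n * dim), n, dim)
            dirs <- dirs / sqrt(rowSums(dirs^2))
            dirs * (radii[cl] + stats::rnorm(n, sd = noise))
        }))
        labels <- rep(seq_len(nClasses), nPerClass)
        rownames(X) <- .defaultIds(nrow(X), "sh")
        labeledDataset(X, labels,
                       classLevels = paste0("R", seq_len(nClasses)))
    })
}

#' Default per-class residue frequency profiles
#'
#' Builds up to four class profiles over the 20 standard residues: each
#' class's five signature residues (hydrophobic, charged, polar, or the
#' remaining group) are boosted by `shift` above the uniform frequency 0.05
#' and the other fifteen residues share the remainder equally.
#'
#' @param nClasses number of classes (<= 4).
#' @param shift boost applied to each signature residue (default 0.05).
#' @return matrix (classes x 20) of frequencies, rows summing to 1.
#' @export
proteinProfiles <- function(nClasses = 4L, shift = 0.05) {
    groups <- list(hydrophobic = c("A", "I", "L", "M", "V"),
                   charged = c("D", "E", "K", "R", "H"),
                   polar = c("N", "Q", "S", "T", "Y"),
                   other = c("C", "F", "G", "P", "W"))
    if (nClasses > length(groups))
        stop("at most ", length(groups), " default profiles are available")
    prof <- matrix(0, nClasses, 20L, dimnames = list(NULL, AA20))
    for (cl in seq_len(nClasses)) {
        sig <- groups[[cl]]
        prof[cl, sig] <- 0.05 + shift
        prof[cl, setdiff(AA20, sig)] <- (1 - 5 * (0.05 + shift)) / 15
    }
    prof
}

#' Membrane-like five-class residue profiles
#'
#' A synthetic emulation of the five membrane protein types A--E: classes
#' A, B, D and E take the four [proteinProfiles()] signatures, while class C
#' (the multipass-transmembrane analogue, the natural stage-1 target of the
#' hierarchical pipeline) is strongly enriched in hydrophobic and aromatic
#' residues (A, F, I, L, V, W), as multipass transmembrane segments are.
#'
#' @param shift signature boost for the non-target classes (default 0.05).
#' @param targetFreq per-residue frequency of the six class-C signature
#'   residues (default 0.10).
#' @return matrix (5 x 20) of residue frequencies with rownames
#'   `c("A", "B", "C", "D", "E")`, rows summing to 1.
#' @export
membraneProfiles <- function(shift = 0.05, targetFreq = 0.10) {
    base <- proteinProfiles(4L, shift = shift)
    sig <- c("A", "F", "I", "L", "V", "W")
    target <- stats::setNames(rep((1 - 6 * targetFreq) / 14, 20L), AA20)
    target[sig] <- targetFreq
    prof <- rbind(base[1:2, ], C = target, base[3:4, ])
    rownames(prof) <- c("A", "B", "C", "D", "E")
    prof
}

#' Composition-biased synthetic proteins
#'
#' Draws protein sequences i.i.d. from per-class residue frequency profiles,
#' with lengths uniform in `lengthRange` — sufficient structure for a method
#' that only ever sees amino-acid composition. Optionally writes a FASTA
#' file and a matching `id<TAB>label` table that round-trip through
#' [readFasta()] and [aaComposition()].
#'
#' @param nPerClass sequences per class (scalar or per class).
#' @param profiles matrix (classes x 20, columns in [AA20] order) of residue
#'   frequencies; rows are renormalised to sum to 1 and must be
#'   non-negative. Defaults to [proteinProfiles()] for the number of classes
#'   implied by `nPerClass`.
#' @param lengthRange integer range of sequence lengths (default 200--400).
#' @param seed mandatory RNG seed.
#' @param fastaPath,labelsPath optional output paths.
#' @return list with `sequences` (an `AAStringSet`), `labels` (character),
#'   and `dataset` (the composition [LabeledDataset-class]).
#' @export
makeBiasedProteins <- function(nPerClass, profiles = NULL,
                               lengthRange = c(200L, 400L), seed,
                               fastaPath = NULL, labelsPath = NULL) {
    if (is.null(profiles))
        profiles <- proteinProfiles(max(length(nPerClass), 2L))
    profiles <- as.matrix(profiles)
    if (ncol(profiles) != 20L)
        stop("profiles must have 20 columns (standard residues)")
    if (any(profiles < 0))
        stop("negative residue frequency in profile")
    if (any(rowSums(profiles) <= 0))
        stop("profile rows must have positive total frequency")
    profiles <- profiles / rowSums(profiles)
    nClasses <- nrow(profiles)
    nPerClass <- rep_len(as.integer(nPerClass), nClasses)
    if (any(nPerClass < 1L))
        stop("nPerClass must be positive")
    classLevels <- if (!is.null(rownames(profiles))) rownames(profiles)
                   else paste0("class", seq_len(nClasses))
    lenChoices <- seq.int(lengthRange[1], lengthRange[2])
    .withSeed(seed, {
        lens <- lenChoices[sample.int(length(lenChoices), sum(nPerClass),
                                      replace = TRUE)]
        labels <- rep(seq_len(nClasses), nPerClass)
        seqs <- vapply(seq_along(lens), function(i)
            paste(sample(AA20, lens[i], replace = TRUE,
                         prob = profiles[labels[i], ]), collapse = ""),
            character(1))
        ids <- sprintf("P%04d", seq_along(seqs))
        sset <- Biostrings::AAStringSet(seqs)
        names(sset) <- ids
        if (!is.null(fastaPath))
            .atomicWrite(fastaPath, function(tmp)
                Biostrings::writeXStringSet(sset, tmp))
        if (!is.null(labelsPath))
            .atomicWrite(labelsPath, function(tmp)
                utils::write.table(
                    data.frame(id = ids, label = classLevels[labels]),
                    tmp, sep = "\t", quote = FALSE, row.names = FALSE))
        comp <- suppressWarnings(aaComposition(sset))
        list(sequences = sset, labels = classLevels[labels],
             dataset = labeledDataset(comp, labels, ids = ids,
                                      classLevels = classLevels))
    })
}
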