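#' @include objects.R
NULL

#' Simulate the randomized-PAM plasmid library
#'
#' Generates library molecules laid out as
#' \code{anchor | randomized 8-mer | protospacer | downstream}.  The
#' randomized bases are drawn uniformly unless a skew table is supplied.  The
#' drawn 8-mer of every molecule is stored in \code{mcols(x)$pam} as ground
#' truth, and the design travels in \code{metadata(x)$design} so downstream
#' steps share the same geometry.
#'
#' @param design a \code{\link{PamLibraryDesign}}.
#' @param nMolecules number of molecules to generate (> 0).
#' @param seed optional integer seed; the same seed reproduces the library
#'   exactly.
#' @param baseProbs optional 4 x \code{randomizedLen} matrix (rows A,C,G,T,
#'   columns summing to 1) skewing the randomized-base composition.
#'
#' @return a named \code{DNAStringSet} of molecules with truth 8-mers in
#'   \code{mcols()}.
#' @examples
#' lib <- simulateLibrary(PamLibraryDesign(), 5, seed = 1)
#' mcols(lib)$pam
#' @export
simulateLibrary <- function(design, nMolecules, seed = NULL,
                            baseProbs = NULL) {
    stopifnot(is(design, "PamLibraryDesign"))
    validObject(design)
    nMolecules <- as.integer(nMolecules)
    if (is.na(nMolecules) || nMolecules < 1L)
        stop("'nMolecules' must be a positive integer")
    L <- randomizedLen(design)
    if (!is.null(baseProbs)) {
        stopifnot(is.matrix(baseProbs), nrow(baseProbs) == 4L,
                  ncol(baseProbs) == L,
                  all(abs(colSums(baseProbs) - 1) < 1e-6))
        if (is.null(rownames(baseProbs)))
            rownames(baseProbs) <- .DNA_BASES
    }
    pams <- .withSeed(seed, {
        cols <- lapply(seq_len(L), function(i) {
            p <- if (is.null(baseProbs)) rep(0.25, 4L)
                 else baseProbs[.DNA_BASES, i]
            sample(.DNA_BASES, nMolecules, replace = TRUE, prob = p)
        })
        do.call(paste0, cols)
    })
    seqs <- paste0(as.character(anchorSeq(design)), pams,
                   as.character(spacerSeq(design)),
                   as.character(design@downstream))
    mol <- DNAStringSet(seqs)
    names(mol) <- sprintf("mol%0*d", nchar(nMolecules), seq_len(nMolecules))
    mcols(mol)$pam <- pams
    metadata(mol)$design <- design
    mol
}

# Per-molecule cleavage probability: PWM likelihood of the randomized 8-mer,
# rescaled so the best PAM cleaves with probability maxCleavageProb.
.cleavageProb <- function(pams, model) {
    W <- model@pamPWM
    L <- ncol(W)
    logp <- numeric(length(pams))
    for (i in seq_len(L)) {
        b <- substr(pams, i, i)
        logp <- logp + log(W[cbind(match(b, .DNA_BASES), i)])
    }
    best <- sum(log(apply(W, 2L, max)))
    model@maxCleavageProb * exp(logp - best)
}

# Inject substitution errors into character sequences at a fixed per-base rate.
.addSubstitutions <- function(seqs, rate) {
    if (rate <= 0)
        return(seqs)
    lens <- nchar(seqs)
    total <- sum(lens)
    hits <- which(runif(total) < rate)
    if (!length(hits))
        return(seqs)
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    read_idx <- findInterval(hits, starts)
    pos <- hits - starts[read_idx] + 1L
    for (j in seq_along(hits)) {
        i <- read_idx[j]
        cur <- substr(seqs[i], pos[j], pos[j])
        substr(seqs[i], pos[j], pos[j]) <-
            sample(setdiff(.DNA_BASES, cur), 1L)
    }
    seqs
}

#' Simulate cleavage, blunting, adapter ligation and sequencing
#'
#' Each molecule is cleaved with probability given by the nuclease model's
#' PAM preference applied to its randomized 8-mer.  A cleaved molecule is cut
#' on the target strand \code{cutSite} PAM-distal protospacer bases from the
#' PAM (or, when flagged as background with probability
#' \code{backgroundRate}, at a uniformly random position).  The staggered
#' non-target-strand cut is resolved by blunting to the target-strand
#' coordinate, the adapter is ligated onto the blunt end, and sequencing
#' starts at the ligated adapter and proceeds across the cut fragment toward
#' the PAM and anchor, i.e. a read is
#' \code{adapter + reverse_complement(anchor..cut fragment)} truncated to
#' \code{readLen}.  Substitution errors and per-base Phred qualities
#' (independent normal, clipped) are then applied.
#'
#' @param molecules molecules from \code{\link{simulateLibrary}} (the design
#'   is taken from \code{metadata(molecules)$design} unless given).
#' @param model a \code{\link{NucleaseModel}}.
#' @param readLen sequencing read length; must be able to span adapter, cut
#'   fragment, PAM and anchor for an on-target cut.
#' @param qualityModel list with \code{mean}, \code{sd}, \code{min},
#'   \code{max} describing the per-base Phred score distribution.
#' @param seed optional integer seed.
#' @param design the \code{PamLibraryDesign}; defaults to the one attached to
#'   \code{molecules}.
#' @param blunt logical; resolve the staggered non-target-strand cut to the
#'   target-strand coordinate (the assay blunts before ligation).  With
#'   \code{blunt = FALSE} the fragment retains the non-target-strand overhang.
#'
#' @return a \code{\link{CleavageReadSet}}.
#' @examples
#' lib <- simulateLibrary(PamLibraryDesign(), 2000, seed = 1)
#' rs <- simulateCleavageReads(lib, NucleaseModel("TTTV"), seed = 2)
#' rs
#' @export
simulateCleavageReads <- function(molecules, model, readLen = 150L,
                                  qualityModel = list(mean = 35, sd = 4,
                                                      min = 2, max = 41),
                                  seed = NULL, design = NULL, blunt = TRUE) {
    stopifnot(is(model, "NucleaseModel"))
    validObject(model)
    if (is.null(design))
        design <- metadata(molecules)$design
    if (is.null(design))
        stop("no 'design' supplied and none attached to 'molecules'")
    pams <- mcols(molecules)$pam
    if (is.null(pams))
        stop("'molecules' carry no truth 8-mers; use simulateLibrary()")
    anchorLen <- length(anchorSeq(design))
    L <- randomizedLen(design)
    adapterChr <- as.character(adapterSeq(design))
    readLen <- as.integer(readLen)
    minLen <- nchar(adapterChr) + model@cutSite + L + anchorLen
    if (readLen < minLen)
        stop(sprintf(paste0("readLen = %d cannot span adapter + cut fragment",
                            " + PAM + anchor (need >= %d)"), readLen, minLen))
    molChr <- as.character(molecules)
    molLen <- nchar(molChr)
    targetCutPos <- anchorLen + L + model@cutSite  # last retained base
    if (any(targetCutPos > molLen))
        stop("cut site lies beyond the molecule; extend spacer/downstream")

    .withSeed(seed, {
        p <- .cleavageProb(pams, model)
        cleaved <- runif(length(p)) < p
        idx <- which(cleaved)
        n <- length(idx)
        if (n == 0L)
            stop("no molecule was cleaved; increase nMolecules or maxCleavageProb")
        bg <- runif(n) < model@backgroundRate
        k <- rep(targetCutPos, n)
        if (any(bg))  # uniformly random blunt-end position
            k[bg] <- 1L + floor(runif(sum(bg)) * (molLen[idx][bg] - 1L))
        if (!blunt)
            k <- pmin(k + model@stagger, molLen[idx])
        frag <- substr(molChr[idx], 1L, k)
        reads <- paste0(adapterChr,
                        as.character(reverseComplement(DNAStringSet(frag))))
        reads <- substr(reads, 1L, readLen)
        reads <- .addSubstitutions(reads, model@errorRate)
        lens <- nchar(reads)
        q <- round(rnorm(sum(lens), qualityModel$mean, qualityModel$sd))
        q <- pmin(pmax(q, qualityModel$min), qualityModel$max)
        qstr <- intToUtf8(q + 33L)
        ends <- cumsum(lens)
        quals <- substring(qstr, ends - lens + 1L, ends)
        ids <- sprintf("read%0*d", nchar(n), seq_len(n))
        seqs <- DNAStringSet(reads)
        names(seqs) <- ids
        qs <- PhredQuality(quals)
        names(qs) <- ids
        truth <- DataFrame(read_id = ids,
                           true_pam = pams[idx],
                           true_cut = k - anchorLen - L,
                           background = bg)
        new("CleavageReadSet",
            reads = QualityScaledDNAStringSet(seqs, qs),
            truth = truth, design = design,
            nMolecules = length(molecules))
    })
}

#' One-call assay simulation
#'
#' Convenience wrapper running \code{\link{simulateLibrary}} and
#' \code{\link{simulateCleavageReads}} with a single seed.
#'
#' @inheritParams simulateCleavageReads
#' @inheritParams simulateLibrary
#' @param ... passed to \code{\link{simulateCleavageReads}}.
#' @return a \code{\link{CleavageReadSet}}.
#' @export
simulateAssay <- function(design, model, nMolecules, seed = NULL, ...) {
    .withSeed(seed, {
        lib <- simulateLibrary(design, nMolecules)
        simulateCleavageReads(lib, model, design = design, ...)
    })
}

#' Write simulated reads and ground truth
#'
#' \code{exportFastq} writes Sanger/Phred+33 FASTQ; \code{exportTruth} writes
#' the hidden truth table as TSV (\code{read_id}, \code{true_pam},
#' \code{true_cut}, \code{background_flag}).
#'
#' @param x a \code{\link{CleavageReadSet}}.
#' @param file output path.
#' @return the path, invisibly.
#' @export
exportFastq <- function(x, file) {
    stopifnot(is(x, "CleavageReadSet"))
    writeQualityScaledXStringSet(x@reads, file)
    invisible(file)
}

#' @rdname exportFastq
#' @export
exportTruth <- function(x, file) {
    stopifnot(is(x, "CleavageReadSet"))
    df <- as.data.frame(x@truth)
    names(df)[names(df) == "background"] <- "background_flag"
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}
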