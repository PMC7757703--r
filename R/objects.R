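#' @include AllClasses.R AllGenerics.R
NULL

## Default assay geometry. The anchor is the 28 bp of constant backbone
## adjacent to the randomized region; the adapter is the double-stranded
## sequence ligated onto blunted cleavage products.
.DEFAULT_ANCHOR <- "GGCTTTAGATCCGGTCACCTGAAGCTTG"
.DEFAULT_SPACER <- "GACGCATAAAGATGAGACGCTGGA"
.DEFAULT_ADAPTER <- "AGATCGGAAGAGC"
.DEFAULT_DOWNSTREAM <- "CATGGTCATAGCTGTTTCCT"

#' Construct a library design
#'
#' @param anchor constant 28-bp backbone sequence adjacent to the randomized
#'   region.
#' @param randomizedLen number of randomized bases (the candidate PAM width).
#' @param spacer constant protospacer sequence (default 24 bp).
#' @param adapter adapter sequence ligated at the blunted cut.
#' @param downstream constant context 3' of the protospacer.
#'
#' @return a \code{PamLibraryDesign}.
#' @examples
#' PamLibraryDesign()
#' @export
PamLibraryDesign <- function(anchor = .DEFAULT_ANCHOR,
                             randomizedLen = 8L,
                             spacer = .DEFAULT_SPACER,
                             adapter = .DEFAULT_ADAPTER,
                             downstream = .DEFAULT_DOWNSTREAM) {
    new("PamLibraryDesign",
        anchor = DNAString(.normalizeDNA(anchor, "anchor")),
        randomizedLen = as.integer(randomizedLen),
        spacer = DNAString(.normalizeDNA(spacer, "spacer")),
        adapter = DNAString(.normalizeDNA(adapter, "adapter")),
        downstream = DNAString(.normalizeDNA(downstream, "downstream")))
}

#' @rdname PamLibraryDesign
#' @export
setMethod("anchorSeq", "PamLibraryDesign", function(x) x@anchor)

#' @rdname PamLibraryDesign
#' @export
setMethod("adapterSeq", "PamLibraryDesign", function(x) x@adapter)

#' @rdname PamLibraryDesign
#' @export
setMethod("spacerSeq", "PamLibraryDesign", function(x) x@spacer)

#' @rdname PamLibraryDesign
#' @export
setMethod("randomizedLen", "PamLibraryDesign", function(x) x@randomizedLen)

setMethod("show", "PamLibraryDesign", function(object) {
    cat("PamLibraryDesign\n")
    cat(sprintf("  anchor     (%2d bp): %s\n", length(object@anchor),
                as.character(object@anchor)))
    cat(sprintf("  randomized (%2d bp): %s\n", object@randomizedLen,
                strrep("N", object@randomizedLen)))
    cat(sprintf("  spacer     (%2d bp): %s\n", length(object@spacer),
                as.character(object@spacer)))
    cat(sprintf("  adapter    (%2d bp): %s\n", length(object@adapter),
                as.character(object@adapter)))
    if (length(object@downstream))
        cat(sprintf("  downstream (%2d bp): %s\n", length(object@downstream),
                    as.character(object@downstream)))
})

#' Position weight matrix from an IUPAC motif
#'
#' Builds a per-position base-probability matrix over the randomized region
#' from a degenerate motif.  The motif is right-aligned: its last character
#' describes the base adjacent to the protospacer, matching how Cas12a-family
#' PAMs such as TTTV or YYN are written 5' of the protospacer.  Positions not
#' covered by the motif, and N positions, are uniform.  At a constrained
#' position the bases allowed by the IUPAC code share probability
#' \code{fidelity} equally and the remaining bases share \code{1 - fidelity}.
#'
#' @param motif IUPAC motif string, e.g. \code{"TTTV"}.
#' @param width width of the randomized region (default 8).
#' @param fidelity total probability assigned to the allowed bases of a
#'   constrained position (default 0.97).
#'
#' @return 4 x \code{width} column-stochastic matrix with rows A,C,G,T.
#' @examples
#' pwmFromIUPAC("TTTV")["T", ]
#' @export
pwmFromIUPAC <- function(motif, width = 8L, fidelity = 0.97) {
    motif <- toupper(as.character(motif))
    stopifnot(nchar(motif) <= width, fidelity > 0, fidelity <= 1)
    chars <- strsplit(motif, "", fixed = TRUE)[[1]]
    if (!all(chars %in% names(IUPAC_CODE_MAP)))
        stop("motif contains non-IUPAC characters")
    W <- matrix(0.25, nrow = 4L, ncol = width,
                dimnames = list(.DNA_BASES, NULL))
    offset <- width - nchar(motif)   # right-align
    for (i in seq_along(chars)) {
        allowed <- strsplit(IUPAC_CODE_MAP[[chars[i]]], "", fixed = TRUE)[[1]]
        if (length(allowed) == 4L)
            next
        col <- rep((1 - fidelity) / (4 - length(allowed)), 4L)
        names(col) <- .DNA_BASES
        col[allowed] <- fidelity / length(allowed)
        W[, offset + i] <- col
    }
    W
}

#' Construct a nuclease model
#'
#' @param pam either a 4 x L column-stochastic matrix (rows A,C,G,T) or an
#'   IUPAC motif string passed to \code{\link{pwmFromIUPAC}}.
#' @param maxCleavageProb cleavage probability of the best-matching PAM.
#' @param cutSite target-strand cut position, in PAM-distal protospacer bases
#'   (1-based; default 22).
#' @param stagger offset between the target- and non-target-strand cuts.
#' @param backgroundRate fraction of cleavage events placed at a uniformly
#'   random position (crude-lysate background).
#' @param errorRate per-base substitution sequencing-error rate.
#' @param width randomized-region width used when \code{pam} is a motif.
#' @param fidelity motif fidelity used when \code{pam} is a motif.
#'
#' @return a \code{NucleaseModel}.
#' @examples
#' NucleaseModel("TTTV")
#' @export
NucleaseModel <- function(pam = "TTTV", maxCleavageProb = 0.9,
                          cutSite = 22L, stagger = 5L,
                          backgroundRate = 0.05, errorRate = 0.001,
                          width = 8L, fidelity = 0.97) {
    W <- if (is.matrix(pam)) {
        storage.mode(pam) <- "double"
        pam
    } else {
        pwmFromIUPAC(pam, width = width, fidelity = fidelity)
    }
    new("NucleaseModel", pamPWM = W,
        maxCleavageProb = as.numeric(maxCleavageProb),
        cutSite = as.integer(cutSite), stagger = as.integer(stagger),
        backgroundRate = as.numeric(backgroundRate),
        errorRate = as.numeric(errorRate))
}

setMethod("show", "NucleaseModel", function(object) {
    cat("NucleaseModel\n")
    best <- apply(object@pamPWM, 2L, function(col) {
        top <- .DNA_BASES[col >= max(col) - 1e-12]
        mergeIUPACLetters(paste(sort(top), collapse = ""))
    })
    cat(sprintf("  preferred PAM      : %s\n", paste(best, collapse = "")))
    cat(sprintf("  max cleavage prob  : %.3f\n", object@maxCleavageProb))
    cat(sprintf("  target-strand cut  : %d (PAM-distal bases)\n",
                object@cutSite))
    cat(sprintf("  stagger            : %d\n", object@stagger))
    cat(sprintf("  background rate    : %.3f\n", object@backgroundRate))
    cat(sprintf("  substitution errors: %.4f\n", object@errorRate))
})

#' @rdname CleavageReadSet
#' @export
setMethod("readTruth", "CleavageReadSet", function(x) x@truth)

#' @rdname CleavageReadSet
#' @export
setMethod("sequencedReads", "CleavageReadSet", function(x) x@reads)

#' @rdname CleavageReadSet
#' @export
setMethod("length", "CleavageReadSet", function(x) length(x@reads))

#' @rdname CleavageReadSet
#' @export
setMethod("names", "CleavageReadSet", function(x) names(x@reads))

setMethod("show", "CleavageReadSet", function(object) {
    cat(sprintf("CleavageReadSet: %d reads from %d molecules (%d uncleaved)\n",
                length(object@reads), object@nMolecules,
                object@nMolecules - length(object@reads)))
    if (length(object@reads)) {
        bg <- sum(object@truth$background)
        cat(sprintf("  background cuts: %d (%.1f%%)\n", bg,
                    100 * bg / length(object@reads)))
    }
})

#' @rdname PamProfile
#' @export
setMethod("pamCounts", "PamProfile", function(x) x@counts)

#' @rdname PamProfile
#' @export
setMethod("pamFreqs", "PamProfile", function(x) x@freqs)

#' @rdname PamProfile
#' @export
setMethod("infoBits", "PamProfile", function(x) x@infoBits)

setMethod("show", "PamProfile", function(object) {
    cat(sprintf("PamProfile over %d positions (%d PAMs", ncol(object@freqs),
                object@nRetained))
    if (!is.na(object@fractionFiltered))
        cat(sprintf(", %.1f%% cut-site filtered", 100 * object@fractionFiltered))
    cat(")\n")
    cat(sprintf("  consensus: %s\n", object@consensus))
    cat(sprintf("  info bits: %s\n",
                paste(sprintf("%.2f", object@infoBits), collapse = " ")))
})

#' @rdname PamCallResult
#' @export
setMethod("pamObservations", "PamCallResult", function(x) x@observations)

#' @rdname PamCallResult
#' @export
setMethod("cutSiteDistribution", "PamCallResult", function(x) x@distribution)

#' @rdname PamCallResult
#' @export
setMethod("pamProfile", "PamCallResult", function(x) x@profile)

#' @rdname PamCallResult
#' @export
setMethod("pamConsensus", "PamCallResult", function(x) x@consensus)

#' @rdname PamCallResult
#' @export
setMethod("cutSite", "PamCallResult", function(x) x@cutSite)

#' @rdname PamCallResult
#' @export
setMethod("readAccounting", "PamCallResult", function(x) x@accounting)

setMethod("show", "PamCallResult", function(object) {
    cat("PamCallResult\n")
    cat(sprintf("  consensus PAM : %s\n", object@consensus))
    cat(sprintf("  cut site      : %d (PAM-distal bases, target strand)\n",
                object@cutSite))
    acc <- object@accounting
    cat("  read accounting:\n")
    for (nm in names(acc))
        cat(sprintf("    %-18s %d\n", nm, acc[[nm]]))
})

#' @rdname SgRNADesign
#' @export
setMethod("guideScaffold", "SgRNADesign", function(x) x@scaffold)

#' @rdname SgRNADesign
#' @export
setMethod("guideSpacer", "SgRNADesign", function(x) x@spacer)

#' @rdname SgRNADesign
#' @export
setMethod("fullGuide", "SgRNADesign", function(x) x@fullGuide)

setMethod("show", "SgRNADesign", function(object) {
    cat("SgRNADesign (universal single-guide RNA)\n")
    cat(sprintf("  scaffold (%d nt): %s\n", length(object@scaffold),
                as.character(object@scaffold)))
    cat(sprintf("  spacer   (%d nt): %s\n", length(object@spacer),
                as.character(object@spacer)))
    if (nrow(object@stemLoop))
        cat(sprintf("  stem-loop: %s[N%d]%s at scaffold position %d\n",
                    object@stemLoop$stem5[1L], object@stemLoop$loop_len[1L],
                    object@stemLoop$stem3[1L], object@stemLoop$start[1L]))
    else
        cat("  stem-loop: none detected in scaffold\n")
})

setMethod("show", "EditQuantResult", function(object) {
    s <- object@summary
    cat("EditQuantResult\n")
    cat(sprintf("  cut at between-base %d (%s strand), window %d-%d\n",
                object@cut$cut, object@cut$strand,
                object@cut$window[1L], object@cut$window[2L]))
    cat(sprintf("  reads: %d (%d aligned)\n", s$total, s$aligned))
    for (nm in names(s$counts))
        cat(sprintf("    %-18s %d\n", nm, s$counts[[nm]]))
    cat(sprintf("  edited fraction: %.4f\n", s$editedFraction))
    if (!is.null(s$correctedFraction))
        cat(sprintf("  background-corrected: %.4f\n", s$correctedFraction))
})
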