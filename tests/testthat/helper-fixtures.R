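suppressPackageStartupMessages({
    library(Biostrings)
    library(S4Vectors)
})

# Plain-R reverse complement, independent of the package internals.
rc_chr <- function(x) {
    vapply(x, function(s) {
        paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1L]]),
              collapse = "")
    }, character(1L), USE.NAMES = FALSE)
}

# Build an assay read by string arithmetic from the documented geometry:
# the sequencer starts in the ligated adapter and reads across the blunted
# fragment, so read = adapter + revcomp(anchor + PAM + protospacer[1..cut]).
makeAssayRead <- function(pam, cutOffset, design = PamLibraryDesign()) {
    proto <- as.character(spacerSeq(design))
    stopifnot(cutOffset <= nchar(proto))
    frag <- paste0(as.character(anchorSeq(design)), pam,
                   substr(proto, 1L, cutOffset))
    paste0(as.character(adapterSeq(design)), rc_chr(frag))
}

# Quality-scaled reads whose per-read mean Phred scores are exactly `meanQ`.
makeQualReads <- function(meanQ, width = 4L) {
    seqs <- DNAStringSet(rep(strrep("A", width), length(meanQ)))
    quals <- PhredQuality(vapply(meanQ, function(q)
        strrep(intToUtf8(q + 33L), width), character(1L)))
    ids <- sprintf("r%d", seq_along(meanQ))
    names(seqs) <- ids
    names(quals) <- ids
    QualityScaledDNAStringSet(seqs, quals)
}

# Brute-force stem-loop oracle: exhaustive substring scan with no regex.
stemLoopOracle <- function(x, stem = "TCTAC", loops = 1:8) {
    rc <- rc_chr(stem)
    k <- nchar(stem)
    hits <- list()
    for (i in seq_len(nchar(x))) {
        if (substr(x, i, i + k - 1L) != stem)
            next
        for (l in loops) {
            j <- i + k + l
            if (j + k - 1L > nchar(x))
                next
            if (substr(x, j, j + k - 1L) == rc)
                hits[[length(hits) + 1L]] <-
                    data.frame(start = i, loop_len = l)
        }
    }
    if (length(hits)) {
        h <- do.call(rbind, hits)
        h[order(h$start, h$loop_len), , drop = FALSE]
    } else {
        data.frame(start = integer(), loop_len = integer())
    }
}

# Random DNA string.
randomDNA <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
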