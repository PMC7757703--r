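#' @include objects.R
NULL

.CANONICAL_STEM <- "TCTAC"
.RARE_STEM <- "CCTGC"

.motifClass <- function(stem5) {
    if (stem5 == .CANONICAL_STEM) "canonical_VA"
    else if (stem5 == .RARE_STEM) "rare"
    else "generic"
}

.emptyHits <- function() {
    DataFrame(start = integer(), stem5 = character(), loop_len = integer(),
              stem3 = character(), end = integer(), motif_class = character())
}

#' Scan a CRISPR direct repeat for the palindromic stem-loop motif
#'
#' Finds occurrences of \code{stem5 + N{loop} + reverse_complement(stem5)}
#' for every loop length in \code{loopRange}.  The canonical Type V-A motif
#' is \code{TCTAC-N(1..8)-GTAGA} (at the RNA level,
#' \code{UCUAC[N]GUAGAU}); a rare variant uses the \code{CCTGC/GCAGG} stem.
#' By default hits are reported leftmost-first and non-overlapping (among
#' candidates at the same start, the shortest loop wins); set
#' \code{overlapping = TRUE} to emit every occurrence.  Mixed-case and
#' U-containing input is normalized to uppercase DNA before scanning.
#'
#' @param x a repeat sequence (character, \code{DNAString} or
#'   \code{RNAString}).
#' @param stem5 5' stem sequence (>= 4 nt; default \code{"TCTAC"}).
#' @param loopRange integer length-2 vector, inclusive loop-length range
#'   (default \code{c(1, 8)}).
#' @param overlapping report all overlapping occurrences.
#'
#' @return a \code{DataFrame} with one row per hit: \code{start} (1-based
#'   position of the stem in the repeat), \code{stem5}, \code{loop_len},
#'   \code{stem3}, \code{end}, \code{motif_class}; zero rows when no hit.
#' @examples
#' scanRepeat("GGTCTACACGTGTAGACC")
#' @export
scanRepeat <- function(x, stem5 = .CANONICAL_STEM, loopRange = c(1L, 8L),
                       overlapping = FALSE) {
    x <- .normalizeDNA(x, "repeat")
    stem5 <- .normalizeDNA(stem5, "stem")
    if (nchar(stem5) < 4L)
        stop("'stem5' must be at least 4 nt")
    loopRange <- as.integer(loopRange)
    stopifnot(length(loopRange) == 2L, loopRange[1L] >= 1L,
              loopRange[2L] >= loopRange[1L])
    stem3 <- .revcomp(stem5)
    hits <- list()
    for (loop in seq(loopRange[1L], loopRange[2L])) {
        # lookahead regex so occurrences sharing a start are all seen
        pat <- sprintf("(?=%s[ACGT]{%d}%s)", stem5, loop, stem3)
        m <- gregexpr(pat, x, perl = TRUE)[[1L]]
        if (m[1L] != -1L)
            hits[[length(hits) + 1L]] <-
                data.frame(start = as.integer(m), loop_len = loop)
    }
    if (!length(hits))
        return(.emptyHits())
    h <- do.call(rbind, hits)
    h <- h[order(h$start, h$loop_len), , drop = FALSE]
    h$end <- h$start + 2L * nchar(stem5) + h$loop_len - 1L
    if (!overlapping) {
        keep <- logical(nrow(h))
        lastEnd <- 0L
        for (i in seq_len(nrow(h))) {
            if (h$start[i] > lastEnd) {
                keep[i] <- TRUE
                lastEnd <- h$end[i]
            }
        }
        h <- h[keep, , drop = FALSE]
    }
    DataFrame(start = h$start, stem5 = stem5, loop_len = h$loop_len,
              stem3 = stem3, end = h$end, motif_class = .motifClass(stem5))
}

#' Classify a CRISPR array from its direct repeats
#'
#' An array is classified \code{VA_canonical} if any repeat contains the
#' canonical \code{TCTAC/GTAGA} stem-loop, otherwise \code{VA_rare} if any
#' repeat contains the rare \code{CCTGC/GCAGG} stem-loop, otherwise
#' \code{unclassified}.  The loop-length histogram summarizes all hits of the
#' motif that determined the classification.
#'
#' @param repeats character vector or \code{DNAStringSet} of direct-repeat
#'   sequences.
#' @param loopRange inclusive loop-length range (default \code{c(1, 8)}).
#'
#' @return list with \code{classification}, \code{loopHistogram} (named
#'   integer vector) and \code{hits} (a \code{DataFrame} with a
#'   \code{repeat_id} column).
#' @examples
#' classifyArray(c(r1 = "ATTTCTACTATTGTAGATTT"))$classification
#' @export
classifyArray <- function(repeats, loopRange = c(1L, 8L)) {
    nms <- names(repeats)
    reps <- as.character(repeats)   # strips names on plain vectors
    names(reps) <- nms
    if (length(reps) == 0L)
        stop("at least one repeat is required")
    if (is.null(names(reps)))
        names(reps) <- sprintf("repeat%d", seq_along(reps))
    scanAll <- function(stem) {
        out <- lapply(names(reps), function(id) {
            h <- scanRepeat(reps[[id]], stem5 = stem, loopRange = loopRange)
            if (nrow(h)) cbind(DataFrame(repeat_id = id), h) else NULL
        })
        out <- out[!vapply(out, is.null, logical(1L))]
        if (length(out)) do.call(rbind, out)
        else cbind(DataFrame(repeat_id = character()), .emptyHits())
    }
    hits <- scanAll(.CANONICAL_STEM)
    classification <- "VA_canonical"
    if (nrow(hits) == 0L) {
        hits <- scanAll(.RARE_STEM)
        classification <- if (nrow(hits)) "VA_rare" else "unclassified"
    }
    hist <- if (nrow(hits)) {
        tab <- table(hits$loop_len)
        setNames(as.integer(tab), names(tab))
    } else {
        setNames(integer(0L), character(0L))
    }
    list(classification = classification, loopHistogram = hist, hits = hits)
}

#' Design the universal single-guide RNA
#'
#' Builds the universal sgRNA for a Type V-A nuclease: the scaffold is the 3'
#' \code{scaffoldLen} nucleotides of the CRISPR direct repeat (transcribed to
#' RNA), followed by the spacer.  With the defaults (20-nt scaffold, 24-nt
#' spacer) the guide is 44 nt.  The stem-loop is predicted within the
#' scaffold and reported (scaffold coordinates).
#'
#' @param repeat_ CRISPR direct-repeat sequence (DNA; >= \code{scaffoldLen}
#'   nt).
#' @param spacer spacer sequence (DNA or RNA; default length 24 enforced via
#'   \code{spacerLen}).
#' @param scaffoldLen number of 3' repeat nucleotides used as scaffold
#'   (default 20).
#' @param spacerLen required spacer length (default 24; set \code{NULL} to
#'   accept any length).
#' @param stem5 stem used for stem-loop prediction within the scaffold.
#'
#' @return an \code{\link{SgRNADesign}}.
#' @examples
#' rep36 <- paste0(strrep("G", 21), "TCTACACGTGTAGAT")
#' designSgRNA(rep36, paste0(strrep("A", 12), strrep("C", 12)))
#' @export
designSgRNA <- function(repeat_, spacer, scaffoldLen = 20L, spacerLen = 24L,
                        stem5 = .CANONICAL_STEM) {
    rep_ <- .normalizeDNA(repeat_, "repeat")
    spc <- .normalizeDNA(spacer, "spacer")
    scaffoldLen <- as.integer(scaffoldLen)
    if (nchar(rep_) < scaffoldLen)
        stop(sprintf("repeat (%d nt) is shorter than the scaffold length (%d)",
                     nchar(rep_), scaffoldLen))
    if (!is.null(spacerLen) && nchar(spc) != spacerLen)
        stop(sprintf("spacer must be %d nt (got %d)", spacerLen, nchar(spc)))
    scaffoldDNA <- substr(rep_, nchar(rep_) - scaffoldLen + 1L, nchar(rep_))
    hits <- scanRepeat(scaffoldDNA, stem5 = stem5)
    toRNA <- function(s) RNAString(chartr("T", "U", s))
    new("SgRNADesign",
        scaffold = toRNA(scaffoldDNA),
        spacer = toRNA(spc),
        fullGuide = toRNA(paste0(scaffoldDNA, spc)),
        stemLoop = hits)
}

#' Generic stem-loop search (any palindromic stem)
#'
#' Extension beyond the two named Type V-A motifs: enumerates every position
#' where a stem of exactly \code{stemLen} bases is followed, after a loop in
#' \code{loopRange}, by its exact reverse complement (no G-U wobble).  Not
#' used for V-A classification.
#'
#' @param x repeat sequence.
#' @param stemLen stem length (>= 4).
#' @param loopRange inclusive loop-length range.
#' @return \code{DataFrame} in the same shape as \code{\link{scanRepeat}}
#'   (all hits, overlapping included, \code{motif_class = "generic"} unless
#'   the stem is a named motif).
#' @export
findStemLoops <- function(x, stemLen = 4L, loopRange = c(1L, 8L)) {
    x <- .normalizeDNA(x, "sequence")
    stemLen <- as.integer(stemLen)
    if (stemLen < 4L)
        stop("'stemLen' must be at least 4")
    n <- nchar(x)
    out <- list()
    for (i in seq_len(max(0L, n - 2L * stemLen - loopRange[1L] + 1L))) {
        stem <- substr(x, i, i + stemLen - 1L)
        rc <- .revcomp(stem)
        for (loop in seq(loopRange[1L], loopRange[2L])) {
            j <- i + stemLen + loop
            if (j + stemLen - 1L > n)
                break
            if (substr(x, j, j + stemLen - 1L) == rc)
                out[[length(out) + 1L]] <-
                    DataFrame(start = i, stem5 = stem, loop_len = loop,
                              stem3 = rc, end = j + stemLen - 1L,
                              motif_class = .motifClass(stem))
        }
    }
    if (length(out)) do.call(rbind, out) else .emptyHits()
}
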