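#' @include objects.R
NULL

#' Locate the predicted cut site in an amplicon
#'
#' The spacer must match the amplicon exactly, on either strand, exactly
#' once.  The cut is placed \code{offset} bases from the 3' end of the spacer
#' match (negative values move back into the protospacer), strand-aware, and
#' is expressed as a between-base coordinate: the number of amplicon bases 5'
#' of the cut.  A spacer occupying 0-based positions 50-73 on the forward
#' strand with the default offset of -4 therefore yields cut coordinate 70.
#' The quantification window covers the cut-adjacent base (the base
#' immediately 5' of the cut) plus \code{window} bases on each side
#' (\code{2 * window + 1} amplicon positions, clipped at the amplicon ends).
#'
#' @param amplicon amplicon reference sequence.
#' @param spacer guide spacer sequence (DNA or RNA).
#' @param offset signed cleavage offset from the 3' end of the spacer match
#'   (default -4).
#' @param window number of bases flanking the predicted cut on each side
#'   (default 10).
#'
#' @return list with \code{cut} (between-base coordinate), \code{strand}
#'   (\code{"+"}/\code{"-"}), \code{window} (1-based first/last amplicon base
#'   of the quantification window), \code{offset} and \code{windowHalf}.
#' @examples
#' amp <- paste0(strrep("A", 50), "GACGCATAAAGATGAGACGCTGGA", strrep("G", 50))
#' locateCut(amp, "GACGCATAAAGATGAGACGCTGGA")$cut
#' @export
locateCut <- function(amplicon, spacer, offset = -4L, window = 10L) {
    amp <- .normalizeDNA(amplicon, "amplicon")
    spc <- .normalizeDNA(spacer, "spacer")
    offset <- as.integer(offset)
    window <- as.integer(window)
    if (window < 1L)
        stop("'window' must be >= 1")
    fwd <- matchPattern(spc, DNAString(amp))
    rev <- matchPattern(.revcomp(spc), DNAString(amp))
    nTotal <- length(fwd) + length(rev)
    if (nTotal == 0L)
        stop("spacer does not match the amplicon on either strand")
    if (nTotal > 1L)
        stop("spacer matches the amplicon more than once")
    if (length(fwd) == 1L) {
        b <- BiocGenerics::end(fwd)[1L]       # 1-based last base of match
        cut <- b + offset                     # between-base coordinate
        strand <- "+"
    } else {
        a <- BiocGenerics::start(rev)[1L]     # spacer 3' end maps here
        cut <- (a - 1L) - offset
        strand <- "-"
    }
    if (cut < 1L || cut > nchar(amp) - 1L)
        stop("predicted cut falls outside the amplicon")
    win <- c(max(1L, cut - window), min(nchar(amp), cut + window))
    list(cut = cut, strand = strand, window = win,
         offset = offset, windowHalf = window)
}

# Decompose one global alignment (gapped pattern/subject strings) into
# events.  Insertions are recorded at a between-base reference coordinate
# (refStart == refEnd == number of reference bases 5' of the insertion);
# deletion and substitution events span reference bases [refStart, refEnd].
# Consecutive mismatch columns merge into a single substitution event.
.alignmentEvents <- function(patChar, subChar) {
    p <- strsplit(patChar, "", fixed = TRUE)[[1L]]
    s <- strsplit(subChar, "", fixed = TRUE)[[1L]]
    refpos <- cumsum(s != "-")
    state <- ifelse(p == "-", "deletion",
             ifelse(s == "-", "insertion",
             ifelse(p != s, "substitution", "match")))
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != "match"
    if (!any(keep))
        return(data.frame(type = character(), size = integer(),
                          refStart = integer(), refEnd = integer()))
    data.frame(
        type = r$values[keep],
        size = r$lengths[keep],
        refStart = ifelse(r$values[keep] == "insertion",
                          refpos[starts[keep]], refpos[starts[keep]]),
        refEnd = refpos[ends[keep]])
}

.eventOverlapsWindow <- function(ev, win) {
    if (ev$type == "insertion")
        ev$refStart >= win[1L] - 1L && ev$refStart <= win[2L]
    else
        ev$refStart <= win[2L] && ev$refEnd >= win[1L]
}

#' Classify amplicon reads into editing-outcome categories
#'
#' Each read is aligned globally to the amplicon with affine gap penalties
#' (defaults: match 2, mismatch -4, gap open 10, gap extend 1); the better of
#' the forward and reverse-complement alignments is kept, so classification
#' is reverse-complement invariant.  Alignment events (insertions, deletions,
#' and runs of consecutive substitutions, sized by run length) overlapping
#' the quantification window are collected, and the read is categorized by
#' the largest overlapping event: none -> \code{unedited}, 1 bp ->
#' \code{small_indel_or_mut}, >= 2 bp -> \code{large_event}.  Reads whose
#' best alignment scores below \code{minScoreFrac} of the perfect-match score
#' are \code{unaligned}.
#'
#' @param reads \code{DNAStringSet}, \code{QualityScaledDNAStringSet},
#'   character vector, or FASTQ path.
#' @param amplicon amplicon reference sequence.
#' @param cutWindow result of \code{\link{locateCut}} (or an integer vector
#'   \code{c(first, last)} of window bases).
#' @param match,mismatch,gapOpening,gapExtension alignment parameters.
#' @param minScoreFrac unaligned threshold as a fraction of each read's
#'   perfect-match score (default 0.5).
#'
#' @return \code{DataFrame}: \code{read_id}, \code{category}, \code{strand},
#'   \code{score}, \code{largest_event}, \code{n_events} (events overlapping
#'   the window), \code{events} (compact text description).
#' @export
classifyReads <- function(reads, amplicon, cutWindow,
                          match = 2, mismatch = -4,
                          gapOpening = 10, gapExtension = 1,
                          minScoreFrac = 0.5) {
    if (is.character(reads) && length(reads) == 1L && file.exists(reads))
        reads <- readQualityScaledDNAStringSet(reads)
    seqs <- suppressWarnings(DNAStringSet(reads))
    if (is.null(names(seqs)))
        names(seqs) <- sprintf("read%0*d", nchar(length(seqs)),
                               seq_along(seqs))
    win <- if (is.list(cutWindow)) cutWindow$window else as.integer(cutWindow)
    amp <- DNAString(.normalizeDNA(amplicon, "amplicon"))
    mat <- nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                        baseOnly = TRUE)
    alnF <- pairwiseAlignment(seqs, amp, type = "global",
                              substitutionMatrix = mat,
                              gapOpening = gapOpening,
                              gapExtension = gapExtension)
    alnR <- pairwiseAlignment(reverseComplement(seqs), amp, type = "global",
                              substitutionMatrix = mat,
                              gapOpening = gapOpening,
                              gapExtension = gapExtension)
    useR <- score(alnR) > score(alnF)
    bestScore <- ifelse(useR, score(alnR), score(alnF))
    minScore <- minScoreFrac * match * width(seqs)
    patF <- as.character(pattern(alnF)); subF <- as.character(subject(alnF))
    patR <- as.character(pattern(alnR)); subR <- as.character(subject(alnR))

    n <- length(seqs)
    category <- character(n)
    largest <- integer(n)
    nEvents <- integer(n)
    evText <- character(n)
    for (i in seq_len(n)) {
        if (bestScore[i] < minScore[i]) {
            category[i] <- "unaligned"
            largest[i] <- NA_integer_
            nEvents[i] <- NA_integer_
            evText[i] <- ""
            next
        }
        ev <- if (useR[i]) .alignmentEvents(patR[i], subR[i])
              else .alignmentEvents(patF[i], subF[i])
        inWin <- logical(nrow(ev))
        for (j in seq_len(nrow(ev)))
            inWin[j] <- .eventOverlapsWindow(ev[j, ], win)
        ev <- ev[inWin, , drop = FALSE]
        nEvents[i] <- nrow(ev)
        largest[i] <- if (nrow(ev)) max(ev$size) else 0L
        category[i] <- if (nrow(ev) == 0L) "unedited"
                       else if (max(ev$size) == 1L) "small_indel_or_mut"
                       else "large_event"
        evText[i] <- if (nrow(ev))
            paste(sprintf("%s:%d@%d", substr(ev$type, 1L, 3L), ev$size,
                          ev$refStart), collapse = ",")
            else ""
    }
    DataFrame(read_id = names(seqs), category = category,
              strand = ifelse(useR, "-", "+"), score = bestScore,
              largest_event = largest, n_events = nEvents, events = evText)
}

#' Editing frequency from outcome classifications
#'
#' Editing frequency is the fraction of aligned reads classified as edited
#' (\code{small_indel_or_mut} + \code{large_event}); unaligned reads are
#' excluded from the denominator.  When a mock/control edited fraction (or
#' control classification table) is supplied, the background-corrected
#' frequency \code{max(0, edited - control)} is also reported.
#'
#' @param classifications \code{DataFrame} from \code{\link{classifyReads}}
#'   (or a character vector of categories).
#' @param control optional numeric control edited fraction, or a control
#'   classification table.
#'
#' @return list: \code{counts} (per category), \code{total}, \code{aligned},
#'   \code{editedFraction}, and \code{correctedFraction} when a control was
#'   given.
#' @export
editingFrequency <- function(classifications, control = NULL) {
    cats <- if (is.character(classifications)) classifications
            else classifications$category
    if (length(cats) == 0L)
        stop("no classifications supplied")
    levels <- c("unedited", "small_indel_or_mut", "large_event", "unaligned")
    if (!all(cats %in% levels))
        stop("unknown outcome category")
    counts <- table(factor(cats, levels = levels))
    aligned <- sum(counts[c("unedited", "small_indel_or_mut", "large_event")])
    if (aligned == 0L)
        stop("no read aligned to the amplicon")
    edited <- sum(counts[c("small_indel_or_mut", "large_event")]) / aligned
    out <- list(counts = setNames(as.integer(counts), levels),
                total = length(cats), aligned = as.integer(aligned),
                editedFraction = edited)
    if (!is.null(control)) {
        ctrl <- if (is.numeric(control)) control
                else editingFrequency(control)$editedFraction
        out$correctedFraction <- max(0, edited - ctrl)
    }
    out
}

#' Quantify editing outcomes at a target site
#'
#' End-to-end amplicon quantification: locates the predicted cut from the
#' spacer match (\code{offset} bases from the spacer 3' end, default -4),
#' classifies every read within the \code{window}-base quantification window
#' and summarizes editing frequency, optionally background corrected against
#' mock-control reads.  Note: the -4 offset convention is inherited from the
#' quantification tool this re-implements and is unusual for a Cas12a-style
#' nuclease (which cuts PAM-distal); it is applied verbatim and recorded in
#' the result parameters.
#'
#' @param reads treated amplicon reads (\code{DNAStringSet}, character, or
#'   FASTQ path).
#' @param amplicon amplicon reference.
#' @param spacer guide spacer.
#' @param offset cleavage offset (default -4).
#' @param window window half-width in bases (default 10).
#' @param control optional mock-control reads (same forms as \code{reads}) or
#'   a numeric control edited fraction.
#' @param ... alignment parameters passed to \code{\link{classifyReads}}.
#'
#' @return an \code{\link{EditQuantResult}}.
#' @examples
#' amp <- paste0(strrep("ACGT", 20), "GACGCATAAAGATGAGACGCTGGA",
#'               strrep("TGCA", 20))
#' res <- quantifyEditing(c(r1 = amp), amp, "GACGCATAAAGATGAGACGCTGGA")
#' res@summary$editedFraction
#' @export
quantifyEditing <- function(reads, amplicon, spacer, offset = -4L,
                            window = 10L, control = NULL, ...) {
    cut <- locateCut(amplicon, spacer, offset = offset, window = window)
    cls <- classifyReads(reads, amplicon, cut, ...)
    ctrl <- NULL
    if (!is.null(control)) {
        ctrl <- if (is.numeric(control)) control
                else editingFrequency(classifyReads(control, amplicon, cut,
                                                    ...))$editedFraction
    }
    summ <- editingFrequency(cls, control = ctrl)
    new("EditQuantResult", classifications = cls, summary = summ, cut = cut,
        parameters = list(offset = offset, window = window,
                          offset_convention = paste(
                              "offset counted from the spacer 3' end;",
                              "-4 replicates the upstream tool's convention")))
}
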