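#' @include simlib.R
NULL

.asQualityReads <- function(x) {
    if (is(x, "CleavageReadSet"))
        x@reads
    else if (is(x, "QualityScaledDNAStringSet"))
        x
    else if (is.character(x) && length(x) == 1L && file.exists(x))
        readQualityScaledDNAStringSet(x)
    else
        stop("expected a CleavageReadSet, QualityScaledDNAStringSet or FASTQ path")
}

#' Filter reads by mean Phred quality
#'
#' A read passes when its mean per-base Phred score is strictly greater than
#' the threshold (default 20).  The mean-per-read interpretation keeps
#' anchor/adapter exact matching intact (no within-read trimming).
#'
#' @param x a \code{\link{CleavageReadSet}}, a
#'   \code{QualityScaledDNAStringSet}, or a FASTQ path.
#' @param threshold Phred threshold (default 20, strict inequality).
#'
#' @return list with \code{reads} (the passing
#'   \code{QualityScaledDNAStringSet}) and \code{report} (kept/removed counts
#'   and the threshold).
#' @examples
#' rs <- simulateAssay(PamLibraryDesign(), NucleaseModel(), 2000, seed = 1)
#' qualityFilter(rs)$report
#' @export
qualityFilter <- function(x, threshold = 20) {
    reads <- .asQualityReads(x)
    if (length(reads) == 0L)
        stop("no reads supplied")
    meanQ <- BiocGenerics::mean(as(quality(reads), "IntegerList"))
    keep <- meanQ > threshold
    list(reads = reads[keep],
         report = list(kept = sum(keep), removed = sum(!keep),
                       threshold = threshold))
}

# Locate a pattern in each sequence; returns list(n = match count vector,
# start = first-match start vector).
.exactHits <- function(pattern, seqs) {
    m <- vmatchPattern(pattern, seqs, fixed = TRUE)
    st <- startIndex(m)
    list(n = elementNROWS(m),
         start = vapply(st, function(s) if (length(s)) s[[1L]] else NA_integer_,
                        integer(1L)))
}

#' Anchor reads and extract PAM observations
#'
#' Implements the extraction procedure of the cleavage assay: the constant
#' 28-bp backbone anchor is located in each read by exact substring match
#' (forward first, then the reverse-complement presentation), the
#' \code{randomizedLen} bases immediately adjacent on the PAM side are taken
#' as the putative PAM, the adapter is located by exact match, and the cut
#' offset is the number of protospacer bases between the end of the PAM and
#' the blunt-end/adapter junction (first protospacer base = offset 1).  Reads
#' lacking an exact anchor or adapter match are excluded with a categorized
#' reason: \code{no_anchor}, \code{ambiguous_anchor}, \code{no_adapter},
#' \code{ambiguous_adapter}, or \code{bad_geometry} (junction inside the PAM
#' or anchor, as happens for background cuts upstream of the protospacer).
#'
#' @param reads a \code{QualityScaledDNAStringSet}, \code{DNAStringSet},
#'   \code{\link{CleavageReadSet}} or character vector of read sequences.
#' @param design the \code{\link{PamLibraryDesign}} providing anchor, adapter
#'   and randomized width.
#' @param adapter adapter override (defaults to the design's adapter).
#'
#' @return list with \code{observations} (a \code{DataFrame}:
#'   \code{read_id}, \code{pam}, \code{cut_offset}, \code{orientation}) and
#'   \code{exclusions} (a \code{DataFrame}: \code{read_id}, \code{reason}).
#' @export
anchorReads <- function(reads, design, adapter = adapterSeq(design)) {
    stopifnot(is(design, "PamLibraryDesign"))
    if (is(reads, "CleavageReadSet"))
        reads <- reads@reads
    seqs <- suppressWarnings(DNAStringSet(reads))  # drops qualities, keeps names
    if (is.null(names(seqs)))
        names(seqs) <- sprintf("read%0*d", nchar(length(seqs)),
                               seq_along(seqs))
    anchor <- anchorSeq(design)
    L <- randomizedLen(design)
    anchorLen <- length(anchor)
    adapterRC <- reverseComplement(DNAString(as.character(adapter)))

    fwd <- .exactHits(anchor, seqs)
    rev <- .exactHits(reverseComplement(anchor), seqs)
    nAnchor <- fwd$n + rev$n

    reason <- rep(NA_character_, length(seqs))
    reason[nAnchor == 0L] <- "no_anchor"
    reason[nAnchor > 1L] <- "ambiguous_anchor"

    ok <- which(is.na(reason))
    # canonical orientation: anchor reads forward (anchor -> PAM -> cut)
    canon <- seqs[ok]
    flip <- rev$n[ok] == 1L
    if (any(flip))
        canon[flip] <- reverseComplement(canon[flip])
    aStart <- ifelse(flip,
                     width(seqs[ok]) - (rev$start[ok] + anchorLen - 1L) + 1L,
                     fwd$start[ok])
    # adapter appears reverse-complemented in canonical orientation
    ad <- .exactHits(adapterRC, canon)
    r2 <- rep(NA_character_, length(ok))
    r2[ad$n == 0L] <- "no_adapter"
    r2[ad$n > 1L] <- "ambiguous_adapter"
    pamEnd <- aStart + anchorLen + L - 1L
    cutOffset <- ad$start - pamEnd - 1L
    r2[is.na(r2) & cutOffset < 1L] <- "bad_geometry"
    reason[ok] <- r2

    good <- ok[is.na(r2)]
    goodLocal <- which(is.na(r2))
    pam <- substr(as.character(canon[goodLocal]),
                  aStart[goodLocal] + anchorLen,
                  pamEnd[goodLocal])
    obs <- DataFrame(read_id = names(seqs)[good],
                     pam = unname(pam),
                     cut_offset = unname(cutOffset[goodLocal]),
                     orientation = ifelse(flip[goodLocal],
                                          "reverse", "forward"))
    excl <- DataFrame(read_id = names(seqs)[!is.na(reason)],
                      reason = reason[!is.na(reason)])
    list(observations = obs, exclusions = excl)
}

#' Filter observations by cut-site frequency
#'
#' Computes the modal cut offset over all anchored observations (ties broken
#' toward the smaller offset) and retains only observations whose offset lies
#' within \code{[modal - halfWidth, modal + halfWidth]}.  This removes the
#' low level of background cleavage occurring at random positions.
#'
#' @param observations \code{DataFrame} from \code{\link{anchorReads}} (needs
#'   a \code{cut_offset} column).
#' @param halfWidth window half-width (default 2, i.e. modal +/- 2).
#'
#' @return list with \code{retained} (filtered observations),
#'   \code{distribution} (a \code{\link{CutSiteDistribution}}) and
#'   \code{fractionFiltered}.
#' @export
cutSiteFilter <- function(observations, halfWidth = 2L) {
    off <- observations$cut_offset
    if (is.null(off) || length(off) == 0L)
        stop("no observations to filter")
    halfWidth <- as.integer(halfWidth)
    tab <- table(off)
    counts <- setNames(as.integer(tab), names(tab))
    offs <- as.integer(names(counts))
    modal <- min(offs[counts == max(counts)])   # tie -> smaller offset
    dist <- new("CutSiteDistribution", counts = counts,
                modal = as.integer(modal), halfWidth = halfWidth)
    keep <- off >= modal - halfWidth & off <= modal + halfWidth
    list(retained = observations[keep, , drop = FALSE],
         distribution = dist,
         fractionFiltered = sum(!keep) / length(keep))
}

#' Infer the target-strand cut site
#'
#' The cut site is the modal blunt-end offset, in PAM-distal protospacer
#' bases (1-based from the first protospacer base); ties are broken toward
#' the smaller offset.
#'
#' @param distribution a \code{\link{CutSiteDistribution}} (or the list
#'   returned by \code{\link{cutSiteFilter}}).
#' @return integer modal offset.
#' @export
inferCutSite <- function(distribution) {
    if (is.list(distribution) && !is.null(distribution$distribution))
        distribution <- distribution$distribution
    stopifnot(is(distribution, "CutSiteDistribution"))
    distribution@modal
}

.entropyBits <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
}

#' Build a positional PAM profile
#'
#' Tallies per-position base counts over the retained PAMs, converts to
#' column-stochastic frequencies, optionally normalizes by the input-library
#' base composition (frequency ratio, renormalized per column), and computes
#' per-position information content \code{2 - H} in bits.
#'
#' @param observations retained observations (\code{DataFrame} with a
#'   \code{pam} column), a character vector of PAMs, or the list returned by
#'   \code{\link{cutSiteFilter}}.
#' @param background optional 4 x L matrix of input-library base frequencies
#'   (rows A,C,G,T) used for normalization; off by default.
#' @param includeThreshold consensus inclusion threshold passed to
#'   \code{\link{callConsensus}} for the profile's stored consensus.
#' @param fractionFiltered optionally recorded cut-site-filter loss.
#'
#' @return a \code{\link{PamProfile}}.
#' @export
buildProfile <- function(observations, background = NULL,
                         includeThreshold = 0.15,
                         fractionFiltered = NA_real_) {
    if (is.list(observations) && !is.null(observations$retained)) {
        if (is.na(fractionFiltered))
            fractionFiltered <- observations$fractionFiltered
        observations <- observations$retained
    }
    pams <- if (is.character(observations)) observations
            else observations$pam
    if (is.null(pams) || length(pams) == 0L)
        stop("no retained PAMs to profile")
    cm <- consensusMatrix(DNAStringSet(pams))
    counts <- matrix(0L, nrow = 4L, ncol = ncol(cm),
                     dimnames = list(.DNA_BASES, NULL))
    for (b in .DNA_BASES)
        if (b %in% rownames(cm)) counts[b, ] <- cm[b, ]
    freqs <- sweep(counts, 2L, colSums(counts), "/")
    if (!is.null(background)) {
        stopifnot(is.matrix(background), nrow(background) == 4L,
                  ncol(background) == ncol(freqs))
        if (is.null(rownames(background)))
            rownames(background) <- .DNA_BASES
        freqs <- freqs / background[.DNA_BASES, ]
        freqs <- sweep(freqs, 2L, colSums(freqs), "/")
    }
    info <- 2 - apply(freqs, 2L, .entropyBits)
    prof <- new("PamProfile", counts = counts, freqs = freqs,
                infoBits = pmin(pmax(info, 0), 2),
                consensus = "N", nRetained = length(pams),
                fractionFiltered = as.numeric(fractionFiltered))
    prof@consensus <- callConsensus(prof, includeThreshold)
    prof
}

#' Call an IUPAC consensus motif from a PAM profile
#'
#' Each position is coded by the smallest IUPAC letter covering all bases
#' whose frequency is at or above \code{includeThreshold}; positions coded N
#' are then trimmed from the PAM-distal (left) side so the minimal
#' informative motif is reported (e.g. \code{TTTV}, \code{TTN}, \code{YYN}).
#' The threshold must be below 0.25 for unconstrained positions to be coded N
#' (empirical frequencies of a uniform position scatter around 0.25 and sum
#' to 1, so at 0.25 and above some base always falls short).
#'
#' @param profile a \code{\link{PamProfile}} (or bare 4 x L frequency
#'   matrix).
#' @param includeThreshold minimum frequency for a base to enter the code
#'   (default 0.15).
#' @return IUPAC consensus string.
#' @examples
#' m <- matrix(c(.485, .485, .015, .015), 4, dimnames = list(c("C","T","A","G")))
#' callConsensus(m[c("A","C","G","T"), , drop = FALSE])
#' @export
callConsensus <- function(profile, includeThreshold = 0.15) {
    freqs <- if (is(profile, "PamProfile")) profile@freqs else profile
    stopifnot(is.matrix(freqs), nrow(freqs) == 4L)
    if (is.null(rownames(freqs)))
        rownames(freqs) <- .DNA_BASES
    codes <- vapply(seq_len(ncol(freqs)), function(i) {
        bases <- rownames(freqs)[freqs[, i] >= includeThreshold]
        if (!length(bases))   # defensive; cannot occur for threshold <= 0.25
            bases <- rownames(freqs)[which.max(freqs[, i])]
        mergeIUPACLetters(paste(sort(bases), collapse = ""))
    }, character(1L))
    motif <- sub("^N+", "", paste(codes, collapse = ""))
    if (motif == "") "N" else motif
}

#' Run the full PAM-calling pipeline
#'
#' Quality filtering (mean Phred > threshold), exact anchoring and PAM/cut
#' extraction, cut-site frequency filtering (modal +/- halfWidth), profile
#' construction and consensus/cut-site calling, with complete read
#' accounting: every input read lands in exactly one bucket
#' (\code{quality_failed}, an anchoring exclusion reason,
#' \code{cutsite_filtered}, or \code{retained}).
#'
#' @param x reads: a \code{\link{CleavageReadSet}},
#'   \code{QualityScaledDNAStringSet} or FASTQ path.
#' @param design the \code{\link{PamLibraryDesign}}; defaults to the one
#'   carried by a \code{CleavageReadSet}.
#' @param qThreshold mean-Phred threshold (default 20, strict).
#' @param halfWidth cut-site window half-width (default 2).
#' @param includeThreshold consensus inclusion threshold (default 0.15).
#' @param background optional input-library base composition for profile
#'   normalization.
#'
#' @return a \code{\link{PamCallResult}}.
#' @examples
#' rs <- simulateAssay(PamLibraryDesign(), NucleaseModel("TTV"), 20000,
#'                     seed = 7)
#' res <- callPam(rs)
#' pamConsensus(res); cutSite(res)
#' @export
callPam <- function(x, design = NULL, qThreshold = 20, halfWidth = 2L,
                    includeThreshold = 0.15, background = NULL) {
    if (is(x, "CleavageReadSet") && is.null(design))
        design <- x@design
    if (is.null(design))
        stop("a 'design' is required")
    reads <- .asQualityReads(x)
    nInput <- length(reads)
    qf <- qualityFilter(reads, qThreshold)
    anch <- anchorReads(qf$reads, design)
    if (nrow(anch$observations) == 0L)
        stop("no read could be anchored; check design anchor/adapter")
    cs <- cutSiteFilter(anch$observations, halfWidth)
    prof <- buildProfile(cs$retained, background = background,
                         includeThreshold = includeThreshold,
                         fractionFiltered = cs$fractionFiltered)
    reasons <- c("no_anchor", "ambiguous_anchor", "no_adapter",
                 "ambiguous_adapter", "bad_geometry")
    exclTab <- table(factor(anch$exclusions$reason, levels = reasons))
    accounting <- c(input = nInput,
                    quality_failed = qf$report$removed,
                    setNames(as.integer(exclTab), reasons),
                    cutsite_filtered =
                        nrow(anch$observations) - nrow(cs$retained),
                    retained = nrow(cs$retained))
    new("PamCallResult",
        observations = cs$retained,
        distribution = cs$distribution,
        profile = prof,
        consensus = prof@consensus,
        cutSite = inferCutSite(cs$distribution),
        accounting = accounting,
        parameters = list(qThreshold = qThreshold, halfWidth = halfWidth,
                          includeThreshold = includeThreshold,
                          backgroundNormalized = !is.null(background)))
}

#' Write PAM-calling outputs
#'
#' Writes the retained-PAM table, cut-site histogram and profile matrix as
#' TSV, plus a JSON run report (all accounting buckets, fraction filtered,
#' consensus, cut site and coordinate convention).
#'
#' @param result a \code{\link{PamCallResult}}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
writePamCallOutputs <- function(result, dir, prefix = "pamcall") {
    stopifnot(is(result, "PamCallResult"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(suffix) file.path(dir, paste0(prefix, suffix))
    write.table(as.data.frame(result@observations), p("_retained.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    d <- result@distribution
    write.table(data.frame(cut_offset = as.integer(names(d@counts)),
                           count = d@counts),
                p("_cutsites.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    prof <- cbind(base = .DNA_BASES, as.data.frame(result@profile@freqs))
    write.table(prof, p("_profile.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    report <- list(
        accounting = as.list(result@accounting),
        fraction_filtered = result@profile@fractionFiltered,
        consensus = result@consensus,
        cut_site = result@cutSite,
        coordinate_convention = paste(
            "cut offsets are 1-based PAM-distal protospacer positions;",
            "the blunt end lies after the reported base"),
        parameters = result@parameters)
    jsonlite::write_json(report, p("_report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(c(p("_retained.tsv"), p("_cutsites.tsv"), p("_profile.tsv"),
                p("_report.json")))
}
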