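#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
NULL

.DNA_BASES <- c("A", "C", "G", "T")

.validDNA <- function(x) grepl("^[ACGT]+$", x)

#' Layout of the randomized-PAM plasmid library
#'
#' Describes the shared geometry of the cleavage-assay library: a constant
#' backbone anchor (28 bp by default) immediately 5' of a fully randomized
#' region (8 bases by default, the candidate PAM), followed by the constant
#' protospacer targeted by the guide, and optional constant downstream
#' context.  The adapter is the double-stranded sequence ligated onto blunted
#' cleavage products before sequencing.  Both the simulator and the PAM
#' caller work from the same design object, so recovered coordinates are
#' directly comparable to simulated ground truth.
#'
#' @slot anchor \code{DNAString}, the constant backbone sequence adjacent to
#'   the randomized region (default 28 bp).
#' @slot randomizedLen integer, number of fully randomized bases (default 8).
#' @slot spacer \code{DNAString}, the constant protospacer (default 24 bp).
#' @slot adapter \code{DNAString}, the sequencing adapter ligated at the
#'   blunted cut.
#' @slot downstream \code{DNAString}, constant context 3' of the protospacer.
#'
#' @seealso \code{\link{PamLibraryDesign}} for the constructor.
#' @exportClass PamLibraryDesign
setClass("PamLibraryDesign",
    slots = c(
        anchor = "DNAString",
        randomizedLen = "integer",
        spacer = "DNAString",
        adapter = "DNAString",
        downstream = "DNAString"
    )
)

setValidity("PamLibraryDesign", function(object) {
    msg <- character()
    for (nm in c("anchor", "spacer", "adapter", "downstream")) {
        s <- as.character(slot(object, nm))
        if (nm != "downstream" && nchar(s) == 0L)
            msg <- c(msg, sprintf("'%s' must be non-empty", nm))
        if (nchar(s) > 0L && !.validDNA(s))
            msg <- c(msg, sprintf("'%s' must contain only A/C/G/T", nm))
    }
    if (length(object@randomizedLen) != 1L || is.na(object@randomizedLen) ||
        object@randomizedLen < 1L)
        msg <- c(msg, "'randomizedLen' must be a single integer >= 1")
    if (length(msg)) msg else TRUE
})

#' Generative model of a PAM-dependent nuclease
#'
#' Encodes how a nuclease acts on the randomized library: a per-position
#' base-probability matrix over the randomized region (the PAM preference),
#' the maximum cleavage probability attained by the best-matching PAM, the
#' target-strand cut position (counted in PAM-distal protospacer bases,
#' 1-based; 22 for the nucleases this package models), the stagger between
#' target- and non-target-strand cuts, a background rate of cleavage at
#' uniformly random positions (emulating crude-lysate nuclease activity), and
#' a substitution sequencing-error rate.
#'
#' The probability that a molecule with randomized 8-mer \eqn{p} is cleaved is
#' \deqn{P(cleave | p) = maxCleavageProb \prod_i W[p_i, i] / \max_q \prod_i W[q_i, i]}
#' i.e. the PWM likelihood rescaled so the best PAM cleaves with probability
#' \code{maxCleavageProb}.
#'
#' @slot pamPWM 4 x L numeric matrix, rows A/C/G/T, columns summing to 1.
#'   Column 1 is the PAM-distal end of the randomized region; column L is the
#'   base adjacent to the protospacer.
#' @slot maxCleavageProb numeric in (0, 1], cleavage probability of the best
#'   PAM.
#' @slot cutSite integer >= 1, target-strand cut position in PAM-distal
#'   protospacer bases.
#' @slot stagger integer >= 0, offset of the non-target-strand cut.
#' @slot backgroundRate numeric in [0, 1], fraction of cleavage events placed
#'   at a uniformly random position.
#' @slot errorRate numeric in [0, 1], per-base substitution error rate.
#'
#' @seealso \code{\link{NucleaseModel}}, \code{\link{pwmFromIUPAC}}
#' @exportClass NucleaseModel
setClass("NucleaseModel",
    slots = c(
        pamPWM = "matrix",
        maxCleavageProb = "numeric",
        cutSite = "integer",
        stagger = "integer",
        backgroundRate = "numeric",
        errorRate = "numeric"
    )
)

setValidity("NucleaseModel", function(object) {
    msg <- character()
    W <- object@pamPWM
    if (!is.numeric(W) || nrow(W) != 4L ||
        !identical(rownames(W), .DNA_BASES))
        msg <- c(msg, "'pamPWM' must be a 4 x L numeric matrix with rows A,C,G,T")
    else if (any(W < 0) || any(abs(colSums(W) - 1) > 1e-6))
        msg <- c(msg, "'pamPWM' columns must be non-negative and sum to 1")
    if (object@maxCleavageProb <= 0 || object@maxCleavageProb > 1)
        msg <- c(msg, "'maxCleavageProb' must be in (0, 1]")
    if (object@cutSite < 1L)
        msg <- c(msg, "'cutSite' must be >= 1")
    if (object@stagger < 0L)
        msg <- c(msg, "'stagger' must be >= 0")
    if (object@backgroundRate < 0 || object@backgroundRate > 1)
        msg <- c(msg, "'backgroundRate' must be in [0, 1]")
    if (object@errorRate < 0 || object@errorRate > 1)
        msg <- c(msg, "'errorRate' must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Simulated cleavage-assay reads with per-read ground truth
#'
#' Container for reads produced by \code{\link{simulateCleavageReads}}:
#' quality-scaled sequences plus a hidden truth table (true PAM 8-mer, true
#' cut offset in PAM-distal protospacer bases, background flag) keyed by read
#' id, together with the library design and molecule accounting needed for
#' round-trip validation.
#'
#' @slot reads \code{QualityScaledDNAStringSet} of simulated reads.
#' @slot truth \code{DataFrame} with columns \code{read_id}, \code{true_pam},
#'   \code{true_cut}, \code{background}; one row per read.
#' @slot design the \code{PamLibraryDesign} the reads were simulated from.
#' @slot nMolecules integer, number of library molecules exposed to cleavage.
#'
#' @exportClass CleavageReadSet
setClass("CleavageReadSet",
    slots = c(
        reads = "QualityScaledDNAStringSet",
        truth = "DataFrame",
        design = "PamLibraryDesign",
        nMolecules = "integer"
    )
)

setValidity("CleavageReadSet", function(object) {
    msg <- character()
    tr <- object@truth
    need <- c("read_id", "true_pam", "true_cut", "background")
    if (!all(need %in% colnames(tr)))
        msg <- c(msg, sprintf("truth must have columns %s",
                              paste(need, collapse = ", ")))
    else if (nrow(tr) != length(object@reads) ||
             !setequal(tr$read_id, names(object@reads)))
        msg <- c(msg, "truth table must cover exactly the read ids")
    if (length(object@reads) &&
        !all(width(object@reads) == width(Biostrings::quality(object@reads))))
        msg <- c(msg, "sequence and quality widths must agree")
    if (object@nMolecules < length(object@reads))
        msg <- c(msg, "'nMolecules' cannot be smaller than the read count")
    if (length(msg)) msg else TRUE
})

#' Distribution of observed cut-site offsets
#'
#' Histogram of blunt-end offsets (PAM-distal protospacer bases, 1-based)
#' across anchored reads, the modal offset (ties broken toward the smaller
#' offset), and the retained window \code{[modal - halfWidth, modal + halfWidth]}
#' used by the cut-site frequency filter.
#'
#' @slot counts named integer vector; names are offsets, values are read
#'   counts.
#' @slot modal integer, modal offset.
#' @slot halfWidth integer, window half-width (2 by default).
#'
#' @exportClass CutSiteDistribution
setClass("CutSiteDistribution",
    slots = c(counts = "integer", modal = "integer", halfWidth = "integer")
)

setValidity("CutSiteDistribution", function(object) {
    msg <- character()
    if (is.null(names(object@counts)) || any(object@counts < 0L))
        msg <- c(msg, "'counts' must be a named non-negative integer vector")
    else {
        off <- as.integer(names(object@counts))
        mx <- max(object@counts)
        winners <- off[object@counts == mx]
        if (!(object@modal %in% winners) || object@modal != min(winners))
            msg <- c(msg, "'modal' must be the smallest offset attaining the maximal count")
    }
    if (object@halfWidth < 0L)
        msg <- c(msg, "'halfWidth' must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Positional PAM profile
#'
#' Per-position base counts, frequencies and information content over the
#' retained PAM 8-mers, plus the IUPAC consensus called at the default
#' inclusion threshold.  Position 1 is the PAM-distal end of the randomized
#' region; the last position abuts the protospacer.
#'
#' @slot counts 4 x L integer matrix of base counts (rows A/C/G/T).
#' @slot freqs 4 x L column-stochastic frequency matrix (background
#'   normalized when a background composition was supplied).
#' @slot infoBits length-L numeric vector, \code{2 - H(column)} in bits.
#' @slot consensus IUPAC consensus string (distal N positions trimmed).
#' @slot nRetained integer, number of PAMs profiled.
#' @slot fractionFiltered numeric, fraction of anchored reads removed by the
#'   cut-site frequency filter (NA when the profile was built directly).
#'
#' @exportClass PamProfile
setClass("PamProfile",
    slots = c(
        counts = "matrix",
        freqs = "matrix",
        infoBits = "numeric",
        consensus = "character",
        nRetained = "integer",
        fractionFiltered = "numeric"
    )
)

setValidity("PamProfile", function(object) {
    msg <- character()
    if (!identical(rownames(object@counts), .DNA_BASES) ||
        !identical(rownames(object@freqs), .DNA_BASES))
        msg <- c(msg, "count/frequency matrices must have rows A,C,G,T")
    if (ncol(object@counts) != ncol(object@freqs) ||
        length(object@infoBits) != ncol(object@freqs))
        msg <- c(msg, "matrix widths and infoBits length must agree")
    if (ncol(object@freqs) && any(abs(colSums(object@freqs) - 1) > 1e-9))
        msg <- c(msg, "frequency columns must sum to 1")
    if (any(object@infoBits < -1e-9 | object@infoBits > 2 + 1e-9))
        msg <- c(msg, "information content must lie in [0, 2] bits")
    if (length(msg)) msg else TRUE
})

#' Result of the full PAM-calling pipeline
#'
#' Bundles everything \code{\link{callPam}} computes: retained observations,
#' the cut-site distribution, the PAM profile, the called consensus and cut
#' site, and complete read accounting (every input read is assigned to
#' exactly one bucket).
#'
#' @slot observations \code{DataFrame} of retained observations
#'   (\code{read_id}, \code{pam}, \code{cut_offset}).
#' @slot distribution \code{CutSiteDistribution} over all anchored reads.
#' @slot profile \code{PamProfile} over retained PAMs.
#' @slot consensus called IUPAC consensus string.
#' @slot cutSite inferred modal cut offset.
#' @slot accounting named integer vector: \code{input}, \code{quality_failed},
#'   anchoring exclusion reasons, \code{cutsite_filtered}, \code{retained}.
#' @slot parameters list of pipeline parameters used.
#'
#' @exportClass PamCallResult
setClass("PamCallResult",
    slots = c(
        observations = "DataFrame",
        distribution = "CutSiteDistribution",
        profile = "PamProfile",
        consensus = "character",
        cutSite = "integer",
        accounting = "integer",
        parameters = "list"
    )
)

setValidity("PamCallResult", function(object) {
    acc <- object@accounting
    if (!("input" %in% names(acc)))
        return("accounting must contain an 'input' entry")
    if (acc[["input"]] != sum(acc[names(acc) != "input"]))
        return("accounting buckets must sum to the input read count")
    TRUE
})

#' A designed universal single-guide RNA
#'
#' The universal sgRNA comprises the 3' 20 nucleotides of the CRISPR direct
#' repeat (the scaffold, carrying the stem-loop) followed by a 24-nucleotide
#' spacer, for a 44-nt guide.
#'
#' @slot scaffold \code{RNAString}, 3' portion of the repeat (default 20 nt).
#' @slot spacer \code{RNAString} spacer (default 24 nt).
#' @slot fullGuide \code{RNAString}, scaffold followed by spacer.
#' @slot stemLoop \code{DataFrame} of stem-loop hits predicted within the
#'   scaffold (zero rows when none found).
#'
#' @exportClass SgRNADesign
setClass("SgRNADesign",
    slots = c(
        scaffold = "RNAString",
        spacer = "RNAString",
        fullGuide = "RNAString",
        stemLoop = "DataFrame"
    )
)

setValidity("SgRNADesign", function(object) {
    if (length(object@fullGuide) !=
        length(object@scaffold) + length(object@spacer))
        return("full guide must be scaffold followed by spacer")
    if (as.character(object@fullGuide) !=
        paste0(as.character(object@scaffold), as.character(object@spacer)))
        return("full guide must equal scaffold + spacer")
    TRUE
})

#' Amplicon editing-outcome quantification result
#'
#' Per-read outcome classifications around a predicted cut site together with
#' category counts and the editing frequency normalized to aligned reads.
#'
#' @slot classifications \code{DataFrame}, one row per read: category,
#'   alignment strand and score, and the largest event overlapping the
#'   quantification window.
#' @slot summary list: category counts, aligned count, edited fraction and
#'   (when a control was supplied) the background-corrected fraction.
#' @slot cut list describing the located cut (between-base coordinate,
#'   strand, window bases).
#' @slot parameters list of quantification parameters.
#'
#' @exportClass EditQuantResult
setClass("EditQuantResult",
    slots = c(
        classifications = "DataFrame",
        summary = "list",
        cut = "list",
        parameters = "list"
    )
)
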