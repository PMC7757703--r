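#' @include AllClasses.R
NULL

#' @rdname PamLibraryDesign
#' @param x an object with library-design geometry.
#' @export
setGeneric("anchorSeq", function(x) standardGeneric("anchorSeq"))

#' @rdname PamLibraryDesign
#' @export
setGeneric("adapterSeq", function(x) standardGeneric("adapterSeq"))

#' @rdname PamLibraryDesign
#' @export
setGeneric("spacerSeq", function(x) standardGeneric("spacerSeq"))

#' @rdname PamLibraryDesign
#' @export
setGeneric("randomizedLen", function(x) standardGeneric("randomizedLen"))

#' @rdname CleavageReadSet
#' @param x a \code{CleavageReadSet}.
#' @export
setGeneric("readTruth", function(x) standardGeneric("readTruth"))

#' @rdname CleavageReadSet
#' @export
setGeneric("sequencedReads", function(x) standardGeneric("sequencedReads"))

#' @rdname PamProfile
#' @param x a profiled object.
#' @export
setGeneric("pamCounts", function(x) standardGeneric("pamCounts"))

#' @rdname PamProfile
#' @export
setGeneric("pamFreqs", function(x) standardGeneric("pamFreqs"))

#' @rdname PamProfile
#' @export
setGeneric("infoBits", function(x) standardGeneric("infoBits"))

#' @rdname PamCallResult
#' @param x a \code{PamCallResult}.
#' @export
setGeneric("pamObservations", function(x) standardGeneric("pamObservations"))

#' @rdname PamCallResult
#' @export
setGeneric("cutSiteDistribution",
    function(x) standardGeneric("cutSiteDistribution"))

#' @rdname PamCallResult
#' @export
setGeneric("pamProfile", function(x) standardGeneric("pamProfile"))

#' @rdname PamCallResult
#' @export
setGeneric("pamConsensus", function(x) standardGeneric("pamConsensus"))

#' @rdname PamCallResult
#' @export
setGeneric("cutSite", function(x) standardGeneric("cutSite"))

#' @rdname PamCallResult
#' @export
setGeneric("readAccounting", function(x) standardGeneric("readAccounting"))

#' @rdname SgRNADesign
#' @param x an \code{SgRNADesign}.
#' @export
setGeneric("guideScaffold", function(x) standardGeneric("guideScaffold"))

#' @rdname SgRNADesign
#' @export
setGeneric("guideSpacer", function(x) standardGeneric("guideSpacer"))

#' @rdname SgRNADesign
#' @export
setGeneric("fullGuide", function(x) standardGeneric("fullGuide"))
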