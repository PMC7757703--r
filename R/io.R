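#' @include objects.R
NULL

#' Read and write assay configuration
#'
#' The library design and nuclease model share one YAML key-value file with
#' two top-level blocks.  Schema:
#' \preformatted{
#' design:
#'   anchor: <28-bp DNA>       spacer: <DNA>
#'   adapter: <DNA>            downstream: <DNA>
#'   randomized_len: <int>
#' model:
#'   pam: <IUPAC motif>        # or pam_pwm: 4xL matrix, rows A,C,G,T
#'   fidelity: <0..1>          max_cleavage_prob: <0..1>
#'   cut_site: <int>           stagger: <int>
#'   background_rate: <0..1>   error_rate: <0..1>
#' }
#'
#' @param file path to the YAML config.
#' @return \code{readAssayConfig}: list with elements \code{design}
#'   (\code{PamLibraryDesign}) and \code{model} (\code{NucleaseModel}).
#' @export
readAssayConfig <- function(file) {
    cfg <- yaml::read_yaml(file)
    d <- cfg$design
    if (is.null(d))
        stop("config lacks a 'design' block")
    design <- PamLibraryDesign(
        anchor = d$anchor %||% .DEFAULT_ANCHOR,
        randomizedLen = d$randomized_len %||% 8L,
        spacer = d$spacer %||% .DEFAULT_SPACER,
        adapter = d$adapter %||% .DEFAULT_ADAPTER,
        downstream = d$downstream %||% .DEFAULT_DOWNSTREAM)
    m <- cfg$model %||% list()
    pam <- if (!is.null(m$pam_pwm)) {
        W <- do.call(cbind, lapply(m$pam_pwm, as.numeric))
        rownames(W) <- .DNA_BASES
        W
    } else {
        m$pam %||% "TTTV"
    }
    model <- NucleaseModel(
        pam = pam,
        maxCleavageProb = m$max_cleavage_prob %||% 0.9,
        cutSite = m$cut_site %||% 22L,
        stagger = m$stagger %||% 5L,
        backgroundRate = m$background_rate %||% 0.05,
        errorRate = m$error_rate %||% 0.001,
        width = randomizedLen(design),
        fidelity = m$fidelity %||% 0.97)
    list(design = design, model = model)
}

#' @rdname readAssayConfig
#' @param design a \code{\link{PamLibraryDesign}}.
#' @param model a \code{\link{NucleaseModel}}.
#' @export
writeAssayConfig <- function(design, model, file) {
    cfg <- list(
        design = list(
            anchor = as.character(anchorSeq(design)),
            randomized_len = randomizedLen(design),
            spacer = as.character(spacerSeq(design)),
            adapter = as.character(adapterSeq(design)),
            downstream = as.character(design@downstream)),
        model = list(
            pam_pwm = lapply(seq_len(ncol(model@pamPWM)),
                             function(i) as.numeric(model@pamPWM[, i])),
            max_cleavage_prob = model@maxCleavageProb,
            cut_site = model@cutSite,
            stagger = model@stagger,
            background_rate = model@backgroundRate,
            error_rate = model@errorRate))
    yaml::write_yaml(cfg, file)
    invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an input-library background composition
#'
#' TSV with columns \code{base} (A/C/G/T) and one column per randomized
#' position; returns the 4 x L matrix accepted by \code{\link{buildProfile}}.
#'
#' @param file TSV path.
#' @return 4 x L numeric matrix.
#' @export
readBackgroundComposition <- function(file) {
    df <- read.delim(file, check.names = FALSE)
    if (!"base" %in% names(df))
        stop("background TSV needs a 'base' column")
    m <- as.matrix(df[, setdiff(names(df), "base"), drop = FALSE])
    rownames(m) <- df$base
    m <- m[.DNA_BASES, , drop = FALSE]
    storage.mode(m) <- "double"
    m
}
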