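#' @include pamcall.R
NULL

utils::globalVariables(c("pos", "ymin", "ymax", "base", "label"))

#' Sequence logo of a PAM profile
#'
#' Draws an information-content logo: at each randomized position the bases
#' are stacked as letter-labelled rectangles whose total height is the
#' position's information content (\code{2 - H} bits) and whose individual
#' heights are proportional to base frequency, most frequent base on top.
#'
#' @param profile a \code{\link{PamProfile}} or \code{\link{PamCallResult}}.
#' @param minHeight base contributions below this height (bits) are drawn
#'   without a letter to avoid clutter.
#' @return a \code{ggplot} object.
#' @export
plotPamLogo <- function(profile, minHeight = 0.05) {
    if (is(profile, "PamCallResult"))
        profile <- pamProfile(profile)
    stopifnot(is(profile, "PamProfile"))
    f <- pamFreqs(profile)
    info <- infoBits(profile)
    pieces <- do.call(rbind, lapply(seq_len(ncol(f)), function(i) {
        h <- f[, i] * info[i]
        ord <- order(h)                     # stack tallest on top
        data.frame(pos = i, base = rownames(f)[ord], h = h[ord],
                   ymin = cumsum(c(0, h[ord]))[seq_len(4L)],
                   ymax = cumsum(h[ord]))
    }))
    pieces$label <- ifelse(pieces$h >= minHeight, pieces$base, "")
    cols <- c(A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839")
    ggplot2::ggplot(pieces) +
        ggplot2::geom_rect(ggplot2::aes(
            xmin = pos - 0.42, xmax = pos + 0.42,
            ymin = ymin, ymax = ymax, fill = base),
            alpha = 0.85) +
        ggplot2::geom_text(ggplot2::aes(
            x = pos, y = (ymin + ymax) / 2,
            label = label), colour = "white", fontface = "bold") +
        ggplot2::scale_fill_manual(values = cols, guide = "none") +
        ggplot2::scale_x_continuous(breaks = seq_len(ncol(f))) +
        ggplot2::coord_cartesian(ylim = c(0, 2)) +
        ggplot2::labs(x = "randomized position (PAM-distal to proximal)",
                      y = "information (bits)",
                      title = sprintf("PAM consensus: %s",
                                      profile@consensus)) +
        ggplot2::theme_minimal()
}
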