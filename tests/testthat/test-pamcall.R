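test_that("quality filter keeps reads with mean Phred strictly above threshold", {
    reads <- makeQualReads(c(10, 15, 20, 21, 30, 40))
    out <- qualityFilter(reads, threshold = 20)
    expect_equal(out$report$kept, 3)
    expect_equal(out$report$removed, 3)
    # a read at exactly the threshold is removed (strict inequality)
    expect_false("r3" %in% names(out$reads))
    expect_true(all(c("r4", "r5", "r6") %in% names(out$reads)))
    expect_equal(qualityFilter(makeQualReads(30))$report$kept, 1)
})

test_that("anchoring extracts the PAM and cut offset from hand-built reads", {
    design <- PamLibraryDesign()
    read <- makeAssayRead("TTTAGGCA", 22, design)
    out <- anchorReads(c(r1 = read), design)
    expect_equal(nrow(out$observations), 1)
    expect_equal(out$observations$pam, "TTTAGGCA")
    expect_equal(out$observations$cut_offset, 22)
    # the reverse-complement presentation yields the identical observation
    out2 <- anchorReads(c(r1 = rc_chr(read)), design)
    expect_equal(out2$observations$pam, "TTTAGGCA")
    expect_equal(out2$observations$cut_offset, 22)
    # other offsets are measured exactly
    for (off in c(1, 5, 24)) {
        o <- anchorReads(c(x = makeAssayRead("ACGTACGT", off, design)), design)
        expect_equal(o$observations$cut_offset, off)
    }
})

test_that("reads without exact anchor or adapter matches are excluded with reasons", {
    design <- PamLibraryDesign()
    good <- makeAssayRead("TTTAGGCA", 22, design)
    # one mismatch inside the 28-bp anchor region of the read
    anchorRC <- rc_chr(as.character(anchorSeq(design)))
    pos <- regexpr(anchorRC, good, fixed = TRUE)[1] + 10L
    mismatched <- good
    substr(mismatched, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                            substr(good, pos, pos))[1]
    noAdapter <- sub(as.character(adapterSeq(design)), "", good, fixed = TRUE)
    twoAnchors <- paste0(good, anchorRC)
    out <- anchorReads(c(a = mismatched, b = noAdapter, c = twoAnchors),
                       design)
    expect_equal(nrow(out$observations), 0)
    excl <- setNames(out$exclusions$reason, out$exclusions$read_id)
    expect_equal(excl[["a"]], "no_anchor")
    expect_equal(excl[["b"]], "no_adapter")
    expect_equal(excl[["c"]], "ambiguous_anchor")
})

test_that("cut-site filter retains the modal window and reports the loss", {
    obs <- S4Vectors::DataFrame(
        read_id = sprintf("r%d", 1:100),
        pam = strrep("A", 8),
        cut_offset = c(rep(22L, 96), rep(7L, 2), rep(30L, 2)))
    out <- cutSiteFilter(obs)
    expect_equal(nrow(out$retained), 96)
    expect_equal(out$fractionFiltered, 0.04)
    expect_equal(inferCutSite(out), 22)
    # degenerate single-site case: everything retained
    one <- cutSiteFilter(S4Vectors::DataFrame(cut_offset = rep(22L, 10)))
    expect_equal(nrow(one$retained), 10)
    expect_equal(one$fractionFiltered, 0)
    # offsets within the +/- 2 window are kept
    win <- cutSiteFilter(S4Vectors::DataFrame(
        cut_offset = c(rep(22L, 10), 20L, 24L, 19L, 25L)))
    expect_equal(sort(win$retained$cut_offset), c(20, rep(22, 10), 24))
    expect_error(cutSiteFilter(S4Vectors::DataFrame(cut_offset = integer())),
                 "no observations")
})

test_that("modal ties break toward the smaller offset", {
    obs <- S4Vectors::DataFrame(cut_offset = c(rep(22L, 50), rep(10L, 50)))
    out <- cutSiteFilter(obs)
    expect_equal(inferCutSite(out$distribution), 10)
    expect_true(all(out$retained$cut_offset == 10))
    expect_equal(inferCutSite(cutSiteFilter(
        S4Vectors::DataFrame(cut_offset = 5L))), 5)
})

test_that("profiles are column-stochastic with information in [0, 2] bits", {
    prof <- buildProfile(rep("TTTAGGCA", 50))
    expect_true(all(abs(colSums(pamFreqs(prof)) - 1) < 1e-9))
    expect_equal(infoBits(prof), rep(2, 8))
    expect_equal(prof@consensus, "TTTAGGCA")
    # empirical uniform PAMs carry ~0 information
    set.seed(8)
    unif <- vapply(seq_len(1e5), function(i) randomDNA(8), character(1))
    u <- buildProfile(unif)
    expect_true(all(infoBits(u) >= 0 & infoBits(u) < 0.02))
})

test_that("background normalization divides out the input-library skew", {
    skew <- matrix(0.25, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
    skew[, 3] <- c(0.4, 0.2, 0.2, 0.2)
    pams <- c(rep("TTAAAAAA", 40), rep("TTCAAAAA", 20),
              rep("TTGAAAAA", 20), rep("TTTAAAAA", 20))
    raw <- buildProfile(pams)
    norm <- buildProfile(pams, background = skew)
    expect_gt(raw@freqs["A", 3], raw@freqs["C", 3])
    expect_true(all(abs(norm@freqs[, 3] - 0.25) < 1e-9))
    expect_true(all(abs(colSums(norm@freqs) - 1) < 1e-9))
})

test_that("IUPAC consensus codes follow the inclusion threshold", {
    mkcol <- function(a, c, g, t) {
        matrix(c(a, c, g, t), nrow = 4,
               dimnames = list(c("A", "C", "G", "T"), NULL))
    }
    expect_equal(callConsensus(mkcol(0, 0.5, 0, 0.5)), "Y")
    expect_equal(callConsensus(mkcol(0.26, 0.25, 0.25, 0.24),
                               includeThreshold = 0.25), "V")
    expect_equal(callConsensus(mkcol(0.25, 0.25, 0.25, 0.25)), "N")
    # distal N positions trim; the proximal N is reported
    m <- cbind(mkcol(0.25, 0.25, 0.25, 0.25), mkcol(0.01, 0.01, 0.01, 0.97),
               mkcol(0.01, 0.01, 0.01, 0.97), mkcol(0.25, 0.25, 0.25, 0.25))
    expect_equal(callConsensus(m), "TTN")
    expect_equal(callConsensus(mkcol(0.25, 0.25, 0.25, 0.25)), "N")
})

test_that("the pipeline recovers ground-truth PAM and cut site (round trip)", {
    design <- PamLibraryDesign()
    truths <- c("TTTV", "TTV", "TTN", "YYN", "YTV")
    seeds <- c(101, 102, 103, 104, 105)
    for (i in seq_along(truths)) {
        model <- NucleaseModel(truths[i], maxCleavageProb = 0.9,
                               backgroundRate = 0.05)
        rs <- simulateAssay(design, model, 5e4, seed = seeds[i])
        res <- callPam(rs)
        expect_equal(pamConsensus(res), truths[i],
                     label = sprintf("consensus for truth %s", truths[i]))
        expect_equal(cutSite(res), 22,
                     label = sprintf("cut site for truth %s", truths[i]))
    }
})

test_that("read accounting is conserved on every pipeline run", {
    design <- PamLibraryDesign()
    for (bg in c(0.02, 0.1)) {
        rs <- simulateAssay(design, NucleaseModel("TTN", backgroundRate = bg),
                            3e4, seed = round(1000 * bg))
        acc <- readAccounting(callPam(rs))
        expect_equal(acc[["input"]], length(rs))
        expect_equal(acc[["input"]],
                     sum(acc[setdiff(names(acc), "input")]))
        expect_equal(acc[["retained"]],
                     nrow(pamObservations(callPam(rs))))
    }
})

test_that("reverse-complementing every read changes no observation", {
    design <- PamLibraryDesign()
    rs <- simulateAssay(design, NucleaseModel("TTV", backgroundRate = 0.05),
                        2e4, seed = 77)
    seqs <- DNAStringSet(sequencedReads(rs))
    fwd <- anchorReads(seqs, design)
    rev <- anchorReads(reverseComplement(seqs), design)
    of <- fwd$observations[order(fwd$observations$read_id), ]
    or <- rev$observations[order(rev$observations$read_id), ]
    expect_equal(of$read_id, or$read_id)
    expect_equal(of$pam, or$pam)
    expect_equal(of$cut_offset, or$cut_offset)
})

test_that("cut-site filter loss matches the background surviving anchoring", {
    # With a PAM-indifferent nuclease, error-free sequencing and background
    # rate b, a background blunt end is anchorable iff it leaves >= 1
    # protospacer base (43 of the 79 possible positions for the default
    # 80-bp molecule), and is retained iff it lands in the modal +/- 2
    # window (offsets 20..24, i.e. 5 of those 43).  Expected filtered
    # fraction among anchored reads:
    #   b * (38/79) / ((1 - b) + b * (43/79))
    design <- PamLibraryDesign()
    b <- 0.1
    model <- NucleaseModel("NNNNNNNN", backgroundRate = b, errorRate = 0)
    rs <- simulateAssay(design, model, 2e4, seed = 88)
    res <- callPam(rs)
    molLen <- 28 + 8 + 24 + 20
    pAnch <- (1 - b) + b * (43 / (molLen - 1))
    pf <- b * (38 / (molLen - 1)) / pAnch
    nAnch <- sum(readAccounting(res)[c("cutsite_filtered", "retained")])
    observed <- pamProfile(res)@fractionFiltered
    expect_lt(abs(observed - pf), 3 * sqrt(pf * (1 - pf) / nAnch))
})

test_that("pipeline outputs are written completely", {
    rs <- simulateAssay(PamLibraryDesign(), NucleaseModel("TTV"), 2e4,
                        seed = 91)
    res <- callPam(rs)
    dir <- tempfile()
    paths <- writePamCallOutputs(res, dir)
    expect_true(all(file.exists(paths)))
    report <- jsonlite::read_json(file.path(dir, "pamcall_report.json"))
    expect_equal(report$consensus, "TTV")
    expect_equal(report$cut_site, 22)
    expect_equal(report$accounting$input, length(rs))
    hist <- read.delim(file.path(dir, "pamcall_cutsites.tsv"))
    expect_equal(sum(hist$count),
                 sum(readAccounting(res)[c("cutsite_filtered", "retained")]))
})
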