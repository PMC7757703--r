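test_that("library molecules follow the designed layout", {
    design <- PamLibraryDesign(anchor = strrep("A", 28),
                               spacer = strrep("C", 24),
                               downstream = "")
    lib <- simulateLibrary(design, 1, seed = 3)
    mol <- as.character(lib[[1]])
    expect_equal(nchar(mol), 60)
    expect_equal(substr(mol, 29, 36), mcols(lib)$pam[1])
    expect_equal(substr(mol, 1, 28), strrep("A", 28))
    expect_equal(substr(mol, 37, 60), strrep("C", 24))
    # deterministic under a fixed seed
    lib2 <- simulateLibrary(design, 1, seed = 3)
    expect_identical(as.character(lib), as.character(lib2))
})

test_that("randomized bases are uniform and inputs are validated", {
    lib <- simulateLibrary(PamLibraryDesign(), 1e5, seed = 7)
    pams <- mcols(lib)$pam
    for (i in c(1, 4, 8)) {
        f <- table(factor(substr(pams, i, i), levels = c("A", "C", "G", "T")))
        expect_true(all(abs(f / 1e5 - 0.25) < 0.01),
                    label = sprintf("position %d within 0.25 +/- 0.01", i))
    }
    expect_error(simulateLibrary(PamLibraryDesign(), 0), "positive")
    expect_error(PamLibraryDesign(anchor = "ACGTX"), "A/C/G/T")
})

test_that("a skewed input-library composition is honoured", {
    skew <- matrix(0.25, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
    skew[, 1] <- c(0.7, 0.1, 0.1, 0.1)
    lib <- simulateLibrary(PamLibraryDesign(), 2e4, seed = 5, baseProbs = skew)
    fA <- mean(substr(mcols(lib)$pam, 1, 1) == "A")
    expect_lt(abs(fA - 0.7), 3 * sqrt(0.7 * 0.3 / 2e4))
})

test_that("a point-mass PAM model cleaves only its PAM at the modelled cut", {
    design <- PamLibraryDesign()
    model <- NucleaseModel("TTTACGTA", fidelity = 1, backgroundRate = 0,
                           errorRate = 0)
    lib <- simulateLibrary(design, 3e5, seed = 11)
    rs <- simulateCleavageReads(lib, model, seed = 12)
    truth <- readTruth(rs)
    expect_gt(length(rs), 0)
    expect_true(all(truth$true_pam == "TTTACGTA"))
    expect_true(all(truth$true_cut == 22))
    expect_true(all(!truth$background))
})

test_that("pure background cleavage cuts uniformly over the molecule", {
    design <- PamLibraryDesign()
    model <- NucleaseModel("NNNNNNNN", backgroundRate = 1,
                           errorRate = 0)
    rs <- simulateAssay(design, model, 8000, seed = 21)
    molLen <- 28 + 8 + 24 + 20
    # blunt ends are uniform over positions 1..molLen-1; in offset
    # coordinates that is -(28 + 8) + 1 .. molLen - 36 - 1 + ... full range
    offs <- readTruth(rs)$true_cut
    lev <- seq(1 - 36, molLen - 1 - 36)
    expect_true(all(offs %in% lev))
    p <- stats::chisq.test(table(factor(offs, levels = lev)),
                           p = rep(1 / length(lev), length(lev)))$p.value
    expect_gt(p, 0.001)
})

test_that("blunting resolves the staggered cut to the target-strand coordinate", {
    design <- PamLibraryDesign()
    model <- NucleaseModel("TTV", stagger = 5, backgroundRate = 0,
                           errorRate = 0)
    lib <- simulateLibrary(design, 2e4, seed = 31)
    blunted <- simulateCleavageReads(lib, model, seed = 32, blunt = TRUE)
    raw <- simulateCleavageReads(lib, model, seed = 32, blunt = FALSE)
    expect_true(all(readTruth(blunted)$true_cut == 22))
    expect_true(all(readTruth(raw)$true_cut == 27))
})

test_that("the FASTQ output is byte-identical under a fixed seed", {
    design <- PamLibraryDesign()
    model <- NucleaseModel("TTV")
    f1 <- tempfile(fileext = ".fastq")
    f2 <- tempfile(fileext = ".fastq")
    exportFastq(simulateAssay(design, model, 5000, seed = 99), f1)
    exportFastq(simulateAssay(design, model, 5000, seed = 99), f2)
    expect_identical(readLines(f1), readLines(f2))
    f3 <- tempfile(fileext = ".fastq")
    exportFastq(simulateAssay(design, model, 5000, seed = 100), f3)
    expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("molecule and truth accounting is conserved", {
    rs <- simulateAssay(PamLibraryDesign(), NucleaseModel("TTN"), 3e4,
                        seed = 41)
    expect_lte(length(rs), rs@nMolecules)
    truth <- readTruth(rs)
    expect_setequal(truth$read_id, names(rs))
    expect_equal(nrow(truth), length(rs))
    reads <- sequencedReads(rs)
    expect_true(all(width(reads) == width(quality(reads))))
})

test_that("empirical cleavage fractions converge to the PWM product", {
    # PWM informative only at the protospacer-adjacent position, so
    # molecules group into four classes of known cleavage probability
    W <- matrix(0.25, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
    W[, 8] <- c(A = 0.1, C = 0.1, G = 0.1, T = 0.7)
    model <- NucleaseModel(W, maxCleavageProb = 0.9, backgroundRate = 0,
                           errorRate = 0)
    lib <- simulateLibrary(PamLibraryDesign(), 1e5, seed = 51)
    rs <- simulateCleavageReads(lib, model, seed = 52)
    last <- substr(mcols(lib)$pam, 8, 8)
    cleavedLast <- substr(readTruth(rs)$true_pam, 8, 8)
    for (b in c("A", "C", "G", "T")) {
        nb <- sum(last == b)
        phat <- sum(cleavedLast == b) / nb
        p <- 0.9 * W[b, 8] / 0.7
        expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / nb),
                  label = sprintf("class %s within 3 SE", b))
    }
})

test_that("reads too short to span the assay geometry are rejected", {
    lib <- simulateLibrary(PamLibraryDesign(), 10, seed = 61)
    expect_error(simulateCleavageReads(lib, NucleaseModel(), readLen = 40),
                 "cannot span")
})

test_that("assay config round-trips through YAML", {
    design <- PamLibraryDesign()
    model <- NucleaseModel("YYN", cutSite = 19, backgroundRate = 0.08)
    f <- tempfile(fileext = ".yaml")
    writeAssayConfig(design, model, f)
    cfg <- readAssayConfig(f)
    expect_equal(as.character(anchorSeq(cfg$design)),
                 as.character(anchorSeq(design)))
    expect_equal(cfg$model@pamPWM, model@pamPWM, tolerance = 1e-9)
    expect_equal(cfg$model@cutSite, 19L)
    expect_equal(cfg$model@backgroundRate, 0.08)
})
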