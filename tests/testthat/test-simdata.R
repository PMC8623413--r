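test_that("genome simulation is deterministic and matches requested dimensions", {
    spec <- genomeSpec(2, 2, 3000, repeatFraction = 0.2, gc = 0.4, seed = 11)
    g1 <- simulateGenome(spec)
    g2 <- simulateGenome(spec)
    expect_identical(as.character(genomeSequences(g1)),
                     as.character(genomeSequences(g2)))
    expect_equal(unname(Biostrings::width(genomeSequences(g1))),
                 rep(3000L, 4))
    expect_equal(sum(genomeTruth(g1)$class == "Y"), 2L)
    # reads are deterministic too
    cfg <- readSimConfig("male", 5, seed = 3)
    r1 <- simulateReads(g1, cfg)
    r2 <- simulateReads(g1, cfg)
    expect_identical(as.character(simReads(r1)), as.character(simReads(r2)))
})

test_that("without repeats, Y and autosomal k-mer sets are disjoint", {
    g <- simulateGenome(genomeSpec(2, 1, 3000, repeatFraction = 0, seed = 5))
    seqs <- as.character(genomeSequences(g))
    ySet <- unique(oracleKmerWindows(seqs[["Y1"]], 15L))
    xaSet <- unique(c(oracleKmerWindows(seqs[["A1"]], 15L),
                      oracleKmerWindows(seqs[["A2"]], 15L)))
    expect_length(intersect(ySet, xaSet), 0L)
})

test_that("degenerate genome requests behave as specified", {
    expect_error(simulateGenome(genomeSpec(0, 0, 1000)), "at least one")
    g <- simulateGenome(genomeSpec(2, 0, 1000, seed = 1))
    expect_false(any(genomeTruth(g)$class == "Y"))
})

test_that("female read sets sample no fragments from Y scaffolds", {
    g <- simulateGenome(genomeSpec(2, 2, 5000, seed = 2))
    f <- simulateReads(g, readSimConfig("female", 8, seed = 4))
    expect_false(any(grepl("^Y", readPlacements(f)$scaffold)))
    m <- simulateReads(g, readSimConfig("male", 8, seed = 4))
    expect_true(any(grepl("^Y", readPlacements(m)$scaffold)))
})

test_that("male Y depth is about half the autosomal target", {
    g <- simulateGenome(genomeSpec(1, 1, 120000, seed = 6))
    m <- simulateReads(g, readSimConfig("male", 20, seed = 7))
    bins <- binDepth(readPlacements(m), scaffoldLengths(g))
    yMean <- mean(bins$depth[bins$scaffold == "Y1"])
    expect_lt(abs(yMean - 10) / 10, 0.15)
    aMean <- mean(bins$depth[bins$scaffold == "A1"])
    expect_lt(abs(aMean - 20) / 20, 0.15)
})

test_that("error-free reads are exact substrings of a scaffold", {
    g <- simulateGenome(genomeSpec(1, 0, 4000, seed = 8))
    r <- simulateReads(g, readSimConfig("male", 3, errorRate = 0, seed = 9))
    sc <- as.character(genomeSequences(g))[[1L]]
    scRc <- oracleRevComp(sc)
    reads <- as.character(simReads(r))
    hits <- vapply(reads, function(x)
        grepl(x, sc, fixed = TRUE) || grepl(x, scRc, fixed = TRUE), TRUE)
    expect_true(all(hits))
})

test_that("pooled libraries cover the Y at depth * maleFraction / 2", {
    g <- simulateGenome(genomeSpec(1, 1, 100000, seed = 10))
    p <- simulateReads(g, readSimConfig("pooled", 8.4, maleFraction = 0.5,
                                        seed = 11))
    bins <- binDepth(readPlacements(p), scaffoldLengths(g))
    yMean <- mean(bins$depth[bins$scaffold == "Y1"])
    expect_lt(abs(yMean - 2.1) / 2.1, 0.2)
})

test_that("segdup implantation conserves sequence at zero mutation rates", {
    g <- simulateGenome(genomeSpec(1, 0, 20000, seed = 12))
    before <- sum(Biostrings::width(genomeSequences(g)))
    g2 <- implantSegdup(g, "A1", 5001, 7000, nCopies = 10, seed = 13)
    expect_equal(sum(Biostrings::width(genomeSequences(g2))) - before,
                 10L * 2000L)
    src <- substring(as.character(genomeSequences(g))[["A1"]], 5001, 7000)
    g3 <- implantSegdup(g, "A1", 5001, 7000, nCopies = 1, seed = 14)
    expect_identical(as.character(genomeSequences(g3))[["A1_Ydup1"]], src)
    expect_equal(copyMap(g3)$n_substitutions, 0L)
})

test_that("per-copy divergence matches its binomial expectation", {
    g <- simulateGenome(genomeSpec(1, 0, 110000, seed = 15))
    g2 <- implantSegdup(g, "A1", 1, 100000, nCopies = 1, divergence = 0.01,
                        seed = 16)
    nSub <- copyMap(g2)$n_substitutions
    expect_lt(abs(nSub - 1000), 3 * sqrt(100000 * 0.01 * 0.99))
})

test_that("implantation rejects invalid intervals", {
    g <- simulateGenome(genomeSpec(1, 0, 1000, seed = 1))
    expect_error(implantSegdup(g, "A1", 500, 2000, 1), "outside")
    expect_error(implantSegdup(g, "A1", 10, 20, 0), "nCopies")
})

test_that("pseudogenize is the identity at zero rates", {
    cds <- randomCds(50, seed = 20)
    p <- pseudogenize(cds, 0, 0)
    expect_identical(p$cds, cds)
    expect_equal(nrow(p$events), 0L)
    expect_error(pseudogenize("ATG", 0, 0), "shorter")
})

test_that("a forced frameshift is detected by the integrity check", {
    cds <- "ATGGCATAA"  # one internal codon
    p <- pseudogenize(cds, stopRate = 0, frameshiftRate = 1, seed = 21)
    expect_equal(p$events$type, "frameshift")
    expect_equal(checkCdsIntegrity(p$cds, cds)$status, "frameshift")
})

test_that("premature-stop frequency follows the per-codon closed form", {
    nCodons <- 30L
    r <- 0.02
    cds <- randomCds(nCodons, seed = 22)
    nInternal <- nCodons - 2L
    hits <- vapply(seq_len(1000L), function(i) {
        p <- pseudogenize(cds, stopRate = r, frameshiftRate = 0, seed = i)
        any(p$events$type == "stop")
    }, TRUE)
    expected <- 1 - (1 - r)^nInternal
    se <- sqrt(expected * (1 - expected) / 1000)
    expect_lt(abs(mean(hits) - expected), 3.5 * se)
})

test_that("event-history simulation respects rate-zero boundaries", {
    tree <- ape::read.tree(text = "((a:10,b:10):10,(c:10,d:10):10):5;")
    for (s in 1:10) {
        h <- simulateEventHistory(tree, gainRate = 0.5, lossRate = 0,
                                  seed = s)
        expect_equal(nrow(lossEvents(h)), 0L)
    }
    h0 <- simulateEventHistory(tree, gainRate = 0, lossRate = 0.1, seed = 1)
    expect_equal(nrow(gainEvents(h0)), 0L)
    expect_equal(nrow(lossEvents(h0)), 0L)
    expect_error(simulateEventHistory(tree, -1, 0.1), ">= 0")
})

test_that("total gains match the Poisson mean over replicates", {
    tree <- ape::read.tree(text = "((a:10,b:10):10,(c:10,d:10):10):5;")
    total <- sum(tree$edge.length) + tree$root.edge  # 65 My
    gainRate <- 30 / total
    gains <- vapply(seq_len(500L), function(s)
        nrow(gainEvents(simulateEventHistory(tree, gainRate, 0.02,
                                             seed = s))), 0L)
    se <- sqrt(30 / 500)
    expect_lt(abs(mean(gains) - 30), 3 * se)
})
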