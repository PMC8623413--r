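# constant-depth per-base table over one scaffold
constantDepth <- function(len, depth, scaffold = "s") {
    data.frame(scaffold = scaffold, pos = seq_len(len), depth = depth)
}

test_that("binning a constant depth returns that constant in every bin", {
    bins <- binDepth(constantDepth(10000, 8), c(s = 10000L))
    expect_equal(nrow(bins), 10L)
    expect_equal(bins$depth, rep(8, 10))
    expect_equal(bins$end - bins$start, rep(1000L, 10))
})

test_that("a trailing partial bin spans the scaffold remainder", {
    bins <- binDepth(constantDepth(1500, 3), c(s = 1500L))
    expect_equal(nrow(bins), 2L)
    expect_equal(bins$start, c(0L, 1000L))
    expect_equal(bins$end, c(1000L, 1500L))
    expect_equal(bins$depth, c(3, 3))
})

test_that("binned simulated depth matches its Poisson expectation", {
    g <- simulateGenome(genomeSpec(1, 0, 200000, seed = 61))
    r <- simulateReads(g, readSimConfig("male", 20, seed = 62))
    bins <- binDepth(readPlacements(r), scaffoldLengths(g))
    expect_lt(abs(mean(bins$depth) - 20) / 20, 0.02)
    # per-bin spread: ~200 read starts per bin, each adding ~0.1x
    expect_lt(max(abs(bins$depth[-nrow(bins)] - 20)), 3.5 * sqrt(220) * 0.1)
})

test_that("negative depths and tiny bins are rejected", {
    expect_error(binDepth(constantDepth(100, -1), c(s = 100L)), "negative")
    expect_error(binDepth(constantDepth(100, 1), c(s = 100L), binBp = 50),
                 ">= 100")
})

test_that("normalization is the identity at baseline and flags female-zero bins", {
    m <- data.frame(scaffold = "s", start = c(0, 1000), end = c(1000, 2000),
                    depth = c(20, 30))
    f <- data.frame(scaffold = "s", start = c(0, 1000), end = c(1000, 2000),
                    depth = c(20, 0))
    tr <- normalizeDepth(m, f, maleBaseline = 20, femaleBaseline = 20)
    expect_equal(tr$male_norm, c(1, 1.5))
    expect_equal(tr$female_zero, c(FALSE, TRUE))
    expect_error(normalizeDepth(m, f, maleBaseline = 0, femaleBaseline = 20),
                 "zero baseline")
})

test_that("an implanted male excess appears at the expected normalized ratio", {
    len <- 50000L
    m <- constantDepth(len, 20)
    m$depth[10001:20000] <- 20 * 6     # 10 extra hemizygous copies
    f <- constantDepth(len, 20)
    tr <- normalizeDepth(binDepth(m, c(s = len)), binDepth(f, c(s = len)),
                         maleBaseline = 20, femaleBaseline = 20)
    inside <- tr$start >= 10000 & tr$end <= 20000
    expect_equal(mean(tr$male_norm[inside]), 6)
    expect_equal(mean(tr$female_norm[inside]), 1)
})

test_that("a flat track produces no calls and short runs are filtered", {
    flat <- data.frame(scaffold = "s", start = seq(0, 49000, 1000),
                       end = seq(1000, 50000, 1000),
                       male_norm = 1, female_norm = 1, female_zero = FALSE)
    expect_length(callSegdups(flat), 0L)
    short <- flat
    short$male_norm[10:12] <- 3        # 3 kb run < 10 kb minimum
    expect_length(callSegdups(short), 0L)
    expect_length(callSegdups(short, minLenBp = 3000), 1L)
})

test_that("call boundaries land within one bin of an implanted duplication", {
    g <- simulateGenome(genomeSpec(2, 0, 300000, seed = 63))
    g2 <- implantSegdup(g, "A1", 100001, 140000, nCopies = 4,
                        divergence = 0.01, seed = 64)
    m <- simulateReads(g2, readSimConfig("male", 20, seed = 65))
    f <- simulateReads(g2, readSimConfig("female", 20, seed = 66))
    sl <- scaffoldLengths(g)
    tr <- normalizeDepth(binDepth(placementsOnSource(m, g2), sl),
                         binDepth(readPlacements(f), sl),
                         xaScaffolds = c("A1", "A2"))
    calls <- callSegdups(tr)
    expect_length(calls, 1L)
    expect_lte(abs(GenomicRanges::start(calls) - 100001), 1000)
    expect_lte(abs(GenomicRanges::end(calls) - 140000), 1000)
    calls <- estimateCopyNumber(calls, tr)
    expect_lte(abs(GenomicRanges::mcols(calls)$est_copies - 4), 1)
})

test_that("copy-number estimation inverts the hemizygous-depth algebra", {
    mkTrack <- function(maleNorm) {
        data.frame(scaffold = "s", start = seq(0, 19000, 1000),
                   end = seq(1000, 20000, 1000),
                   male_norm = maleNorm, female_norm = 1,
                   female_zero = FALSE)
    }
    call <- GenomicRanges::GRanges("s", IRanges::IRanges(1, 20000))
    est <- function(mn) GenomicRanges::mcols(
        estimateCopyNumber(call, mkTrack(mn)))$est_copies
    expect_equal(est(1.5), 1L)         # one hemizygous Y copy
    expect_equal(est(6.0), 10L)        # 1 + n/2 = 6
    low <- estimateCopyNumber(call, mkTrack(0.9))
    expect_equal(GenomicRanges::mcols(low)$est_copies, 1L)
    expect_true(GenomicRanges::mcols(low)$low_confidence)
})

test_that("raising the elevation threshold never grows the called span", {
    set.seed(67)
    tr <- data.frame(scaffold = "s", start = seq(0, 99000, 1000),
                     end = seq(1000, 100000, 1000),
                     male_norm = c(rep(1, 30), runif(40, 1, 8), rep(1, 30)),
                     female_norm = 1, female_zero = FALSE)
    span <- function(thr) {
        calls <- callSegdups(tr, minMaleNorm = thr)
        if (!length(calls)) 0 else
            sum(GenomicRanges::end(calls) - GenomicRanges::start(calls) + 1)
    }
    spans <- vapply(c(1.4, 2, 3, 4, 6), span, 0)
    expect_true(all(diff(spans) <= 0))
})

test_that("calls never overlap and zero-gap calls are contiguous runs", {
    tr <- data.frame(scaffold = "s", start = seq(0, 59000, 1000),
                     end = seq(1000, 60000, 1000),
                     male_norm = rep(c(1, 4), each = 10, times = 3),
                     female_norm = 1, female_zero = FALSE)
    calls <- callSegdups(tr, maxGapBins = 0)
    expect_length(calls, 3L)
    ov <- GenomicRanges::findOverlaps(calls, calls)
    expect_equal(length(ov), length(calls))  # only self-overlaps
    # with a large allowed gap the runs merge into one long call
    merged <- callSegdups(tr, maxGapBins = 10)
    expect_length(merged, 1L)
})

test_that("male-specific SNP counting applies every filter", {
    # identical pileups: nothing male-specific
    sites <- data.frame(scaffold = "s", pos = 1:3,
                        mA = 10, mC = 0, mG = 5, mT = 0,
                        fA = 10, fC = 0, fG = 5, fT = 0)
    expect_equal(countMaleSpecificSnps(sites), 0L)
    # the documented positive case: male A:10,G:10; female A:12,G:0
    one <- data.frame(scaffold = "s", pos = 100,
                      mA = 10, mC = 0, mG = 10, mT = 0,
                      fA = 12, fC = 0, fG = 0, fT = 0)
    expect_equal(countMaleSpecificSnps(one), 1L)
    # low female depth makes a site unassessable
    one$fA <- 3
    expect_equal(countMaleSpecificSnps(one), 0L)
    # allele below the male support threshold
    two <- data.frame(scaffold = "s", pos = 101,
                      mA = 20, mC = 2, mG = 0, mT = 0,
                      fA = 20, fC = 0, fG = 0, fT = 0)
    expect_equal(countMaleSpecificSnps(two), 0L)
})

test_that("SNP count over a diverged copy follows the binomial expectation", {
    src <- randomSeq(100000, 68)
    g <- makeGenome(c(src = src), "XA")
    g2 <- implantSegdup(g, "src", 1, 100000, nCopies = 1, divergence = 0.01,
                        seed = 69)
    copy <- as.character(genomeSequences(g2))[["src_Ydup1"]]
    sites <- pileupFromCopies(src, copy, maleDepth = 20, femaleDepth = 20)
    n <- countMaleSpecificSnps(sites)
    expect_lt(abs(n - 1000), 3 * sqrt(100000 * 0.01 * 0.99))
})
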