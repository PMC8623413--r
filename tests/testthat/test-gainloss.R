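quartetTree <- ape::read.tree(text = "((a:10,b:10):10,(c:10,d:10):10):5;")

test_that("a focal-only Y gene is acquired on the focal terminal branch", {
    # five progressively more distant autosomal outgroups: the terminal-gain
    # scenario costs 2 (gain + source loss); ancestral Y-linkage costs 7
    tr <- ape::read.tree(
        text = "(((((w:1,o1:1):1,o2:2):1,o3:3):1,o4:4):1,o5:5):1;")
    st <- c(w = "Y", o1 = "XA", o2 = "XA", o3 = "XA", o4 = "XA", o5 = "XA")
    sc <- inferAcquisitionBranch(st, tr)
    focalEdge <- which(tr$edge[, 2] == which(tr$tip.label == "w"))
    expect_equal(sc$branch, focalEdge)
    expect_equal(sc$cost, 2)
    stemCost <- sc$candidates$cost[sc$candidates$branch == 0]
    expect_equal(stemCost, 7)   # gain + 5 Y losses + 1 source loss
})

test_that("a gene Y-linked in every species is acquired on the stem", {
    st <- c(a = "Y", b = "Y", c = "Y", d = "Y")
    sc <- inferAcquisitionBranch(st, quartetTree)
    expect_equal(sc$branch, 0)
    expect_equal(sc$cost, 2)    # gain + one shared source loss on the stem
})

test_that("degenerate state vectors are rejected", {
    expect_error(inferAcquisitionBranch(
        c(a = "unknown", b = "unknown", c = "unknown", d = "unknown"),
        quartetTree), "unknown")
    expect_error(inferAcquisitionBranch(
        c(a = "XA", b = "XA", c = "XA", d = "XA"), quartetTree), "no Y")
})

test_that("parsimony equals exhaustive enumeration on mixed quartet patterns", {
    patterns <- list(
        c(a = "Y", b = "XA", c = "XA", d = "XA"),
        c(a = "Y", b = "Y", c = "XA", d = "XA"),
        c(a = "Y", b = "absent", c = "XA", d = "XA"),
        c(a = "Y", b = "Y", c = "absent", d = "XA"),
        c(a = "Y", b = "unknown", c = "XA", d = "absent"),
        c(a = "Y", b = "XA", c = "Y", d = "XA"))
    for (st in patterns) {
        sc <- inferAcquisitionBranch(st, quartetTree)
        oracle <- oracleScenarioCosts(st, quartetTree)
        got <- sc$candidates[order(sc$candidates$branch), ]
        want <- oracle[order(oracle$branch), ]
        expect_equal(got$branch, want$branch)
        expect_equal(got$cost, want$cost)
        expect_true(sc$branch %in%
                        oracle$branch[oracle$cost == min(oracle$cost)])
        expect_setequal(sc$ties,
                        oracle$branch[oracle$cost == min(oracle$cost)])
    }
})

test_that("basal acquisitions aggregate onto the stem with no losses", {
    st <- c(a = "Y", b = "Y", c = "Y", d = "Y")
    scens <- lapply(1:8, function(i) inferAcquisitionBranch(st, quartetTree))
    names(scens) <- paste0("gene", 1:8)
    em <- buildEventMap(scens, quartetTree)
    expect_equal(nrow(gainEvents(em)), 8L)
    expect_true(all(gainEvents(em)$branch == 0L))
    expect_equal(nrow(lossEvents(em)), 0L)
    # every gene gained exactly once: single-origin conservation
    expect_equal(sort(gainEvents(em)$gene), sort(names(scens)))
})

test_that("an empty scenario set yields an empty map", {
    em <- buildEventMap(list(), quartetTree)
    expect_equal(nrow(gainEvents(em)), 0L)
    expect_equal(lossExposure(em), 0)
})

test_that("a loss that cannot follow its gain is rejected", {
    expect_error(
        eventMap(quartetTree,
                 gains = data.frame(gene = "g", branch = 1L),
                 losses = data.frame(gene = "g", branch = 5L)),
        "precedes")
    expect_error(
        eventMap(quartetTree,
                 gains = data.frame(gene = "g", branch = 1L),
                 losses = data.frame(gene = "x", branch = 1L)),
        "no gain")
})

test_that("a simulated history passes through the estimator unchanged", {
    h <- simulateEventHistory(quartetTree, gainRate = 0.5, lossRate = 0.05,
                              seed = 81)
    est <- estimateGainLossRatio(h)
    direct <- gainLossFit(nrow(gainEvents(h)), nrow(lossEvents(h)),
                          gainExposure(h), lossExposure(h))
    expect_equal(ratioEstimate(est), ratioEstimate(direct))
    expect_equal(est@pValue, direct@pValue)
    # residency truth is internally consistent: losses only shorten it
    expect_lte(lossExposure(h),
               nrow(gainEvents(h)) * (sum(quartetTree$edge.length) + 5))
})

test_that("equal counts over equal exposures give ratio 1 and p near 1", {
    est <- gainLossFit(10, 10, 100, 100)
    expect_equal(ratioEstimate(est), 1)
    expect_gt(est@pValue, 0.99)
    expect_lt(est@ciLow, 1)
    expect_gt(est@ciHigh, 1)
})

test_that("zero observed losses yield a flagged lower-bound estimate", {
    est <- gainLossFit(12, 0, 60, 40)
    expect_true(est@boundary)
    expect_equal(ratioEstimate(est), Inf)
    expect_equal(est@ciHigh, Inf)
    expect_true(is.finite(est@ciLow) && est@ciLow > 0)
    est0 <- gainLossFit(0, 5, 60, 40)
    expect_equal(ratioEstimate(est0), 0)
    expect_equal(est0@ciLow, 0)
    expect_true(is.finite(est0@ciHigh))
})

test_that("the estimator is deterministic and the CI brackets the MLE", {
    e1 <- gainLossFit(25, 3, 250, 120)
    e2 <- gainLossFit(25, 3, 250, 120)
    expect_identical(ratioEstimate(e1), ratioEstimate(e2))
    expect_identical(c(e1@ciLow, e1@ciHigh), c(e2@ciLow, e2@ciHigh))
    expect_lt(e1@ciLow, ratioEstimate(e1))
    expect_gt(e1@ciHigh, ratioEstimate(e1))
    # profile CI endpoints sit where the profile drops by qchisq(.95,1)/2:
    # they must be strictly inside a wider-confidence interval
    wide <- gainLossFit(25, 3, 250, 120, conf = 0.99)
    expect_lt(wide@ciLow, e1@ciLow)
    expect_gt(wide@ciHigh, e1@ciHigh)
})

test_that("the estimator recovers a known ratio in quick simulation", {
    tr <- ape::read.tree(text = paste0(
        "(((s1:10,s2:10):10,(s3:10,s4:10):10):10,",
        "((s5:10,s6:10):10,(s7:10,s8:10):10):10):10;"))
    ratios <- vapply(1:30, function(s) {
        h <- simulateEventHistory(tr, gainRate = 0.25, lossRate = 0.025,
                                  seed = 9000 + s)
        est <- estimateGainLossRatio(h)
        ratioEstimate(est)
    }, 0)
    expect_gt(median(ratios[is.finite(ratios)]), 4)
    expect_lt(median(ratios[is.finite(ratios)]), 25)
})
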