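#' @include AllClasses.R simdata-events.R
#' @importFrom ape node.depth.edgelength
NULL

## tips (indices) below a branch; branch 0 (stem) covers all tips
.tipsBelow <- function(tree, branch) {
    nt <- length(tree$tip.label)
    node <- .childNode(tree, branch)
    if (node <= nt) return(node)
    out <- integer(0)
    stack <- node
    while (length(stack)) {
        nd <- stack[[1L]]
        stack <- stack[-1L]
        ch <- tree$edge[tree$edge[, 1L] == nd, 2L]
        out <- c(out, ch[ch <= nt])
        stack <- c(stack, ch[ch > nt])
    }
    out
}

## minimum-loss Dollo placement: the copy is present at the child node of
## `startBranch`; `lacking`/`having` are tip indices that definitely lack /
## carry the copy (all other tips are wildcards). Returns the branches on
## which losses are placed (highest possible placement, minimum count).
.dolloLossEdges <- function(tree, startBranch, lacking, having) {
    rec <- function(branch) {
        tips <- .tipsBelow(tree, branch)
        if (!any(tips %in% lacking)) return(integer(0))
        if (!any(tips %in% having)) return(branch)
        node <- .childNode(tree, branch)
        unlist(lapply(.childBranches(tree, node), rec))
    }
    as.integer(rec(startBranch))
}

#' Infer the branch on which a gene was acquired by the Y
#'
#' Single-origin parsimony: the gene is duplicated to the Y exactly once,
#' on some branch (including the stem above the root, branch 0); the source
#' autosomal/X copy and the Y copy may then each be lost, Dollo-style, any
#' number of times. For every candidate acquisition branch the minimal
#' number of loss events explaining the leaf states is computed (a leaf in
#' state `Y` carries the Y copy and has lost the source; `XA` carries only
#' the source; `absent` has lost both; `unknown` is unconstrained), and the
#' scenario minimizing total events (one gain plus all losses) is returned.
#' Ties are reported and resolved toward the most recent acquisition (the
#' branch whose end is furthest from the root).
#'
#' @param states named character vector over the tree's tip labels with
#'   values in `Y`, `XA`, `absent`, `unknown`.
#' @param tree rooted `phylo` with branch lengths.
#' @return a list: `branch` (0 = stem), `cost` (total events),
#'   `yLossBranches`, `sourceLossBranches`, `ties` (all branches attaining
#'   the minimal cost), and `candidates` (a `data.frame` of branch costs).
#' @examples
#' tr <- ape::read.tree(text = "((a:1,b:1):1,c:2):1;")
#' inferAcquisitionBranch(c(a = "Y", b = "XA", c = "XA"), tr)$branch
#' @export
inferAcquisitionBranch <- function(states, tree) {
    stopifnot(inherits(tree, "phylo"))
    tips <- tree$tip.label
    if (!all(tips %in% names(states)))
        stop("states must be named with the tree's tip labels")
    states <- states[tips]
    if (all(states == "unknown"))
        stop("all states are unknown")
    bad <- !states %in% c("Y", "XA", "absent", "unknown")
    if (any(bad))
        stop("invalid states: ", paste(unique(states[bad]), collapse = ", "))
    yTips <- which(states == "Y")
    if (!length(yTips))
        stop("gene has no Y state at any leaf")
    xaTips <- which(states == "XA")
    absentTips <- which(states == "absent")
    yLacking <- c(xaTips, absentTips)       # tips without the Y copy
    srcLacking <- c(yTips, absentTips)      # tips without the source copy
    nEdge <- nrow(tree$edge)
    cand <- data.frame(branch = 0:nEdge, cost = NA_real_)
    scen <- vector("list", nEdge + 1L)
    for (b in 0:nEdge) {
        below <- .tipsBelow(tree, b)
        if (!all(yTips %in% below)) next    # single origin: no Y outside
        yl <- .dolloLossEdges(tree, b, yLacking, yTips)
        sl <- .dolloLossEdges(tree, 0L, srcLacking, xaTips)
        cand$cost[b + 1L] <- 1 + length(yl) + length(sl)
        scen[[b + 1L]] <- list(yLossBranches = yl, sourceLossBranches = sl)
    }
    feasible <- which(!is.na(cand$cost))
    minCost <- min(cand$cost[feasible])
    ties <- cand$branch[feasible][cand$cost[feasible] == minCost]
    # most recent acquisition: branch end furthest from the root
    depth <- node.depth.edgelength(tree)
    tieDepth <- vapply(ties, function(b)
        if (b == 0L) 0 else depth[tree$edge[b, 2L]], 0)
    pick <- ties[order(-tieDepth, -ties)][1L]
    c(list(branch = pick, cost = minCost, ties = ties,
           candidates = cand[feasible, , drop = FALSE]),
      scen[[pick + 1L]])
}

## gene-My of Y-residency for a gene gained at (branch, time), with losses
## at the given (branch, time) pairs pruning the lineage below them
.residency <- function(tree, gainBranch, gainTime, lossBranch, lossTime) {
    total <- 0
    rec <- function(branch, t0) {
        len <- .branchLength(tree, branch)
        li <- match(branch, lossBranch)
        if (!is.na(li)) {
            if (lossTime[li] < t0)
                stop("loss precedes gain on branch ", branch)
            total <<- total + lossTime[li] - t0
            return(invisible())
        }
        total <<- total + len - t0
        for (cb in .childBranches(tree, .childNode(tree, branch)))
            rec(cb, 0)
    }
    rec(gainBranch, gainTime)
    total
}

#' Construct an event map from explicit gain and loss tables
#'
#' Low-level constructor. Event times default to branch midpoints (a loss
#' on its gene's gain branch is placed at three quarters of the branch so
#' it follows the gain). Exposures are computed from the tree when omitted:
#' gain exposure is the total branch time (stem included), loss exposure is
#' the summed gene-My of Y-residency implied by the events.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param gains `data.frame` with columns `gene`, `branch` and optionally
#'   `time`.
#' @param losses `data.frame` with columns `gene`, `branch` and optionally
#'   `time`; only Y-copy losses belong here.
#' @param gainExposure,lossExposure optional explicit exposures.
#' @param trueRatio generating ratio when known (simulation truth).
#' @return an [EventMap-class].
#' @export
eventMap <- function(tree, gains, losses = NULL, gainExposure = NULL,
                     lossExposure = NULL, trueRatio = NA_real_) {
    stopifnot(inherits(tree, "phylo"))
    gains <- as.data.frame(gains)
    if (is.null(losses))
        losses <- data.frame(gene = character(0), branch = integer(0))
    losses <- as.data.frame(losses)
    if (is.null(gains$time))
        gains$time <- .branchLength(tree, gains$branch) / 2
    if (nrow(losses) && is.null(losses$time)) {
        losses$time <- .branchLength(tree, losses$branch) / 2
        onGain <- losses$branch == gains$branch[match(losses$gene,
                                                      gains$gene)]
        losses$time[onGain] <- .branchLength(tree,
                                             losses$branch[onGain]) * 0.75
    }
    if (is.null(gainExposure))
        gainExposure <- sum(tree$edge.length) + .stemLength(tree)
    # a loss must lie on the gain branch or a descendant of it
    atOrBelow <- function(l, g) {
        (g == 0L || l != 0L) &&
            all(.tipsBelow(tree, l) %in% .tipsBelow(tree, g))
    }
    for (i in seq_len(nrow(losses))) {
        gi <- match(losses$gene[i], gains$gene)
        if (is.na(gi))
            stop("loss of a gene with no gain: ", losses$gene[i])
        if (!atOrBelow(losses$branch[i], gains$branch[gi]))
            stop("loss precedes gain for gene ", losses$gene[i])
    }
    if (is.null(lossExposure)) {
        lossExposure <- 0
        for (i in seq_len(nrow(gains))) {
            sel <- losses$gene == gains$gene[i]
            lossExposure <- lossExposure +
                .residency(tree, gains$branch[i], gains$time[i],
                           losses$branch[sel], losses$time[sel])
        }
    }
    new("EventMap", tree = tree,
        gains = DataFrame(gene = gains$gene,
                          branch = as.integer(gains$branch),
                          time = gains$time),
        losses = DataFrame(gene = as.character(losses$gene),
                           branch = as.integer(losses$branch),
                           time = as.numeric(losses$time)),
        gainExposure = gainExposure, lossExposure = lossExposure,
        trueRatio = trueRatio)
}

#' Aggregate per-gene acquisition scenarios into an event map
#'
#' Takes the scenarios returned by [inferAcquisitionBranch()] (a named list,
#' names being gene ids) and maps each gene's gain and Y-copy losses onto
#' the tree at branch midpoints. Source-copy losses concern the autosomal
#' copy and are not Y gene losses, so they do not enter the map. A scenario
#' whose loss is not below its gain is rejected.
#'
#' @param scenarios named list of [inferAcquisitionBranch()] results.
#' @param tree rooted `phylo` with branch lengths.
#' @return an [EventMap-class].
#' @export
buildEventMap <- function(scenarios, tree) {
    if (!length(scenarios))
        return(eventMap(tree,
                        data.frame(gene = character(0), branch = integer(0)),
                        lossExposure = 0))
    if (is.null(names(scenarios)))
        stop("scenarios must be a named list (names = gene ids)")
    gains <- data.frame(gene = names(scenarios),
                        branch = vapply(scenarios, `[[`, 0, "branch"))
    losses <- do.call(rbind, lapply(names(scenarios), function(g) {
        yl <- scenarios[[g]]$yLossBranches
        if (!length(yl)) return(NULL)
        data.frame(gene = g, branch = yl)
    }))
    # .residency() inside eventMap() errors on a loss that precedes its gain
    eventMap(tree, gains, losses)
}

#' Poisson gain-loss rate fit from event counts and exposures
#'
#' Model: gains ~ Poisson(g x My of branch time), losses ~ Poisson(l x
#' gene-My of Y-residency). ML estimates are G/T_gain and L/T_loss; the
#' reported ratio is their quotient after exposure normalization. The
#' p-value is a likelihood-ratio test of equal rates (chi-square, 1 df) and
#' the confidence interval is a profile-likelihood interval on the ratio,
#' solved on the log scale to a tolerance of 1e-8. With zero losses (or
#' zero gains) the estimate is a one-sided bound: the far bound of the CI
#' is infinite (or zero) and the result is flagged.
#'
#' @param gains,losses event counts G and L.
#' @param gainExposure total branch time (My).
#' @param lossExposure total gene-My of Y-residency.
#' @param conf confidence level (default 0.95).
#' @return a [GainLossEstimate-class].
#' @examples
#' gainLossFit(gains = 25, losses = 1, gainExposure = 250,
#'             lossExposure = 250)
#' @export
gainLossFit <- function(gains, losses, gainExposure, lossExposure,
                        conf = 0.95) {
    G <- as.integer(gains)
    L <- as.integer(losses)
    Tg <- gainExposure
    Tl <- lossExposure
    if (Tg + Tl <= 0)
        stop("total exposure must be > 0")
    if (G + L == 0L)
        stop("no events to fit")
    ll <- function(g, l) {
        (if (G > 0L) G * log(g) else 0) - g * Tg +
            (if (L > 0L) L * log(l) else 0) - l * Tl
    }
    ghat <- G / Tg
    lhat <- if (Tl > 0) L / Tl else 0
    llhat <- ll(ghat, lhat)
    r0 <- (G + L) / (Tg + Tl)
    stat <- max(0, 2 * (llhat - ll(r0, r0)))
    pValue <- pchisq(stat, df = 1L, lower.tail = FALSE)
    # profile log-likelihood of the ratio rho = g / l
    pl <- function(rho) {
        lr <- (G + L) / (rho * Tg + Tl)
        (if (G > 0L) G * log(rho * lr) else 0) +
            (if (L > 0L) L * log(lr) else 0) - (G + L)
    }
    q <- qchisq(conf, df = 1L) / 2
    if (L > 0L && G > 0L) {
        ratio <- ghat / lhat
        thr <- pl(ratio) - q
        boundary <- FALSE
    } else if (L == 0L) {
        ratio <- Inf
        thr <- (G * log(G / Tg) - G) - q     # supremum of the profile
        boundary <- TRUE
    } else {                                  # G == 0
        ratio <- 0
        thr <- (L * log(L / Tl) - L) - q
        boundary <- TRUE
    }
    f <- function(x) pl(exp(x)) - thr
    solveSide <- function(from, step) {
        # move `from` against `step` until inside the region (f >= 0),
        # then expand along `step` until f < 0 and bisect
        it0 <- 0L
        while (f(from) < 0 && it0 < 200L) {
            from <- from - step
            it0 <- it0 + 1L
        }
        x1 <- from
        x2 <- from + step
        it <- 0L
        while (f(x2) > 0 && it < 200L) {
            x1 <- x2
            x2 <- x2 + step
            it <- it + 1L
        }
        if (f(x2) > 0) return(if (step < 0) 0 else Inf)
        exp(uniroot(f, lower = min(x1, x2), upper = max(x1, x2),
                    tol = 1e-8)$root)
    }
    anchor <- if (is.finite(ratio) && ratio > 0) log(ratio)
              else if (L == 0L) log(G * Tl / Tg + 1) + 5
              else log(L * Tg / Tl + 1) * -1 - 5
    ciLow <- if (G == 0L) 0 else solveSide(anchor, -0.5)
    ciHigh <- if (L == 0L) Inf else solveSide(anchor, 0.5)
    new("GainLossEstimate", ratio = ratio, pValue = pValue,
        ciLow = ciLow, ciHigh = ciHigh, gains = G, losses = L,
        gainExposure = Tg, lossExposure = Tl, boundary = boundary)
}

#' @describeIn estimateGainLossRatio fit the Poisson rate model to an
#'   event map's counts and exposures.
#' @export
setMethod("estimateGainLossRatio", "EventMap", function(x, ...) {
    gainLossFit(nrow(x@gains), nrow(x@losses), x@gainExposure,
                x@lossExposure, ...)
})
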