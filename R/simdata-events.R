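#' @include AllClasses.R simdata.R
NULL

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Pseudogenize a coding sequence
#'
#' Introduces premature stop codons and frameshifting 1-bp indels into a CDS
#' at per-codon rates, returning the mutated sequence together with the list
#' of introduced defects, so downstream integrity checks can be validated
#' round-trip. Internal codons (all but the initial ATG and the terminal
#' stop) are eligible; each independently receives a stop with probability
#' `stopRate` and a frameshift (insertion or deletion of one base, equal
#' probability) with probability `frameshiftRate`. With both rates zero the
#' input is returned unchanged.
#'
#' @param cds coding sequence (character or `DNAString`): length a multiple
#'   of 3, at least 6 nt, starting with ATG.
#' @param stopRate per-codon probability of a premature stop.
#' @param frameshiftRate per-codon probability of a frameshifting indel.
#' @param seed integer RNG seed.
#' @return a list with `cds` (mutated sequence) and `events` (a `data.frame`
#'   with columns `type` in `"stop"`/`"frameshift"` and `codon`).
#' @examples
#' p <- pseudogenize("ATGAAACCCGGGTAA", stopRate = 1, frameshiftRate = 0,
#'                   seed = 1)
#' p$events
#' @export
pseudogenize <- function(cds, stopRate, frameshiftRate, seed = 1L) {
    cds <- as.character(cds)
    n <- nchar(cds)
    if (n < 6L)
        stop("CDS shorter than 6 nt")
    if (n %% 3L != 0L)
        stop("CDS length must be a multiple of 3")
    if (substring(cds, 1L, 3L) != "ATG")
        stop("CDS must start with ATG")
    nCodons <- n %/% 3L
    internal <- seq.int(2L, nCodons - 1L)
    events <- data.frame(type = character(0), codon = integer(0))
    if (length(internal) == 0L || (stopRate <= 0 && frameshiftRate <= 0))
        return(list(cds = cds, events = events))
    set.seed(as.integer(seed))
    codons <- substring(cds, 3L * seq_len(nCodons) - 2L, 3L * seq_len(nCodons))
    hitStop <- internal[runif(length(internal)) < stopRate]
    for (i in hitStop) {
        codons[i] <- sample(.STOP_CODONS, 1L)
        events <- rbind(events, data.frame(type = "stop", codon = i))
    }
    hitFs <- internal[runif(length(internal)) < frameshiftRate]
    for (i in hitFs) {
        if (runif(1) < 0.5) {
            codons[i] <- substring(codons[i], 2L)            # 1-bp deletion
        } else {
            codons[i] <- paste0(sample(.BASES, 1L), codons[i])  # insertion
        }
        events <- rbind(events, data.frame(type = "frameshift", codon = i))
    }
    events <- events[order(events$codon), , drop = FALSE]
    rownames(events) <- NULL
    list(cds = paste(codons, collapse = ""), events = events)
}

## --- gain/loss history simulation --------------------------------------

## edge bookkeeping on an ape tree: branch ids are rows of tree$edge, with
## branch 0 the stem above the root (length tree$root.edge or 0)
.stemLength <- function(tree) {
    if (is.null(tree$root.edge)) 0 else tree$root.edge
}

.branchLength <- function(tree, branch) {
    ifelse(branch == 0L, .stemLength(tree), tree$edge.length[branch])
}

.childNode <- function(tree, branch) {
    rootNode <- length(tree$tip.label) + 1L
    ifelse(branch == 0L, rootNode, tree$edge[branch, 2L])
}

.childBranches <- function(tree, node) {
    which(tree$edge[, 1L] == node)
}

#' Simulate a gain/loss event history on a species tree
#'
#' Gains are drawn per branch as Poisson(`gainRate` x branch time) at
#' uniform positions (the stem above the root, of length `tree$root.edge`,
#' is included). Each gained gene then survives down the tree, with losses
#' as the first event of an exponential clock at `lossRate` per gene per My
#' along every lineage of residency; a lineage loses the gene at most once
#' and a gene can only be lost after being gained. `ancestralGenes` are
#' treated as present from the top of the stem and are recorded as gains on
#' branch 0 at time 0.
#'
#' @param tree rooted `phylo` with branch lengths in My.
#' @param gainRate gains per My of branch time (>= 0).
#' @param lossRate losses per gene per My of Y-residency (>= 0).
#' @param seed integer RNG seed.
#' @param ancestralGenes character vector of genes resident at the root.
#' @return an [EventMap-class] with exact truth exposures and the generating
#'   ratio in its `trueRatio` slot.
#' @examples
#' tr <- ape::read.tree(text = "((a:10,b:10):10,(c:10,d:10):10):5;")
#' h <- simulateEventHistory(tr, gainRate = 0.2, lossRate = 0.02, seed = 1)
#' h
#' @export
simulateEventHistory <- function(tree, gainRate, lossRate, seed = 1L,
                                 ancestralGenes = character(0)) {
    stopifnot(inherits(tree, "phylo"))
    if (gainRate < 0 || lossRate < 0)
        stop("rates must be >= 0")
    if (is.null(tree$edge.length))
        stop("tree must have branch lengths")
    set.seed(as.integer(seed))
    nEdge <- nrow(tree$edge)
    branches <- 0:nEdge
    lens <- .branchLength(tree, branches)
    gains <- list()
    for (b in branches) {
        len <- lens[b + 1L]
        if (len <= 0 && b == 0L && length(ancestralGenes) == 0L) next
        ng <- if (gainRate > 0 && len > 0) rpois(1L, gainRate * len) else 0L
        if (ng > 0L)
            gains[[length(gains) + 1L]] <- data.frame(
                branch = b, time = sort(runif(ng, 0, len)))
    }
    gains <- if (length(gains)) do.call(rbind, gains) else
        data.frame(branch = integer(0), time = numeric(0))
    if (length(ancestralGenes))
        gains <- rbind(data.frame(branch = 0L,
                                  time = rep(0, length(ancestralGenes))),
                       gains)
    nGenes <- nrow(gains)
    gene <- if (length(ancestralGenes))
        c(ancestralGenes,
          sprintf("g%03d", seq_len(nGenes - length(ancestralGenes))))
    else sprintf("g%03d", seq_len(nGenes))
    losses <- list()
    residency <- 0
    for (i in seq_len(nGenes)) {
        # survival descent from (branch, time); iterative stack
        stack <- list(c(gains$branch[i], gains$time[i]))
        while (length(stack)) {
            fr <- stack[[length(stack)]]
            stack[[length(stack)]] <- NULL
            b <- fr[1L]; t0 <- fr[2L]
            len <- .branchLength(tree, b)
            rem <- len - t0
            x <- if (lossRate > 0) rexp(1L, lossRate) else Inf
            if (x < rem) {
                residency <- residency + x
                losses[[length(losses) + 1L]] <- data.frame(
                    gene = gene[i], branch = b, time = t0 + x)
            } else {
                residency <- residency + rem
                for (cb in .childBranches(tree, .childNode(tree, b)))
                    stack[[length(stack) + 1L]] <- c(cb, 0)
            }
        }
    }
    losses <- if (length(losses)) do.call(rbind, losses) else
        data.frame(gene = character(0), branch = integer(0),
                   time = numeric(0))
    new("EventMap", tree = tree,
        gains = DataFrame(gene = gene, branch = as.integer(gains$branch),
                          time = gains$time),
        losses = DataFrame(gene = losses$gene,
                           branch = as.integer(losses$branch),
                           time = losses$time),
        gainExposure = sum(tree$edge.length) + .stemLength(tree),
        lossExposure = residency,
        trueRatio = if (lossRate > 0) gainRate / lossRate else Inf)
}
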