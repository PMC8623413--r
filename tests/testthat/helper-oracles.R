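# Independent oracles: explicit string-set k-mer algebra and exhaustive
# scenario enumeration. Deliberately naive; no shared code with the package.

oracleRevComp <- function(x) {
    vapply(x, function(s) {
        paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "",
                           fixed = TRUE)[[1L]]), collapse = "")
    }, "", USE.NAMES = FALSE)
}

# every canonical k-mer window of one sequence (duplicates kept), windows
# containing non-ACGT characters excluded; the reverse complement of window
# i is the mirrored window of the reverse-complemented sequence
oracleKmerWindows <- function(seq, k) {
    L <- nchar(seq)
    n <- L - k + 1L
    if (n <= 0L) return(character(0))
    idx <- seq_len(n)
    w <- substring(seq, idx, idx + k - 1L)
    rcs <- oracleRevComp(seq)
    rw <- substring(rcs, L - k + 2L - idx, L + 1L - idx)
    keep <- !grepl("N", w, fixed = TRUE)
    w <- w[keep]
    rw <- rw[keep]
    ifelse(w <= rw, w, rw)
}

# distinct canonical k-mers of a read set, computed in chunks
oracleReadKmerSet <- function(reads, k, chunk = 40000L) {
    reads <- as.character(reads)
    parts <- list()
    i <- 1L
    while (i <= length(reads)) {
        j <- min(i + chunk - 1L, length(reads))
        w <- oracleKmerWindows(paste(reads[i:j], collapse = "N"), k)
        parts[[length(parts) + 1L]] <- unique(w)
        i <- j + 1L
    }
    unique(unlist(parts, use.names = FALSE))
}

# full YGS computation by explicit set algebra over k-mer strings
oracleYgs <- function(assembly, maleReads, femaleReads, k,
                      minValid = 20L, cutoff = 60) {
    seqs <- as.character(assembly)
    wins <- lapply(seqs, oracleKmerWindows, k = k)
    all <- sort(unlist(wins, use.names = FALSE), method = "radix")
    r <- rle(all)
    singles <- r$values[r$lengths == 1L]
    maleSet <- oracleReadKmerSet(maleReads, k)
    femaleSet <- oracleReadKmerSet(femaleReads, k)
    # one flat membership pass, then per-scaffold tallies
    flat <- unlist(wins, use.names = FALSE)
    scaf <- rep(seq_along(wins), lengths(wins))
    isSingle <- flat %in% singles
    isValid <- isSingle & flat %in% maleSet
    isUnmatched <- isValid & !flat %in% femaleSet
    nValid <- vapply(seq_along(wins), function(i)
        sum(isValid[scaf == i]), 0L)
    nUn <- vapply(seq_along(wins), function(i)
        sum(isUnmatched[scaf == i]), 0L)
    res <- data.frame(scaffold = names(assembly),
                      n_valid = as.integer(nValid),
                      pct_unmatched = ifelse(nValid > 0, 100 * nUn / nValid,
                                             NA_real_),
                      stringsAsFactors = FALSE)
    res$class <- ifelse(res$n_valid < minValid, "unclassified",
                        ifelse(res$pct_unmatched >= cutoff, "Y", "XA"))
    res
}

# ---- exhaustive single-origin parsimony -------------------------------

oracleTipsBelow <- function(tree, branch) {
    nt <- length(tree$tip.label)
    node <- if (branch == 0L) nt + 1L else tree$edge[branch, 2L]
    if (node <= nt) return(node)
    out <- integer(0)
    for (kk in tree$edge[tree$edge[, 1L] == node, 2L]) {
        out <- c(out, if (kk <= nt) kk else
            oracleTipsBelow(tree, which(tree$edge[, 2L] == kk)))
    }
    out
}

# per-branch minimal event counts by enumerating every loss-edge subset
oracleScenarioCosts <- function(states, tree) {
    nE <- nrow(tree$edge)
    branches <- 0:nE
    nb <- length(branches)
    below <- lapply(branches, function(b) oracleTipsBelow(tree, b))
    nt <- length(tree$tip.label)
    ancMask <- vapply(seq_len(nt), function(tip) {
        sum(2^(which(vapply(below, function(s) tip %in% s, TRUE)) - 1L))
    }, 0)
    states <- states[tree$tip.label]
    yTips <- which(states == "Y")
    xaTips <- which(states == "XA")
    abTips <- which(states == "absent")
    allS <- 0:(2^nb - 1L)
    popcnt <- vapply(allS, function(s)
        sum(bitwAnd(s, 2^(0:(nb - 1L))) > 0), 0)
    res <- data.frame(branch = branches, cost = NA_real_)
    # source-copy losses are independent of the gain branch
    okS <- rep(TRUE, length(allS))
    for (tip in xaTips)
        okS <- okS & bitwAnd(allS, ancMask[tip]) == 0
    for (tip in c(yTips, abTips))
        okS <- okS & bitwAnd(allS, ancMask[tip]) != 0
    srcMin <- if (any(okS)) min(popcnt[okS]) else Inf
    for (j in seq_len(nb)) {
        g <- branches[j]
        bel <- below[[j]]
        if (!all(yTips %in% bel)) next
        cladeMask <- sum(2^(which(vapply(below, function(s)
            all(s %in% bel), TRUE)) - 1L))
        okY <- rep(TRUE, length(allS))
        for (tip in intersect(yTips, bel))
            okY <- okY & bitwAnd(allS, bitwAnd(ancMask[tip], cladeMask)) == 0
        for (tip in intersect(c(xaTips, abTips), bel))
            okY <- okY & bitwAnd(allS, bitwAnd(ancMask[tip], cladeMask)) != 0
        if (!any(okY)) next
        res$cost[j] <- 1 + min(popcnt[okY]) + srcMin
    }
    res[!is.na(res$cost), , drop = FALSE]
}

# ---- misc fixtures ----------------------------------------------------

# random intact CDS: ATG, nCodons-2 non-stop codons, TAA
randomCds <- function(nCodons, seed = 1L) {
    set.seed(seed)
    b <- c("A", "C", "G", "T")
    codons <- apply(expand.grid(b, b, b), 1L, paste, collapse = "")
    codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
    paste0("ATG", paste(sample(codons, nCodons - 2L, replace = TRUE),
                        collapse = ""), "TAA")
}

# hand-built genome object from explicit sequences and class labels
makeGenome <- function(seqs, classes) {
    new("SyntheticGenome",
        sequences = Biostrings::DNAStringSet(seqs),
        truth = S4Vectors::DataFrame(scaffold = names(seqs),
                                     class = classes),
        repeats = Biostrings::DNAStringSet(),
        segdups = YTraffic:::.emptySegdupDF(),
        copyMap = YTraffic:::.emptyCopyMapDF())
}

randomSeq <- function(n, seed) {
    set.seed(seed)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
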