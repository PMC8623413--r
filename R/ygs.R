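#' @include AllClasses.R kmer.R
NULL

#' Classify scaffolds as Y-linked or X/autosomal from sexed read k-mers
#'
#' The chromosome-of-origin (YGS) procedure: for each scaffold, take the
#' k-mers occurring exactly once in the whole assembly ("single-copy"),
#' keep those also observed in the male read set ("valid", which screens
#' assembly artifacts), and score the scaffold by the percentage of valid
#' single-copy k-mers absent from the female read set. Scaffolds with fewer
#' than `minValid` valid k-mers are uninformative and left unclassified;
#' otherwise the scaffold is called `Y` when the percentage is at or above
#' `cutoff`, else `XA`.
#'
#' @param assembly `DNAStringSet` (or character vector) of scaffolds; must
#'   be named.
#' @param maleIndex,femaleIndex [KmerIndex-class] objects built from male
#'   and female reads with [buildKmerIndex()].
#' @param assemblyIndex optional precomputed assembly [KmerIndex-class];
#'   built from `assembly` when omitted.
#' @param minValid minimum number of valid single-copy k-mers required to
#'   classify a scaffold (default 20).
#' @param cutoff percent-unmatched threshold for calling Y (default 60; a
#'   tie at the cutoff classifies as Y).
#' @param femaleMinCount minimum female-read occurrences for a k-mer to
#'   count as matched (default 1).
#' @return a `DataFrame` with one row per scaffold: `scaffold`, `length_bp`,
#'   `n_kmers_total`, `n_single_copy`, `n_valid`, `n_unmatched_female`,
#'   `pct_unmatched`, `class`; parameters are stored in `metadata()`.
#'
#' @examples
#' g <- simulateGenome(genomeSpec(2, 1, 4000, seed = 1))
#' male <- simulateReads(g, readSimConfig("male", 15, seed = 2))
#' female <- simulateReads(g, readSimConfig("female", 15, seed = 3))
#' cls <- classifyScaffolds(genomeSequences(g),
#'     buildKmerIndex(simReads(male), 15, "male_reads"),
#'     buildKmerIndex(simReads(female), 15, "female_reads"))
#' cls[, c("scaffold", "pct_unmatched", "class")]
#' @export
classifyScaffolds <- function(assembly, maleIndex, femaleIndex,
                              assemblyIndex = NULL, minValid = 20L,
                              cutoff = 60, femaleMinCount = 1L) {
    stopifnot(is(maleIndex, "KmerIndex"), is(femaleIndex, "KmerIndex"))
    if (is.null(names(assembly)) || anyDuplicated(names(assembly)))
        stop("assembly scaffolds must have unique names")
    if (is.null(assemblyIndex))
        assemblyIndex <- buildKmerIndex(assembly, k = maleIndex@k,
                                        source = "assembly")
    k <- assemblyIndex@k
    if (maleIndex@k != k || femaleIndex@k != k)
        stop("all indexes must be built with the same k")
    seqs <- as.character(assembly)
    n <- length(seqs)
    res <- data.frame(scaffold = names(assembly),
                      length_bp = nchar(seqs),
                      n_kmers_total = integer(n),
                      n_single_copy = integer(n),
                      n_valid = integer(n),
                      n_unmatched_female = integer(n),
                      pct_unmatched = numeric(n),
                      class = character(n),
                      stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
        codes <- .canonicalCodes(seqs[i], k)
        res$n_kmers_total[i] <- length(codes)
        if (!length(codes)) {
            res$pct_unmatched[i] <- NA_real_
            next
        }
        sc <- codes[.lookupCounts(assemblyIndex, codes) == 1L]
        res$n_single_copy[i] <- length(sc)
        valid <- sc[.lookupCounts(maleIndex, sc) >= 1L]
        res$n_valid[i] <- length(valid)
        unmatched <- sum(.lookupCounts(femaleIndex, valid) < femaleMinCount)
        res$n_unmatched_female[i] <- unmatched
        res$pct_unmatched[i] <- if (length(valid))
            100 * unmatched / length(valid) else NA_real_
    }
    res$class <- ifelse(res$n_valid < minValid, "unclassified",
                        ifelse(res$pct_unmatched >= cutoff, "Y", "XA"))
    out <- DataFrame(res)
    metadata(out) <- list(k = k, minValid = as.integer(minValid),
                          cutoff = cutoff,
                          femaleMinCount = as.integer(femaleMinCount))
    out
}

#' Summarize a scaffold classification per class and cutoff
#'
#' Re-applies each cutoff to the percent-unmatched scores (the unclassified
#' set, fixed by `minValid`, is unaffected by the cutoff) and totals
#' scaffold counts and Mbp per class, plus a 1\%-resolution histogram of the
#' scores. Raising the cutoff can only shrink the Y class, so Y Mbp is
#' non-increasing in the cutoff.
#'
#' @param classification output of [classifyScaffolds()].
#' @param cutoffs numeric cutoffs to tabulate (default `c(60, 80)`).
#' @return a [YgsSummary-class].
#' @export
ygsSummary <- function(classification, cutoffs = c(60, 80)) {
    if (nrow(classification) == 0L)
        stop("empty classification")
    md <- metadata(classification)
    minValid <- if (!is.null(md$minValid)) md$minValid else 20L
    rows <- list()
    for (co in cutoffs) {
        cls <- ifelse(classification$n_valid < minValid, "unclassified",
                      ifelse(classification$pct_unmatched >= co, "Y", "XA"))
        for (cl in c("Y", "XA", "unclassified")) {
            sel <- cls == cl
            rows[[length(rows) + 1L]] <- data.frame(
                cutoff = co, class = cl, n_scaffolds = sum(sel),
                mbp = sum(classification$length_bp[sel]) / 1e6)
        }
    }
    pct <- classification$pct_unmatched[
        classification$class != "unclassified"]
    pct <- pct[!is.na(pct)]
    h <- tabulate(pmin(floor(pct), 100) + 1L, nbins = 101L)
    new("YgsSummary", totals = do.call(rbind, rows),
        histogram = as.integer(h), cutoffs = as.numeric(cutoffs),
        minValid = as.integer(minValid))
}

#' Write a per-scaffold classification table to TSV
#'
#' @param classification output of [classifyScaffolds()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeYgsTsv <- function(classification, path) {
    utils::write.table(as.data.frame(classification), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
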