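#' @include AllClasses.R
NULL

#' Size of a kb-coordinate interval
#'
#' Report convention for segmental-duplication coordinates: the size is the
#' plain difference of the kb endpoints (no +1), matching how published
#' duplication tables derive size from location.
#'
#' @param startKb,endKb interval endpoints in kb, `endKb >= startKb`.
#' @return `endKb - startKb`, vectorized.
#' @examples
#' intervalSizeKb(11183, 11448)  # 265
#' @export
intervalSizeKb <- function(startKb, endKb) {
    if (any(endKb < startKb))
        stop("end must be >= start")
    endKb - startKb
}

#' Segmental-duplication report with totals
#'
#' Validates per-duplication rows, recomputes `size_kb` from the kb
#' coordinates, and appends a totals row (column-wise sums of size and gene
#' counts). Genes that disappeared are the complement
#' `n_genes - n_functional - n_pseudogenes`.
#'
#' @param rows `data.frame` with columns `chr`, `scaffold`, `start_kb`,
#'   `end_kb`, `n_genes`, `n_functional`, `n_pseudogenes`.
#' @return a `data.frame` of the rows plus a final `total` row; `size_kb`
#'   is inserted after the coordinates.
#' @export
segdupTable <- function(rows) {
    rows <- as.data.frame(rows)
    need <- c("chr", "scaffold", "start_kb", "end_kb", "n_genes",
              "n_functional", "n_pseudogenes")
    if (!all(need %in% names(rows)))
        stop("missing columns: ",
             paste(setdiff(need, names(rows)), collapse = ", "))
    if (any(rows$n_functional + rows$n_pseudogenes > rows$n_genes))
        stop("functional + pseudogenes cannot exceed gene count")
    rows$size_kb <- intervalSizeKb(rows$start_kb, rows$end_kb)
    out <- rows[, c("chr", "scaffold", "start_kb", "end_kb", "size_kb",
                    "n_genes", "n_functional", "n_pseudogenes")]
    total <- data.frame(chr = "total", scaffold = NA_character_,
                        start_kb = NA_real_, end_kb = NA_real_,
                        size_kb = sum(out$size_kb),
                        n_genes = sum(out$n_genes),
                        n_functional = sum(out$n_functional),
                        n_pseudogenes = sum(out$n_pseudogenes))
    rbind(out, total)
}

#' Catalog of Y-linked genes
#'
#' Combines previously known Y-linked genes with newly identified ones.
#' A multicopy locus annotated under several names is supplied as one entry
#' (e.g. `"GK20618, GK20619"` or a character vector inside a list) and is
#' counted once.
#'
#' @param previouslyKnown character vector of known gene entries.
#' @param newGenes character vector or list of new gene entries (a list
#'   element with several ids is one multicopy entry).
#' @return a list with `n_total`, `n_known`, `n_new`, `n_multicopy` and the
#'   entry vectors.
#' @examples
#' geneCatalog(paste0("k", 1:8), as.list(paste0("n", 1:14)))$n_total  # 22
#' @export
geneCatalog <- function(previouslyKnown, newGenes) {
    if (!is.list(newGenes))
        newGenes <- lapply(strsplit(as.character(newGenes), ",\\s*"),
                           identity)
    knownIds <- unlist(strsplit(as.character(previouslyKnown), ",\\s*"))
    newIds <- unlist(newGenes)
    if (anyDuplicated(c(knownIds, newIds)))
        stop("duplicate gene ids across or within lists")
    list(n_total = length(previouslyKnown) + length(newGenes),
         n_known = length(previouslyKnown),
         n_new = length(newGenes),
         n_multicopy = sum(lengths(newGenes) > 1L),
         known = as.character(previouslyKnown),
         new = vapply(newGenes, paste, "", collapse = ", "))
}

#' Expected Y-chromosome depth of a pooled-sex library
#'
#' In a pool sequenced to `totalAutosomalDepth` fold-coverage on the
#' autosomes, only the male fraction carries a Y, and each male carries one
#' Y against two copies of each autosome, so the expected Y coverage is
#' `depth * maleFraction / 2` (8.4x from unsexed embryos gives 2.1x).
#'
#' @param totalAutosomalDepth autosomal fold-coverage of the pool (> 0).
#' @param maleFraction fraction of males in the pool, in [0, 1].
#' @return expected Y fold-coverage.
#' @examples
#' expectedYDepth(8.4, 0.5)  # 2.1
#' @export
expectedYDepth <- function(totalAutosomalDepth, maleFraction) {
    if (any(totalAutosomalDepth <= 0))
        stop("depth must be > 0")
    if (any(maleFraction < 0 | maleFraction > 1))
        stop("maleFraction must be in [0, 1]")
    totalAutosomalDepth * maleFraction / 2
}

#' Write and re-read a report table as TSV
#'
#' @param x a `data.frame` report.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeReportTsv <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeReportTsv
#' @export
readReportTsv <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
}
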