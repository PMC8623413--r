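#' @include AllClasses.R
#' @importFrom Biostrings DNAStringSet reverseComplement width writeXStringSet
#' @importFrom S4Vectors DataFrame
#' @importFrom stats rpois rbinom rexp runif median qchisq pchisq uniroot
NULL

.BASES <- c("A", "C", "G", "T")

.randomDNA <- function(n, gc) {
    if (n <= 0L) return("")
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(.BASES, n, replace = TRUE, prob = p), collapse = "")
}

.emptySegdupDF <- function() {
    DataFrame(scaffold = character(0), start = integer(0), end = integer(0),
              n_copies = integer(0))
}

.emptyCopyMapDF <- function() {
    DataFrame(copy = character(0), source_scaffold = character(0),
              source_start = integer(0), source_end = integer(0),
              n_substitutions = integer(0), n_indels = integer(0))
}

#' Construct a synthetic-genome specification
#'
#' @param nAutosomal number of autosomal/X ("XA") scaffolds.
#' @param nY number of Y scaffolds.
#' @param scaffoldLength scaffold length in bp (> 0).
#' @param repeatFraction fraction of each scaffold drawn from a shared repeat
#'   library planted on both XA and Y scaffolds, in [0, 1].
#' @param gc GC content in [0, 1].
#' @param seed integer RNG seed.
#' @return a [GenomeSpec-class].
#' @examples
#' genomeSpec(3, 2, 10000, repeatFraction = 0.1, seed = 7)
#' @export
genomeSpec <- function(nAutosomal, nY, scaffoldLength, repeatFraction = 0,
                       gc = 0.5, seed = 1L) {
    new("GenomeSpec", nAutosomal = as.integer(nAutosomal),
        nY = as.integer(nY), scaffoldLength = as.integer(scaffoldLength),
        repeatFraction = as.numeric(repeatFraction), gc = as.numeric(gc),
        seed = as.integer(seed))
}

#' Simulate a genome with labelled Y and XA scaffolds
#'
#' Background sequence is i.i.d. at the configured GC content. When
#' `repeatFraction > 0` a library of repeats (0.5-5 kb) is generated once and
#' copies are planted on every scaffold — the same repeats appear on Y and XA
#' scaffolds, so their k-mers are multi-copy in the assembly and must be
#' screened out by single-copy filtering downstream. The truth table is a
#' sidecar, never encoded in sequence headers.
#'
#' Determinism: the same spec (including seed) yields byte-identical
#' sequences.
#'
#' @param spec a [GenomeSpec-class], see [genomeSpec()].
#' @return a [SyntheticGenome-class]; scaffolds are named `A1..` and `Y1..`.
#' @examples
#' g <- simulateGenome(genomeSpec(2, 1, 5000, seed = 1))
#' genomeTruth(g)
#' @export
simulateGenome <- function(spec) {
    stopifnot(is(spec, "GenomeSpec"))
    validObject(spec)
    set.seed(spec@seed)
    L <- spec@scaffoldLength
    reps <- DNAStringSet()
    if (spec@repeatFraction > 0) {
        nrep <- 20L
        maxRep <- max(100L, L %/% 2L)
        lens <- pmin(sample(500:5000, nrep, replace = TRUE), maxRep)
        reps <- DNAStringSet(vapply(lens, .randomDNA, "", gc = spec@gc))
        names(reps) <- paste0("rep", seq_len(nrep))
    }
    buildScaffold <- function() {
        if (spec@repeatFraction == 0 || length(reps) == 0L)
            return(.randomDNA(L, spec@gc))
        target <- spec@repeatFraction * L
        pick <- integer(0)
        tot <- 0
        while (tot < target) {
            i <- sample.int(length(reps), 1L)
            pick <- c(pick, i)
            tot <- tot + width(reps)[i]
        }
        bgTotal <- max(0L, L - sum(width(reps)[pick]))
        # split background into length(pick)+1 chunks
        cuts <- sort(sample.int(bgTotal + 1L, length(pick), replace = TRUE)) - 1L
        chunk <- diff(c(0L, cuts, bgTotal))
        parts <- character(2L * length(pick) + 1L)
        for (j in seq_along(pick)) {
            parts[2L * j - 1L] <- .randomDNA(chunk[j], spec@gc)
            parts[2L * j] <- as.character(reps[[pick[j]]])
        }
        parts[length(parts)] <- .randomDNA(chunk[length(chunk)], spec@gc)
        substr(paste(parts, collapse = ""), 1L, L)
    }
    ids <- c(if (spec@nAutosomal > 0L) paste0("A", seq_len(spec@nAutosomal)),
             if (spec@nY > 0L) paste0("Y", seq_len(spec@nY)))
    cls <- c(rep("XA", spec@nAutosomal), rep("Y", spec@nY))
    seqs <- DNAStringSet(vapply(ids, function(i) buildScaffold(), ""))
    names(seqs) <- ids
    new("SyntheticGenome", sequences = seqs,
        truth = DataFrame(scaffold = ids, class = cls),
        repeats = reps, segdups = .emptySegdupDF(),
        copyMap = .emptyCopyMapDF())
}

#' Construct a read-simulation configuration
#'
#' @param sex `"male"`, `"female"` or `"pooled"`.
#' @param depth target autosomal fold-coverage.
#' @param readLength read length in bp (default 100, single-end).
#' @param errorRate per-base substitution probability in [0, 0.1].
#' @param maleFraction fraction of males in a pooled library (used only when
#'   `sex = "pooled"`; 0.5 emulates unsexed embryos).
#' @param seed integer RNG seed.
#' @return a [ReadSimConfig-class].
#' @examples
#' readSimConfig("female", depth = 10, seed = 2)
#' @export
readSimConfig <- function(sex, depth, readLength = 100L, errorRate = 0,
                          maleFraction = 0.5, seed = 1L) {
    new("ReadSimConfig", sex = sex, depth = as.numeric(depth),
        readLength = as.integer(readLength), errorRate = as.numeric(errorRate),
        maleFraction = as.numeric(maleFraction), seed = as.integer(seed))
}

## per-scaffold sampling rate given the sex model
.scaffoldRate <- function(class, config) {
    yFactor <- switch(config@sex,
        male = 0.5,                      # hemizygous: one Y per diploid male
        female = 0,
        pooled = config@maleFraction / 2)
    ifelse(class == "Y", config@depth * yFactor, config@depth)
}

#' Simulate a sexed short-read set
#'
#' Read starts are uniform along each scaffold; the number of reads per
#' scaffold is Poisson with mean chosen so the expected per-base depth on XA
#' scaffolds equals `depth`. Y scaffolds are sampled at half the autosomal
#' rate in males (hemizygosity), at zero rate in females, and at
#' `depth * maleFraction / 2` in pooled libraries. Substitution errors are
#' injected i.i.d. at `errorRate`.
#'
#' @param genome a [SyntheticGenome-class].
#' @param config a [ReadSimConfig-class].
#' @return a [SimulatedReads-class] whose placements record the true origin
#'   of every read (1-based closed scaffold coordinates).
#' @examples
#' g <- simulateGenome(genomeSpec(1, 1, 2000, seed = 1))
#' r <- simulateReads(g, readSimConfig("female", 5, seed = 3))
#' table(readPlacements(r)$scaffold)
#' @export
simulateReads <- function(genome, config) {
    stopifnot(is(genome, "SyntheticGenome"), is(config, "ReadSimConfig"))
    validObject(config)
    seqs <- genomeSequences(genome)
    if (length(seqs) == 0L)
        stop("empty scaffold set")
    rl <- config@readLength
    truth <- genomeTruth(genome)
    rate <- .scaffoldRate(truth$class[match(names(seqs), truth$scaffold)],
                          config)
    if (any(rate > 0 & width(seqs) < rl))
        stop("readLength exceeds the length of a sampled scaffold")
    set.seed(config@seed)
    readsBy <- vector("list", length(seqs))
    placBy <- vector("list", length(seqs))
    for (i in seq_along(seqs)) {
        if (rate[i] <= 0) next
        len <- width(seqs)[i]
        nStart <- len - rl + 1L
        lambda <- rate[i] * nStart / rl
        n <- rpois(1L, lambda)
        if (n == 0L) next
        starts <- sample.int(nStart, n, replace = TRUE)
        strand <- sample(c("+", "-"), n, replace = TRUE)
        frag <- substring(as.character(seqs[[i]]), starts, starts + rl - 1L)
        minus <- strand == "-"
        if (any(minus))
            frag[minus] <- as.character(
                reverseComplement(DNAStringSet(frag[minus])))
        if (config@errorRate > 0) {
            nerr <- rbinom(n, rl, config@errorRate)
            for (j in which(nerr > 0L)) {
                ch <- strsplit(frag[j], "", fixed = TRUE)[[1L]]
                pos <- sample.int(rl, nerr[j])
                for (p in pos) {
                    ch[p] <- sample(setdiff(.BASES, ch[p]), 1L)
                }
                frag[j] <- paste(ch, collapse = "")
            }
        }
        readsBy[[i]] <- frag
        placBy[[i]] <- data.frame(scaffold = names(seqs)[i], start = starts,
                                  end = starts + rl - 1L, strand = strand,
                                  stringsAsFactors = FALSE)
    }
    frag <- unlist(readsBy, use.names = FALSE)
    plac <- do.call(rbind, placBy)
    if (is.null(plac)) {
        reads <- DNAStringSet()
        placements <- DataFrame(read = character(0), scaffold = character(0),
                                start = integer(0), end = integer(0),
                                strand = character(0))
    } else {
        ids <- sprintf("r%06d", seq_along(frag))
        reads <- DNAStringSet(frag)
        names(reads) <- ids
        placements <- DataFrame(read = ids, scaffold = plac$scaffold,
                                start = as.integer(plac$start),
                                end = as.integer(plac$end),
                                strand = plac$strand)
    }
    new("SimulatedReads", reads = reads, placements = placements,
        config = config)
}

## mutate one sequence: substitutions at `divergence`, 1-bp indels at
## `indelRate` (insertion or deletion with equal probability)
.mutateCopy <- function(seq, divergence, indelRate) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
    n <- length(ch)
    nSub <- 0L
    nIndel <- 0L
    if (divergence > 0) {
        idx <- which(runif(n) < divergence)
        for (p in idx) ch[p] <- sample(setdiff(.BASES, ch[p]), 1L)
        nSub <- length(idx)
    }
    if (indelRate > 0) {
        idx <- which(runif(n) < indelRate)
        for (p in idx) {
            if (runif(1) < 0.5) {
                ch[p] <- ""                         # deletion
            } else {
                ch[p] <- paste0(sample(.BASES, 1L), ch[p])  # insertion
            }
        }
        nIndel <- length(idx)
    }
    list(seq = paste(ch, collapse = ""), nSub = nSub, nIndel = nIndel)
}

#' Implant an autosome-to-Y segmental duplication
#'
#' Copies an interval of a source scaffold `nCopies` times onto new Y
#' scaffolds, each copy independently mutated with point substitutions at
#' `divergence` and 1-bp indels at `indelRate`. The truth tables record the
#' interval, the copy count and the per-copy mutation counts. This emulates
#' multi-copy duplications that subsequently diverged inside the Y.
#'
#' @param genome a [SyntheticGenome-class].
#' @param scaffold source scaffold id.
#' @param start,end 1-based closed interval on the source scaffold.
#' @param nCopies number of Y copies (>= 1).
#' @param divergence per-base substitution probability per copy.
#' @param indelRate per-base indel probability per copy.
#' @param seed integer RNG seed.
#' @return the modified [SyntheticGenome-class]; copies are appended as Y
#'   scaffolds named `<scaffold>_Ydup<i>`.
#' @examples
#' g <- simulateGenome(genomeSpec(1, 0, 5000, seed = 1))
#' g2 <- implantSegdup(g, "A1", 1001, 2000, nCopies = 3, seed = 2)
#' segdupTruth(g2)
#' @export
implantSegdup <- function(genome, scaffold, start, end, nCopies,
                          divergence = 0, indelRate = 0, seed = 1L) {
    stopifnot(is(genome, "SyntheticGenome"))
    seqs <- genomeSequences(genome)
    if (!scaffold %in% names(seqs))
        stop("unknown source scaffold: ", scaffold)
    len <- width(seqs)[match(scaffold, names(seqs))]
    start <- as.integer(start); end <- as.integer(end)
    if (start < 1L || end > len || start > end)
        stop("interval outside scaffold")
    if (nCopies < 1L)
        stop("nCopies must be >= 1")
    set.seed(as.integer(seed))
    src <- substring(as.character(seqs[[scaffold]]), start, end)
    ids <- paste0(scaffold, "_Ydup", seq_len(nCopies))
    muts <- lapply(seq_len(nCopies), function(i)
        .mutateCopy(src, divergence, indelRate))
    copies <- DNAStringSet(vapply(muts, `[[`, "", "seq"))
    names(copies) <- ids
    newSeqs <- c(seqs, copies)
    truth <- rbind(genomeTruth(genome),
                   DataFrame(scaffold = ids, class = rep("Y", nCopies)))
    segdups <- rbind(segdupTruth(genome),
                     DataFrame(scaffold = scaffold, start = start, end = end,
                               n_copies = as.integer(nCopies)))
    cm <- rbind(copyMap(genome),
                DataFrame(copy = ids, source_scaffold = scaffold,
                          source_start = start, source_end = end,
                          n_substitutions =
                              vapply(muts, `[[`, 0L, "nSub"),
                          n_indels = vapply(muts, `[[`, 0L, "nIndel")))
    new("SyntheticGenome", sequences = newSeqs, truth = truth,
        repeats = repeatLibrary(genome), segdups = segdups, copyMap = cm)
}

#' Project read placements from duplication copies onto their source
#'
#' Reads sampled from implanted Y duplication scaffolds are relocated to the
#' corresponding interval of the autosomal source scaffold, emulating what a
#' read aligner does when male reads from the Y copies pile up on the source
#' region. Exact when copies were implanted without indels; with indels the
#' projection is approximate (offsets drift by the net indel length).
#'
#' @param reads a [SimulatedReads-class].
#' @param genome the [SyntheticGenome-class] carrying the copy map.
#' @return a `DataFrame` of placements with copy-derived reads relocated.
#' @export
placementsOnSource <- function(reads, genome) {
    plac <- readPlacements(reads)
    cm <- copyMap(genome)
    if (!nrow(cm)) return(plac)
    i <- match(plac$scaffold, cm$copy)
    hit <- !is.na(i)
    if (any(hit)) {
        off <- cm$source_start[i[hit]] - 1L
        srcEnd <- cm$source_end[i[hit]]
        plac$scaffold[hit] <- cm$source_scaffold[i[hit]]
        plac$start[hit] <- pmin(plac$start[hit] + off, srcEnd)
        plac$end[hit] <- pmin(plac$end[hit] + off, srcEnd)
    }
    plac
}

#' Deterministic expected-depth pileup over a duplicated interval
#'
#' Builds allele counts at every position where a Y copy differs from its
#' autosomal source, under the expected-depth model: the diploid source
#' contributes `maleDepth` (and `femaleDepth`) reads of the reference base in
#' each sex, and every hemizygous Y copy contributes `maleDepth / 2` male
#' reads of its own base. Useful for testing male-specific SNP counting
#' without an aligner. Copies must be indel-free (same length as source).
#'
#' @param sourceSeq source interval sequence (character or `DNAString`).
#' @param copies `DNAStringSet` or character vector of Y copies.
#' @param maleDepth,femaleDepth autosomal fold-coverage per sex.
#' @param scaffold scaffold id reported in the pileup.
#' @param sourceStart 1-based position of the first base of `sourceSeq`.
#' @return a `data.frame` of variant sites with columns `scaffold`, `pos`,
#'   `mA`, `mC`, `mG`, `mT`, `fA`, `fC`, `fG`, `fT`.
#' @export
pileupFromCopies <- function(sourceSeq, copies, maleDepth = 20,
                             femaleDepth = 20, scaffold = "src",
                             sourceStart = 1L) {
    src <- strsplit(as.character(sourceSeq), "", fixed = TRUE)[[1L]]
    copies <- as.character(copies)
    if (any(nchar(copies) != length(src)))
        stop("copies must be indel-free (same length as source)")
    cc <- lapply(copies, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
    diffAny <- Reduce(`|`, lapply(cc, function(ch) ch != src))
    pos <- which(diffAny)
    if (!length(pos)) {
        return(data.frame(scaffold = character(0), pos = integer(0),
                          mA = numeric(0), mC = numeric(0), mG = numeric(0),
                          mT = numeric(0), fA = numeric(0), fC = numeric(0),
                          fG = numeric(0), fT = numeric(0)))
    }
    m <- matrix(0, nrow = length(pos), ncol = 4L,
                dimnames = list(NULL, .BASES))
    f <- m
    srcIdx <- match(src[pos], .BASES)
    for (r in seq_along(pos)) {
        m[r, srcIdx[r]] <- maleDepth
        f[r, srcIdx[r]] <- femaleDepth
    }
    for (ch in cc) {
        ci <- match(ch[pos], .BASES)
        for (r in seq_along(pos)) m[r, ci[r]] <- m[r, ci[r]] + maleDepth / 2
    }
    data.frame(scaffold = scaffold, pos = sourceStart + pos - 1L,
               mA = m[, 1], mC = m[, 2], mG = m[, 3], mT = m[, 4],
               fA = f[, 1], fC = f[, 2], fG = f[, 3], fT = f[, 4])
}

#' Named scaffold lengths of a genome
#'
#' @param genome a [SyntheticGenome-class] (or any named `DNAStringSet`).
#' @return named integer vector of lengths in bp, as [binDepth()] expects.
#' @export
scaffoldLengths <- function(genome) {
    seqs <- if (is(genome, "SyntheticGenome")) genomeSequences(genome)
            else genome
    stats::setNames(width(seqs), names(seqs))
}

#' Write synthetic data to standard formats
#'
#' Writes scaffolds as FASTA, reads as FASTQ (constant quality), and the
#' truth tables as TSV sidecars.
#'
#' @param genome a [SyntheticGenome-class].
#' @param dir output directory (created if missing).
#' @param reads optional named list of [SimulatedReads-class] objects; each
#'   is written as `<name>.fastq`.
#' @return invisibly, the paths written.
#' @export
exportSyntheticData <- function(genome, dir, reads = list()) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(dir, "scaffolds.fasta")
    writeXStringSet(genomeSequences(genome), paths)
    tp <- file.path(dir, "truth.tsv")
    utils::write.table(as.data.frame(genomeTruth(genome)), tp, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, tp)
    if (nrow(segdupTruth(genome))) {
        sp <- file.path(dir, "segdups.tsv")
        utils::write.table(as.data.frame(segdupTruth(genome)), sp, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        paths <- c(paths, sp)
    }
    for (nm in names(reads)) {
        rp <- file.path(dir, paste0(nm, ".fastq"))
        rr <- simReads(reads[[nm]])
        writeXStringSet(rr, rp, format = "fastq",
                        qualities = Biostrings::BStringSet(
                            strrep("I", width(rr))))
        paths <- c(paths, rp)
    }
    invisible(paths)
}
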