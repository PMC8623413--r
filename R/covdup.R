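#' @include AllClasses.R
#' @importFrom IRanges IRanges Views coverage viewMeans
#' @importFrom GenomicRanges GRanges seqnames start end mcols mcols<-
#' @importFrom S4Vectors Rle runValue
NULL

#' Bin read depth along scaffolds
#'
#' Computes mean per-base depth in non-overlapping bins (default 1 kb; the
#' last bin of a scaffold may be shorter). Input is either a table of read
#' placements (columns `scaffold`, `start`, `end`, 1-based closed — e.g.
#' [readPlacements()] output or [placementsOnSource()]) or a per-base depth
#' table (columns `scaffold`, `pos`, `depth`, 1-based), the shape produced
#' by standard depth tools. Every base of every scaffold belongs to exactly
#' one bin; bases with no reads count as depth 0.
#'
#' @param x placements or per-base depth `data.frame`/`DataFrame`.
#' @param scaffoldLengths named vector of scaffold lengths in bp.
#' @param binBp bin width in bp (>= 100).
#' @return a `data.frame` with columns `scaffold`, `start`, `end` (0-based
#'   half-open), `depth`.
#' @export
binDepth <- function(x, scaffoldLengths, binBp = 1000L) {
    binBp <- as.integer(binBp)
    if (binBp < 100L)
        stop("binBp must be >= 100")
    x <- as.data.frame(x)
    perBase <- all(c("pos", "depth") %in% names(x))
    if (!perBase && !all(c("start", "end") %in% names(x)))
        stop("x must have columns scaffold/start/end or scaffold/pos/depth")
    if (perBase && any(x$depth < 0))
        stop("negative depths")
    if (is.null(names(scaffoldLengths)))
        stop("scaffoldLengths must be named")
    out <- vector("list", length(scaffoldLengths))
    for (i in seq_along(scaffoldLengths)) {
        sc <- names(scaffoldLengths)[i]
        len <- as.integer(scaffoldLengths[i])
        starts0 <- seq.int(0L, len - 1L, by = binBp)
        ends0 <- pmin(starts0 + binBp, len)
        sub <- x[x$scaffold == sc, , drop = FALSE]
        if (perBase) {
            cov <- numeric(len)
            if (nrow(sub)) cov[sub$pos] <- sub$depth
            cs <- c(0, cumsum(cov))
            depth <- (cs[ends0 + 1L] - cs[starts0 + 1L]) / (ends0 - starts0)
        } else if (nrow(sub)) {
            cov <- coverage(IRanges(pmax(sub$start, 1L),
                                    pmin(sub$end, len)), width = len)
            depth <- viewMeans(Views(cov, start = starts0 + 1L,
                                     end = ends0))
        } else {
            depth <- numeric(length(starts0))
        }
        out[[i]] <- data.frame(scaffold = sc, start = starts0, end = ends0,
                               depth = as.numeric(depth))
    }
    do.call(rbind, out)
}

#' Median autosomal baseline depth
#'
#' Baseline for sex-depth normalization: the median bin depth over
#' confidently XA-classified scaffolds, robust to the duplications being
#' sought.
#'
#' @param bins output of [binDepth()].
#' @param xaScaffolds character vector of XA scaffold ids (e.g. from
#'   [classifyScaffolds()]).
#' @return a positive scalar.
#' @export
autosomalBaseline <- function(bins, xaScaffolds) {
    sel <- bins$scaffold %in% xaScaffolds
    if (!any(sel))
        stop("no bins on the given XA scaffolds")
    b <- median(bins$depth[sel])
    if (b <= 0)
        stop("zero baseline")
    b
}

#' Normalize male and female depth tracks to their autosomal baselines
#'
#' Divides each sex's binned depth by its autosomal diploid baseline, so an
#' unduplicated autosomal bin sits near 1.0 in both sexes and each
#' hemizygous Y copy of a region adds about 0.5 to the normalized male
#' track. Bins with zero female depth but positive male depth are flagged
#' as candidate Y-only sequence.
#'
#' @param maleBins,femaleBins outputs of [binDepth()] over the same bins.
#' @param maleBaseline,femaleBaseline baseline depths (> 0); computed with
#'   [autosomalBaseline()] over `xaScaffolds` when omitted.
#' @param xaScaffolds XA scaffold ids used when baselines are omitted.
#' @return a `data.frame` track: `scaffold`, `start`, `end`, `male_norm`,
#'   `female_norm`, `female_zero`.
#' @export
normalizeDepth <- function(maleBins, femaleBins, maleBaseline = NULL,
                           femaleBaseline = NULL, xaScaffolds = NULL) {
    key <- function(b) paste(b$scaffold, b$start)
    if (nrow(maleBins) != nrow(femaleBins) ||
        !all(key(maleBins) == key(femaleBins)))
        stop("male and female bins must cover identical intervals")
    if (is.null(maleBaseline))
        maleBaseline <- autosomalBaseline(maleBins, xaScaffolds)
    if (is.null(femaleBaseline))
        femaleBaseline <- autosomalBaseline(femaleBins, xaScaffolds)
    if (maleBaseline <= 0 || femaleBaseline <= 0)
        stop("zero baseline")
    data.frame(scaffold = maleBins$scaffold, start = maleBins$start,
               end = maleBins$end,
               male_norm = maleBins$depth / maleBaseline,
               female_norm = femaleBins$depth / femaleBaseline,
               female_zero = femaleBins$depth == 0 & maleBins$depth > 0)
}

#' Call segmental duplications from a normalized male/female track
#'
#' Replaces visual inspection of coverage with an explicit rule: maximal
#' runs of bins with normalized male depth at or above `minMaleNorm` and
#' normalized female depth below `minMaleNorm`, allowing interruptions of up
#' to `maxGapBins` bins, are emitted as calls when they span at least
#' `minLenBp`. Coordinates are bin-aligned. The default threshold of 1.4
#' makes a single hemizygous Y copy (expected normalized male 1.5) the
#' smallest detectable event.
#'
#' @param track output of [normalizeDepth()].
#' @param minMaleNorm male-elevation threshold (default 1.4).
#' @param minLenBp minimum call span in bp (default 10000).
#' @param maxGapBins maximum run interruption in bins (default 5).
#' @return a `GRanges` (1-based) with metadata columns `mean_male_norm`,
#'   `mean_female_norm`, `n_bins`; zero-length when nothing is called.
#' @export
callSegdups <- function(track, minMaleNorm = 1.4, minLenBp = 10000L,
                        maxGapBins = 5L) {
    if (!nrow(track))
        stop("track is empty")
    calls <- list()
    for (sc in unique(track$scaffold)) {
        tr <- track[track$scaffold == sc, , drop = FALSE]
        tr <- tr[order(tr$start), , drop = FALSE]
        elev <- which(tr$male_norm >= minMaleNorm &
                      tr$female_norm < minMaleNorm)
        if (!length(elev)) next
        grp <- cumsum(c(1L, diff(elev) > maxGapBins + 1L))
        for (g in unique(grp)) {
            bins <- elev[grp == g]
            s0 <- tr$start[bins[1L]]
            e0 <- tr$end[bins[length(bins)]]
            if (e0 - s0 < minLenBp) next
            inside <- tr$start >= s0 & tr$end <= e0
            calls[[length(calls) + 1L]] <- data.frame(
                scaffold = sc, start = s0 + 1L, end = e0,
                mean_male_norm = mean(tr$male_norm[inside]),
                mean_female_norm = mean(tr$female_norm[inside]),
                n_bins = sum(inside))
        }
    }
    if (!length(calls)) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(mean_male_norm = numeric(0),
                               mean_female_norm = numeric(0),
                               n_bins = integer(0))
        return(gr)
    }
    df <- do.call(rbind, calls)
    gr <- GRanges(df$scaffold, IRanges(df$start, df$end))
    mcols(gr) <- DataFrame(mean_male_norm = df$mean_male_norm,
                           mean_female_norm = df$mean_female_norm,
                           n_bins = df$n_bins)
    gr
}

#' Estimate the intra-Y copy number of segmental-duplication calls
#'
#' With the diploid autosomal source still present, one hemizygous Y copy
#' adds 0.5 to the normalized male depth over the source region, so n Y
#' copies give a normalized male depth of about 1 + n/2 against a female
#' depth of 1. The estimate is `round(2 * (mean male norm - mean female
#' norm))` over the call; a nonpositive estimate is reported as 1 with a
#' low-confidence flag.
#'
#' @param calls `GRanges` from [callSegdups()].
#' @param track output of [normalizeDepth()].
#' @return `calls` with metadata columns `est_copies` (integer >= 1) and
#'   `low_confidence` (logical) added.
#' @export
estimateCopyNumber <- function(calls, track) {
    n <- length(calls)
    est <- integer(n)
    low <- logical(n)
    for (i in seq_len(n)) {
        sc <- as.character(seqnames(calls)[i])
        s0 <- start(calls)[i] - 1L
        e0 <- end(calls)[i]
        sel <- track$scaffold == sc & track$start >= s0 & track$end <= e0
        if (!any(sel))
            stop("call does not overlap the track")
        raw <- round(2 * (mean(track$male_norm[sel]) -
                          mean(track$female_norm[sel])))
        if (raw < 1) {
            est[i] <- 1L
            low[i] <- TRUE
        } else {
            est[i] <- as.integer(raw)
        }
    }
    mcols(calls)$est_copies <- est
    mcols(calls)$low_confidence <- low
    calls
}

#' Count male-specific SNP sites in a pileup
#'
#' A site is male-specific when some allele is seen in at least
#' `minMaleAlt` male reads making up at least `minMaleFraction` of the male
#' depth, with zero female reads of that allele while the female depth is at
#' least `minFemaleDepth` — the diagnostic for a diverged Y-linked copy of
#' the region.
#'
#' @param sites pileup `data.frame` with columns `scaffold`, `pos` and
#'   allele counts `mA`, `mC`, `mG`, `mT`, `fA`, `fC`, `fG`, `fT`.
#' @param region optional restriction: a `GRanges` of length 1 or a list
#'   with `scaffold`, `start`, `end` (1-based closed).
#' @param minMaleAlt minimum male reads of the allele (default 3).
#' @param minMaleFraction minimum fraction of male depth (default 0.1).
#' @param minFemaleDepth minimum female depth for the site to be assessable
#'   (default 5).
#' @return integer count of male-specific sites.
#' @export
countMaleSpecificSnps <- function(sites, region = NULL, minMaleAlt = 3L,
                                  minMaleFraction = 0.1,
                                  minFemaleDepth = 5L) {
    if (!is.null(region)) {
        if (is(region, "GRanges")) {
            region <- list(scaffold = as.character(seqnames(region)[1L]),
                           start = start(region)[1L], end = end(region)[1L])
        }
        sites <- sites[sites$scaffold == region$scaffold &
                       sites$pos >= region$start &
                       sites$pos <= region$end, , drop = FALSE]
    }
    if (!nrow(sites)) return(0L)
    m <- as.matrix(sites[, c("mA", "mC", "mG", "mT")])
    f <- as.matrix(sites[, c("fA", "fC", "fG", "fT")])
    maleDepth <- rowSums(m)
    femaleDepth <- rowSums(f)
    ok <- m >= minMaleAlt & m >= minMaleFraction * maleDepth & f == 0
    sum(rowSums(ok) > 0 & femaleDepth >= minFemaleDepth)
}

#' Write segmental-duplication calls as BED (plus TSV of evidence)
#'
#' @param calls `GRanges` of calls (optionally with copy-number columns).
#' @param path output BED path; a sibling `.tsv` with all metadata columns
#'   is written alongside.
#' @return invisibly, the BED path.
#' @export
writeSegdupBed <- function(calls, path) {
    bed <- data.frame(chrom = as.character(seqnames(calls)),
                      start = start(calls) - 1L, end = end(calls))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    tsv <- cbind(bed, as.data.frame(mcols(calls)))
    utils::write.table(tsv, sub("\\.bed$", ".tsv", path), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
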