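#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom Biostrings DNAStringSet
NULL

#' Parameters of a synthetic genome
#'
#' Describes the synthetic genome the simulator builds: a set of autosomal/X
#' ("XA") scaffolds and a set of Y scaffolds of fixed length, with a
#' configurable fraction of each scaffold drawn from a shared repeat library
#' (the same repeat sequences are planted on XA and Y scaffolds, so that
#' single-copy k-mer filtering is exercised downstream).
#'
#' @slot nAutosomal number of XA scaffolds.
#' @slot nY number of Y scaffolds.
#' @slot scaffoldLength length of every scaffold in bp.
#' @slot repeatFraction approximate fraction of each scaffold covered by
#'   planted repeats, in [0, 1].
#' @slot gc GC content of background sequence and repeats, in [0, 1].
#' @slot seed integer RNG seed; the same spec yields byte-identical output.
#'
#' @seealso [genomeSpec()], [simulateGenome()]
#' @exportClass GenomeSpec
setClass("GenomeSpec",
    representation(
        nAutosomal = "integer",
        nY = "integer",
        scaffoldLength = "integer",
        repeatFraction = "numeric",
        gc = "numeric",
        seed = "integer"
    )
)

setValidity("GenomeSpec", function(object) {
    msg <- character(0)
    if (object@nAutosomal < 0L || object@nY < 0L)
        msg <- c(msg, "scaffold counts must be non-negative")
    if (object@nAutosomal + object@nY == 0L)
        msg <- c(msg, "at least one scaffold must be requested")
    if (object@scaffoldLength <= 0L)
        msg <- c(msg, "scaffoldLength must be > 0")
    if (object@repeatFraction < 0 || object@repeatFraction > 1)
        msg <- c(msg, "repeatFraction must be in [0, 1]")
    if (object@gc < 0 || object@gc > 1)
        msg <- c(msg, "gc must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Synthetic genome with ground truth
#'
#' Container returned by [simulateGenome()] and extended by
#' [implantSegdup()]: the scaffold sequences, a sidecar truth table labelling
#' every scaffold as Y or XA, the shared repeat library, and (after
#' implantation) the implanted-interval table and the per-copy map from Y
#' duplication scaffolds back to their source interval.
#'
#' @slot sequences `DNAStringSet` of scaffolds.
#' @slot truth `DataFrame` with columns `scaffold`, `class` (`"Y"`/`"XA"`).
#' @slot repeats `DNAStringSet`, the shared repeat library.
#' @slot segdups `DataFrame` of implanted intervals
#'   (`scaffold`, `start`, `end`, `n_copies`), 1-based closed coordinates.
#' @slot copyMap `DataFrame` mapping each implanted copy scaffold to its
#'   source (`copy`, `source_scaffold`, `source_start`, `source_end`,
#'   `n_substitutions`, `n_indels`).
#'
#' @exportClass SyntheticGenome
setClass("SyntheticGenome",
    representation(
        sequences = "DNAStringSet",
        truth = "DataFrame",
        repeats = "DNAStringSet",
        segdups = "DataFrame",
        copyMap = "DataFrame"
    )
)

setValidity("SyntheticGenome", function(object) {
    msg <- character(0)
    if (length(object@sequences) != nrow(object@truth))
        msg <- c(msg, "every sequence must have exactly one truth entry")
    if (!setequal(names(object@sequences), object@truth$scaffold))
        msg <- c(msg, "truth scaffold ids must match sequence names")
    if (nrow(object@segdups)) {
        len <- width(object@sequences)[match(object@segdups$scaffold,
                                             names(object@sequences))]
        bad <- object@segdups$start < 1L | object@segdups$end > len |
            object@segdups$start > object@segdups$end
        if (any(bad | is.na(bad)))
            msg <- c(msg, "implanted intervals must lie within their scaffold")
    }
    if (length(msg)) msg else TRUE
})

#' Read-simulation parameters
#'
#' Sex-aware sampling model: female read sets sample zero fragments from Y
#' scaffolds; male read sets sample Y scaffolds at half the autosomal rate
#' (hemizygosity); `sex = "pooled"` mixes the two with `maleFraction`, so an
#' unsexed pool at `maleFraction = 0.5` yields a Y depth of one quarter of
#' the autosomal depth (e.g. 8.4x autosomal -> 2.1x Y).
#'
#' @slot sex one of `"male"`, `"female"`, `"pooled"`.
#' @slot depth target autosomal fold-coverage (> 0).
#' @slot readLength read length in bp.
#' @slot errorRate per-base substitution probability, in [0, 0.1].
#' @slot maleFraction fraction of male individuals in a pooled library.
#' @slot seed integer RNG seed.
#'
#' @seealso [readSimConfig()], [simulateReads()]
#' @exportClass ReadSimConfig
setClass("ReadSimConfig",
    representation(
        sex = "character",
        depth = "numeric",
        readLength = "integer",
        errorRate = "numeric",
        maleFraction = "numeric",
        seed = "integer"
    )
)

setValidity("ReadSimConfig", function(object) {
    msg <- character(0)
    if (!object@sex %in% c("male", "female", "pooled"))
        msg <- c(msg, "sex must be 'male', 'female' or 'pooled'")
    if (object@depth <= 0)
        msg <- c(msg, "depth must be > 0")
    if (object@readLength <= 0L)
        msg <- c(msg, "readLength must be > 0")
    if (object@errorRate < 0 || object@errorRate > 0.1)
        msg <- c(msg, "errorRate must be in [0, 0.1]")
    if (object@maleFraction < 0 || object@maleFraction > 1)
        msg <- c(msg, "maleFraction must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Simulated read set with provenance
#'
#' Reads plus a placement table recording where every read was sampled from
#' (truth provenance used by depth binning and by tests; it is never written
#' into FASTQ headers consumed downstream).
#'
#' @slot reads `DNAStringSet` of reads.
#' @slot placements `DataFrame` with columns `read`, `scaffold`, `start`,
#'   `end` (1-based closed), `strand`.
#' @slot config the [ReadSimConfig-class] used.
#'
#' @exportClass SimulatedReads
setClass("SimulatedReads",
    representation(
        reads = "DNAStringSet",
        placements = "DataFrame",
        config = "ReadSimConfig"
    )
)

setValidity("SimulatedReads", function(object) {
    if (length(object@reads) != nrow(object@placements))
        return("one placement row per read is required")
    TRUE
})

#' Canonical k-mer index
#'
#' Occurrence counts of canonical k-mers (lexicographic minimum of a k-mer
#' and its reverse complement) over a sequence set; windows containing
#' non-ACGT symbols are excluded. Codes are 2-bit packed into doubles and
#' kept sorted, so membership lookups are binary searches.
#'
#' @slot k k-mer length (7-26).
#' @slot codes sorted numeric vector of distinct canonical k-mer codes.
#' @slot counts integer vector of occurrence counts, parallel to `codes`.
#' @slot source label: `"assembly"`, `"male_reads"` or `"female_reads"`.
#'
#' @seealso [buildKmerIndex()]
#' @exportClass KmerIndex
setClass("KmerIndex",
    representation(
        k = "integer",
        codes = "numeric",
        counts = "integer",
        source = "character"
    )
)

setValidity("KmerIndex", function(object) {
    msg <- character(0)
    if (object@k < 7L || object@k > 26L)
        msg <- c(msg, "k must be in [7, 26]")
    if (length(object@codes) != length(object@counts))
        msg <- c(msg, "codes and counts must be parallel")
    if (length(object@counts) && any(object@counts < 1L))
        msg <- c(msg, "counts must be >= 1")
    if (is.unsorted(object@codes, strictly = TRUE))
        msg <- c(msg, "codes must be strictly sorted")
    if (length(msg)) msg else TRUE
})

#' Per-class summary of a YGS classification
#'
#' @slot totals `data.frame` with one row per (cutoff, class): scaffold count
#'   and Mbp.
#' @slot histogram integer vector of scaffold counts of percent-unmatched
#'   values binned at 1\% resolution (bins `[0,1), ..., [99,100), [100]`).
#' @slot cutoffs numeric cutoffs summarized.
#' @slot minValid minimum number of valid single-copy k-mers used.
#'
#' @seealso [ygsSummary()]
#' @exportClass YgsSummary
setClass("YgsSummary",
    representation(
        totals = "data.frame",
        histogram = "integer",
        cutoffs = "numeric",
        minValid = "integer"
    )
)

#' Gains and losses mapped onto a species tree
#'
#' Branches are identified by the row index of `tree$edge` (the `ape`
#' convention); branch `0` denotes the stem above the root (length
#' `tree$root.edge`, or 0 when absent). Exposures are the denominators of
#' the Poisson rate model: total branch time (My) for gains, and total
#' gene-My of Y-residency for losses.
#'
#' @slot tree rooted `phylo` object with branch lengths.
#' @slot gains `DataFrame` with columns `gene`, `branch`, `time` (time from
#'   the start of the branch at which the gain occurred).
#' @slot losses `DataFrame` with columns `gene`, `branch`, `time`.
#' @slot gainExposure total branch time in My.
#' @slot lossExposure total gene-My of Y-residency.
#' @slot trueRatio generating gain/loss rate ratio when simulated, else `NA`.
#'
#' @seealso [simulateEventHistory()], [buildEventMap()], [eventMap()]
#' @exportClass EventMap
setClass("EventMap",
    representation(
        tree = "ANY",
        gains = "DataFrame",
        losses = "DataFrame",
        gainExposure = "numeric",
        lossExposure = "numeric",
        trueRatio = "numeric"
    )
)

setValidity("EventMap", function(object) {
    msg <- character(0)
    if (!inherits(object@tree, "phylo"))
        msg <- c(msg, "tree must be a 'phylo' object")
    if (object@gainExposure < 0 || object@lossExposure < 0)
        msg <- c(msg, "exposures must be non-negative")
    if (nrow(object@losses) &&
        !all(object@losses$gene %in% object@gains$gene))
        msg <- c(msg, "every lost gene must have a gain event")
    if (length(msg)) msg else TRUE
})

#' Gain-loss rate-ratio estimate
#'
#' @slot ratio ML estimate of gain rate / loss rate (exposure-normalized,
#'   dimensionless); `Inf` when no losses were observed.
#' @slot pValue likelihood-ratio test p-value against equal rates.
#' @slot ciLow,ciHigh 95\% profile-likelihood interval bounds.
#' @slot gains,losses observed event counts G and L.
#' @slot gainExposure,lossExposure the exposures used.
#' @slot boundary `TRUE` when G or L is zero and the estimate is only a
#'   one-sided bound.
#'
#' @seealso [estimateGainLossRatio()]
#' @exportClass GainLossEstimate
setClass("GainLossEstimate",
    representation(
        ratio = "numeric",
        pValue = "numeric",
        ciLow = "numeric",
        ciHigh = "numeric",
        gains = "integer",
        losses = "integer",
        gainExposure = "numeric",
        lossExposure = "numeric",
        boundary = "logical"
    )
)

setValidity("GainLossEstimate", function(object) {
    msg <- character(0)
    if (!is.infinite(object@ratio) && object@ratio < 0)
        msg <- c(msg, "ratio must be >= 0")
    if (object@losses > 0L && object@gains > 0L &&
        (object@ciLow > object@ratio || object@ciHigh < object@ratio))
        msg <- c(msg, "CI must bracket the estimate")
    if (length(msg)) msg else TRUE
})
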