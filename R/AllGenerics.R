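#' @include AllClasses.R
NULL

#' Accessors for simulation and result containers
#'
#' Slot accessors for the package's S4 containers; prefer these over direct
#' slot access.
#'
#' @param x an object of the documented class.
#' @return the requested component.
#' @name accessors
#' @aliases genomeSequences genomeTruth repeatLibrary segdupTruth copyMap
#'   simReads readPlacements kmerLength kmerSource nDistinctKmers gainEvents
#'   lossEvents gainExposure lossExposure ratioEstimate
#'
#' @examples
#' g <- simulateGenome(genomeSpec(2, 1, 5000, seed = 1))
#' genomeSequences(g)
#' head(genomeTruth(g))
NULL

#' @rdname accessors
#' @export
setGeneric("genomeSequences", function(x) standardGeneric("genomeSequences"))
#' @rdname accessors
#' @export
setGeneric("genomeTruth", function(x) standardGeneric("genomeTruth"))
#' @rdname accessors
#' @export
setGeneric("repeatLibrary", function(x) standardGeneric("repeatLibrary"))
#' @rdname accessors
#' @export
setGeneric("segdupTruth", function(x) standardGeneric("segdupTruth"))
#' @rdname accessors
#' @export
setGeneric("copyMap", function(x) standardGeneric("copyMap"))
#' @rdname accessors
#' @export
setGeneric("simReads", function(x) standardGeneric("simReads"))
#' @rdname accessors
#' @export
setGeneric("readPlacements", function(x) standardGeneric("readPlacements"))
#' @rdname accessors
#' @export
setGeneric("kmerLength", function(x) standardGeneric("kmerLength"))
#' @rdname accessors
#' @export
setGeneric("kmerSource", function(x) standardGeneric("kmerSource"))
#' @rdname accessors
#' @export
setGeneric("nDistinctKmers", function(x) standardGeneric("nDistinctKmers"))
#' @rdname accessors
#' @export
setGeneric("gainEvents", function(x) standardGeneric("gainEvents"))
#' @rdname accessors
#' @export
setGeneric("lossEvents", function(x) standardGeneric("lossEvents"))
#' @rdname accessors
#' @export
setGeneric("gainExposure", function(x) standardGeneric("gainExposure"))
#' @rdname accessors
#' @export
setGeneric("lossExposure", function(x) standardGeneric("lossExposure"))
#' @rdname accessors
#' @export
setGeneric("ratioEstimate", function(x) standardGeneric("ratioEstimate"))

#' Estimate the gain-loss rate ratio
#'
#' @param x an [EventMap-class] (or see [gainLossFit()] for raw counts).
#' @param ... passed to [gainLossFit()] (e.g. `conf`).
#' @export
setGeneric("estimateGainLossRatio",
    function(x, ...) standardGeneric("estimateGainLossRatio"))

setMethod("genomeSequences", "SyntheticGenome", function(x) x@sequences)
setMethod("genomeTruth", "SyntheticGenome", function(x) x@truth)
setMethod("repeatLibrary", "SyntheticGenome", function(x) x@repeats)
setMethod("segdupTruth", "SyntheticGenome", function(x) x@segdups)
setMethod("copyMap", "SyntheticGenome", function(x) x@copyMap)
setMethod("simReads", "SimulatedReads", function(x) x@reads)
setMethod("readPlacements", "SimulatedReads", function(x) x@placements)
setMethod("kmerLength", "KmerIndex", function(x) x@k)
setMethod("kmerSource", "KmerIndex", function(x) x@source)
setMethod("nDistinctKmers", "KmerIndex", function(x) length(x@codes))
setMethod("gainEvents", "EventMap", function(x) x@gains)
setMethod("lossEvents", "EventMap", function(x) x@losses)
setMethod("gainExposure", "EventMap", function(x) x@gainExposure)
setMethod("lossExposure", "EventMap", function(x) x@lossExposure)
setMethod("ratioEstimate", "GainLossEstimate", function(x) x@ratio)

setMethod("show", "GenomeSpec", function(object) {
    cat("GenomeSpec:", object@nAutosomal, "XA +", object@nY, "Y scaffolds of",
        object@scaffoldLength, "bp; repeatFraction", object@repeatFraction,
        "; GC", object@gc, "; seed", object@seed, "\n")
})

setMethod("show", "SyntheticGenome", function(object) {
    tab <- table(object@truth$class)
    cat("SyntheticGenome with", length(object@sequences), "scaffolds (",
        sum(width(object@sequences)), "bp ):",
        paste(names(tab), tab, collapse = ", "), "\n")
    if (nrow(object@segdups))
        cat("  ", nrow(object@segdups), "implanted segmental duplication(s),",
            nrow(object@copyMap), "Y copies\n")
})

setMethod("show", "SimulatedReads", function(object) {
    cat("SimulatedReads:", length(object@reads), object@config@sex,
        "reads of", object@config@readLength, "bp (target depth",
        object@config@depth, "x, error rate", object@config@errorRate, ")\n")
})

setMethod("show", "KmerIndex", function(object) {
    cat("KmerIndex (", object@source, "): ", length(object@codes),
        " distinct canonical ", object@k, "-mers, ",
        sum(as.numeric(object@counts)), " total occurrences\n", sep = "")
})

setMethod("show", "YgsSummary", function(object) {
    cat("YgsSummary (minValid =", object@minValid, ")\n")
    print(object@totals)
})

setMethod("show", "EventMap", function(object) {
    cat("EventMap on a", length(object@tree$tip.label), "taxon tree:",
        nrow(object@gains), "gains,", nrow(object@losses), "losses\n")
    cat("  gain exposure", signif(object@gainExposure, 4), "My;",
        "loss exposure", signif(object@lossExposure, 4), "gene-My\n")
})

setMethod("show", "GainLossEstimate", function(object) {
    cat("Gain-loss rate ratio:", signif(object@ratio, 4),
        if (object@boundary) "(boundary: one-sided bound)" else "", "\n")
    cat("  G =", object@gains, "over", signif(object@gainExposure, 4),
        "My; L =", object@losses, "over", signif(object@lossExposure, 4),
        "gene-My\n")
    cat("  LRT p =", signif(object@pValue, 3), "; 95% CI [",
        signif(object@ciLow, 4), ",", signif(object@ciHigh, 4), "]\n")
})
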