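#' @include AllClasses.R
#' @importFrom Biostrings DNAString pairwiseAlignment nucleotideSubstitutionMatrix
#'   alignedPattern alignedSubject pid translate
#' @importFrom GenomicRanges findOverlaps
NULL

.alignCds <- function(candidate, reference) {
    # match 1, mismatch -1, affine gaps open 4 / extend 1
    pairwiseAlignment(DNAString(candidate), DNAString(reference),
                      type = "global",
                      substitutionMatrix = nucleotideSubstitutionMatrix(
                          match = 1, mismatch = -1, baseOnly = TRUE),
                      gapOpening = 4, gapExtension = 1)
}

#' Check the integrity of a candidate coding sequence
#'
#' Globally aligns the candidate to an intact reference CDS (match 1,
#' mismatch -1, gap open 4, gap extend 1) and classifies it:
#' `frameshift` when the net indel length within the alignment is not a
#' multiple of 3 (compensating indels that restore the frame do not count),
#' otherwise `premature_stop` when the candidate contains an in-frame stop
#' codon before its final codon, otherwise `intact`. An empty candidate is
#' `truncated`. The defect position is the 1-based reference codon of the
#' first frame-breaking indel, or the candidate codon of the first premature
#' stop.
#'
#' @param candidate candidate CDS (character or `DNAString`; possibly
#'   degenerate).
#' @param reference intact reference CDS: length a multiple of 3, ending in
#'   a stop codon.
#' @return a list with `status` (one of `intact`, `premature_stop`,
#'   `frameshift`, `truncated`) and `defect_codon` (`NA` when intact).
#' @examples
#' ref <- "ATGAAACCCGGGTAA"
#' checkCdsIntegrity(ref, ref)$status
#' checkCdsIntegrity("ATGAAACCCGGGATAA", ref)$status  # 1-bp insertion
#' @export
checkCdsIntegrity <- function(candidate, reference) {
    reference <- as.character(reference)
    candidate <- as.character(candidate)
    if (nchar(reference) %% 3L != 0L)
        stop("reference CDS length must be a multiple of 3")
    refStop <- substring(reference, nchar(reference) - 2L, nchar(reference))
    if (!refStop %in% .STOP_CODONS)
        stop("reference CDS must end in a stop codon")
    if (nchar(candidate) == 0L)
        return(list(status = "truncated", defect_codon = NA_integer_))
    net <- nchar(candidate) - nchar(reference)
    if (net %% 3L != 0L) {
        # locate the first frame-breaking indel on the alignment
        aln <- .alignCds(candidate, reference)
        p <- strsplit(as.character(alignedPattern(aln)), "")[[1L]]
        s <- strsplit(as.character(alignedSubject(aln)), "")[[1L]]
        shift <- 0L
        refPos <- 0L
        defect <- NA_integer_
        for (i in seq_along(p)) {
            if (s[i] != "-") refPos <- refPos + 1L
            if (p[i] == "-") shift <- shift - 1L
            if (s[i] == "-") shift <- shift + 1L
            if (shift %% 3L != 0L) {
                defect <- (max(refPos, 1L) - 1L) %/% 3L + 1L
                break
            }
        }
        return(list(status = "frameshift", defect_codon = defect))
    }
    nCodons <- nchar(candidate) %/% 3L
    if (nCodons >= 2L) {
        codons <- substring(candidate, 3L * seq_len(nCodons) - 2L,
                            3L * seq_len(nCodons))
        premature <- which(codons[-nCodons] %in% .STOP_CODONS)
        if (length(premature))
            return(list(status = "premature_stop",
                        defect_codon = premature[1L]))
    }
    list(status = "intact", defect_codon = NA_integer_)
}

#' Percent nucleotide identity between two sequences
#'
#' Global alignment identity (alignment columns with matching bases over
#' alignment length), used for the recent-duplication flag (>= 96\%) and the
#' full-length copy-count rule (>= 95\%).
#'
#' @param a,b sequences (character or `DNAString`).
#' @return identity as a proportion in [0, 1].
#' @export
nucleotideIdentity <- function(a, b) {
    pid(.alignCds(as.character(a), as.character(b)), type = "PID1") / 100
}

#' Count full-length copies of a gene at an identity threshold
#'
#' Bookkeeping rule for per-gene copy counts: candidates aligning to the
#' reference copy at or above `threshold` nucleotide identity count as
#' full-length copies (default 0.95; distinct from the 0.96 recent-origin
#' flag, which is a separate rule).
#'
#' @param candidates `DNAStringSet` or character vector of candidate copies.
#' @param reference the reference copy.
#' @param threshold identity threshold (default 0.95).
#' @return integer count.
#' @export
fullLengthCopyCount <- function(candidates, reference, threshold = 0.95) {
    sum(vapply(as.character(candidates), nucleotideIdentity, 0,
               b = as.character(reference)) >= threshold)
}

#' Expression share of each copy within a copy group
#'
#' Normalizes TPM values of all copies of a gene (Y plus autosomal) to
#' proportions summing to 1. An all-zero group returns all-zero shares with
#' attribute `allZero = TRUE`.
#'
#' @param tpm non-negative numeric vector of TPM values, one per copy
#'   (names preserved).
#' @return proportions in [0, 1]; `attr(, "allZero")` is `TRUE` when no
#'   copy is expressed.
#' @examples
#' expressionShare(c(Y = 3, A = 97))
#' @export
expressionShare <- function(tpm) {
    if (any(tpm < 0))
        stop("TPM values must be >= 0")
    s <- sum(tpm)
    if (s == 0) {
        out <- tpm
        attr(out, "allZero") <- TRUE
        return(out)
    }
    out <- tpm / s
    attr(out, "allZero") <- FALSE
    out
}

#' Classify a gene copy as functional or pseudogene
#'
#' Conjunction rule: a copy is functional iff its CDS is intact and it
#' contributes more than `shareThreshold` (default 10\%) of the copy
#' group's expression. The recent-duplication flag is set when nucleotide
#' identity to the counterpart copy is at or above `recentIdentity`
#' (default 96\%).
#'
#' @param integrity output of [checkCdsIntegrity()] (or its `status`
#'   string).
#' @param expressionShare this copy's share from [expressionShare()].
#' @param identityToCounterpart optional identity proportion to the
#'   counterpart copy.
#' @param shareThreshold expression-share threshold (default 0.10, strict
#'   inequality).
#' @param recentIdentity recent-origin identity threshold (default 0.96).
#' @return a list with `status` (`"functional"`/`"pseudogene"`),
#'   `integrity`, `expression_share`, `recent_flag`.
#' @examples
#' classifyFate(list(status = "intact"), 0.03)$status  # low share
#' @export
classifyFate <- function(integrity, expressionShare,
                         identityToCounterpart = NA_real_,
                         shareThreshold = 0.10, recentIdentity = 0.96) {
    status <- if (is.list(integrity)) integrity$status else integrity
    functional <- identical(status, "intact") &&
        expressionShare > shareThreshold
    list(status = if (functional) "functional" else "pseudogene",
         integrity = status,
         expression_share = as.numeric(expressionShare),
         recent_flag = !is.na(identityToCounterpart) &&
             identityToCounterpart >= recentIdentity)
}

#' Infer the duplication mechanism of a Y-linked gene copy
#'
#' A gene lying within a called segmental duplication certainly arose by a
#' DNA-mediated duplication (`DNA_segdup`). Otherwise, at least one intron
#' position (CDS-relative) shared exactly with the outgroup ortholog
#' indicates a DNA duplication (`DNA_intron_conserved`). When the outgroup
#' ortholog is intron-less (or outgroup data are missing) the mechanism is
#' `undetermined`: absence of introns from the Y copy alone is not evidence
#' of RNA mediation, because intron loss can be lineage-specific.
#'
#' @param geneRange `GRanges` of the gene's location (length 1), or `NULL`
#'   when unknown.
#' @param segdupCalls `GRanges` of segmental-duplication calls.
#' @param yIntrons numeric CDS-relative intron positions of the Y copy.
#' @param outgroupIntrons numeric CDS-relative intron positions of the
#'   outgroup ortholog, or `NULL` when missing.
#' @return a list with `call` (one of `DNA_segdup`, `DNA_intron_conserved`,
#'   `undetermined`) and `reason`.
#' @export
inferMechanism <- function(geneRange, segdupCalls, yIntrons = numeric(0),
                           outgroupIntrons = NULL) {
    sharedSeq <- !is.null(geneRange) && length(segdupCalls) &&
        any(as.character(seqnames(geneRange)) %in%
            as.character(seqnames(segdupCalls)))
    if (sharedSeq && length(findOverlaps(geneRange, segdupCalls)) > 0L)
        return(list(call = "DNA_segdup",
                    reason = "gene lies within a segmental duplication"))
    if (is.null(outgroupIntrons))
        return(list(call = "undetermined", reason = "no outgroup data"))
    if (length(outgroupIntrons) == 0L)
        return(list(call = "undetermined", reason = "outgroup intron-less"))
    if (length(intersect(yIntrons, outgroupIntrons)) >= 1L)
        return(list(call = "DNA_intron_conserved",
                    reason = "shared intron position with outgroup"))
    list(call = "undetermined",
         reason = "no shared intron positions (loss may be lineage-specific)")
}
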