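#' @include AllClasses.R
NULL

## 2-bit base codes; anything but A/C/G/T (either case) is NA and every
## window containing it is dropped. Codes are packed into doubles: a k-mer
## is sum(base * 4^j), exact for k <= 26 (52 bits).

.baseCodes <- local({
    m <- rep(NA_real_, 256L)
    m[utf8ToInt("A")] <- 0; m[utf8ToInt("a")] <- 0
    m[utf8ToInt("C")] <- 1; m[utf8ToInt("c")] <- 1
    m[utf8ToInt("G")] <- 2; m[utf8ToInt("g")] <- 2
    m[utf8ToInt("T")] <- 3; m[utf8ToInt("t")] <- 3
    m
})

## canonical (strand-collapsed) k-mer codes of one string, excluding windows
## with ambiguous bases; returns a numeric vector, one entry per valid window
.canonicalCodes <- function(seq, k) {
    v <- utf8ToInt(seq)
    L <- length(v)
    n <- L - k + 1L
    if (n <= 0L) return(numeric(0))
    base <- .baseCodes[v]
    bad <- is.na(base)
    b0 <- base
    b0[bad] <- 0
    fwd <- numeric(n)
    rc <- numeric(n)
    for (j in seq_len(k)) {
        bj <- b0[j:(j + n - 1L)]
        fwd <- fwd * 4 + bj            # Horner: base[j] weighted 4^(k-j)
        rc <- rc + (3 - bj) * 4^(j - 1L)
    }
    canon <- pmin(fwd, rc)
    if (any(bad)) {
        cs <- cumsum(bad)
        inwin <- cs[k:L] - c(0, cs)[seq_len(n)]
        canon <- canon[inwin == 0L]
    }
    canon
}

## canonical codes of a set of sequences, chunked so transient vectors stay
## bounded; sequences are joined with 'N' so no window spans two of them
.canonicalCodesSet <- function(seqs, k, chunkBp = 4e6) {
    seqs <- as.character(seqs)
    if (!length(seqs)) return(numeric(0))
    grp <- findInterval(cumsum(as.numeric(nchar(seqs))) - 1,
                        seq(0, sum(nchar(seqs)), by = chunkBp))
    out <- lapply(split(seqs, grp), function(chunk)
        .canonicalCodes(paste(chunk, collapse = "N"), k))
    unlist(out, use.names = FALSE)
}

#' Build a canonical k-mer occurrence index
#'
#' Counts total occurrences of every canonical k-mer (lexicographic minimum
#' of a k-mer and its reverse complement) across a sequence set. Windows
#' containing ambiguous bases are excluded; sequences shorter than `k`
#' contribute nothing (an empty index is not an error).
#'
#' @param sequences a `DNAStringSet` or character vector (assembly scaffolds
#'   or reads).
#' @param k k-mer length in 7-26 (default 15, the usual choice for
#'   chromosome-of-origin classification).
#' @param source label recorded on the index: `"assembly"`, `"male_reads"`
#'   or `"female_reads"`.
#' @return a [KmerIndex-class].
#'
#' @examples
#' idx <- buildKmerIndex("ACGTACGTAC", k = 4, source = "assembly")
#' nDistinctKmers(idx)
#' @export
buildKmerIndex <- function(sequences, k = 15L,
                           source = c("assembly", "male_reads",
                                      "female_reads")) {
    source <- match.arg(source)
    k <- as.integer(k)
    if (k < 7L || k > 26L)
        stop("k must be in [7, 26]")
    codes <- .canonicalCodesSet(sequences, k)
    if (!length(codes)) {
        return(new("KmerIndex", k = k, codes = numeric(0),
                   counts = integer(0), source = source))
    }
    codes <- sort(codes, method = "quick")
    r <- rle(codes)
    new("KmerIndex", k = k, codes = r$values,
        counts = as.integer(r$lengths), source = source)
}

## occurrence counts in `index` for a vector of canonical codes (0 = absent)
.lookupCounts <- function(index, codes) {
    if (!length(index@codes)) return(integer(length(codes)))
    pos <- findInterval(codes, index@codes)
    hit <- pos > 0L & index@codes[pmax(pos, 1L)] == codes
    out <- integer(length(codes))
    out[hit] <- index@counts[pos[hit]]
    out
}
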