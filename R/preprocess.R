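#' Trim 3' adapter, low-quality ends and poly(A) tails
#'
#' Cleanup order: (a) locate the 3' adapter — full internal matches or
#' prefix matches reaching the read end, at least `minMatch` bases, up to
#' 10% mismatches, longest match preferred (ties to the rightmost start) —
#' and cut it and everything after; a trailing poly(A) run of at least
#' `minPolyA` bases followed by fewer than `minMatch` terminal adapter
#' bases is cut the same way, so constructs whose adapter is barely inside
#' the read are still cleaned; (b) trim bases below the quality threshold
#' from the 3' then the 5' end; (c) strip a remaining trailing run of at
#' least `minPolyA` A's. Trimming is idempotent: re-trimming a trimmed read
#' changes nothing.
#'
#' @param reads A [ReadSet].
#' @param adapter 3' adapter sequence (non-empty).
#' @param qualThreshold Phred threshold; bases with quality below it are
#'   trimmed from both ends (default 15).
#' @param minPolyA minimum trailing A-run length stripped (default 5).
#' @param maxErrorRate adapter mismatch tolerance (default 0.1).
#' @param minMatch minimum adapter match length (default 5).
#' @return list with `reads` (trimmed [ReadSet]; reads may become empty) and
#'   `stats` (n_input, n_adapter_trimmed, n_polyA_trimmed).
#' @export
trimReads <- function(reads, adapter, qualThreshold = 15, minPolyA = 5,
                      maxErrorRate = 0.1, minMatch = 5) {
    stopifnot(nchar(adapter) > 0)
    adapter <- toupper(adapter)
    seqs <- readSeqs(reads)
    quals <- readQuals(reads)
    n <- length(reads)
    if (n == 0)
        return(list(reads = reads,
                    stats = c(n_input = 0L, n_adapter_trimmed = 0L,
                              n_polyA_trimmed = 0L)))

    # (a) adapter removal
    cut <- cpp_adapter_pos(seqs, adapter, maxErrorRate, minMatch)
    # short adapter remnant (< minMatch nt) behind a poly(A) run: the read
    # ends in an adapter prefix of length r preceded by >= minPolyA A's;
    # cut at the remnant start (the run itself goes in step (c))
    for (r in seq(minMatch - 1L, 1L)) {
        unfound <- cut < 0L
        if (!any(unfound)) break
        L <- nchar(seqs[unfound])
        ends_in_prefix <- L > r &
            substring(seqs[unfound], L - r + 1L, L) ==
                substr(adapter, 1L, r)
        run_before <- grepl(sprintf("A{%d,}.{%d}$", minPolyA, r),
                            seqs[unfound])
        ok <- ends_in_prefix & run_before
        cut[which(unfound)[ok]] <- (L - r)[ok]
    }
    adapter_trimmed <- cut >= 0L
    keep_to <- ifelse(adapter_trimmed, cut, nchar(seqs))
    seqs <- substr(seqs, 1L, keep_to)
    quals <- substr(quals, 1L, keep_to)

    # (b) quality trimming, 3' then 5'
    rng <- cpp_qual_range(quals, as.integer(qualThreshold), 33L)
    seqs <- substr(seqs, rng[, 1] + 1L, rng[, 2])
    quals <- substr(quals, rng[, 1] + 1L, rng[, 2])

    # (c) trailing poly(A) run
    polyre <- sprintf("A{%d,}$", minPolyA)
    m <- regexpr(polyre, seqs)
    polyA_trimmed <- m > 0L
    keep_to <- ifelse(polyA_trimmed, m - 1L, nchar(seqs))
    seqs <- substr(seqs, 1L, keep_to)
    quals <- substr(quals, 1L, keep_to)

    list(reads = ReadSet(readIds(reads), seqs, quals),
         stats = c(n_input = n,
                   n_adapter_trimmed = sum(adapter_trimmed),
                   n_polyA_trimmed = sum(polyA_trimmed)))
}

#' Length and N-content read filters
#'
#' Keeps reads of at least `minLen` bases (default 17) whose fraction of
#' unknown bases N does not exceed `maxNFrac` (default 0.10; strictly more
#' removes). Reads failing both filters are counted as too short.
#'
#' @param reads a trimmed [ReadSet].
#' @param minLen minimum kept length (nt).
#' @param maxNFrac maximum tolerated N fraction.
#' @return list with `reads` (passing [ReadSet]) and `report`: named integer
#'   counts n_input, n_removed_short, n_removed_N, n_pass, satisfying
#'   n_pass = n_input - n_removed_short - n_removed_N.
#' @export
filterReads <- function(reads, minLen = 17, maxNFrac = 0.10) {
    seqs <- readSeqs(reads)
    len <- nchar(seqs)
    short <- len < minLen
    nfrac <- ifelse(len > 0,
                    nchar(gsub("[^N]", "", seqs)) / len, 0)
    manyN <- !short & nfrac > maxNFrac
    keep <- !short & !manyN
    list(reads = reads[keep],
         report = c(n_input = length(reads),
                    n_removed_short = sum(short),
                    n_removed_N = sum(manyN),
                    n_pass = sum(keep)))
}

#' Assemble overlapping read pairs
#'
#' Reverse-complements mate 2 and places it against mate 1 at the longest
#' overlap of at least `minOverlap` bases with mismatch rate at most
#' `maxMismatchRate`; mate-1 bases win inside the overlap, and mate-1 bases
#' extending past the end of reverse-complemented mate 2 (read-through into
#' the poly(A) tail or adapter) are discarded. Pairs with no acceptable
#' overlap are returned unmerged.
#'
#' @param r1,r2 [ReadSet]s of equal length, pairs in matching order.
#' @param minOverlap minimum overlap (default 10).
#' @param maxMismatchRate tolerated overlap mismatch rate (default 0.1).
#' @return list with `merged` ([ReadSet] of assembled inserts), `mergedMask`
#'   (logical over input pairs) and `unmergedR1`/`unmergedR2`.
#' @export
mergePairs <- function(r1, r2, minOverlap = 10, maxMismatchRate = 0.1) {
    stopifnot(length(r1) == length(r2))
    if (length(r1) == 0)
        return(list(merged = r1, mergedMask = logical(0),
                    unmergedR1 = r1, unmergedR2 = r2))
    r2rc <- revComp(readSeqs(r2))
    q2rc <- vapply(strsplit(readQuals(r2), "", fixed = TRUE),
                   function(q) paste(rev(q), collapse = ""), character(1))
    sh <- cpp_overlap(readSeqs(r1), r2rc, as.integer(minOverlap),
                      maxMismatchRate)
    ok <- sh >= 0L
    mseq <- paste0(substr(readSeqs(r1)[ok], 1L, sh[ok]), r2rc[ok])
    mqual <- paste0(substr(readQuals(r1)[ok], 1L, sh[ok]), q2rc[ok])
    list(merged = ReadSet(readIds(r1)[ok], mseq, mqual),
         mergedMask = ok,
         unmergedR1 = r1[!ok], unmergedR2 = r2[!ok])
}
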