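ALL_4MERS <- local({
    b <- c("A", "C", "G", "T")
    g <- expand.grid(b, b, b, b, stringsAsFactors = FALSE)[, 4:1]
    sort(apply(g, 1, paste, collapse = ""))
})

#' Fragment-length histogram from single/merged and paired alignments
#'
#' Two strategies, summed: (1) merged (or single-end) read alignments
#' contribute their aligned length directly; (2) read pairs that could not
#' be merged contribute when mate 1 aligns at least `fullLengthThreshold`
#' nt (default 90, just under the read length, i.e. the fragment extends
#' past a single read) and both mates hit the same transcript — the
#' fragment length is then the distance between the two mapping loci plus
#' mate 2's aligned length. Pairs yielding a non-positive length
#' (discordant orientation) are discarded and tallied.
#'
#' @param merged alignments of merged/single-end reads ([alignReads()]
#'   output), or `NULL`.
#' @param pairs data.frame of unmerged-pair alignments with columns
#'   `read_id`, `transcript_id`, `r1_start`, `r1_len`, `r2_start`,
#'   `r2_len` (mates on the same transcript; see [pairFragments()]), or
#'   `NULL`.
#' @param fullLengthThreshold minimum mate-1 aligned length for strategy 2.
#' @return list with `hist` (data.frame length, count) and `n_discordant`.
#' @export
fragmentLengths <- function(merged = NULL, pairs = NULL,
                            fullLengthThreshold = 90) {
    lens <- integer(0)
    n_disc <- 0L
    if (!is.null(merged) && nrow(merged))
        lens <- c(lens, merged$aligned_length[!duplicated(merged$read_id)])
    if (!is.null(pairs) && nrow(pairs)) {
        p <- pairs[pairs$r1_len >= fullLengthThreshold, , drop = FALSE]
        L <- (p$r2_start - p$r1_start) + p$r2_len
        bad <- L <= 0
        n_disc <- sum(bad)
        lens <- c(lens, L[!bad])
    }
    tab <- table(lens)
    list(hist = data.frame(length = as.integer(names(tab)),
                           count = as.integer(tab)),
         n_discordant = n_disc)
}

#' Pair up single-end alignments of unmerged mates
#'
#' Aligns mate 1 and reverse-complemented mate 2 independently and joins
#' them on read id and transcript, keeping one deterministic placement per
#' mate (first by transcript then position).
#'
#' @param r1,r2 unmerged [ReadSet]s (same pairs, same order).
#' @param refset A [ReferenceSet] or sequences accepted by [alignReads()].
#' @param maxMismatch,k passed to [alignReads()].
#' @return data.frame(read_id, transcript_id, r1_start, r1_len, r2_start,
#'   r2_len).
#' @export
pairFragments <- function(r1, r2, refset, maxMismatch = 1, k = 8) {
    a1 <- alignReads(r1, refset, maxMismatch = maxMismatch, k = k)
    r2rc <- ReadSet(readIds(r2), revComp(readSeqs(r2)), readQuals(r2))
    a2 <- alignReads(r2rc, refset, maxMismatch = maxMismatch, k = k)
    if (nrow(a1) == 0 || nrow(a2) == 0)
        return(data.frame(read_id = character(),
                          transcript_id = character(), r1_start = integer(),
                          r1_len = integer(), r2_start = integer(),
                          r2_len = integer(), stringsAsFactors = FALSE))
    m <- merge(a1, a2, by = c("read_id", "transcript_id"),
               suffixes = c("_1", "_2"))
    m <- m[order(m$read_id, m$transcript_id, m$start_1, m$start_2), ,
           drop = FALSE]
    m <- m[!duplicated(m$read_id), , drop = FALSE]
    data.frame(read_id = m$read_id, transcript_id = m$transcript_id,
               r1_start = m$start_1, r1_len = m$aligned_length_1,
               r2_start = m$start_2, r2_len = m$aligned_length_2,
               stringsAsFactors = FALSE)
}

#' Fraction of fragments below 50 nt, between 50 and 200 nt, above 200 nt
#'
#' @param hist data.frame(length, count) as from [fragmentLengths()].
#' @return named numeric: `lt50`, `mid50_200`, `gt200`; sums to 1.
#' @export
lengthClassFractions <- function(hist) {
    if (is.null(hist) || nrow(hist) == 0 || sum(hist$count) == 0)
        stop("empty length histogram")
    n <- sum(hist$count)
    c(lt50 = sum(hist$count[hist$length < 50]) / n,
      mid50_200 = sum(hist$count[hist$length >= 50 &
                                 hist$length <= 200]) / n,
      gt200 = sum(hist$count[hist$length > 200]) / n)
}

#' Extract fragment end bases and 4-mer end motifs from the reference
#'
#' For a fragment at 0-based half-open `[start, end)` on its transcript,
#' the 5' end base is the reference base at `start` and the 3' end base the
#' last aligned base, at `end - 1`. Each end's 4-mer motif spans two bases
#' inside and two outside the fragment: `[start - 2, start + 2)` at the 5'
#' end and `[end - 2, end + 2)` at the 3' end; a motif is reported only
#' when its window lies fully inside the transcript (fragments at the edge
#' still contribute end bases).
#'
#' @param fragments data.frame with columns `transcript_id`, `start`,
#'   `end`.
#' @param refset A [ReferenceSet].
#' @param end3Unaligned use the first unaligned base (`end`) as the 3' end
#'   instead of the last aligned one (alternative reading of the 3'-end
#'   definition; default `FALSE`).
#' @return `fragments` with added columns end5_base, end3_base, motif5,
#'   motif3 (NA where the window overruns the transcript).
#' @export
endContexts <- function(fragments, refset, end3Unaligned = FALSE) {
    seqs <- as.character(refSequences(refset))
    lens <- transcriptLengths(refset)
    s <- seqs[fragments$transcript_id]
    L <- unname(lens[fragments$transcript_id])
    st <- fragments$start
    en <- fragments$end
    e3 <- if (end3Unaligned) en else en - 1L
    fragments$end5_base <- substr(s, st + 1L, st + 1L)
    fragments$end3_base <- ifelse(e3 < L,
                                  substr(s, e3 + 1L, e3 + 1L),
                                  NA_character_)
    m5 <- substr(s, st - 1L, st + 2L)
    fragments$motif5 <- ifelse(st - 2L >= 0L & st + 2L <= L, m5,
                               NA_character_)
    m3off <- if (end3Unaligned) en else en - 1L
    m3 <- substr(s, m3off, m3off + 3L)
    fragments$motif3 <- ifelse(m3off - 1L >= 0L & m3off + 3L <= L, m3,
                               NA_character_)
    fragments
}

#' Terminal-base statistics of fragment ends
#'
#' Frequencies of A/C/G/T at the 5' and 3' fragment ends, the 3'
#' pyrimidine/purine ratio `(C+T)/(A+G)` and the 5' adenine rate. An
#' RNase-A-degraded library shows an elevated 3' pyrimidine ratio and a 5'
#' adenine preference; heat-fragmented material sits near the reference
#' base composition.
#'
#' @param contexts output of [endContexts()].
#' @return list: `end5_base_freq`, `end3_base_freq` (named 4-vectors
#'   summing to 1), `py_pu_ratio_3p` (`Inf` with a warning when no purine
#'   3' end is observed), `adenine_rate_5p`.
#' @export
endStatistics <- function(contexts) {
    stopifnot(nrow(contexts) >= 1)
    baseFreq <- function(x) {
        x <- x[!is.na(x) & x %in% c("A", "C", "G", "T")]
        tab <- table(factor(x, levels = c("A", "C", "G", "T")))
        stats::setNames(as.numeric(tab) / sum(tab), c("A", "C", "G", "T"))
    }
    f5 <- baseFreq(contexts$end5_base)
    f3 <- baseFreq(contexts$end3_base)
    pu <- f3[["A"]] + f3[["G"]]
    py <- f3[["C"]] + f3[["T"]]
    if (pu == 0) {
        warning("no purine 3' ends observed; ratio reported as Inf")
        ratio <- Inf
    } else ratio <- py / pu
    list(end5_base_freq = f5, end3_base_freq = f3,
         py_pu_ratio_3p = ratio, adenine_rate_5p = f5[["A"]])
}

#' 256-entry 4-mer end-motif percentage profile
#'
#' Counts the 4-mer motif at the chosen fragment end over all contexts
#' where the motif window was defined, excluding motifs containing N, and
#' normalizes to percentages over all 256 lexicographic 4-mers
#' (AAAA ... TTTT).
#'
#' @param contexts output of [endContexts()].
#' @param end `"three_prime"` or `"five_prime"`.
#' @return named numeric of length 256 summing to 100.
#' @export
motifProfile <- function(contexts, end = c("three_prime", "five_prime")) {
    end <- match.arg(end)
    x <- if (end == "three_prime") contexts$motif3 else contexts$motif5
    x <- x[!is.na(x)]
    x <- x[!grepl("N", x, fixed = TRUE)]
    if (!length(x)) stop("no defined ", end, " motifs")
    tab <- table(factor(x, levels = ALL_4MERS))
    stats::setNames(100 * as.numeric(tab) / sum(tab), ALL_4MERS)
}

#' Build a per-sample FragmentProfile
#'
#' Convenience wrapper combining [fragmentLengths()] (histogram supplied or
#' derived from fragment coordinates), [lengthClassFractions()],
#' [endContexts()], [endStatistics()] and [motifProfile()].
#'
#' @param fragments data.frame(transcript_id, start, end).
#' @param refset A [ReferenceSet].
#' @param hist optional precomputed length histogram; default from
#'   `fragments`.
#' @return A [FragmentProfile].
#' @export
fragmentProfile <- function(fragments, refset, hist = NULL) {
    if (is.null(hist)) {
        tab <- table(fragments$end - fragments$start)
        hist <- data.frame(length = as.integer(names(tab)),
                           count = as.integer(tab))
    }
    ctx <- endContexts(fragments, refset)
    st <- endStatistics(ctx)
    m3 <- tryCatch(motifProfile(ctx, "three_prime"),
                   error = function(e) stats::setNames(
                       rep(NA_real_, 256), ALL_4MERS))
    m5 <- tryCatch(motifProfile(ctx, "five_prime"),
                   error = function(e) stats::setNames(
                       rep(NA_real_, 256), ALL_4MERS))
    new("FragmentProfile", length_hist = hist,
        class_fractions = lengthClassFractions(hist),
        end5_base_freq = st$end5_base_freq,
        end3_base_freq = st$end3_base_freq,
        motif5 = m5, motif3 = m3,
        py_pu_ratio_3p = st$py_pu_ratio_3p,
        adenine_rate_5p = st$adenine_rate_5p)
}

setMethod("show", "FragmentProfile", function(object) {
    cf <- object@class_fractions
    cat("FragmentProfile:", sum(object@length_hist$count), "fragments\n")
    cat(sprintf("  <50 nt: %.1f%%  50-200 nt: %.1f%%  >200 nt: %.1f%%\n",
                100 * cf[["lt50"]], 100 * cf[["mid50_200"]],
                100 * cf[["gt200"]]))
    cat(sprintf("  3' py/pu ratio: %.3f  5' adenine rate: %.3f\n",
                object@py_pu_ratio_3p, object@adenine_rate_5p))
})
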