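#' Forward-strand best-stratum alignment
#'
#' End-to-end placement of each full read on the forward strand of the
#' reference transcripts, allowing at most `maxMismatch` mismatches and
#' reporting every placement in the best stratum only: if a read has any
#' 0-mismatch placement, all and only its 0-mismatch placements are
#' returned; otherwise all 1-mismatch placements; otherwise nothing. No
#' soft-clipping and no reverse-complement search. Rows are ordered by
#' read, then (transcript_id, start).
#'
#' @param reads A [ReadSet] or character vector of read sequences (names
#'   used as read ids).
#' @param refs A [ReferenceSet], a named character vector or a
#'   `DNAStringSet` of transcript sequences.
#' @param maxMismatch maximum mismatches (default 1).
#' @param k seed length for the index (default 8; reads shorter than `2k`
#'   are scanned exhaustively).
#' @return data.frame(read_id, transcript_id, start, aligned_length,
#'   mismatches) with 0-based `start`.
#' @export
alignReads <- function(reads, refs, maxMismatch = 1, k = 8) {
    if (is(reads, "ReadSet")) {
        ids <- readIds(reads); seqs <- readSeqs(reads)
    } else {
        seqs <- as.character(reads)
        ids <- if (is.null(names(seqs))) as.character(seq_along(seqs))
               else names(seqs)
    }
    if (is(refs, "ReferenceSet")) refs <- refSequences(refs)
    rid <- names(refs)
    rseq <- as.character(refs)
    if (is.null(rid)) rid <- as.character(seq_along(rseq))
    if (length(seqs) == 0 || length(rseq) == 0)
        return(data.frame(read_id = character(), transcript_id = character(),
                          start = integer(), aligned_length = integer(),
                          mismatches = integer(), stringsAsFactors = FALSE))
    h <- cpp_align(seqs, rseq, as.integer(k), as.integer(maxMismatch))
    out <- data.frame(read_id = ids[h$read],
                      transcript_id = rid[h$ref],
                      start = h$start,
                      aligned_length = nchar(seqs)[h$read],
                      mismatches = h$mismatches,
                      stringsAsFactors = FALSE)
    out <- out[order(match(out$read_id, ids), out$transcript_id,
                     out$start), ]
    rownames(out) <- NULL
    out
}

# join alignments on miRNA hairpins against the mature table and apply the
# positional rule: |read start - mature start| <= maxStartOffset and
# |read end - mature end| <= maxEndOffset; among qualifying matures choose
# the smallest start offset, ties by smallest end offset.
mirnaMatchMatures <- function(aln, matures, maxStartOffset = 3,
                              maxEndOffset = 5) {
    if (nrow(aln) == 0 || nrow(matures) == 0)
        return(cbind(aln[0, , drop = FALSE],
                     data.frame(mature_name = character())))
    aln$.row <- seq_len(nrow(aln))
    m <- merge(aln, matures, by.x = "transcript_id", by.y = "hairpin_id",
               suffixes = c("", ".mat"))
    if (nrow(m) == 0)
        return(cbind(aln[0, setdiff(names(aln), ".row"), drop = FALSE],
                     data.frame(mature_name = character())))
    so <- abs(m$start - m$start.mat)
    eo <- abs((m$start + m$aligned_length) - m$end)
    m <- m[so <= maxStartOffset & eo <= maxEndOffset, , drop = FALSE]
    so <- abs(m$start - m$start.mat)
    eo <- abs((m$start + m$aligned_length) - m$end)
    if (nrow(m) == 0)
        return(cbind(aln[0, setdiff(names(aln), ".row"), drop = FALSE],
                     data.frame(mature_name = character())))
    o <- order(m$.row, so, eo, m$mature_name)
    m <- m[o, , drop = FALSE]
    m <- m[!duplicated(m$.row), , drop = FALSE]
    res <- aln[m$.row, setdiff(names(aln), ".row"), drop = FALSE]
    res$mature_name <- m$mature_name
    rownames(res) <- NULL
    res
}

#' Mature-position filter for one miRNA hairpin alignment
#'
#' A read aligned to a hairpin precursor is accepted as a mature miRNA read
#' only if its start lies within 3 nt of an annotated mature start and its
#' end within 5 nt of that mature's end; among several qualifying matures
#' the one with the smallest start offset wins (ties by end offset).
#'
#' @param start,end 0-based half-open read coordinates on the hairpin.
#' @param matures mature table rows for this hairpin (`mature_name`,
#'   `start`, `end`).
#' @param maxStartOffset,maxEndOffset positional tolerances (defaults 3
#'   and 5).
#' @return list with `status` ("kept", "rejected" or "no_mature") and
#'   `mature_name` (`NA` unless kept).
#' @export
mirnaPositionalFilter <- function(start, end, matures, maxStartOffset = 3,
                                  maxEndOffset = 5) {
    if (is.null(matures) || nrow(matures) == 0)
        return(list(status = "no_mature", mature_name = NA_character_))
    aln <- data.frame(read_id = "r", transcript_id = "h", start = start,
                      aligned_length = end - start, mismatches = 0L,
                      stringsAsFactors = FALSE)
    mt <- data.frame(mature_name = matures$mature_name, hairpin_id = "h",
                     start = matures$start, end = matures$end,
                     stringsAsFactors = FALSE)
    res <- mirnaMatchMatures(aln, mt, maxStartOffset, maxEndOffset)
    if (nrow(res) == 0)
        list(status = "rejected", mature_name = NA_character_)
    else
        list(status = "kept", mature_name = res$mature_name[1])
}

#' Hierarchical tier assignment of cleaned reads
#'
#' Applies the alignment tiers in order. Reads hitting the depletion tier
#' (rRNA/Y RNA/vault RNA) are removed and counted. Each remaining read is
#' assigned at the first subsequent tier where it has at least one
#' best-stratum alignment: on the miRNA tier the mature-position filter
#' applies (reads failing it fall through to later tiers when
#' `mirnaFallthrough = TRUE`, the default); on the tRNA/piRNA tier a read
#' hitting both biotypes in the same stratum is assigned to tRNA only
#' (annotation-confidence priority); within a tier, a read split across
#' several targets contributes weight `1/n` to each. Reads unassigned at
#' every tier are reported unmapped.
#'
#' @param reads A [ReadSet] of cleaned reads.
#' @param refset A [ReferenceSet].
#' @param maxMismatch,k passed to [alignReads()].
#' @param mirnaFallthrough let reads failing the mature-position filter try
#'   later tiers instead of being dropped.
#' @return list with `assignments` (data.frame read_id, tier, biotype,
#'   targets (list column), n_targets, weight), `hits_long` (best-stratum
#'   transcript hit sets of long-tier reads, for the TPM EM), `depleted`
#'   and `unmapped` (read ids), and `counts` (named totals satisfying
#'   n_input = n_depleted + n_assigned + n_unmapped).
#' @export
assignTiers <- function(reads, refset, maxMismatch = 1, k = 8,
                        mirnaFallthrough = TRUE) {
    ann <- refAnnotation(refset)
    seqs <- refSequences(refset)
    tiers <- tierDefinitions(refset)
    ids <- readIds(reads)
    remaining <- seq_along(ids)
    depleted <- character(0)
    dropped_mirna <- character(0)
    out <- list()
    hits_long <- NULL

    for (tn in names(tiers)) {
        if (!length(remaining)) break
        sel <- ann$biotype %in% tiers[[tn]]
        if (!any(sel)) next
        aln <- alignReads(reads[remaining], seqs[ann$transcript_id[sel]],
                          maxMismatch = maxMismatch, k = k)
        if (nrow(aln) == 0) next
        if (tn == "depletion") {
            hit <- unique(aln$read_id)
            depleted <- c(depleted, hit)
            remaining <- remaining[!(ids[remaining] %in% hit)]
            next
        }
        aln$biotype <- ann$biotype[match(aln$transcript_id,
                                         ann$transcript_id)]
        aln$gene_id <- ann$gene_id[match(aln$transcript_id,
                                         ann$transcript_id)]
        if (tn == "miRNA") {
            kept <- mirnaMatchMatures(aln, matureMiRNAs(refset))
            claimed <- unique(aln$read_id)
            passed <- unique(kept$read_id)
            asg <- aggregateTargets(kept, "mature_name", tn, "miRNA")
            out[[tn]] <- asg
            if (mirnaFallthrough) {
                remaining <- remaining[!(ids[remaining] %in% passed)]
            } else {
                dropped_mirna <- c(dropped_mirna, setdiff(claimed, passed))
                remaining <- remaining[!(ids[remaining] %in% claimed)]
            }
            next
        }
        if (tn == "small") {
            # tRNA outranks piRNA within the same best stratum
            both <- stats::aggregate(
                biotype ~ read_id, aln,
                function(b) all(c("tRNA", "piRNA") %in% b))
            amb <- both$read_id[both$biotype]
            aln <- aln[!(aln$read_id %in% amb & aln$biotype == "piRNA"), ,
                       drop = FALSE]
            asg <- aggregateTargets(aln, "gene_id", tn, NULL)
            out[[tn]] <- asg
        } else if (tn == "long") {
            hits_long <- aln[, c("read_id", "transcript_id", "gene_id",
                                 "biotype", "start", "aligned_length",
                                 "mismatches")]
            asg <- aggregateTargets(aln, "gene_id", tn, NULL,
                                    biotypePriority = c("mRNA", "lncRNA"))
            out[[tn]] <- asg
        } else {
            asg <- aggregateTargets(aln, "gene_id", tn, NULL)
            out[[tn]] <- asg
        }
        remaining <- remaining[!(ids[remaining] %in% out[[tn]]$read_id)]
    }

    assignments <- do.call(rbind, unname(out))
    if (is.null(assignments))
        assignments <- data.frame(read_id = character(), tier = character(),
                                  biotype = character(),
                                  n_targets = integer(), weight = numeric(),
                                  stringsAsFactors = FALSE)
    assignments <- assignments[order(match(assignments$read_id, ids)), ,
                               drop = FALSE]
    rownames(assignments) <- NULL
    unmapped <- ids[remaining]
    counts <- c(n_input = length(ids), n_depleted = length(depleted),
                n_assigned = nrow(assignments),
                n_mirna_dropped = length(dropped_mirna),
                n_unmapped = length(unmapped))
    list(assignments = assignments, hits_long = hits_long,
         depleted = depleted, unmapped = unmapped, counts = counts)
}

# collapse per-alignment rows into one row per read with a target list
aggregateTargets <- function(aln, target_col, tier, biotype_label,
                             biotypePriority = NULL) {
    if (nrow(aln) == 0)
        return(data.frame(read_id = character(), tier = character(),
                          biotype = character(), n_targets = integer(),
                          weight = numeric(), stringsAsFactors = FALSE))
    sp <- split(aln[[target_col]], aln$read_id)
    targets <- lapply(sp, function(x) sort(unique(x)))
    if (is.null(biotype_label)) {
        bt <- vapply(split(aln$biotype, aln$read_id), function(b) {
            b <- unique(b)
            if (!is.null(biotypePriority)) {
                pr <- intersect(biotypePriority, b)
                if (length(pr)) return(pr[1])
            }
            sort(b)[1]
        }, character(1))
    } else {
        bt <- rep(biotype_label, length(targets))
    }
    df <- data.frame(read_id = names(targets), tier = tier,
                     biotype = as.character(bt),
                     n_targets = lengths(targets),
                     weight = 1 / lengths(targets),
                     stringsAsFactors = FALSE)
    df$targets <- unname(targets)
    df[, c("read_id", "tier", "biotype", "targets", "n_targets", "weight")]
}

#' Sense/antisense orientation diagnostic
#'
#' Aligns each read both as-is and reverse-complemented (the one analysis
#' where the forward-only constraint is relaxed) and classifies it by its
#' best stratum: forward-only or tied counts sense, reverse-only counts
#' antisense. Fractions are reported per biotype (tier-priority biotype of
#' the winning orientation's hits).
#'
#' @param reads A [ReadSet].
#' @param refset A [ReferenceSet].
#' @param maxMismatch,k passed to [alignReads()].
#' @return data.frame(biotype, n, sense_frac, antisense_frac); fractions
#'   sum to 1 per biotype.
#' @export
senseAntisenseRatio <- function(reads, refset, maxMismatch = 1, k = 8) {
    seqs <- refSequences(refset)
    ann <- refAnnotation(refset)
    tier_order <- unlist(tierDefinitions(refset), use.names = FALSE)
    fwd <- alignReads(reads, seqs, maxMismatch = maxMismatch, k = k)
    rc <- ReadSet(readIds(reads), revComp(readSeqs(reads)))
    rev <- alignReads(rc, seqs, maxMismatch = maxMismatch, k = k)
    fmm <- tapply(fwd$mismatches, fwd$read_id, min)
    rmm <- tapply(rev$mismatches, rev$read_id, min)
    ids <- union(names(fmm), names(rmm))
    if (!length(ids))
        return(data.frame(biotype = character(), n = integer(),
                          sense_frac = numeric(),
                          antisense_frac = numeric()))
    f <- fmm[ids]; r <- rmm[ids]
    f[is.na(f)] <- Inf; r[is.na(r)] <- Inf
    sense <- f <= r
    pickBiotype <- function(aln, id) {
        b <- unique(ann$biotype[match(
            aln$transcript_id[aln$read_id == id], ann$transcript_id)])
        b[order(match(b, tier_order))][1]
    }
    bt <- vapply(seq_along(ids), function(i) {
        if (sense[i]) pickBiotype(fwd, ids[i]) else pickBiotype(rev, ids[i])
    }, character(1))
    res <- do.call(rbind, lapply(split(sense, bt), function(s) {
        data.frame(n = length(s), sense_frac = mean(s),
                   antisense_frac = mean(!s))
    }))
    data.frame(biotype = rownames(res), res, row.names = NULL,
               stringsAsFactors = FALSE)
}
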