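# Independent oracles and small fixtures shared across tests.

# brute-force aligner: every offset of every reference, counting mismatches
# character by character; best (minimum) mismatch stratum only.
bruteAlign <- function(read, refs, maxMismatch = 1) {
    rch <- strsplit(read, "")[[1]]
    L <- length(rch)
    hits <- list()
    for (id in names(refs)) {
        sch <- strsplit(refs[[id]], "")[[1]]
        if (length(sch) < L) next
        for (start in 0:(length(sch) - L)) {
            mm <- sum(rch != sch[(start + 1):(start + L)])
            if (mm <= maxMismatch)
                hits[[length(hits) + 1]] <- data.frame(
                    transcript_id = id, start = start, mismatches = mm,
                    stringsAsFactors = FALSE)
        }
    }
    if (!length(hits))
        return(data.frame(transcript_id = character(), start = integer(),
                          mismatches = integer(), stringsAsFactors = FALSE))
    h <- do.call(rbind, hits)
    h <- h[h$mismatches == min(h$mismatches), , drop = FALSE]
    h <- h[order(h$transcript_id, h$start), , drop = FALSE]
    rownames(h) <- NULL
    h
}

# exact two-sided rank-sum p by full enumeration of group-1 rank subsets
wilcoxEnumP <- function(g1, g2) {
    n1 <- length(g1); n2 <- length(g2)
    ranks <- rank(c(g1, g2))
    W_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
    combs <- utils::combn(n1 + n2, n1)
    allranks <- rank(seq_len(n1 + n2))
    Ws <- apply(combs, 2, function(ix) sum(allranks[ix])) -
        n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-9)
}

# random DNA of length n
randSeq <- function(n, gc = 0.5) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}

# hand-built reference covering every tier
makeTinyRefset <- function(seed = 42) {
    set.seed(seed)
    seqs <- c(
        rRNA_1 = randSeq(300),
        Y_RNA_1 = randSeq(100),
        miRNA_hairpin_1 = randSeq(80),
        tRNA_1 = randSeq(75),
        piRNA_1 = randSeq(30),
        piRNA_2 = randSeq(30),
        mRNA_1 = randSeq(600),
        mRNA_2 = randSeq(400),
        lncRNA_1 = randSeq(500),
        other_ncRNA_1 = randSeq(150))
    ann <- data.frame(
        transcript_id = names(seqs),
        gene_id = paste0("gene_", names(seqs)),
        biotype = sub("_[0-9]+$", "", names(seqs)),
        stringsAsFactors = FALSE)
    matures <- data.frame(mature_name = "mir_1.mature",
                          hairpin_id = "miRNA_hairpin_1",
                          start = 10L, end = 32L, stringsAsFactors = FALSE)
    cfRNAfrag:::newReferenceSet(
        Biostrings::DNAStringSet(seqs), ann, matures)
}

subseq_chr <- function(refset, id, start, end) {
    substring(as.character(refSequences(refset))[[id]], start + 1, end)
}
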