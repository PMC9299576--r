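test_that("planted reads align uniquely and strata suppress worse hits", {
    set.seed(71)
    tA <- randSeq(300); tB <- randSeq(300)
    read <- substr(tA, 101, 130)
    refs <- c(A = tA, B = tB)
    h <- alignReads(c(r = read), refs)
    expect_equal(nrow(h), 1)
    expect_equal(h$transcript_id, "A")
    expect_equal(h$start, 100)
    expect_equal(h$mismatches, 0)

    # plant an exact copy in A and a 1-mismatch copy in B: only A reported
    mut <- read
    substr(mut, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                   substr(mut, 15, 15))[1]
    refs2 <- c(A = paste0(tA, read), B = paste0(tB, mut))
    h2 <- alignReads(c(r = read), refs2)
    expect_true(all(h2$transcript_id == "A"))
    expect_true(all(h2$mismatches == 0))

    # with no exact hit anywhere, all 1-mismatch hits are reported
    h3 <- alignReads(c(r = mut), c(B = paste0(tB, read)))
    expect_true(all(h3$mismatches == 1))
    expect_true(nrow(h3) >= 1)
})

test_that("aligner matches the brute-force oracle on randomized instances", {
    set.seed(72)
    for (rep in 1:200) {
        refs <- setNames(vapply(1:5, function(i) randSeq(300), ""),
                         paste0("t", 1:5))
        # half the reads are planted (with an occasional mutation),
        # half are random
        if (rep %% 2 == 0) {
            src <- sample(5, 1)
            st <- sample(280, 1)
            read <- substr(refs[[src]], st, st + 19)
            if (rep %% 4 == 0) {
                p <- sample(20, 1)
                substr(read, p, p) <- sample(c("A", "C", "G", "T"), 1)
            }
        } else read <- randSeq(20)
        got <- alignReads(c(r = read), refs)
        want <- bruteAlign(read, refs)
        expect_equal(got[, c("transcript_id", "start", "mismatches")],
                     want, ignore_attr = TRUE)
    }
})

test_that("depletion-tier reads never reach later tiers", {
    ref <- makeTinyRefset()
    rd <- ReadSet("dep1", subseq_chr(ref, "rRNA_1", 50, 80))
    asg <- assignTiers(rd, ref)
    expect_equal(unname(asg$counts["n_depleted"]), 1L)
    expect_equal(nrow(asg$assignments), 0)
})

test_that("tRNA outranks piRNA; equal-stratum multi-gene hits split weight", {
    ref <- makeTinyRefset()
    seqs <- as.character(refSequences(ref))
    # a read present verbatim in both a tRNA and a piRNA
    shared <- substr(seqs[["piRNA_1"]], 1, 22)
    seqs2 <- seqs
    seqs2[["tRNA_1"]] <- paste0(substr(seqs[["tRNA_1"]], 1, 50), shared)
    ref2 <- cfRNAfrag:::newReferenceSet(Biostrings::DNAStringSet(seqs2),
                                        refAnnotation(ref),
                                        matureMiRNAs(ref))
    asg <- assignTiers(ReadSet("x", shared), ref2)
    a <- asg$assignments
    expect_equal(a$biotype, "tRNA")
    expect_equal(a$targets[[1]], "gene_tRNA_1")
    expect_equal(a$weight, 1.0)

    # a read hitting two piRNAs only splits 0.5/0.5
    seqs3 <- seqs
    seqs3[["piRNA_2"]] <- seqs3[["piRNA_1"]]
    ref3 <- cfRNAfrag:::newReferenceSet(Biostrings::DNAStringSet(seqs3),
                                        refAnnotation(ref),
                                        matureMiRNAs(ref))
    asg3 <- assignTiers(ReadSet("y", substr(seqs3[["piRNA_1"]], 1, 25)),
                        ref3)
    a3 <- asg3$assignments
    expect_equal(a3$n_targets, 2L)
    expect_equal(a3$weight, 0.5)
    expect_setequal(a3$targets[[1]], c("gene_piRNA_1", "gene_piRNA_2"))
})

test_that("the mature-position filter enforces the 3/5 nt offsets", {
    matures <- data.frame(mature_name = "m1", start = 10L, end = 32L,
                          stringsAsFactors = FALSE)
    # offsets (2, 1): kept
    expect_equal(mirnaPositionalFilter(12, 33, matures)$status, "kept")
    # boundary offsets (3, 5): kept
    expect_equal(mirnaPositionalFilter(13, 37, matures)$status, "kept")
    expect_equal(mirnaPositionalFilter(7, 27, matures)$status, "kept")
    # start offset 4 > 3: rejected
    expect_equal(mirnaPositionalFilter(14, 33, matures)$status, "rejected")
    # end offset 6 > 5: rejected
    expect_equal(mirnaPositionalFilter(10, 38, matures)$status, "rejected")
    # no annotated mature: distinct status
    expect_equal(mirnaPositionalFilter(10, 32,
        matures[0, , drop = FALSE])$status, "no_mature")
    # two qualifying matures: smallest start offset wins
    m2 <- data.frame(mature_name = c("near", "far"),
                     start = c(11L, 13L), end = c(33L, 33L),
                     stringsAsFactors = FALSE)
    expect_equal(mirnaPositionalFilter(11, 33, m2)$mature_name, "near")
})

test_that("mature-positioned hairpin reads are assigned, others fall through", {
    ref <- makeTinyRefset()
    mt <- matureMiRNAs(ref)  # mature at [10, 32) on an 80-nt hairpin
    good <- ReadSet("good", subseq_chr(ref, "miRNA_hairpin_1", 11, 33))
    off <- ReadSet("off", subseq_chr(ref, "miRNA_hairpin_1", 40, 70))
    asg <- assignTiers(good, ref)
    expect_equal(asg$assignments$tier, "miRNA")
    expect_equal(asg$assignments$targets[[1]], "mir_1.mature")
    asg2 <- assignTiers(off, ref)
    # fell through every tier: hairpin interior matches nothing else
    expect_equal(asg2$unmapped, "off")
    asg3 <- assignTiers(off, ref, mirnaFallthrough = FALSE)
    expect_equal(unname(asg3$counts["n_mirna_dropped"]), 1L)
})

test_that("read counts are conserved across tiers", {
    ref <- makeTinyRefset()
    cfg <- simulationConfig(seed = 73, n_fragments = 3000)
    lib <- generateLibrary(cfg, ref)
    f <- filterReads(trimReads(lib$r1, cfg$adapter_3p)$reads)
    asg <- assignTiers(f$reads, ref)
    expect_equal(unname(asg$counts["n_input"]),
                 unname(asg$counts["n_depleted"] +
                        asg$counts["n_assigned"] +
                        asg$counts["n_mirna_dropped"] +
                        asg$counts["n_unmapped"]))
})

test_that("adding transcripts to a later tier never changes earlier tiers", {
    ref <- makeTinyRefset()
    cfg <- simulationConfig(seed = 74, n_fragments = 800)
    lib <- generateLibrary(cfg, ref)
    f <- filterReads(trimReads(lib$r1, cfg$adapter_3p)$reads)
    asg1 <- assignTiers(f$reads, ref)
    # append an extra lncRNA (long tier) and an extra other_ncRNA
    set.seed(75)
    seqs <- c(as.character(refSequences(ref)),
              lncRNA_new = randSeq(400), other_ncRNA_new = randSeq(200))
    ann <- rbind(refAnnotation(ref), data.frame(
        transcript_id = c("lncRNA_new", "other_ncRNA_new"),
        gene_id = c("gene_lncRNA_new", "gene_other_ncRNA_new"),
        biotype = c("lncRNA", "other_ncRNA")))
    ref2 <- cfRNAfrag:::newReferenceSet(Biostrings::DNAStringSet(seqs),
                                        ann, matureMiRNAs(ref))
    asg2 <- assignTiers(f$reads, ref2)
    for (tn in c("miRNA", "small")) {
        a1 <- asg1$assignments[asg1$assignments$tier == tn, ]
        a2 <- asg2$assignments[asg2$assignments$tier == tn, ]
        expect_equal(a1$read_id, a2$read_id)
        expect_equal(a1$targets, a2$targets)
    }
    expect_equal(asg1$depleted, asg2$depleted)
})

test_that("sense/antisense fractions reflect the simulated orientation mix", {
    ref <- makeTinyRefset()
    seqs <- as.character(refSequences(ref))
    set.seed(76)
    n <- 5000
    starts <- sample(550, n, replace = TRUE)
    fwd <- substring(seqs[["mRNA_1"]], starts, starts + 29)
    sense <- runif(n) < 0.8
    reads <- ifelse(sense, fwd, cfRNAfrag:::revComp(fwd))
    res <- senseAntisenseRatio(ReadSet(paste0("r", 1:n), reads), ref)
    row <- res[res$biotype == "mRNA", ]
    se <- sqrt(0.8 * 0.2 / n)
    expect_lt(abs(row$sense_frac - 0.8), 3 * se)
    expect_equal(row$sense_frac + row$antisense_frac, 1)

    # pure construction limits
    all_s <- senseAntisenseRatio(ReadSet("s", fwd[1]), ref)
    expect_equal(all_s$sense_frac, 1.0)
    all_a <- senseAntisenseRatio(ReadSet("a", cfRNAfrag:::revComp(fwd[1])),
                                 ref)
    expect_equal(all_a$antisense_frac, 1.0)
})
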