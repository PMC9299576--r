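test_that("the paired-read rule computes the worked fragment length", {
    pairs <- data.frame(read_id = "p1", transcript_id = "t",
                        r1_start = 100L, r1_len = 90L,
                        r2_start = 300L, r2_len = 80L)
    fl <- fragmentLengths(pairs = pairs)
    expect_equal(fl$hist$length, 280L)
    expect_equal(fl$hist$count, 1L)

    # mate 1 below the threshold: pair not used
    pairs$r1_len <- 89L
    expect_equal(nrow(fragmentLengths(pairs = pairs)$hist), 0)

    # discordant orientation gives non-positive length: discarded + tallied
    disc <- data.frame(read_id = "p2", transcript_id = "t",
                       r1_start = 300L, r1_len = 95L,
                       r2_start = 100L, r2_len = 80L)
    fl2 <- fragmentLengths(pairs = disc)
    expect_equal(fl2$n_discordant, 1L)
    expect_equal(nrow(fl2$hist), 0)

    # merged alignments contribute their aligned length
    merged <- data.frame(read_id = "m1", aligned_length = 42L)
    expect_equal(fragmentLengths(merged = merged)$hist$length, 42L)
})

test_that("length classes split at 50 and 200 inclusive of the middle", {
    h <- data.frame(length = c(49L, 50L, 200L, 201L), count = rep(1L, 4))
    cf <- lengthClassFractions(h)
    expect_equal(unname(cf), c(0.25, 0.50, 0.25))
    h20 <- data.frame(length = 20L, count = 7L)
    expect_equal(unname(lengthClassFractions(h20)["lt50"]), 1.0)
    expect_error(lengthClassFractions(data.frame(length = integer(),
                                                 count = integer())),
                 "empty")
})

test_that("end contexts read bases and motifs off the reference", {
    ann <- data.frame(transcript_id = "t", gene_id = "g", biotype = "mRNA",
                      stringsAsFactors = FALSE)
    ref <- cfRNAfrag:::newReferenceSet(
        Biostrings::DNAStringSet(c(t = "TTAACGTTCCGG")), ann)
    ctx <- endContexts(data.frame(transcript_id = "t", start = 4L,
                                  end = 8L), ref)
    expect_equal(ctx$end5_base, "C")
    expect_equal(ctx$end3_base, "T")
    expect_equal(ctx$motif5, "AACG")
    expect_equal(ctx$motif3, "TTCC")

    # fragment at the transcript edge: motif absent, base still defined
    edge <- endContexts(data.frame(transcript_id = "t", start = 0L,
                                   end = 6L), ref)
    expect_true(is.na(edge$motif5))
    expect_equal(edge$end5_base, "T")
})

test_that("contexts agree with an independent slicing oracle", {
    ref <- makeTinyRefset()
    seqs <- as.character(refSequences(ref))
    set.seed(91)
    ids <- sample(c("mRNA_1", "mRNA_2", "lncRNA_1"), 1000, replace = TRUE)
    L <- nchar(seqs[ids])
    start <- vapply(L, function(l) sample.int(l - 20, 1) - 1L, integer(1))
    end <- pmin(start + sample(18:60, 1000, replace = TRUE), L)
    ctx <- endContexts(data.frame(transcript_id = ids, start = start,
                                  end = end), ref)
    for (i in sample(1000, 200)) {
        ch <- strsplit(seqs[[ids[i]]], "")[[1]]
        expect_identical(ctx$end5_base[i], ch[start[i] + 1])
        expect_identical(ctx$end3_base[i], ch[end[i]])
        m5 <- if (start[i] >= 2 && start[i] + 2 <= length(ch))
            paste(ch[(start[i] - 1):(start[i] + 2)], collapse = "")
            else NA_character_
        m3 <- if (end[i] >= 2 && end[i] + 2 <= length(ch))
            paste(ch[(end[i] - 1):(end[i] + 2)], collapse = "")
            else NA_character_
        expect_identical(ctx$motif5[i], m5)
        expect_identical(ctx$motif3[i], m3)
    }
    # universal consistency: the 3' base is the 2nd character of its motif
    ok <- !is.na(ctx$motif3)
    expect_identical(substr(ctx$motif3[ok], 2, 2), ctx$end3_base[ok])
    ok5 <- !is.na(ctx$motif5)
    expect_identical(substr(ctx$motif5[ok5], 3, 3), ctx$end5_base[ok5])
})

test_that("end statistics compute base frequencies and ratios", {
    ctx <- data.frame(end5_base = c("A", "A", "C", "G"),
                      end3_base = c("T", "T", "C", "G"),
                      motif5 = NA_character_, motif3 = NA_character_,
                      stringsAsFactors = FALSE)
    st <- endStatistics(ctx)
    expect_equal(st$py_pu_ratio_3p, 3.0)
    expect_equal(st$adenine_rate_5p, 0.5)
    expect_equal(sum(st$end5_base_freq), 1)
    expect_equal(sum(st$end3_base_freq), 1)
    allpy <- data.frame(end5_base = "A", end3_base = c("C", "T"),
                        stringsAsFactors = FALSE)
    expect_warning(st2 <- endStatistics(allpy), "Inf")
    expect_equal(st2$py_pu_ratio_3p, Inf)
})

test_that("motif profiles have 256 entries summing to 100", {
    ctx <- data.frame(motif3 = rep("AACG", 7), motif5 = NA_character_,
                      stringsAsFactors = FALSE)
    mp <- motifProfile(ctx, "three_prime")
    expect_length(mp, 256)
    expect_equal(unname(mp["AACG"]), 100)
    expect_equal(sum(mp), 100)
    expect_error(motifProfile(ctx, "five_prime"), "no defined")
    # N-containing motifs are excluded from numerator and denominator
    ctxN <- data.frame(motif3 = c("AACG", "ANCG"), motif5 = NA_character_,
                       stringsAsFactors = FALSE)
    expect_equal(unname(motifProfile(ctxN, "three_prime")["AACG"]), 100)

    # uniform fragments on a uniform reference: flat profile (long
    # reference so end positions barely repeat and counts are multinomial)
    set.seed(92)
    n <- 10000
    big <- randSeq(60000)
    refBig <- cfRNAfrag:::newReferenceSet(
        Biostrings::DNAStringSet(c(big = big)),
        data.frame(transcript_id = "big", gene_id = "g", biotype = "mRNA",
                   stringsAsFactors = FALSE))
    starts <- sample(59000, n) + 10
    ctxU <- endContexts(data.frame(transcript_id = "big",
                                   start = starts, end = starts + 30),
                        refBig)
    mpU <- motifProfile(ctxU, "three_prime")
    chi <- suppressWarnings(chisq.test(table(factor(
        ctxU$motif3[!is.na(ctxU$motif3)], levels = names(mpU)))))
    expect_gt(chi$p.value, 0.01)
})

test_that("3' pyrimidine ratio rises with cleavage bias and is ~1 unbiased", {
    ref <- makeTinyRefset()
    ann <- data.frame(transcript_id = "u", gene_id = "g", biotype = "mRNA",
                      stringsAsFactors = FALSE)
    set.seed(93)
    s <- randSeq(4000, gc = 0.5)
    refU <- cfRNAfrag:::newReferenceSet(Biostrings::DNAStringSet(c(u = s)),
                                        ann)
    ratios <- vapply(c(1, 2, 4, 8), function(w) {
        set.seed(94)
        fr <- fragmentTranscript(s, 20000, wPy = w)
        st <- endStatistics(endContexts(
            data.frame(transcript_id = "u", start = fr$start, end = fr$end),
            refU))
        st$py_pu_ratio_3p
    }, numeric(1))
    expect_true(all(diff(ratios) > 0))
    # heat-like control: w_py = 1 matches the reference composition
    f_py <- mean(strsplit(s, "")[[1]] %in% c("C", "T"))
    expect_equal(ratios[1], f_py / (1 - f_py), tolerance = 0.1)
})

test_that("fragmentProfile bundles histogram, classes, ends and motifs", {
    ref <- makeTinyRefset()
    set.seed(95)
    starts <- sample(400, 500, replace = TRUE) + 20
    frag <- data.frame(transcript_id = "mRNA_1", start = starts,
                       end = starts + sample(c(30, 120), 500, TRUE))
    pr <- fragmentProfile(frag, ref)
    expect_s4_class(pr, "FragmentProfile")
    expect_equal(sum(pr@class_fractions), 1)
    expect_equal(sum(pr@motif3), 100, tolerance = 1e-6)
    expect_length(pr@motif3, 256)
})
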