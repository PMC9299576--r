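test_that("simulated transcriptomes hit the target GC and are reproducible", {
    ref <- simulateTranscriptome(seed = 3,
        nGenesPerBiotype = c(mRNA = 10), lengthRanges = list(mRNA = c(500, 500)))
    seqs <- as.character(refSequences(ref))
    gcs <- vapply(seqs, function(s)
        mean(strsplit(s, "")[[1]] %in% c("G", "C")), numeric(1))
    # binomial CI at n = 5000 bases
    expect_gt(mean(gcs), 0.40)
    expect_lt(mean(gcs), 0.60)

    ref2 <- simulateTranscriptome(seed = 3,
        nGenesPerBiotype = c(mRNA = 10), lengthRanges = list(mRNA = c(500, 500)))
    expect_identical(as.character(refSequences(ref)),
                     as.character(refSequences(ref2)))

    refgc <- simulateTranscriptome(seed = 4,
        nGenesPerBiotype = c(mRNA = 3), gc = 1.0)
    expect_false(any(grepl("[AT]", as.character(refSequences(refgc)))))
})

test_that("hairpins embed one valid mature each", {
    ref <- simulateTranscriptome(seed = 5,
        nGenesPerBiotype = c(miRNA_hairpin = 12))
    mt <- matureMiRNAs(ref)
    expect_equal(nrow(mt), 12)
    w <- mt$end - mt$start
    expect_true(all(w >= 20 & w <= 23))
    hl <- transcriptLengths(ref)[mt$hairpin_id]
    expect_true(all(mt$start >= 0 & mt$end <= hl))
})

test_that("cleavage bias follows the closed-form pyrimidine fraction", {
    set.seed(21)
    s <- randSeq(2000, gc = 0.5)  # E[f_py] = 0.5
    bases <- strsplit(s, "")[[1]]
    f_py <- mean(bases %in% c("C", "T"))
    n <- 10000

    # unbiased: 3'-pyrimidine fraction equals the base composition
    fr1 <- fragmentTranscript(s, n, wPy = 1)
    end3 <- bases[fr1$end]
    p1 <- mean(end3 %in% c("C", "T"))
    se <- sqrt(f_py * (1 - f_py) / n)
    expect_lt(abs(p1 - f_py), 3 * se)

    # w_py = 4: expected fraction w f_py / (w f_py + f_pu)
    fr4 <- fragmentTranscript(s, n, wPy = 4)
    p4 <- mean(bases[fr4$end] %in% c("C", "T"))
    expected <- 4 * f_py / (4 * f_py + (1 - f_py))
    expect_lt(abs(p4 - expected), 3 * sqrt(expected * (1 - expected) / n))

    # w_py -> Inf: every cut 3' of a pyrimidine
    frI <- fragmentTranscript(s, 500, wPy = Inf)
    expect_true(all(bases[frI$end] %in% c("C", "T")))

    # degenerate purine-only sequence still fragments
    frG <- fragmentTranscript(strrep("AG", 50), 100, wPy = 4)
    expect_equal(nrow(frG), 100)
    expect_true(all(frG$end > frG$start))

    # fragments lie within the transcript
    expect_true(all(fr4$start >= 0 & fr4$end <= nchar(s)))
    # RNase channel carries 5'OH/3'P
    expect_true(all(fr4$end_chemistry == "OH5_P3"))
    frMix <- fragmentTranscript(s, 2000, wPy = 4, rnaseAProb = 0.5)
    expect_true(all(sort(unique(frMix$end_chemistry)) ==
                    c("OH5_P3", "P5_OH3")))
})

test_that("capture gating follows PNK treatment and end chemistry", {
    ref <- makeTinyRefset()
    cfg_off <- simulationConfig(seed = 8, n_fragments = 300,
        rnasea_channel_prob = 1.0, pnk_treated = FALSE,
        depletion_enabled = FALSE)
    expect_error(generateLibrary(cfg_off, ref), "captured|config|PNK")
    lib <- generateLibrary(cfg_off, ref, allowEmpty = TRUE)
    expect_equal(length(lib$r1), 0)
    expect_equal(nrow(lib$truth), 300)
    expect_false(any(lib$truth$captured))

    cfg_on <- simulationConfig(seed = 8, n_fragments = 300,
        rnasea_channel_prob = 1.0, pnk_treated = TRUE,
        depletion_enabled = FALSE)
    lib_on <- generateLibrary(cfg_on, ref)
    expect_true(all(lib_on$truth$captured))
    # capture invariant: captured implies PNK or pre-phosphorylated ends
    cfg_mix <- simulationConfig(seed = 9, n_fragments = 2000,
        rnasea_channel_prob = 0.6, pnk_treated = FALSE)
    tr <- generateLibrary(cfg_mix, ref)$truth
    expect_true(all(tr$end_chemistry[tr$captured] == "P5_OH3"))
})

test_that("depletion removes the abundant-RNA tier at the configured rate", {
    ref <- makeTinyRefset()
    cfg <- simulationConfig(seed = 10, n_fragments = 5000,
        depletion_enabled = TRUE, depletion_frac = 1.0)
    tr <- generateLibrary(cfg, ref)$truth
    dep <- tr$biotype %in% c("rRNA", "Y_RNA", "vtRNA")
    expect_false(any(tr$captured[dep]))
    expect_true(all(tr$reason[dep & tr$end_chemistry == "OH5_P3"] %in%
                    c("depleted", "end_chemistry", "ok")))
})

test_that("read layout is fragment + poly(A) + adapter truncated to length", {
    # single mRNA so the fragment origin is known; long adapter makes the
    # truncation arithmetic visible
    ann <- data.frame(transcript_id = "m1", gene_id = "g1",
                      biotype = "mRNA", stringsAsFactors = FALSE)
    set.seed(30)
    s <- randSeq(400)
    ref <- cfRNAfrag:::newReferenceSet(
        Biostrings::DNAStringSet(c(m1 = s)), ann)
    adapter <- paste(rep("AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC", 2),
                     collapse = "")  # 68 nt
    cfg <- simulationConfig(seed = 12, n_fragments = 200,
        biotype_mix = c(mRNA = 1), depletion_enabled = FALSE,
        adapter_3p = adapter, polyA_len = 20, read_length = 100,
        length_mixture = lengthMixture(short_fraction = 1, short_min = 30,
                                       short_mean = 31))
    lib <- generateLibrary(cfg, ref)
    tr <- lib$truth[lib$truth$captured, ]
    i <- which(tr$length == 30)[1]
    expect_false(is.na(i))
    rd <- readSeqs(lib$r1)[match(tr$fragment_id[i], readIds(lib$r1))]
    insert <- substring(s, tr$start[i] + 1, tr$end[i])
    expect_equal(nchar(rd), 100)
    expect_equal(rd, paste0(insert, strrep("A", 20),
                            substr(adapter, 1, 50)))
})

test_that("the library is byte-deterministic under its seed", {
    ref <- makeTinyRefset()
    cfg <- simulationConfig(seed = 77, n_fragments = 500, paired = TRUE)
    a <- generateLibrary(cfg, ref)
    b <- generateLibrary(cfg, ref)
    expect_identical(readSeqs(a$r1), readSeqs(b$r1))
    expect_identical(readSeqs(a$r2), readSeqs(b$r2))
    expect_identical(a$truth, b$truth)
    td <- withr::local_tempdir()
    writeFastq(a$r1, file.path(td, "a.fastq"))
    writeFastq(b$r1, file.path(td, "b.fastq"))
    expect_identical(readLines(file.path(td, "a.fastq")),
                     readLines(file.path(td, "b.fastq")))
})
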