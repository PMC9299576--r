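#' Default fragment-length mixture
#'
#' cfRNA fragment lengths are modeled as a two-component mixture: a short,
#' degraded component (offset geometric with mode `short_min`, emulating the
#' sub-50-nt fragments that dominate most biofluids) and a long component
#' (uniform between `long_min` and `long_max`, the partially intact tail).
#'
#' @param short_fraction mass of the short component.
#' @param short_min,short_mean minimum and mean of the short component (nt).
#' @param long_min,long_max range of the long component (nt).
#' @return A list usable as the `length_mixture` of [simulationConfig()].
#' @export
lengthMixture <- function(short_fraction = 0.9, short_min = 20,
                          short_mean = 32, long_min = 50, long_max = 500) {
    stopifnot(short_fraction >= 0, short_fraction <= 1,
              short_min >= 1, short_mean > short_min, long_min <= long_max)
    list(short_fraction = short_fraction, short_min = short_min,
         short_mean = short_mean, long_min = long_min, long_max = long_max)
}

drawFragmentLengths <- function(n, mix) {
    short <- stats::runif(n) < mix$short_fraction
    p <- 1 / (mix$short_mean - mix$short_min + 1)
    len <- integer(n)
    len[short] <- mix$short_min + stats::rgeom(sum(short), p)
    len[!short] <- sample(seq(mix$long_min, mix$long_max), sum(!short),
                          replace = TRUE)
    pmax(len, 1L)
}

#' Configuration of a synthetic cfRNA library
#'
#' Bundles every generative parameter of the simulator: transcript abundance
#' (log-normal over genes within each biotype), the biotype mixture of
#' fragments, RNase-A cleavage bias (`w_py`, the relative weight of cutting
#' 3' of a pyrimidine; purine weight fixed at 1), the two-channel fragment
#' end chemistry (`rnasea_channel_prob` is the probability a fragment comes
#' from RNase-A degradation and so carries 5'-OH/3'-P ends; the remainder
#' are pre-phosphorylated 5'-P/3'-OH with unbiased ends), PNK-treatment
#' capture gating, in-silico depletion of the abundant-RNA tier, the
#' fragment-length mixture, and the library layout (read length, pairing,
#' poly(A) tail, 3' adapter).
#'
#' @param seed integer RNG seed (mandatory; the whole library is
#'   deterministic given the config).
#' @param n_fragments number of fragments generated before capture.
#' @param biotype_mix named proportions over biotypes (sum 1).
#' @param abundance_meanlog,abundance_sdlog log-normal gene-abundance model.
#' @param w_py relative cleavage weight 3' of C/T (>= 1; `Inf` allowed).
#' @param rnasea_channel_prob probability of the RNase-A end-chemistry
#'   channel.
#' @param pnk_treated logical; when `FALSE` only 5'-P/3'-OH fragments are
#'   captured.
#' @param depletion_enabled,depletion_frac drop depletion-tier fragments
#'   with this probability at capture.
#' @param length_mixture see [lengthMixture()].
#' @param read_length sequencing read length (nt).
#' @param paired emit mate 2 (reverse complement from the fragment 3' end).
#' @param adapter_3p 3' sequencing adapter appended after the poly(A) tail.
#' @param polyA_len poly(A) tail length added to every fragment.
#' @param error_rate uniform substitution error rate on reads.
#' @param low_qual_tail number of read tail bases written at Q2 to exercise
#'   quality trimming (0 = constant Q40).
#' @return A validated `SimulationConfig` list.
#' @export
simulationConfig <- function(seed,
    n_fragments = 10000,
    biotype_mix = c(rRNA = 0.18, Y_RNA = 0.05, vtRNA = 0.02,
                    miRNA_hairpin = 0.25, tRNA = 0.10, piRNA = 0.05,
                    mRNA = 0.20, lncRNA = 0.10, other_ncRNA = 0.05),
    abundance_meanlog = 0, abundance_sdlog = 1.5,
    w_py = 4, rnasea_channel_prob = 0.8, pnk_treated = TRUE,
    depletion_enabled = TRUE, depletion_frac = 0.9,
    length_mixture = lengthMixture(), read_length = 100, paired = FALSE,
    adapter_3p = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC", polyA_len = 20,
    error_rate = 0, low_qual_tail = 0) {
    cfg <- list(seed = as.integer(seed), n_fragments = as.integer(n_fragments),
        biotype_mix = biotype_mix, abundance_meanlog = abundance_meanlog,
        abundance_sdlog = abundance_sdlog, w_py = w_py,
        rnasea_channel_prob = rnasea_channel_prob,
        pnk_treated = isTRUE(pnk_treated),
        depletion_enabled = isTRUE(depletion_enabled),
        depletion_frac = depletion_frac, length_mixture = length_mixture,
        read_length = as.integer(read_length), paired = isTRUE(paired),
        adapter_3p = toupper(adapter_3p), polyA_len = as.integer(polyA_len),
        error_rate = error_rate, low_qual_tail = as.integer(low_qual_tail))
    validateSimulationConfig(cfg)
    structure(cfg, class = "SimulationConfig")
}

validateSimulationConfig <- function(cfg) {
    stopifnot(cfg$n_fragments > 0, cfg$read_length > 0,
              cfg$w_py >= 1, cfg$polyA_len >= 0,
              nchar(cfg$adapter_3p) > 0)
    probs <- c(cfg$rnasea_channel_prob, cfg$depletion_frac, cfg$error_rate)
    if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
    if (is.null(names(cfg$biotype_mix)) ||
        !all(names(cfg$biotype_mix) %in% BIOTYPES))
        stop("biotype_mix must be named by known biotypes")
    if (abs(sum(cfg$biotype_mix) - 1) > 1e-9)
        stop("biotype_mix must sum to 1")
    invisible(TRUE)
}

#' Simulate a biotype-annotated transcriptome
#'
#' Generates random transcript sequences per biotype at a target GC content,
#' with one embedded 20-23 nt mature miRNA per hairpin. Deterministic under
#' `seed`.
#'
#' @param seed integer RNG seed.
#' @param nGenesPerBiotype named integer vector, genes per biotype.
#' @param lengthRanges named list of `c(min, max)` transcript lengths (nt);
#'   defaults are typical for each biotype.
#' @param gc target GC fraction in (0, 1); `gc = 1` yields G/C-only
#'   sequences.
#' @return A [ReferenceSet].
#' @export
simulateTranscriptome <- function(seed,
    nGenesPerBiotype = c(rRNA = 3, Y_RNA = 2, vtRNA = 2, miRNA_hairpin = 30,
                         tRNA = 20, piRNA = 30, mRNA = 40, lncRNA = 15,
                         other_ncRNA = 5),
    lengthRanges = NULL, gc = 0.5) {
    stopifnot(gc > 0, gc <= 1, all(names(nGenesPerBiotype) %in% BIOTYPES))
    defaults <- list(rRNA = c(1000, 1800), Y_RNA = c(80, 110),
                     vtRNA = c(88, 100), miRNA_hairpin = c(60, 90),
                     tRNA = c(70, 90), piRNA = c(26, 32),
                     mRNA = c(500, 3000), lncRNA = c(300, 2000),
                     other_ncRNA = c(100, 300))
    if (is.null(lengthRanges)) lengthRanges <- defaults
    for (b in names(nGenesPerBiotype))
        if (is.null(lengthRanges[[b]])) lengthRanges[[b]] <- defaults[[b]]
    set.seed(seed)
    pbase <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    ids <- character(0); bts <- character(0); seqs <- character(0)
    matures <- emptyMatureTable()
    for (b in intersect(BIOTYPES, names(nGenesPerBiotype))) {
        nb <- nGenesPerBiotype[[b]]
        if (nb < 1) next
        rng <- lengthRanges[[b]]
        lens <- sample(seq(rng[1], rng[2]), nb, replace = TRUE)
        for (i in seq_len(nb)) {
            id <- sprintf("%s_%04d", b, i)
            s <- paste(sample(names(pbase), lens[i], replace = TRUE,
                              prob = pbase), collapse = "")
            ids <- c(ids, id); bts <- c(bts, b); seqs <- c(seqs, s)
            if (b == "miRNA_hairpin") {
                w <- sample(20:23, 1)
                st <- sample.int(lens[i] - w + 1, 1) - 1L
                matures <- rbind(matures, data.frame(
                    mature_name = paste0(id, ".mature"), hairpin_id = id,
                    start = st, end = st + w, stringsAsFactors = FALSE))
            }
        }
    }
    ann <- data.frame(transcript_id = ids,
                      gene_id = paste0("gene_", ids),
                      biotype = bts, stringsAsFactors = FALSE)
    newReferenceSet(stats::setNames(Biostrings::DNAStringSet(seqs), ids),
                    ann, matures)
}

#' Fragment one transcript under RNase-A-like cleavage bias
#'
#' Draws `n` fragments from a transcript. Each fragment is assigned to the
#' RNase-A channel with probability `rnaseAProb`: its 3'-end cut position is
#' then sampled with weight `wPy` at positions whose terminal (5'-of-cut)
#' base is C or T and weight 1 otherwise, and the fragment carries 5'-OH/3'-P
#' ends (`OH5_P3`). Other fragments cut uniformly and carry 5'-P/3'-OH ends
#' (`P5_OH3`). The fragment extent is a draw from the length mixture anchored
#' at the cut, truncated at the transcript 5' end. Under this rule the
#' probability that a cut's 3'-terminal base is a pyrimidine is
#' `wPy * f_py / (wPy * f_py + f_pu)` where `f_py`, `f_pu` are the
#' transcript's base fractions.
#'
#' @param sequence transcript sequence (character, DNA alphabet), >= 20 nt.
#' @param n number of fragments.
#' @param wPy pyrimidine cut weight (>= 1; `Inf` restricts cuts to
#'   pyrimidine positions when any exist).
#' @param mixture a [lengthMixture()].
#' @param rnaseAProb probability of the RNase-A channel per fragment.
#' @return data.frame(start, end, end_chemistry), 0-based half-open.
#' @export
fragmentTranscript <- function(sequence, n, wPy = 4,
                               mixture = lengthMixture(),
                               rnaseAProb = 1) {
    len <- nchar(sequence)
    stopifnot(len >= 20, wPy >= 1, n >= 1)
    bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
    is_py <- bases %in% c("C", "T")
    chem <- ifelse(stats::runif(n) < rnaseAProb, "OH5_P3", "P5_OH3")
    ends <- integer(n)
    biased <- chem == "OH5_P3"
    if (any(biased)) {
        if (is.infinite(wPy)) {
            pool <- which(is_py)
            if (!length(pool)) pool <- seq_len(len)
            ends[biased] <- pool[sample.int(length(pool), sum(biased),
                                            replace = TRUE)]
        } else {
            w <- ifelse(is_py, wPy, 1)
            ends[biased] <- sample.int(len, sum(biased), replace = TRUE,
                                       prob = w)
        }
    }
    if (any(!biased))
        ends[!biased] <- sample.int(len, sum(!biased), replace = TRUE)
    L <- drawFragmentLengths(n, mixture)
    start <- pmax(0L, ends - L)
    data.frame(start = start, end = ends, end_chemistry = chem,
               stringsAsFactors = FALSE)
}

#' Generate a synthetic cfRNA sequencing library with ground truth
#'
#' Samples fragments across the reference proportionally to biotype mixture
#' and gene abundance (mass-weighted: molar abundance times transcript
#' length), fragments each transcript under the configured cleavage model,
#' applies the capture rule (PNK treatment admits every fragment; otherwise
#' only pre-phosphorylated 5'-P/3'-OH fragments ligate) and in-silico
#' depletion of the abundant-RNA tier, then emits reads laid out as
#' fragment + poly(A) tail + 3' adapter, truncated to the read length.
#' In paired mode, mate 2 is the reverse complement read from the fragment
#' 3' end. Deterministic under `config$seed`.
#'
#' @param config a [simulationConfig()].
#' @param refset a [ReferenceSet].
#' @param allowEmpty return an empty library instead of erroring when no
#'   fragment is captured.
#' @return list with `r1` (and `r2` when paired) [ReadSet]s of captured
#'   fragments, `truth` (per-fragment table: coordinates, biotype, end
#'   chemistry, captured flag and reason), and `geneTruth` (per-gene molar
#'   abundance with its TPM-scale normalization over all genes and over the
#'   mRNA/lncRNA tier).
#' @export
generateLibrary <- function(config, refset, allowEmpty = FALSE) {
    validateSimulationConfig(config)
    set.seed(config$seed)
    ann <- refAnnotation(refset)
    lens <- transcriptLengths(refset)
    seqs <- as.character(refSequences(refset))

    mix <- config$biotype_mix[config$biotype_mix > 0]
    mix <- mix[names(mix) %in% unique(ann$biotype)]
    if (!length(mix)) stop("no biotype in biotype_mix present in refset")
    mix <- mix / sum(mix)

    # gene-level molar abundance, log-normal within biotype
    theta <- stats::rlnorm(nrow(ann), config$abundance_meanlog,
                           config$abundance_sdlog)
    names(theta) <- ann$transcript_id
    # fragment-generating weight: biotype share x mass (molar x length)
    w <- numeric(nrow(ann))
    for (b in names(mix)) {
        sel <- ann$biotype == b
        mass <- theta[sel] * lens[ann$transcript_id[sel]]
        w[sel] <- mix[[b]] * mass / sum(mass)
    }
    tx <- sample.int(nrow(ann), config$n_fragments, replace = TRUE, prob = w)

    # fragment each transcript
    parts <- vector("list", nrow(ann))
    for (t in sort(unique(tx))) {
        nt <- sum(tx == t)
        fr <- fragmentTranscript(seqs[[t]], nt, wPy = config$w_py,
                                 mixture = config$length_mixture,
                                 rnaseAProb = config$rnasea_channel_prob)
        fr$transcript_id <- ann$transcript_id[t]
        parts[[t]] <- fr
    }
    truth <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
    rownames(truth) <- NULL
    truth$fragment_id <- sprintf("frag%07d", seq_len(nrow(truth)))
    truth$gene_id <- ann$gene_id[match(truth$transcript_id,
                                       ann$transcript_id)]
    truth$biotype <- ann$biotype[match(truth$transcript_id,
                                       ann$transcript_id)]
    truth$length <- truth$end - truth$start

    # capture gating: PNK treatment admits all end chemistries
    truth$reason <- "ok"
    if (!config$pnk_treated) {
        miss <- truth$end_chemistry != "P5_OH3"
        truth$reason[miss] <- "end_chemistry"
    }
    if (config$depletion_enabled) {
        dep <- truth$biotype %in% DEFAULT_TIERS$depletion &
            truth$reason == "ok" &
            stats::runif(nrow(truth)) < config$depletion_frac
        truth$reason[dep] <- "depleted"
    }
    truth$captured <- truth$reason == "ok"
    truth <- truth[, c("fragment_id", "transcript_id", "gene_id", "biotype",
                       "start", "end", "length", "end_chemistry",
                       "captured", "reason")]

    # effective molar abundance: the biotype mixture is part of the
    # abundance model, so a transcript's true molar share is its biotype
    # share times its within-biotype molar fraction (fragment rate / length)
    theta_eff <- numeric(nrow(ann))
    for (b in names(mix)) {
        sel <- ann$biotype == b
        mass <- theta[sel] * lens[ann$transcript_id[sel]]
        theta_eff[sel] <- mix[[b]] * theta[sel] / sum(mass)
    }
    gt <- data.frame(gene_id = ann$gene_id, biotype = ann$biotype,
                     theta = theta_eff, stringsAsFactors = FALSE)
    gt <- stats::aggregate(theta ~ gene_id + biotype, gt, sum)
    gt$tpm_truth <- 1e6 * gt$theta / sum(gt$theta)
    long <- gt$biotype %in% DEFAULT_TIERS$long
    gt$tpm_truth_long <- NA_real_
    if (any(long))
        gt$tpm_truth_long[long] <- 1e6 * gt$theta[long] / sum(gt$theta[long])

    cap <- truth[truth$captured, , drop = FALSE]
    if (nrow(cap) == 0) {
        if (!allowEmpty)
            stop("no fragment was captured; with pnk_treated = FALSE the ",
                 "library needs rnasea_channel_prob < 1 (or enable PNK ",
                 "treatment)")
        empty <- ReadSet(character(0), character(0))
        return(list(r1 = empty, r2 = if (config$paired) empty else NULL,
                    truth = truth, geneTruth = gt, config = config))
    }

    insert <- substring(seqs[cap$transcript_id], cap$start + 1L, cap$end)
    construct <- paste0(insert, strrep("A", config$polyA_len),
                        config$adapter_3p)
    r1seq <- substr(construct, 1L, config$read_length)
    if (config$error_rate > 0) r1seq <- mutateReads(r1seq, config$error_rate)
    r1 <- ReadSet(cap$fragment_id, r1seq,
                  qualStrings(nchar(r1seq), config$low_qual_tail))
    r2 <- NULL
    if (config$paired) {
        r2seq <- substr(revComp(insert), 1L, config$read_length)
        if (config$error_rate > 0)
            r2seq <- mutateReads(r2seq, config$error_rate)
        r2 <- ReadSet(cap$fragment_id, r2seq,
                      qualStrings(nchar(r2seq), config$low_qual_tail))
    }
    list(r1 = r1, r2 = r2, truth = truth, geneTruth = gt, config = config)
}

qualStrings <- function(widths, low_tail = 0) {
    if (low_tail <= 0) return(strrep("I", widths))
    t <- pmin(low_tail, widths)
    paste0(strrep("I", widths - t), strrep("#", t))
}

mutateReads <- function(seqs, rate) {
    alphabet <- c("A", "C", "G", "T")
    vapply(seqs, function(s) {
        n <- nchar(s)
        k <- stats::rbinom(1, n, rate)
        if (k == 0) return(s)
        pos <- sample.int(n, k)
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        for (p in pos) ch[p] <- sample(setdiff(alphabet, ch[p]), 1)
        paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
}
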