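pipelineDefaults <- function() {
    list(
        seed = 1L,
        outdir = NULL,
        reference = NULL,   # list(fasta, annotation, mature)
        fastq = NULL,       # list(r1, r2)
        simulate = NULL,    # list(transcriptome = <args>, library = <args>)
        preprocess = list(adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                          min_len = 17, max_n_frac = 0.10, qual = 15,
                          min_polyA = 5),
        align = list(k = 8, max_mismatches = 1,
                     rpm_include_depleted = FALSE),
        fragmentomics = list(full_length_threshold = 90),
        merge = list(min_overlap = 10, max_mismatch_rate = 0.1)
    )
}

mergeConfig <- function(defaults, user) {
    for (nm in names(user)) {
        if (is.list(user[[nm]]) && is.list(defaults[[nm]]))
            defaults[[nm]] <- mergeConfig(defaults[[nm]], user[[nm]])
        else defaults[[nm]] <- user[[nm]]
    }
    defaults
}

#' Run the full cfRNA analysis pipeline
#'
#' Orchestrates the stages in order: (optionally) simulate a reference and
#' library, clean reads (adapter/poly(A)/quality trimming, 17-nt and
#' N-content filters), merge pairs, assign reads tier by tier, quantify
#' (RPM for small RNAs, EM TPM for mRNA/lncRNA) and profile fragments
#' (length histogram and classes, end bases, 4-mer motifs). Writes TSV
#' tables and a JSON run manifest recording the seed, a config hash and
#' per-stage read counts (conserved: input = depleted + assigned +
#' unmapped). Outputs are byte-identical across reruns of the same config.
#'
#' @param config a nested list (or path to a YAML file): `seed`, `outdir`,
#'   and either `reference` (paths for [loadReferences()]) plus `fastq`
#'   (paths `r1`, optional `r2`) or `simulate` (lists `transcriptome` and
#'   `library` of arguments for [simulateTranscriptome()] and
#'   [simulationConfig()]); optional `preprocess`, `align`,
#'   `fragmentomics`, `merge` parameter blocks (see `pipelineDefaults`).
#' @return Invisibly, a list of the stage results: `refset`, `truth` (when
#'   simulated), `cleanup`, `assignment` counts, `smallCounts`, `tpm`,
#'   `profile` and `manifest`.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- mergeConfig(pipelineDefaults(), config)
    if (is.null(cfg$outdir)) stop("config$outdir is required")
    dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

    # references
    if (!is.null(cfg$reference)) {
        refset <- loadReferences(cfg$reference$fasta,
                                 cfg$reference$annotation,
                                 cfg$reference$mature)
    } else if (!is.null(cfg$simulate)) {
        targs <- cfg$simulate$transcriptome
        if (is.null(targs$seed)) targs$seed <- cfg$seed
        refset <- do.call(simulateTranscriptome, targs)
    } else stop("config needs either $reference or $simulate")

    # reads
    truth <- NULL
    if (!is.null(cfg$fastq)) {
        r1 <- readFastq(cfg$fastq$r1)
        r2 <- if (!is.null(cfg$fastq$r2)) readFastq(cfg$fastq$r2) else NULL
    } else {
        largs <- cfg$simulate$library
        if (is.null(largs$seed)) largs$seed <- cfg$seed
        lib <- generateLibrary(do.call(simulationConfig, largs), refset)
        r1 <- lib$r1; r2 <- lib$r2; truth <- lib$truth
        utils::write.table(truth, file.path(cfg$outdir, "truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }

    # preprocess
    pp <- cfg$preprocess
    t1 <- trimReads(r1, pp$adapter, qualThreshold = pp$qual,
                    minPolyA = pp$min_polyA)
    f1 <- filterReads(t1$reads, minLen = pp$min_len,
                      maxNFrac = pp$max_n_frac)
    cleanup <- c(t1$stats, f1$report[-1])
    merged_aln <- NULL; pair_tab <- NULL
    if (!is.null(r2)) {
        t2 <- trimReads(r2, pp$adapter, qualThreshold = pp$qual,
                        minPolyA = pp$min_polyA)
        f2 <- filterReads(t2$reads, minLen = pp$min_len,
                          maxNFrac = pp$max_n_frac)
        keep <- intersect(readIds(f1$reads), readIds(f2$reads))
        p1 <- f1$reads[match(keep, readIds(f1$reads))]
        p2 <- f2$reads[match(keep, readIds(f2$reads))]
        mg <- mergePairs(p1, p2, minOverlap = cfg$merge$min_overlap,
                         maxMismatchRate = cfg$merge$max_mismatch_rate)
        solo <- f1$reads[!(readIds(f1$reads) %in% keep)]
        analysis_reads <- ReadSet(
            c(readIds(mg$merged), readIds(mg$unmergedR1), readIds(solo)),
            c(readSeqs(mg$merged), readSeqs(mg$unmergedR1), readSeqs(solo)),
            c(readQuals(mg$merged), readQuals(mg$unmergedR1),
              readQuals(solo)))
        unmerged1 <- mg$unmergedR1; unmerged2 <- mg$unmergedR2
    } else {
        analysis_reads <- f1$reads
        unmerged1 <- NULL; unmerged2 <- NULL
        mg <- NULL
    }
    writeFastq(analysis_reads, file.path(cfg$outdir, "clean.fastq"))

    # tier assignment
    al <- cfg$align
    asg <- assignTiers(analysis_reads, refset,
                       maxMismatch = al$max_mismatches, k = al$k)

    # quantification
    small <- countSmallRNA(asg$assignments)
    total_mapped <- asg$counts[["n_assigned"]] +
        if (isTRUE(al$rpm_include_depleted))
            asg$counts[["n_depleted"]] else 0L
    if (nrow(small) && total_mapped > 0)
        small <- rpmNormalize(small, total_mapped)
    ann <- refAnnotation(refset)
    long_tx <- ann$transcript_id[ann$biotype %in%
                                 tierDefinitions(refset)$long]
    tpm <- tpmEM(asg$hits_long, transcriptLengths(refset)[long_tx],
                 stats::setNames(ann$gene_id, ann$transcript_id)[long_tx])
    gene_tpm <- tpm$gene
    gene_tpm$biotype <- ann$biotype[match(gene_tpm$gene_id, ann$gene_id)]
    utils::write.table(small, file.path(cfg$outdir, "counts_small.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(gene_tpm, file.path(cfg$outdir, "tpm.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    # fragmentomics over the long tier (mRNA/lncRNA fragments)
    profile <- NULL
    if (!is.null(asg$hits_long) && nrow(asg$hits_long)) {
        hl <- asg$hits_long
        hl <- hl[order(hl$read_id, hl$transcript_id, hl$start), ,
                 drop = FALSE]
        hl <- hl[!duplicated(hl$read_id), , drop = FALSE]
        frag <- data.frame(transcript_id = hl$transcript_id,
                           start = hl$start,
                           end = hl$start + hl$aligned_length,
                           stringsAsFactors = FALSE)
        merged_long <- hl
        pair_tab <- NULL
        if (!is.null(unmerged1) && length(unmerged1)) {
            pair_tab <- pairFragments(unmerged1, unmerged2,
                refSequences(refset)[long_tx],
                maxMismatch = al$max_mismatches, k = al$k)
        }
        fl <- fragmentLengths(
            merged = data.frame(read_id = merged_long$read_id,
                                aligned_length = merged_long$aligned_length),
            pairs = pair_tab,
            fullLengthThreshold = cfg$fragmentomics$full_length_threshold)
        if (!is.null(pair_tab) && nrow(pair_tab)) {
            p <- pair_tab[pair_tab$r1_len >=
                          cfg$fragmentomics$full_length_threshold, ,
                          drop = FALSE]
            L <- (p$r2_start - p$r1_start) + p$r2_len
            ok <- L > 0
            frag <- rbind(frag, data.frame(
                transcript_id = p$transcript_id[ok], start = p$r1_start[ok],
                end = p$r1_start[ok] + L[ok], stringsAsFactors = FALSE))
        }
        profile <- fragmentProfile(frag, refset, hist = fl$hist)
        writeFragmentProfile(profile, cfg$outdir)
    }

    # manifest with conservation accounting
    cfg_norm <- rapply(cfg, as.character, how = "replace")
    tmp <- tempfile()
    jsonlite::write_json(cfg_norm, tmp, auto_unbox = TRUE)
    manifest <- list(
        package_version = as.character(utils::packageVersion("cfRNAfrag")),
        seed = cfg$seed,
        config_hash = unname(tools::md5sum(tmp)),
        cleanup = as.list(cleanup),
        assignment = as.list(asg$counts),
        conservation = unname(asg$counts["n_input"] ==
            asg$counts["n_depleted"] + asg$counts["n_assigned"] +
            asg$counts["n_mirna_dropped"] + asg$counts["n_unmapped"]))
    unlink(tmp)
    jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)

    invisible(list(refset = refset, truth = truth, cleanup = cleanup,
                   assignment = asg, smallCounts = small, tpm = tpm,
                   geneTpm = gene_tpm, profile = profile,
                   manifest = manifest))
}

writeFragmentProfile <- function(profile, outdir) {
    utils::write.table(profile@length_hist,
                       file.path(outdir, "fragment_hist.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cf <- data.frame(class = names(profile@class_fractions),
                     fraction = as.numeric(profile@class_fractions))
    utils::write.table(cf, file.path(outdir, "class_fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    eb <- data.frame(base = names(profile@end5_base_freq),
                     freq5 = as.numeric(profile@end5_base_freq),
                     freq3 = as.numeric(profile@end3_base_freq))
    utils::write.table(eb, file.path(outdir, "end_bases.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (end in c("motif5", "motif3")) {
        m <- data.frame(motif = names(slot(profile, end)),
                        percent = as.numeric(slot(profile, end)))
        utils::write.table(m, file.path(outdir, paste0(end, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
}
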