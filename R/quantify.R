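#' Weighted small-RNA counts
#'
#' Each assigned read contributes its per-target weight (1/number of
#' best-stratum targets) to every target it hit, giving real-valued counts
#' per mature miRNA / tRNA / piRNA / other ncRNA gene.
#'
#' @param assignments the `assignments` table from [assignTiers()]
#'   (long-tier rows are ignored; those are quantified by [tpmEM()]).
#' @return data.frame(target_id, biotype, tier, count) sorted by target.
#' @export
countSmallRNA <- function(assignments) {
    a <- assignments[assignments$tier != "long", , drop = FALSE]
    if (nrow(a) == 0)
        return(data.frame(target_id = character(), biotype = character(),
                          tier = character(), count = numeric(),
                          stringsAsFactors = FALSE))
    long <- data.frame(
        target_id = unlist(a$targets, use.names = FALSE),
        biotype = rep(a$biotype, lengths(a$targets)),
        tier = rep(a$tier, lengths(a$targets)),
        weight = rep(a$weight, lengths(a$targets)),
        stringsAsFactors = FALSE)
    dt <- data.table::as.data.table(long)
    res <- dt[, list(count = sum(weight)),
              by = c("target_id", "biotype", "tier")]
    res <- as.data.frame(res)
    res <- res[order(res$target_id), ]
    rownames(res) <- NULL
    res
}

#' Reads-per-million normalization
#'
#' `rpm = count * 1e6 / total_mapped`. The denominator is by default the
#' number of reads assigned to any tier after depletion removal; whether
#' depleted reads are included is the caller's choice via `totalMapped`.
#'
#' @param counts data.frame with a `count` column (e.g. [countSmallRNA()]).
#' @param totalMapped positive integer denominator.
#' @return `counts` with an added `rpm` column.
#' @export
rpmNormalize <- function(counts, totalMapped) {
    if (is.null(totalMapped) || totalMapped <= 0)
        stop("totalMapped must be a positive count")
    counts$rpm <- counts$count * 1e6 / totalMapped
    counts
}

#' Transcript-abundance EM for mRNA/lncRNA TPM
#'
#' Reads from the long tier may align to several transcripts in the same
#' best stratum; the EM resolves them. Reads with identical hit sets are
#' collapsed into equivalence classes. The E-step splits each class's reads
#' across its transcripts proportionally to the current read-fraction
#' estimate; the M-step re-estimates read fractions, and transcript molar
#' abundance is read fraction divided by transcript length (effective
#' length = transcript length: cfRNA fragments are much shorter than their
#' transcripts, so no fragment-length correction is applied). Iteration
#' stops when the largest absolute TPM change drops below `tol` or after
#' `maxIter` iterations. The complete-data log-likelihood is non-decreasing
#' across iterations. Gene TPM is the sum over the gene's transcripts; TPM
#' sums to 1e6. With only uniquely-mapping reads the result equals the
#' closed-form count/length normalization.
#'
#' @param hitsLong the `hits_long` table from [assignTiers()] (read_id,
#'   transcript_id, ... best-stratum hits within the long tier), or any
#'   data.frame with `read_id` and `transcript_id`.
#' @param lengths named transcript lengths (nt).
#' @param geneMap optional named character: transcript_id -> gene_id
#'   (default: each transcript is its own gene).
#' @param maxIter,tol stopping rule (defaults 200 and 1e-3 TPM units).
#' @return list with `gene` (data.frame gene_id, tpm), `transcript`
#'   (data.frame transcript_id, gene_id, tpm, est_reads) and `loglik`
#'   (per-iteration complete-data log-likelihood).
#' @export
tpmEM <- function(hitsLong, lengths, geneMap = NULL, maxIter = 200,
                  tol = 1e-3) {
    txs <- names(lengths)
    if (is.null(geneMap)) geneMap <- stats::setNames(txs, txs)
    empty_gene <- data.frame(gene_id = unique(unname(geneMap[txs])),
                             tpm = 0, stringsAsFactors = FALSE)
    if (is.null(hitsLong) || nrow(hitsLong) == 0)
        return(list(gene = empty_gene,
                    transcript = data.frame(transcript_id = txs,
                        gene_id = unname(geneMap[txs]), tpm = 0,
                        est_reads = 0, stringsAsFactors = FALSE),
                    loglik = numeric(0)))
    # equivalence classes: reads sharing an identical hit set
    sp <- split(hitsLong$transcript_id, hitsLong$read_id)
    sig <- vapply(sp, function(x) paste(sort(unique(x)), collapse = "\r"),
                  character(1))
    cls <- table(sig)
    members <- strsplit(names(cls), "\r", fixed = TRUE)
    counts <- as.numeric(cls)
    N <- sum(counts)
    idx <- lapply(members, function(m) match(m, txs))
    L <- as.numeric(lengths)

    alpha <- rep(1 / length(txs), length(txs))  # read fractions
    tpmOf <- function(a) {
        rho <- a / L
        1e6 * rho / sum(rho)
    }
    tpm <- tpmOf(alpha)
    loglik <- numeric(0)
    for (it in seq_len(maxIter)) {
        n_t <- numeric(length(txs))
        ll <- 0
        for (j in seq_along(idx)) {
            a <- alpha[idx[[j]]]
            s <- sum(a)
            if (s <= 0) {
                a <- rep(1 / length(a), length(a)); s <- 1
            } else a <- a / s
            n_t[idx[[j]]] <- n_t[idx[[j]]] + counts[j] * a
            loglikj <- log(max(s, .Machine$double.xmin))
            ll <- ll + counts[j] * loglikj
        }
        loglik <- c(loglik, ll)
        alpha <- n_t / N
        tpm_new <- tpmOf(alpha)
        if (max(abs(tpm_new - tpm)) < tol) {
            tpm <- tpm_new
            break
        }
        tpm <- tpm_new
    }
    tx_tab <- data.frame(transcript_id = txs, gene_id = unname(geneMap[txs]),
                         tpm = tpm, est_reads = alpha * N,
                         stringsAsFactors = FALSE)
    g <- stats::aggregate(tpm ~ gene_id, tx_tab, sum)
    list(gene = g[order(g$gene_id), ], transcript = tx_tab, loglik = loglik)
}

#' Detected-gene summaries
#'
#' A gene counts as detected in a sample when its count reaches `minCount`
#' (default 1), and as detected in the group when that holds in at least
#' `minSamples` samples (default 2).
#'
#' @param mat genes x samples numeric matrix (counts, RPM or TPM).
#' @param minCount per-sample detection threshold.
#' @param minSamples minimum number of samples.
#' @return character vector of detected gene names (rownames of `mat`).
#' @export
detectedGenes <- function(mat, minCount = 1, minSamples = 2) {
    mat <- as.matrix(mat)
    det <- rowSums(mat >= minCount) >= minSamples
    rownames(mat)[det]
}

#' Assemble per-sample abundance tables into a SummarizedExperiment
#'
#' @param tables named list (one per sample) of data.frames with columns
#'   `target_id` (or `gene_id`), `biotype` (optional) and one or more value
#'   columns (`count`, `rpm`, `tpm`).
#' @param values which value columns to carry over as assays.
#' @return A `SummarizedExperiment` with genes as rows, samples as columns,
#'   one assay per value column and biotype in `rowData` when available.
#' @export
combineAbundance <- function(tables, values = c("count", "rpm", "tpm")) {
    stopifnot(length(tables) > 0)
    if (is.null(names(tables)))
        names(tables) <- paste0("sample", seq_along(tables))
    idcol <- if ("target_id" %in% names(tables[[1]])) "target_id"
             else "gene_id"
    genes <- sort(unique(unlist(lapply(tables, `[[`, idcol))))
    values <- intersect(values, names(tables[[1]]))
    assays <- lapply(values, function(v) {
        m <- sapply(tables, function(tb) {
            x <- stats::setNames(tb[[v]], tb[[idcol]])[genes]
            x[is.na(x)] <- 0
            x
        })
        m <- matrix(m, nrow = length(genes),
                    dimnames = list(genes, names(tables)))
        m
    })
    names(assays) <- values
    rd <- S4Vectors::DataFrame(row.names = genes)
    bts <- unlist(lapply(tables, function(tb)
        if ("biotype" %in% names(tb))
            stats::setNames(tb$biotype, tb[[idcol]]) else NULL))
    if (!is.null(bts)) rd$biotype <- bts[match(genes, names(bts))]
    SummarizedExperiment::SummarizedExperiment(assays = assays, rowData = rd)
}
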