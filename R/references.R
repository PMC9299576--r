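#' Load a multi-biotype transcript reference set
#'
#' Reads transcript sequences (FASTA), a 3-column biotype annotation TSV
#' (`transcript_id`, `gene_id`, `biotype`) and a mature-miRNA coordinate TSV
#' (`mature_name`, `hairpin_id`, `start`, `end`; 0-based half-open on the
#' hairpin precursor), and returns a validated [ReferenceSet] with the
#' default tier order (depletion, miRNA, small, long, other). Sequences are
#' uppercased and U is converted to T so reads and references share the DNA
#' alphabet.
#'
#' @param fasta_path FASTA of transcript sequences, ids matching the
#'   annotation.
#' @param annotation_path TSV with columns transcript_id, gene_id, biotype.
#' @param mature_path optional TSV of mature miRNA coordinates; `NULL` for
#'   none.
#' @return A [ReferenceSet].
#' @examples
#' ref <- simulateTranscriptome(seed = 1,
#'     nGenesPerBiotype = c(mRNA = 3, miRNA_hairpin = 2))
#' td <- tempfile(); dir.create(td)
#' paths <- writeReferences(ref, file.path(td, "ref.fa"),
#'     file.path(td, "ann.tsv"), file.path(td, "mature.tsv"))
#' ref2 <- loadReferences(paths$fasta, paths$annotation, paths$mature)
#' @export
loadReferences <- function(fasta_path, annotation_path, mature_path = NULL) {
    seqs <- Biostrings::readBStringSet(fasta_path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    seqs <- Biostrings::DNAStringSet(chartr("acgtunU", "ACGTTNT",
                                            as.character(seqs)))
    ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE,
                             comment.char = "#")
    need <- c("transcript_id", "gene_id", "biotype")
    if (!all(need %in% names(ann)))
        stop("annotation must have columns ", paste(need, collapse = ", "))
    missing_ann <- setdiff(names(seqs), ann$transcript_id)
    if (length(missing_ann))
        stop("FASTA record(s) absent from annotation: ",
             paste(missing_ann, collapse = ", "))
    missing_seq <- setdiff(ann$transcript_id, names(seqs))
    if (length(missing_seq))
        stop("annotation row(s) without FASTA record: ",
             paste(missing_seq, collapse = ", "))
    bad <- setdiff(unique(ann$biotype), BIOTYPES)
    if (length(bad))
        stop("unknown biotype: ", paste(bad, collapse = ", "))
    ann <- ann[match(names(seqs), ann$transcript_id), need]
    rownames(ann) <- NULL
    matures <- emptyMatureTable()
    if (!is.null(mature_path)) {
        matures <- utils::read.delim(mature_path, stringsAsFactors = FALSE,
                                     comment.char = "#")
        mneed <- c("mature_name", "hairpin_id", "start", "end")
        if (!all(mneed %in% names(matures)))
            stop("mature table must have columns ",
                 paste(mneed, collapse = ", "))
        matures <- matures[mneed]
    }
    newReferenceSet(seqs, ann, matures)
}

emptyMatureTable <- function() {
    data.frame(mature_name = character(), hairpin_id = character(),
               start = integer(), end = integer(),
               stringsAsFactors = FALSE)
}

newReferenceSet <- function(sequences, annotation, matures = NULL,
                            tiers = DEFAULT_TIERS) {
    if (is.null(matures)) matures <- emptyMatureTable()
    new("ReferenceSet", sequences = sequences, annotation = annotation,
        matures = matures, tiers = tiers)
}

#' Write a ReferenceSet back to FASTA + TSV
#'
#' Inverse of [loadReferences()]; reloading the written files yields an
#' identical object.
#'
#' @param refset A [ReferenceSet].
#' @param fasta_path,annotation_path,mature_path output file paths.
#' @return Invisibly, a list of the three paths.
#' @export
writeReferences <- function(refset, fasta_path, annotation_path,
                            mature_path) {
    Biostrings::writeXStringSet(refSequences(refset), fasta_path)
    utils::write.table(refAnnotation(refset), annotation_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    con <- file(mature_path, "w")
    writeLines("# mature miRNA coordinates, 0-based half-open on hairpin",
               con)
    utils::write.table(matureMiRNAs(refset), con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    invisible(list(fasta = fasta_path, annotation = annotation_path,
                   mature = mature_path))
}

#' @describeIn ReferenceSet-accessors transcript sequences
#' @export
refSequences <- function(refset) refset@sequences

#' Accessors for ReferenceSet components
#'
#' @param refset A [ReferenceSet].
#' @name ReferenceSet-accessors
#' @return The requested component.
NULL

#' @describeIn ReferenceSet-accessors annotation data.frame
#' @export
refAnnotation <- function(refset) refset@annotation

#' @describeIn ReferenceSet-accessors mature miRNA coordinate table
#' @export
matureMiRNAs <- function(refset) refset@matures

#' @describeIn ReferenceSet-accessors ordered tier definitions
#' @export
tierDefinitions <- function(refset) refset@tiers

#' @describeIn ReferenceSet-accessors named integer vector of transcript
#'   lengths
#' @export
transcriptLengths <- function(refset) {
    stats::setNames(Biostrings::width(refset@sequences),
                    names(refset@sequences))
}

setMethod("show", "ReferenceSet", function(object) {
    tab <- table(object@annotation$biotype)
    cat("ReferenceSet with", length(object@sequences), "transcripts,",
        nrow(object@matures), "mature miRNAs\n")
    cat("  biotypes:",
        paste(names(tab), tab, sep = ":", collapse = " "), "\n")
    cat("  tiers:", paste(names(object@tiers), collapse = " > "), "\n")
})

#' Build a k-mer occurrence index
#'
#' Indexes every k-mer of every transcript to support seed lookups; each
#' stored (transcript_id, offset) pair re-reads to its k-mer.
#'
#' @param refset A [ReferenceSet].
#' @param k k-mer size, at least 8.
#' @return A [KmerIndex].
#' @export
buildKmerIndex <- function(refset, k) {
    k <- as.integer(k)
    if (k < 8L) stop("k must be >= 8")
    seqs <- as.character(refSequences(refset))
    ids <- character(0); offs <- integer(0); kms <- character(0)
    for (id in names(seqs)) {
        s <- seqs[[id]]
        n <- nchar(s) - k + 1L
        if (n < 1L) next
        o <- seq_len(n) - 1L
        kms <- c(kms, substring(s, o + 1L, o + k))
        ids <- c(ids, rep(id, n))
        offs <- c(offs, o)
    }
    map <- new.env(parent = emptyenv(), hash = TRUE)
    if (length(kms)) {
        sp <- split(data.frame(transcript_id = ids, offset = offs,
                               stringsAsFactors = FALSE), kms)
        for (km in names(sp)) assign(km, sp[[km]], envir = map)
    }
    new("KmerIndex", k = k, map = map)
}

#' Query a KmerIndex
#'
#' @param index A [KmerIndex].
#' @param kmer a single k-mer string.
#' @return data.frame(transcript_id, offset); zero rows for an absent k-mer.
#' @export
kmerHits <- function(index, kmer) {
    if (nchar(kmer) != index@k) stop("query length must equal k")
    if (exists(kmer, envir = index@map, inherits = FALSE)) {
        df <- get(kmer, envir = index@map)
        df[order(df$transcript_id, df$offset), , drop = FALSE]
    } else {
        data.frame(transcript_id = character(), offset = integer(),
                   stringsAsFactors = FALSE)
    }
}

setMethod("show", "KmerIndex", function(object) {
    cat("KmerIndex: k =", object@k, "with",
        length(ls(object@map)), "distinct k-mers\n")
})
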