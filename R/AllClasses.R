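#' @import methods
#' @importFrom Biostrings DNAStringSet readBStringSet writeXStringSet
#'   reverseComplement BStringSet
#' @importFrom S4Vectors mcols mcols<-
#' @useDynLib cfRNAfrag, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom data.table as.data.table
NULL

.datatable.aware <- TRUE

BIOTYPES <- c("rRNA", "Y_RNA", "vtRNA", "miRNA_hairpin", "tRNA", "piRNA",
              "mRNA", "lncRNA", "other_ncRNA")

DEFAULT_TIERS <- list(
    depletion = c("rRNA", "Y_RNA", "vtRNA"),
    miRNA     = "miRNA_hairpin",
    small     = c("tRNA", "piRNA"),
    long      = c("mRNA", "lncRNA"),
    other     = "other_ncRNA"
)

#' Biotype-annotated transcript reference set
#'
#' Holds the transcript sequences all alignment tiers run against, a
#' minimal annotation (transcript, gene, biotype), the mature-miRNA
#' coordinate table on hairpin precursors, and the ordered tier definitions
#' that drive hierarchical read assignment: abundant-RNA depletion
#' (rRNA/Y RNA/vault RNA) first, then miRNA hairpins, then tRNA/piRNA, then
#' mRNA/lncRNA, then remaining ncRNA biotypes.
#'
#' All coordinates are 0-based half-open; sequences are stored in DNA space
#' (U converted to T at load).
#'
#' @slot sequences [Biostrings::DNAStringSet] named by transcript_id.
#' @slot annotation data.frame with columns transcript_id, gene_id, biotype.
#' @slot matures data.frame with columns mature_name, hairpin_id, start, end
#'   (0-based half-open on the hairpin).
#' @slot tiers named list, tier name -> character vector of biotypes.
#' @export
setClass("ReferenceSet",
    representation(sequences = "DNAStringSet", annotation = "data.frame",
                   matures = "data.frame", tiers = "list"))

setValidity("ReferenceSet", function(object) {
    ann <- object@annotation
    msgs <- character()
    need <- c("transcript_id", "gene_id", "biotype")
    if (!all(need %in% names(ann)))
        return(paste("annotation must have columns",
                     paste(need, collapse = ", ")))
    if (anyDuplicated(ann$transcript_id))
        msgs <- c(msgs, "duplicated transcript_id in annotation")
    if (!setequal(names(object@sequences), ann$transcript_id))
        msgs <- c(msgs, "sequence names and annotation transcript_id differ")
    bad <- setdiff(unique(ann$biotype), BIOTYPES)
    if (length(bad))
        msgs <- c(msgs, paste("unknown biotype:", paste(bad, collapse = ", ")))
    if (any(Biostrings::width(object@sequences) == 0))
        msgs <- c(msgs, "zero-length transcript sequence")
    tb <- unlist(object@tiers, use.names = FALSE)
    if (anyDuplicated(tb))
        msgs <- c(msgs, "a biotype appears in more than one tier")
    if (!all(ann$biotype %in% tb))
        msgs <- c(msgs, "some transcripts belong to no tier")
    mt <- object@matures
    if (nrow(mt)) {
        if (!all(mt$hairpin_id %in% ann$transcript_id[
                ann$biotype == "miRNA_hairpin"]))
            msgs <- c(msgs, "mature hairpin_id not an annotated miRNA_hairpin")
        hl <- Biostrings::width(object@sequences)[
            match(mt$hairpin_id, names(object@sequences))]
        if (any(mt$start < 0 | mt$start >= mt$end | mt$end > hl))
            msgs <- c(msgs, "mature coordinates out of hairpin bounds")
    }
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' k-mer occurrence index over a ReferenceSet
#'
#' Maps every k-mer of every transcript to its (transcript_id, 0-based
#' offset) occurrence list.
#'
#' @slot k integer k-mer size (>= 8).
#' @slot map environment, k-mer string -> data.frame(transcript_id, offset).
#' @export
setClass("KmerIndex", representation(k = "integer", map = "environment"))

#' A set of sequencing reads with per-base qualities
#'
#' Lightweight container for reads moving through cleanup: identifiers,
#' base strings over {A,C,G,T,N} and Phred quality strings of equal length.
#'
#' @slot id character read identifiers.
#' @slot seq character base strings.
#' @slot qual character Phred+33 quality strings, same widths as `seq`.
#' @export
setClass("ReadSet",
    representation(id = "character", seq = "character", qual = "character"))

setValidity("ReadSet", function(object) {
    if (length(object@id) != length(object@seq) ||
        length(object@seq) != length(object@qual))
        return("id, seq and qual must have equal length")
    if (any(nchar(object@seq) != nchar(object@qual)))
        return("per-read sequence and quality lengths differ")
    TRUE
})

#' Per-sample cfRNA fragment profile
#'
#' Summaries of fragment degradation state: the fragment-length histogram,
#' length-class fractions (<50 nt, 50-200 nt, >200 nt), terminal-base
#' frequencies at the 5' and 3' fragment ends, the two 256-entry 4-mer
#' end-motif percentage vectors, the 3' pyrimidine/purine ratio and the
#' 5' adenine rate.
#'
#' @slot length_hist data.frame(length, count).
#' @slot class_fractions named numeric: lt50, mid50_200, gt200 (sum 1).
#' @slot end5_base_freq,end3_base_freq named numeric over A,C,G,T (sum 1).
#' @slot motif5,motif3 named numeric of length 256 (percentages, sum 100);
#'   all-NA when no motif window was defined.
#' @slot py_pu_ratio_3p numeric, (C+T)/(A+G) at the 3' terminal base.
#' @slot adenine_rate_5p numeric, frequency of A at the 5' terminal base.
#' @export
setClass("FragmentProfile",
    representation(length_hist = "data.frame", class_fractions = "numeric",
                   end5_base_freq = "numeric", end3_base_freq = "numeric",
                   motif5 = "numeric", motif3 = "numeric",
                   py_pu_ratio_3p = "numeric", adenine_rate_5p = "numeric"))

setValidity("FragmentProfile", function(object) {
    msgs <- character()
    if (length(object@class_fractions) != 3 ||
        abs(sum(object@class_fractions) - 1) > 1e-9)
        msgs <- c(msgs, "class_fractions must be 3 values summing to 1")
    for (nm in c("motif5", "motif3")) {
        v <- slot(object, nm)
        if (length(v) != 256)
            msgs <- c(msgs, paste(nm, "must have exactly 256 entries"))
        else if (!all(is.na(v)) && abs(sum(v) - 100) > 1e-6)
            msgs <- c(msgs, paste(nm, "must sum to 100"))
    }
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
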