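#' Construct a ReadSet
#'
#' @param id read identifiers.
#' @param seq base strings over {A,C,G,T,N}.
#' @param qual Phred+33 quality strings; defaults to constant Q40.
#' @return A [ReadSet].
#' @export
ReadSet <- function(id, seq, qual = NULL) {
    if (is.null(qual)) qual <- strrep("I", nchar(seq))
    new("ReadSet", id = as.character(id), seq = toupper(as.character(seq)),
        qual = as.character(qual))
}

#' @describeIn ReadSet read identifiers
#' @param x,object A [ReadSet].
#' @export
readIds <- function(x) x@id

#' @describeIn ReadSet base strings
#' @export
readSeqs <- function(x) x@seq

#' @describeIn ReadSet quality strings
#' @export
readQuals <- function(x) x@qual

#' @export
setMethod("length", "ReadSet", function(x) length(x@id))

#' @export
setMethod("[", "ReadSet", function(x, i, j, ..., drop = TRUE) {
    new("ReadSet", id = x@id[i], seq = x@seq[i], qual = x@qual[i])
})

setMethod("show", "ReadSet", function(object) {
    cat("ReadSet with", length(object), "reads")
    if (length(object))
        cat("; width", min(nchar(object@seq)), "-",
            max(nchar(object@seq)))
    cat("\n")
})

#' Read a FASTQ file into a ReadSet
#'
#' @param path FASTQ file (optionally gzipped).
#' @return A [ReadSet].
#' @export
readFastq <- function(path) {
    x <- Biostrings::readBStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
    ReadSet(id = sub("\\s.*$", "", names(x)),
            seq = as.character(x),
            qual = as.character(S4Vectors::mcols(x)$qualities))
}

#' Write a ReadSet as FASTQ
#'
#' @param reads A [ReadSet].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeFastq <- function(reads, path) {
    con <- file(path, "w")
    on.exit(close(con))
    if (length(reads))
        writeLines(paste0("@", reads@id, "\n", reads@seq, "\n+\n",
                          reads@qual), con)
    invisible(path)
}

revComp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
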