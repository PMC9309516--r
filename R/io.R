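#' Read and write BLAST tabular alignments
#'
#' The tabular (outfmt-6 dialect) alignment format used throughout: the 12
#' standard columns \code{qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore}, optionally extended with a
#' 13th \code{qlen} column carrying the query length (needed to compute
#' query coverage without the reads at hand).
#'
#' @param path file path of a headerless tab-separated alignment table.
#' @return data.frame with named columns.
#' @export
readBlastTab <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore",
            "qlen")
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (!ncol(x) %in% c(12L, 13L))
    stop("expected 12 or 13 tab-separated columns, found ", ncol(x))
  names(x) <- cols[seq_len(ncol(x))]
  x
}

#' @rdname readBlastTab
#' @param aln alignment data.frame as produced by [simulateAlignments()].
#' @export
writeBlastTab <- function(aln, path) {
  utils::write.table(aln, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write FASTQ with qualities
#'
#' Thin wrappers over Biostrings FASTQ I/O (Phred+33), returning and
#' accepting [Biostrings::QualityScaledDNAStringSet].
#'
#' @param path FASTQ file path.
#' @return \code{readFastq}: a QualityScaledDNAStringSet.
#' @export
readFastq <- function(path) {
  # Biostrings warns about dropped metadata columns on every FASTQ read;
  # nothing of ours lives there
  withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' @rdname readFastq
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @export
writeFastq <- function(reads, path) {
  Biostrings::writeQualityScaledXStringSet(reads, path)
  invisible(path)
}
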