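#' Remove host-plant reads
#'
#' Drops every read that aligns to a host-plant genome with at least
#' \code{minIdentity} percent identity and at least \code{minCoverage}
#' percent query coverage (both thresholds inclusive, per the "minimum"
#' wording of the rule). Query coverage is computed along the query as
#' 100 x alignment_length / query_length. Multiple host genomes are
#' supported (removal on a qualifying hit to any of them) and per-genome
#' removal counts are reported, attributing each removed read to the host
#' genome of its highest-scoring qualifying hit.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet], or a character
#'   vector of read ids (then \code{hostAlignments} must carry a
#'   \code{qlen} column).
#' @param hostAlignments alignment data.frame in the [readBlastTab()]
#'   layout, of reads versus the host genome(s).
#' @param minIdentity,minCoverage inclusive thresholds in percent.
#' @param contigMap optional data.frame (\code{contig}, \code{genome_id})
#'   mapping subject contigs to host genomes; by default the genome id is
#'   the subject contig name up to the last \code{"|"}.
#' @return list with \code{kept} (the surviving reads, same class as
#'   \code{reads}), \code{nRemoved}, and \code{perGenome}, a data.frame of
#'   removal counts per host genome.
#' @export
depleteHost <- function(reads, hostAlignments, minIdentity = 60,
                        minCoverage = 60, contigMap = NULL) {
  ids <- if (is.character(reads)) reads else names(reads)
  aln <- hostAlignments
  unknown <- !aln$qseqid %in% ids
  if (any(unknown)) {
    warning(sum(unknown), " alignment record(s) reference unknown reads; ",
            "skipped")
    aln <- aln[!unknown, , drop = FALSE]
  }
  if (is.null(aln$qlen)) {
    if (is.character(reads))
      stop("alignments lack a 'qlen' column and no read sequences were ",
           "supplied to derive query lengths")
    aln$qlen <- Biostrings::width(reads)[match(aln$qseqid, ids)]
  }
  cov <- 100 * aln$length / aln$qlen
  hit <- aln$pident >= minIdentity & cov >= minCoverage
  qual <- aln[hit, , drop = FALSE]
  removed <- unique(qual$qseqid)
  keep <- !ids %in% removed
  perGenome <- if (nrow(qual)) {
    best <- qual[order(qual$qseqid, -qual$bitscore), , drop = FALSE]
    best <- best[!duplicated(best$qseqid), , drop = FALSE]
    bg <- if (is.null(contigMap)) sub("\\|[^|]*$", "", best$sseqid) else
      contigMap$genome_id[match(best$sseqid, contigMap$contig)]
    as.data.frame(table(genome_id = bg), responseName = "n_removed",
                  stringsAsFactors = FALSE)
  } else data.frame(genome_id = character(), n_removed = integer())
  list(kept = if (is.character(reads)) ids[keep] else reads[keep],
       nRemoved = length(removed), perGenome = perGenome)
}
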