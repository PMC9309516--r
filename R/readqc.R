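#' Sliding-window quality trimming of a single read
#'
#' Implements the three-step trimming rule applied to every read before any
#' downstream analysis:
#' \enumerate{
#'   \item scan windows of \code{window} bases from the 5' end, advancing by
#'     \code{step}; the read is truncated at the start of the first window
#'     whose mean Phred quality falls below \code{minMeanQ}. A final partial
#'     window (fewer than \code{window} bases) is evaluated over the bases
#'     it covers, so a short low-quality tail cannot escape the scan.
#'   \item bases are then trimmed from both ends while the terminal base
#'     quality is below \code{minEndQ}.
#'   \item the read is dropped if fewer than \code{minLen} bases remain.
#' }
#' The surviving read is always a contiguous substring of the input.
#'
#' @param qualities integer vector of Phred scores, one per base.
#' @param window,step sliding-window size and step (bases).
#' @param minMeanQ minimum mean window quality.
#' @param minEndQ minimum terminal base quality.
#' @param minLen minimum surviving length; shorter reads are dropped.
#' Because truncation can expose a new low-quality tail and shift the
#' window frame, the three steps are applied repeatedly until the kept
#' range stops changing; this fixpoint makes trimming idempotent.
#'
#' @return integer \code{c(start, end)} of the kept range (1-based,
#'   inclusive), or NULL when the read is dropped.
#' @examples
#' trimRead(rep(30L, 100))          # c(1, 100)
#' trimRead(c(rep(30L, 60), rep(5L, 40)))
#' @export
trimRead <- function(qualities, window = 10L, step = 4L, minMeanQ = 20,
                     minEndQ = 20, minLen = 50L) {
  len <- length(qualities)
  if (len == 0L) stop("read must be non-empty")
  if (window < 1L || step < 1L) stop("window and step must be >= 1")
  cs <- cumsum(c(0, qualities))
  rng <- c(1L, len)
  repeat {
    # window means via cumulative sums; final partial window included
    starts <- seq.int(rng[1L], rng[2L], by = step)
    ends <- pmin(starts + window - 1L, rng[2L])
    means <- (cs[ends + 1L] - cs[starts]) / (ends - starts + 1L)
    bad <- which(means < minMeanQ)
    end <- if (length(bad)) starts[bad[1L]] - 1L else rng[2L]
    if (end < rng[1L]) return(NULL)
    start <- rng[1L]
    while (start <= end && qualities[start] < minEndQ) start <- start + 1L
    while (end >= start && qualities[end] < minEndQ) end <- end - 1L
    if (end - start + 1L < minLen) return(NULL)
    if (start == rng[1L] && end == rng[2L]) return(c(start, end))
    rng <- c(start, end)
  }
}

#' Quality-trim a read set
#'
#' Applies [trimRead()] to every read of a
#' [Biostrings::QualityScaledDNAStringSet], preserving input order, and
#' tallies reads and bases before and after trimming (the per-dataset
#' totals reported for each sequencing library).
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @inheritParams trimRead
#' @return list with \code{reads} (the trimmed, surviving reads) and
#'   \code{stats}, a one-row data.frame with columns \code{n_reads_in},
#'   \code{n_bases_in}, \code{n_reads_out}, \code{n_bases_out}.
#' @export
trimReads <- function(reads, window = 10L, step = 4L, minMeanQ = 20,
                      minEndQ = 20, minLen = 50L) {
  n <- length(reads)
  widths <- Biostrings::width(reads)
  if (n == 0L) {
    stats <- data.frame(n_reads_in = 0L, n_bases_in = 0L,
                        n_reads_out = 0L, n_bases_out = 0L)
    return(list(reads = reads, stats = stats))
  }
  quals <- phredScores(reads)
  ranges <- lapply(quals, trimRead, window = window, step = step,
                   minMeanQ = minMeanQ, minEndQ = minEndQ, minLen = minLen)
  keep <- !vapply(ranges, is.null, logical(1))
  kept <- reads[keep]
  if (any(keep)) {
    rng <- do.call(rbind, ranges[keep])
    nms <- names(kept)
    # narrow drops metadata columns on the way; names are re-attached
    kept <- suppressWarnings(
      IRanges::narrow(kept, start = rng[, 1], end = rng[, 2]))
    names(kept) <- nms
  }
  stats <- data.frame(
    n_reads_in = n, n_bases_in = sum(widths),
    n_reads_out = length(kept), n_bases_out = sum(Biostrings::width(kept)))
  list(reads = kept, stats = stats)
}

#' Quality-trim a FASTQ file
#'
#' File-level wrapper around [trimReads()]; reads Phred+33 FASTQ, writes
#' the surviving trimmed reads, and returns (and optionally writes) the
#' trimming statistics.
#'
#' @param input,output FASTQ paths.
#' @param statsFile optional path for a one-row TSV of the statistics.
#' @inheritParams trimRead
#' @return The stats data.frame, invisibly.
#' @export
trimFastq <- function(input, output, statsFile = NULL, window = 10L,
                      step = 4L, minMeanQ = 20, minEndQ = 20, minLen = 50L) {
  res <- trimReads(readFastq(input), window = window, step = step,
                   minMeanQ = minMeanQ, minEndQ = minEndQ, minLen = minLen)
  writeFastq(res$reads, output)
  if (!is.null(statsFile))
    utils::write.table(res$stats, statsFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(res$stats)
}
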