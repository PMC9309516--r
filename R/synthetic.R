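#' Generate a synthetic reference genome
#'
#' Draws a multi-contig genome with i.i.d. uniform base composition,
#' deterministically for a fixed [GenomeSpec-class] seed. Contigs are named
#' \code{"<genomeId>|<k>"} so a combined set of genomes remains
#' unambiguous; this naming convention is relied on throughout the package
#' to map alignment subject contigs back to genomes.
#'
#' @param spec a [GenomeSpec-class].
#' @return A [Biostrings::DNAStringSet] of the genome's contigs.
#' @examples
#' g <- generateGenome(genomeSpec("g1", contigLengths = c(600, 400), seed = 1))
#' sum(Biostrings::width(g))  # 1000
#' @export
generateGenome <- function(spec) {
  validObject(spec)
  withr_seed(spec@seed, {
    seqs <- vapply(spec@contigLengths, function(len) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = "")
    }, character(1))
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- paste0(spec@genomeId, "|", seq_along(seqs))
  out
}

#' Generate several genomes into one contig set
#'
#' @param specs list of [GenomeSpec-class] objects with unique genome ids.
#' @return A single [Biostrings::DNAStringSet] with all contigs.
#' @export
generateGenomes <- function(specs) {
  ids <- vapply(specs, genomeId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate genome ids: ", paste(unique(ids[duplicated(ids)]),
                                         collapse = ", "))
  # unname: named arguments would send c() to the base list method
  do.call(c, unname(lapply(specs, generateGenome)))
}

#' Contig table of a combined genome set
#'
#' Derives, from contig names of the form \code{"<genomeId>|<k>"}, the
#' per-genome contig order, lengths, and cumulative offsets on the
#' concatenated [0, L) coordinate axis used for section assignment.
#'
#' @param genomes [Biostrings::DNAStringSet] of contigs.
#' @return data.frame with columns \code{genome_id}, \code{contig},
#'   \code{length}, \code{offset} (0-based start of the contig on the
#'   concatenated axis of its genome).
#' @export
contigTable <- function(genomes) {
  cn <- names(genomes)
  gid <- sub("\\|[^|]*$", "", cn)
  len <- Biostrings::width(genomes)
  off <- unlist(lapply(split(len, factor(gid, levels = unique(gid))),
                       function(x) cumsum(c(0, x[-length(x)]))),
                use.names = FALSE)
  # split() keeps within-group order; reassemble in original contig order
  df <- data.frame(genome_id = gid, contig = cn, length = len,
                   stringsAsFactors = FALSE)
  df$offset <- ave(df$length, df$genome_id,
                   FUN = function(x) cumsum(c(0, x[-length(x)])))
  df
}

#' Build a genome manifest from specs
#'
#' @param specs list of [GenomeSpec-class] objects.
#' @param source provenance label recycled over rows ("selected" or
#'   "LAB_AAB_extension").
#' @return data.frame with columns \code{genome_id}, \code{species},
#'   \code{genus}, \code{taxon_class}, \code{total_length}, \code{source}.
#' @export
manifestFromSpecs <- function(specs, source = "selected") {
  data.frame(
    genome_id = vapply(specs, genomeId, character(1)),
    species = vapply(specs, speciesName, character(1)),
    genus = vapply(specs, function(s) s@genus, character(1)),
    taxon_class = vapply(specs, function(s) s@taxonClass, character(1)),
    total_length = vapply(specs, function(s) sum(s@contigLengths),
                          numeric(1)),
    source = source,
    stringsAsFactors = FALSE
  )
}

## two-segment Phred profile: 5' plateau then linear 3' decay
qualityProfile <- function(len, qPlateau = 36, qTail = 28,
                           plateauFrac = 0.7) {
  nPlateau <- max(1L, floor(len * plateauFrac))
  q <- rep(qPlateau, len)
  nTail <- len - nPlateau
  if (nTail > 0)
    q[(nPlateau + 1):len] <- round(qPlateau + (qTail - qPlateau) *
                                     seq_len(nTail) / nTail)
  pmax(q, 0L)
}

mutateBases <- function(seqs, nSub) {
  idx <- which(nSub > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(length(ch), nSub[i])
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate a metagenome read set with truth labels
#'
#' Draws reads from a [CommunityDesign-class]: read origins follow a
#' multinomial over the member genomes, the host genome and a "random"
#' (unplaceable) class; genome and host reads are substrings of their source
#' contig with per-base substitutions planted at the member's divergence
#' rate; random reads have no source. Quality strings follow a two-segment
#' Phred profile (5' plateau, linear 3' decay). Base-calling errors beyond
#' the planted divergence substitutions are not applied, which keeps the
#' alignment identity of every read an exact function of its truth row.
#'
#' @param design a [CommunityDesign-class].
#' @param genomes combined [Biostrings::DNAStringSet] of member (and host)
#'   contigs as produced by [generateGenomes()].
#' @param hostId genome id within \code{genomes} acting as the host plant,
#'   or NULL when \code{hostFraction} is 0.
#' @param hostDivergence substitution rate of host-origin reads from the
#'   host reference.
#' @param qPlateau,qTail,plateauFrac quality-profile parameters (Phred).
#' @return list with \code{reads}
#'   ([Biostrings::QualityScaledDNAStringSet]) and \code{truth}
#'   (data.frame: \code{read_id}, \code{origin}, \code{source_contig},
#'   \code{source_start} 0-based, \code{read_length},
#'   \code{n_substitutions}).
#' @export
simulateReads <- function(design, genomes, hostId = NULL,
                          hostDivergence = 0.02, qPlateau = 36, qTail = 28,
                          plateauFrac = 0.7) {
  validObject(design)
  m <- design@members
  if (!all(m$genome_id %in% sub("\\|[^|]*$", "", names(genomes))))
    stop("members reference genome ids absent from 'genomes'")
  if (design@hostFraction > 0 && is.null(hostId))
    stop("hostFraction > 0 requires 'hostId'")
  ct <- contigTable(genomes)
  contigSeq <- as.character(genomes)

  labels <- c(m$genome_id, "host", "random")
  probs <- c(m$read_fraction, design@hostFraction,
             design@unclassifiedFraction)
  keep <- probs > 0
  labels <- labels[keep]; probs <- probs[keep]

  withr_seed(design@seed, {
    counts <- as.vector(stats::rmultinom(1, design@nReads, probs))
    origin <- sample(rep(labels, counts))
    n <- design@nReads
    lens <- pmax(30L, as.integer(round(stats::rnorm(
      n, design@readLengthMean, design@readLengthSd))))

    seqs <- character(n)
    srcContig <- rep(NA_character_, n)
    srcStart <- rep(NA_integer_, n)
    nSub <- integer(n)

    for (lab in unique(origin)) {
      ii <- which(origin == lab)
      if (lab == "random") {
        seqs[ii] <- vapply(lens[ii], function(L)
          paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""),
          character(1))
        next
      }
      gid <- if (lab == "host") hostId else lab
      div <- if (lab == "host") hostDivergence else
        m$divergence[match(lab, m$genome_id)]
      mode <- if (lab == "host") "uniform" else
        m$coverage_mode[match(lab, m$genome_id)]
      gct <- ct[ct$genome_id == gid, , drop = FALSE]
      L <- sum(gct$length)
      if (mode == "single-region") {
        region <- if (!is.null(m$region) && lab != "host" &&
                      !is.na(m$region[match(lab, m$genome_id)]))
          m$region[match(lab, m$genome_id)] else 1L
        w <- L %/% 10L
        lens[ii] <- pmin(lens[ii], w)
        # whole read constrained inside the chosen tenth
        gpos <- (region - 1L) * w +
          floor(stats::runif(length(ii)) * (w - lens[ii] + 1))
      } else {
        gpos <- floor(stats::runif(length(ii)) * (L - lens[ii] + 1))
      }
      # map concatenated position to contig; truncate reads at contig ends
      ci <- findInterval(gpos, gct$offset)
      cLen <- gct$length[ci]
      within <- as.integer(gpos - gct$offset[ci])
      lens[ii] <- pmin(lens[ii], cLen - within)
      srcContig[ii] <- gct$contig[ci]
      srcStart[ii] <- within
      seqs[ii] <- substring(contigSeq[gct$contig[ci]], within + 1,
                            within + lens[ii])
      nSub[ii] <- stats::rbinom(length(ii), lens[ii], div)
      seqs[ii] <- mutateBases(seqs[ii], nSub[ii])
    }

    quals <- vapply(lens, function(L)
      rawToChar(as.raw(qualityProfile(L, qPlateau, qTail, plateauFrac) +
                         33L)), character(1))
  })

  ids <- sprintf("%s_r%06d", design@sampleId, seq_len(design@nReads))
  reads <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(quals))
  names(reads) <- ids
  truth <- data.frame(read_id = ids, origin = origin,
                      source_contig = srcContig, source_start = srcStart,
                      read_length = lens, n_substitutions = nSub,
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Simulate BLAST-style alignment tables from a truth table
#'
#' Emits, for every genome- or host-origin read, one primary tabular
#' alignment record whose percent identity is exactly
#' 100 x (read_length - n_substitutions) / read_length, whose subject
#' interval equals the planted source interval, and whose bit score ranks
#' the true source first. Random-origin reads get no record. Optionally one
#' decoy secondary hit per read is emitted against a configured "sister"
#' genome at extra divergence, to exercise best-hit tie-breaking and
#' two-cloud detection.
#'
#' @param truth truth table from [simulateReads()]; must cover all reads.
#' @param genomes combined contig set (needed for decoy subject bounds).
#' @param decoyMap named character vector mapping a source genome id to the
#'   sister genome id receiving a decoy hit, or NULL.
#' @param decoyExtraDivergence additional substitution rate of decoy hits
#'   (default +5 percentage points of identity).
#' @return data.frame in BLAST outfmt-6 column order (\code{qseqid},
#'   \code{sseqid}, \code{pident}, \code{length}, \code{mismatch},
#'   \code{gapopen}, \code{qstart}, \code{qend}, \code{sstart}, \code{send},
#'   \code{evalue}, \code{bitscore}) plus a \code{qlen} extension column.
#' @export
simulateAlignments <- function(truth, genomes, decoyMap = NULL,
                               decoyExtraDivergence = 0.05) {
  if (anyNA(truth$read_id) || anyDuplicated(truth$read_id))
    stop("truth table must list every read exactly once")
  t0 <- truth[truth$origin != "random", , drop = FALSE]
  mkRec <- function(qid, contig, start0, len, nsub) {
    data.frame(
      qseqid = qid, sseqid = contig,
      pident = round(100 * (len - nsub) / len, 3),
      length = len, mismatch = nsub, gapopen = 0L,
      qstart = 1L, qend = len,
      sstart = start0 + 1L, send = start0 + len,
      evalue = signif(len * 2^(-(2 * len - 6 * nsub)), 3),
      bitscore = 2 * len - 6 * nsub,
      qlen = len, stringsAsFactors = FALSE)
  }
  out <- mkRec(t0$read_id, t0$source_contig, t0$source_start,
               t0$read_length, t0$n_substitutions)
  if (!is.null(decoyMap)) {
    ct <- contigTable(genomes)
    gid <- sub("\\|[^|]*$", "", t0$source_contig)
    dd <- t0[gid %in% names(decoyMap), , drop = FALSE]
    if (nrow(dd)) {
      sister <- unname(decoyMap[sub("\\|[^|]*$", "", dd$source_contig)])
      # decoy lands on the sister genome's first contig, clamped to bounds
      sct <- ct[match(paste0(sister, "|1"), ct$contig), , drop = FALSE]
      if (anyNA(sct$contig))
        stop("decoyMap references genomes absent from 'genomes'")
      len <- pmin(dd$read_length, sct$length)
      start0 <- pmin(dd$source_start, sct$length - len)
      start0 <- pmax(start0, 0L)
      nsub2 <- dd$n_substitutions + ceiling(decoyExtraDivergence * len)
      dec <- mkRec(dd$read_id, sct$contig, start0, len, pmin(nsub2, len))
      out <- rbind(out, dec)
    }
  }
  rownames(out) <- NULL
  out
}
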