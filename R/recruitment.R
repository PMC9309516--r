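#' Best-hit filtering of read alignments
#'
#' Keeps, for each read, at most one alignment record: after discarding
#' records below \code{minIdentity} percent identity or \code{minCoverage}
#' percent query coverage (inclusive thresholds), the record with the
#' highest bit score wins; ties are broken by higher percent identity, then
#' by lexicographically smallest genome id. Reads with no surviving record
#' are unrecruited.
#'
#' @param alignments data.frame in the [readBlastTab()] layout, including a
#'   \code{qlen} column.
#' @param minIdentity,minCoverage inclusive percent thresholds.
#' @param contigMap optional data.frame (\code{contig}, \code{genome_id});
#'   by default genome ids are the subject contig name up to the last "|".
#' @return data.frame of winning records, one row per recruited read, with
#'   a \code{genome_id} column appended.
#' @export
bestHit <- function(alignments, minIdentity = 60, minCoverage = 60,
                    contigMap = NULL) {
  aln <- alignments
  if (nrow(aln) == 0L) {
    aln$genome_id <- character(0)
    return(aln)
  }
  if (is.null(aln$qlen)) stop("alignments must carry a 'qlen' column")
  aln$genome_id <- if (is.null(contigMap))
    sub("\\|[^|]*$", "", aln$sseqid) else
    contigMap$genome_id[match(aln$sseqid, contigMap$contig)]
  cov <- 100 * aln$length / aln$qlen
  aln <- aln[aln$pident >= minIdentity & cov >= minCoverage, , drop = FALSE]
  if (nrow(aln) == 0L) return(aln)
  o <- order(aln$qseqid, -aln$bitscore, -aln$pident, aln$genome_id)
  aln <- aln[o, , drop = FALSE]
  aln <- aln[!duplicated(aln$qseqid), , drop = FALSE]
  rownames(aln) <- NULL
  aln
}

#' Assign recruited reads to ten genome sections
#'
#' The genome's concatenated coordinate space [0, L) is split into ten
#' half-open sections of length floor(L/10), the last section absorbing the
#' remainder; each read is assigned to the section containing the midpoint
#' of its subject interval.
#'
#' @param totalLength genome length L (>= 10).
#' @param midpoints numeric vector of read midpoints on the concatenated
#'   0-based axis, all within [0, L).
#' @return integer vector of 10 section counts.
#' @export
sectionCounts <- function(totalLength, midpoints) {
  if (totalLength < 10) stop("totalLength must be >= 10")
  if (length(midpoints) && (min(midpoints) < 0 ||
                            max(midpoints) >= totalLength))
    stop("midpoints must lie within [0, totalLength)")
  w <- totalLength %/% 10
  sec <- pmin(floor(midpoints / w) + 1L, 10L)
  tabulate(sec, nbins = 10L)
}

#' Coverage-uniformity statistic (RSD)
#'
#' The standard deviation of the ten per-section read counts divided by
#' their mean. Uniformly recruited genomes score near zero; reads piled
#' into one section score sqrt(10) (about 3.16), far above the 0.8
#' presence-call bound — the behaviour the statistic was designed for.
#' The sample (n-1 denominator) standard deviation is used by default.
#'
#' @param counts integer vector of 10 section counts.
#' @param sdMode "sample" (n-1 denominator) or "population" (n).
#' @return the RSD, or NA (flagged missing) when no reads were recruited.
#' @examples
#' computeRSD(rep(100, 10))              # 0
#' computeRSD(c(10, rep(0, 9)))          # sqrt(10)
#' @export
computeRSD <- function(counts, sdMode = c("sample", "population")) {
  sdMode <- match.arg(sdMode)
  if (length(counts) != 10L) stop("expected 10 section counts")
  if (sum(counts) == 0) return(NA_real_)
  s <- stats::sd(counts)
  if (sdMode == "population") s <- s * sqrt(9 / 10)
  s / mean(counts)
}

#' Read-based average nucleotide identity
#'
#' The unweighted mean percent identity of the reads recruited to one
#' genome — a read-based ANI proxy, not genome-to-genome ANI.
#'
#' @param identities percent identities of the recruited reads.
#' @return mean percent identity, or NA (flagged missing) with no reads.
#' @export
computeANI <- function(identities) {
  if (length(identities) == 0L) return(NA_real_)
  mean(identities)
}

## histogram over 1% identity bins 60..100 (identity 100 falls in bin 100)
identityHistogramOf <- function(identities) {
  bins <- 60:100
  b <- pmin(pmax(floor(identities), 60), 100)
  counts <- as.numeric(tabulate(factor(b, levels = bins), nbins = 41L))
  names(counts) <- bins
  counts
}

#' Detect two read clouds in an identity histogram
#'
#' A fragment recruitment plot sometimes shows two "clouds" of reads — one
#' at high identity (the database species, or a close relative) and one at
#' lower identity (a more distant relative) — visible as a bimodal identity
#' histogram. The histogram is smoothed with a centered 3-bin moving
#' average; local maxima whose basin holds at least \code{minPeakMass} of
#' the recruited reads — and no fewer than \code{minCloudReads} reads, so
#' that sparse histograms cannot support a bimodality claim — count as
#' peaks, and two clouds are reported when two such peaks are separated by
#' a valley no higher than \code{maxValleyRatio} of the smaller peak. Cloud
#' summaries report read counts and mean identity (bin midpoints) on each
#' side of the deepest qualifying valley.
#'
#' @param hist named counts per 1 percent identity bin (60--100), as stored
#'   in a [RecruitmentProfile-class].
#' @param minPeakMass minimum fraction of recruited reads in a peak's basin.
#' @param minCloudReads absolute minimum reads in a peak's basin.
#' @param maxValleyRatio maximum valley height relative to the smaller
#'   peak's smoothed height.
#' @param smoothWindow moving-average width (odd).
#' @return list with \code{twoClouds} (logical) and \code{clouds}, a
#'   data.frame (\code{cloud}, \code{n_reads}, \code{mean_identity}).
#' @export
detectClouds <- function(hist, minPeakMass = 0.05, maxValleyRatio = 0.5,
                         smoothWindow = 3L, minCloudReads = 25L) {
  empty <- data.frame(cloud = character(), n_reads = numeric(),
                      mean_identity = numeric())
  n <- sum(hist)
  if (n == 0) return(list(twoClouds = FALSE, clouds = empty))
  k <- length(hist)
  half <- (smoothWindow - 1L) %/% 2L
  s <- vapply(seq_len(k), function(i)
    mean(hist[max(1L, i - half):min(k, i + half)]), numeric(1))
  # local maxima of the smoothed curve (plateaus count once, at their start)
  left <- c(-Inf, s[-k]); right <- c(s[-1], -Inf)
  peaks <- which(s > 0 & s >= left & s > right | (s > 0 & s > left & s >= right))
  peaks <- peaks[s[peaks] > 0]
  if (length(peaks) < 2L) {
    return(list(twoClouds = FALSE,
                clouds = oneCloud(hist, seq_len(k))))
  }
  # basins: split at the argmin of s between consecutive peaks
  splits <- vapply(seq_len(length(peaks) - 1L), function(j) {
    rng <- (peaks[j]):(peaks[j + 1])
    rng[which.min(s[rng])]
  }, integer(1))
  bounds <- c(0L, splits, k)
  mass <- vapply(seq_along(peaks), function(j)
    sum(hist[(bounds[j] + 1L):bounds[j + 1L]]), numeric(1))
  big <- which(mass >= max(minPeakMass * n, minCloudReads))
  if (length(big) < 2L)
    return(list(twoClouds = FALSE, clouds = oneCloud(hist, seq_len(k))))
  # among qualifying peak pairs, require a deep enough intervening valley
  bestValley <- NA_integer_; bestDepth <- Inf
  found <- FALSE
  for (a in utils::head(big, -1)) {
    for (b in big[big > a]) {
      rng <- (peaks[a]):(peaks[b])
      v <- rng[which.min(s[rng])]
      lim <- maxValleyRatio * min(s[peaks[a]], s[peaks[b]])
      if (s[v] <= lim) {
        found <- TRUE
        if (s[v] < bestDepth) { bestDepth <- s[v]; bestValley <- v }
      }
    }
  }
  if (!found)
    return(list(twoClouds = FALSE, clouds = oneCloud(hist, seq_len(k))))
  lo <- seq_len(bestValley)
  hi <- setdiff(seq_len(k), lo)
  clouds <- rbind(oneCloud(hist, lo, "low"), oneCloud(hist, hi, "high"))
  list(twoClouds = TRUE, clouds = clouds)
}

oneCloud <- function(hist, idx, label = "all") {
  h <- hist[idx]
  mids <- as.numeric(names(hist))[idx] + 0.5
  data.frame(cloud = label, n_reads = sum(h),
             mean_identity = if (sum(h) > 0)
               sum(h * mids) / sum(h) else NA_real_)
}

#' Build per-genome recruitment profiles
#'
#' Runs best-hit recruitment on an alignment table and summarizes, for
#' every genome of the manifest, the recruited reads into a
#' [RecruitmentProfile-class]: read count, read-based ANI, ten-section
#' counts and RSD, identity histogram, and the two-cloud flag. Multi-contig
#' genomes are laid out on one [0, L) axis by concatenating contigs in
#' \code{contigs}-table order.
#'
#' @param alignments alignment table ([readBlastTab()] layout with
#'   \code{qlen}).
#' @param manifest manifest data.frame with at least \code{genome_id} and
#'   \code{total_length}.
#' @param contigs contig table ([contigTable()] layout: \code{genome_id},
#'   \code{contig}, \code{length}, \code{offset}).
#' @param minIdentity,minCoverage recruitment thresholds (percent).
#' @param sdMode RSD denominator mode, see [computeRSD()].
#' @param ... passed to [detectClouds()].
#' @return named list of [RecruitmentProfile-class], one per manifest row.
#' @export
recruitReads <- function(alignments, manifest, contigs, minIdentity = 60,
                         minCoverage = 60, sdMode = "sample", ...) {
  best <- bestHit(alignments, minIdentity, minCoverage,
                  contigMap = contigs[, c("contig", "genome_id")])
  profiles <- lapply(seq_len(nrow(manifest)), function(i) {
    gid <- manifest$genome_id[i]
    L <- manifest$total_length[i]
    rec <- best[best$genome_id == gid, , drop = FALSE]
    off <- contigs$offset[match(rec$sseqid, contigs$contig)]
    mid <- off + (rec$sstart - 1 + rec$send - 1) / 2
    secs <- sectionCounts(L, mid)
    hist <- identityHistogramOf(rec$pident)
    cl <- detectClouds(hist, ...)
    new("RecruitmentProfile", genomeId = gid, nReads = nrow(rec),
        ani = computeANI(rec$pident), sectionCounts = secs,
        rsd = computeRSD(secs, sdMode), identityHistogram = hist,
        twoClouds = cl$twoClouds, cloudSummaries = cl$clouds)
  })
  names(profiles) <- manifest$genome_id
  profiles
}

aniToBand <- function(x) {
  if (is.na(x)) NA_character_
  else if (x >= 95) "95-100"
  else if (x >= 90) "90-95"
  else if (x >= 80) "80-90"
  else if (x >= 70) "70-80"
  else "below-70"
}

#' Relative abundance of a recruited genome
#'
#' Percent of the sample's reads recruited to one genome. The denominator
#' is the sample's total quality-trimmed read count (configurable to the
#' plant-depleted count by passing that total instead).
#'
#' @param profile a [RecruitmentProfile-class] (or a read count).
#' @param totalSampleReads positive denominator.
#' @return percent.
#' @export
relativeAbundance <- function(profile, totalSampleReads) {
  if (totalSampleReads <= 0) stop("totalSampleReads must be positive")
  n <- if (is(profile, "RecruitmentProfile")) nReads(profile) else profile
  100 * n / totalSampleReads
}

#' Rule-based species presence call
#'
#' A species is called present when its genome recruited at least
#' \code{minReads} reads and the RSD is strictly below \code{maxRsd}.
#' The reported ANI band follows the profile's ANI, except that when two
#' read clouds were detected and the high cloud's mean identity exceeds 90
#' percent, the band is taken from the high cloud (the convention used when
#' reporting species whose high-identity cloud qualifies them).
#'
#' @param profile a [RecruitmentProfile-class].
#' @param species species name for reporting (defaults to the genome id).
#' @param minReads minimum recruited reads.
#' @param maxRsd exclusive RSD bound.
#' @param totalSampleReads optional sample total for relative abundance.
#' @return a [PresenceCall-class].
#' @examples
#' p <- new("RecruitmentProfile", genomeId = "g", nReads = 1500L,
#'          ani = 96.2, sectionCounts = rep(150L, 10), rsd = 0.5,
#'          identityHistogram = stats::setNames(
#'            c(rep(0, 36), 1500, rep(0, 4)), 60:100),
#'          twoClouds = FALSE,
#'          cloudSummaries = data.frame(cloud = "all", n_reads = 1500,
#'                                      mean_identity = 96.5))
#' isPresent(callPresence(p))   # TRUE, band "95-100"
#' @export
callPresence <- function(profile, species = genomeId(profile),
                         minReads = 1000L, maxRsd = 0.8,
                         totalSampleReads = NA_real_) {
  fails <- character()
  if (nReads(profile) < minReads) fails <- c(fails, "too_few_reads")
  if (is.na(rsd(profile)) || rsd(profile) >= maxRsd)
    fails <- c(fails, "rsd_too_high")
  bandAni <- ani(profile)
  if (isTRUE(twoClouds(profile))) {
    cs <- cloudSummaries(profile)
    hi <- cs$mean_identity[cs$cloud == "high"]
    if (length(hi) == 1L && !is.na(hi) && hi > 90) bandAni <- hi
  }
  ra <- if (is.na(totalSampleReads)) NA_real_ else
    relativeAbundance(profile, totalSampleReads)
  new("PresenceCall", species = species, genomeId = genomeId(profile),
      present = length(fails) == 0L, aniBand = aniToBand(bandAni),
      twoCloudFlag = isTRUE(twoClouds(profile)), relativeAbundance = ra,
      failReasons = fails)
}

#' Tabulate presence calls for a sample
#'
#' Applies [callPresence()] to every profile and assembles the
#' table-of-species layout: one row per genome with species, taxon group,
#' relative abundance, ANI band, the two-cloud asterisk, and the decision.
#'
#' @param profiles named list of [RecruitmentProfile-class] from
#'   [recruitReads()].
#' @param manifest manifest data.frame (needs \code{genome_id},
#'   \code{species}, \code{taxon_class}).
#' @param totalSampleReads total quality-trimmed reads of the sample.
#' @inheritParams callPresence
#' @return data.frame with columns \code{genome_id}, \code{species},
#'   \code{taxon_class}, \code{n_reads}, \code{ani}, \code{rsd},
#'   \code{relative_abundance}, \code{ani_band}, \code{two_clouds},
#'   \code{present}, \code{fail_reasons}.
#' @export
presenceTable <- function(profiles, manifest, totalSampleReads,
                          minReads = 1000L, maxRsd = 0.8) {
  rows <- lapply(profiles, function(p) {
    i <- match(genomeId(p), manifest$genome_id)
    call <- callPresence(p, species = manifest$species[i],
                         minReads = minReads, maxRsd = maxRsd,
                         totalSampleReads = totalSampleReads)
    data.frame(genome_id = genomeId(p), species = manifest$species[i],
               taxon_class = manifest$taxon_class[i], n_reads = nReads(p),
               ani = ani(p), rsd = rsd(p),
               relative_abundance = relativeAbundanceOf(call),
               ani_band = aniBand(call), two_clouds = twoClouds(call),
               present = isPresent(call),
               fail_reasons = paste(failReasons(call), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Roll up species-level relative abundances
#'
#' Aggregates a long table of per-sample species abundances (as printed in
#' species-presence reports) into per-sample totals with species counts and
#' per-group (class/phylum) totals — the bold rollup rows of the species
#' tables.
#'
#' @param calls long data.frame with columns \code{sample_id},
#'   \code{species}, \code{group} (taxonomic class or phylum) and
#'   \code{percent}.
#' @return list with \code{sampleTotals} (\code{sample_id}, \code{total},
#'   \code{n_species}) and \code{groupTotals} (\code{sample_id},
#'   \code{group}, \code{total}).
#' @export
rollupAbundance <- function(calls) {
  need <- c("sample_id", "species", "group", "percent")
  if (!all(need %in% names(calls)))
    stop("calls must have columns: ", paste(need, collapse = ", "))
  nz <- calls[calls$percent > 0, , drop = FALSE]
  st <- aggregate(percent ~ sample_id, data = nz, FUN = sum)
  names(st)[2] <- "total"
  st$n_species <- as.vector(table(nz$sample_id)[st$sample_id])
  gt <- aggregate(percent ~ sample_id + group, data = nz, FUN = sum)
  names(gt)[3] <- "total"
  list(sampleTotals = st[order(st$sample_id), , drop = FALSE],
       groupTotals = gt[order(gt$sample_id, gt$group), , drop = FALSE])
}
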