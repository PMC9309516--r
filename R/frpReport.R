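#' Render a fragment recruitment plot
#'
#' One dot per recruited read: position of the read's subject-interval
#' midpoint on the genome's concatenated [0, L) axis (x) against percent
#' identity (y, fixed to [60, 100] — reads below the 60 percent
#' consideration threshold never enter a profile). Section boundaries are
#' drawn as grid lines and an annotation box reports n, ANI, RSD and the
#' two-cloud asterisk. Every figure gets a TSV twin holding exactly the
#' plotted numbers.
#'
#' @param profile a [RecruitmentProfile-class].
#' @param alignments best-hit alignment records of the profile's genome
#'   (as returned by [bestHit()], i.e. with a \code{genome_id} column).
#' @param contigs contig table ([contigTable()] layout) for coordinate
#'   concatenation.
#' @param totalLength genome length L.
#' @param file output figure path (.png or .svg); the TSV twin replaces the
#'   extension with \code{.tsv}.
#' @param dpi raster resolution.
#' @return invisibly, a list with \code{file}, \code{tsv} and \code{data}
#'   (the plotted points).
#' @export
renderFrp <- function(profile, alignments, contigs, totalLength, file,
                      dpi = 150) {
  rec <- alignments[alignments$genome_id == genomeId(profile), ,
                    drop = FALSE]
  off <- contigs$offset[match(rec$sseqid, contigs$contig)]
  pts <- data.frame(position = off + (rec$sstart - 1 + rec$send - 1) / 2,
                    identity = rec$pident)
  if (nrow(pts) != nReads(profile))
    stop("alignments are inconsistent with the profile (",
         nrow(pts), " points vs ", nReads(profile), " reads)")
  tsv <- paste0(tools::file_path_sans_ext(file), ".tsv")
  utils::write.table(pts, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  w <- totalLength %/% 10
  lab <- sprintf("n = %d\nANI = %s\nRSD = %s%s", nReads(profile),
                 if (is.na(ani(profile))) "NA" else
                   sprintf("%.2f", ani(profile)),
                 if (is.na(rsd(profile))) "NA" else
                   sprintf("%.3f", rsd(profile)),
                 if (twoClouds(profile)) "\ntwo clouds *" else "")
  g <- ggplot2::ggplot(pts,
                       ggplot2::aes(x = position,
                                    y = identity)) +
    ggplot2::geom_vline(xintercept = c(w * 1:9, totalLength),
                        colour = "grey85") +
    ggplot2::coord_cartesian(xlim = c(0, totalLength), ylim = c(60, 100)) +
    ggplot2::labs(title = paste("Fragment recruitment:",
                                genomeId(profile)),
                  x = "genome position (bp)", y = "percent identity") +
    ggplot2::annotate("label", x = 0, y = 100, hjust = 0, vjust = 1,
                      label = lab, size = 3) +
    ggplot2::theme_minimal()
  g <- if (nrow(pts)) g + ggplot2::geom_point(size = 0.4, alpha = 0.5,
                                              colour = "steelblue") else
    g + ggplot2::annotate("text", x = totalLength / 2, y = 80,
                          label = "no recruited reads")
  ggplot2::ggsave(file, g, width = 7, height = 4, dpi = dpi)
  invisible(list(file = file, tsv = tsv, data = pts))
}

#' Render a taxonomic composition figure
#'
#' Stacked bars of per-method (or per-stage) composition percentages with
#' the reserved categories ("Minorities", "Higher than genus", "Unassigned",
#' "No hits") and, when read counts are supplied, an overlaid marker per
#' bar showing the number of reads used. A TSV twin holds exactly the
#' plotted numbers.
#'
#' @param composition data.frame (\code{method}, \code{category},
#'   \code{percent}) as produced by [categorizeReport()].
#' @param file output figure path (.png/.svg).
#' @param counts optional named numeric vector of per-method read counts.
#' @param dpi raster resolution.
#' @return invisibly, list with \code{file}, \code{tsv}, \code{data}.
#' @export
renderComposition <- function(composition, file, counts = NULL, dpi = 150) {
  sums <- tapply(composition$percent, composition$method, sum)
  if (any(sums > 100.01))
    stop("composition percentages exceed 100% for method(s): ",
         paste(names(sums)[sums > 100.01], collapse = ", "))
  tsv <- paste0(tools::file_path_sans_ext(file), ".tsv")
  utils::write.table(composition, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g <- ggplot2::ggplot(composition,
                       ggplot2::aes(x = method, y = percent,
                                    fill = category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "relative abundance (%)") +
    ggplot2::theme_minimal()
  if (!is.null(counts)) {
    cdf <- data.frame(method = names(counts),
                      scaled = 100 * as.numeric(counts) /
                        max(as.numeric(counts)))
    g <- g + ggplot2::geom_point(
      data = cdf,
      ggplot2::aes(x = method, y = scaled),
      inherit.aes = FALSE, colour = "orange", size = 3)
  }
  ggplot2::ggsave(file, g, width = 7, height = 4, dpi = dpi)
  invisible(list(file = file, tsv = tsv, data = composition))
}
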