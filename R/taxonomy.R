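#' Select genera for the recruitment database
#'
#' A genus enters the recruitment database when at least one genus-level
#' classifier reports it in at least one sample with a relative abundance of
#' at least \code{minAbundance} percent (inclusive).
#'
#' @param reports long-format data.frame of classifier output with columns
#'   \code{method}, \code{sample_id}, \code{genus},
#'   \code{relative_abundance} (percent). Several methods and samples may
#'   be stacked in one data.frame.
#' @param minAbundance inclusive percent threshold.
#' @return sorted character vector of selected genera.
#' @export
selectGenera <- function(reports, minAbundance = 0.1) {
  need <- c("method", "sample_id", "genus", "relative_abundance")
  if (!all(need %in% names(reports)))
    stop("reports must have columns: ", paste(need, collapse = ", "))
  if (any(reports$relative_abundance < 0))
    stop("relative abundances must be non-negative")
  sort(unique(reports$genus[reports$relative_abundance >= minAbundance]))
}

#' Build the recruitment genome manifest
#'
#' One representative genome per species of the selected genera (where a
#' representative is available), extended with a curated list of
#' fermentation-relevant species (lactic and acetic acid bacteria) whose
#' genomes are always included. The \code{source} column records whether a
#' row came from genus selection or from the extension list.
#'
#' @param genera character vector of selected genera (see [selectGenera()]).
#' @param representatives data.frame mapping available species to genomes:
#'   columns \code{species}, \code{genus}, \code{genome_id},
#'   \code{taxon_class}, \code{total_length}.
#' @param extension optional data.frame of the same shape listing the
#'   curated extension species.
#' @return manifest data.frame with the representative columns plus
#'   \code{source} ("selected" or "LAB_AAB_extension").
#' @export
buildManifest <- function(genera, representatives, extension = NULL) {
  need <- c("species", "genus", "genome_id", "taxon_class", "total_length")
  if (!all(need %in% names(representatives)))
    stop("representatives must have columns: ", paste(need, collapse = ", "))
  sel <- representatives[representatives$genus %in% genera, need,
                         drop = FALSE]
  sel$source <- if (nrow(sel)) "selected" else character(0)
  if (!is.null(extension) && nrow(extension)) {
    ext <- extension[, need, drop = FALSE]
    ext$source <- "LAB_AAB_extension"
    ext <- ext[!ext$genome_id %in% sel$genome_id, , drop = FALSE]
    sel <- rbind(sel, ext)
  }
  if (anyDuplicated(sel$genome_id))
    stop("duplicate genome_id in manifest: ",
         paste(unique(sel$genome_id[duplicated(sel$genome_id)]),
               collapse = ", "))
  if (any(sel$total_length <= 0)) stop("total_length must be positive")
  rownames(sel) <- NULL
  sel
}

#' Categorize per-genus read assignments for composition reporting
#'
#' Collapses, per classification method, the genus-level read assignments
#' of one sample into the composition categories used in the stacked-bar
#' figures: named genera, plus the reserved categories "Minorities" (all
#' genera whose relative abundance stays below \code{minorityThreshold}
#' percent in every method), "Higher than genus", "Unassigned" and
#' "No hits".
#'
#' @param assignments data.frame with columns \code{method}, \code{label}
#'   (a genus name or one of the reserved labels "Higher than genus",
#'   "Unassigned", "No hits") and \code{n_reads}.
#' @param totalReads total reads of the sample per method (single number,
#'   or named vector by method); percentages are relative to it.
#' @param minorityThreshold percent below which (in all methods) a genus is
#'   folded into "Minorities".
#' @return data.frame (\code{method}, \code{category}, \code{percent});
#'   per method the percentages sum to 100 (within 0.01) when the
#'   assignments cover all reads.
#' @export
categorizeReport <- function(assignments, totalReads,
                             minorityThreshold = 0.9) {
  if (any(totalReads == 0)) stop("totalReads must be positive")
  reserved <- c("Higher than genus", "Unassigned", "No hits")
  a <- assignments
  tot <- if (length(totalReads) == 1L) rep(totalReads, nrow(a)) else
    unname(totalReads[a$method])
  a$percent <- 100 * a$n_reads / tot
  genera <- setdiff(unique(a$label), reserved)
  peak <- vapply(genera, function(g)
    max(a$percent[a$label == g]), numeric(1))
  minor <- genera[peak < minorityThreshold]
  a$category <- ifelse(a$label %in% minor, "Minorities", a$label)
  out <- aggregate(percent ~ method + category, data = a, FUN = sum)
  out[order(out$method, out$category), , drop = FALSE]
}
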