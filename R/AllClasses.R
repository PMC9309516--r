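#' @import methods
NULL

#' GenomeSpec: blueprint for one synthetic reference genome
#'
#' Describes a toy multi-contig genome used by the synthetic community
#' generator: its identifiers, taxonomy labels, contig lengths and the seed
#' that makes its sequence reproducible.
#'
#' @slot genomeId single genome identifier, unique within a manifest.
#' @slot species,genus,taxonClass taxonomy labels carried through to
#'   presence-call reports (class for bacteria, phylum for fungi).
#' @slot contigLengths integer vector of contig lengths in bases; all > 0.
#' @slot seed integer seed controlling the generated sequence.
#' @exportClass GenomeSpec
setClass("GenomeSpec",
  representation(
    genomeId = "character",
    species = "character",
    genus = "character",
    taxonClass = "character",
    contigLengths = "integer",
    seed = "integer"
  )
)

setValidity("GenomeSpec", function(object) {
  msg <- character()
  if (length(object@genomeId) != 1L || !nzchar(object@genomeId))
    msg <- c(msg, "'genomeId' must be a single non-empty string")
  if (length(object@contigLengths) < 1L || any(object@contigLengths <= 0L))
    msg <- c(msg, "all contig lengths must be positive")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "'seed' must be a single integer")
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeSpec
#'
#' @param genomeId genome identifier (unique within a manifest).
#' @param species,genus,taxonClass taxonomy labels.
#' @param contigLengths positive integer vector of contig lengths (bases).
#' @param seed integer seed for the genome sequence.
#' @return A [GenomeSpec-class] object.
#' @examples
#' genomeSpec("g1", "Pantoea vagans", "Pantoea", "Gammaproteobacteria",
#'            contigLengths = c(60000, 40000), seed = 7)
#' @export
genomeSpec <- function(genomeId, species = genomeId, genus = species,
                       taxonClass = "unknown", contigLengths, seed = 1L) {
  new("GenomeSpec", genomeId = as.character(genomeId),
      species = as.character(species), genus = as.character(genus),
      taxonClass = as.character(taxonClass),
      contigLengths = as.integer(contigLengths), seed = as.integer(seed))
}

setMethod("show", "GenomeSpec", function(object) {
  cat("GenomeSpec", object@genomeId, "(", object@species, ")\n",
      " ", length(object@contigLengths), "contig(s),",
      sum(object@contigLengths), "bases, seed", object@seed, "\n")
})

#' CommunityDesign: composition of one synthetic metagenome sample
#'
#' Fixes, for a single simulated sample, which genomes contribute reads and
#' at which fractions, the per-member divergence from its reference, the
#' host-plant and unclassifiable read fractions, the read number and length
#' model, and the seed. Member read fractions plus the host and
#' unclassified fractions must sum to one.
#'
#' @slot sampleId sample identifier.
#' @slot members data.frame with columns \code{genome_id},
#'   \code{read_fraction} (in [0,1]), \code{divergence} (substitutions per
#'   base, in [0,0.4]) and \code{coverage_mode} ("uniform" or
#'   "single-region"); an optional \code{region} column (1--10) fixes which
#'   tenth of the genome a single-region member occupies.
#' @slot hostFraction,unclassifiedFraction fractions of host-plant and
#'   unplaceable ("no hit") reads.
#' @slot nReads total number of reads to simulate.
#' @slot readLengthMean,readLengthSd read length model in bases.
#' @slot seed integer seed.
#' @exportClass CommunityDesign
setClass("CommunityDesign",
  representation(
    sampleId = "character",
    members = "data.frame",
    hostFraction = "numeric",
    unclassifiedFraction = "numeric",
    nReads = "integer",
    readLengthMean = "numeric",
    readLengthSd = "numeric",
    seed = "integer"
  )
)

setValidity("CommunityDesign", function(object) {
  msg <- character()
  m <- object@members
  need <- c("genome_id", "read_fraction", "divergence", "coverage_mode")
  if (!all(need %in% names(m)))
    msg <- c(msg, paste("members must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (any(m$read_fraction < 0 | m$read_fraction > 1))
      msg <- c(msg, "member read fractions must lie in [0,1]")
    if (any(m$divergence < 0 | m$divergence > 0.4))
      msg <- c(msg, "member divergence must lie in [0, 0.4]")
    if (!all(m$coverage_mode %in% c("uniform", "single-region")))
      msg <- c(msg, "coverage_mode must be 'uniform' or 'single-region'")
    tot <- sum(m$read_fraction) + object@hostFraction +
      object@unclassifiedFraction
    if (abs(tot - 1) > 1e-9)
      msg <- c(msg, sprintf(
        "member + host + unclassified fractions must sum to 1 (got %.12f)",
        tot))
  }
  if (object@hostFraction < 0 || object@hostFraction > 1)
    msg <- c(msg, "hostFraction must lie in [0,1]")
  if (object@unclassifiedFraction < 0 || object@unclassifiedFraction > 1)
    msg <- c(msg, "unclassifiedFraction must lie in [0,1]")
  if (object@nReads < 1L) msg <- c(msg, "nReads must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a CommunityDesign
#'
#' @param sampleId sample identifier.
#' @param members data.frame of community members (see
#'   [CommunityDesign-class]).
#' @param hostFraction,unclassifiedFraction fractions of host-plant and
#'   random unplaceable reads.
#' @param nReads total reads to simulate.
#' @param readLengthMean,readLengthSd read-length model (bases).
#' @param seed integer seed.
#' @return A [CommunityDesign-class] object.
#' @export
communityDesign <- function(sampleId, members, hostFraction = 0,
                            unclassifiedFraction = 0, nReads = 10000L,
                            readLengthMean = 200, readLengthSd = 20,
                            seed = 1L) {
  members <- as.data.frame(members)
  if (is.null(members$coverage_mode)) members$coverage_mode <- "uniform"
  if (is.null(members$divergence)) members$divergence <- 0
  new("CommunityDesign", sampleId = as.character(sampleId),
      members = members, hostFraction = hostFraction,
      unclassifiedFraction = unclassifiedFraction,
      nReads = as.integer(nReads), readLengthMean = readLengthMean,
      readLengthSd = readLengthSd, seed = as.integer(seed))
}

setMethod("show", "CommunityDesign", function(object) {
  cat("CommunityDesign", object@sampleId, ":", object@nReads, "reads,",
      nrow(object@members), "member genome(s),",
      sprintf("host %.1f%%,", 100 * object@hostFraction),
      sprintf("unclassified %.1f%%\n", 100 * object@unclassifiedFraction))
})

#' RecruitmentProfile: per-genome fragment-recruitment summary
#'
#' Aggregates the reads recruited to one reference genome: how many, their
#' mean percent identity (read-based ANI), how they distribute over ten
#' equal genome sections (and the resulting RSD, the standard deviation of
#' section counts divided by their mean), the 1 percent identity histogram,
#' and whether the identity distribution splits into two read clouds.
#'
#' @slot genomeId reference genome identifier.
#' @slot nReads number of recruited reads.
#' @slot ani mean percent identity of recruited reads (NA when no reads).
#' @slot sectionCounts integer vector of length 10 summing to \code{nReads}.
#' @slot rsd coverage-uniformity statistic (NA when no reads).
#' @slot identityHistogram named counts per 1 percent identity bin (60--100).
#' @slot twoClouds logical; TRUE when the identity histogram is bimodal.
#' @slot cloudSummaries data.frame with one row per cloud
#'   (\code{n_reads}, \code{mean_identity}).
#' @exportClass RecruitmentProfile
setClass("RecruitmentProfile",
  representation(
    genomeId = "character",
    nReads = "integer",
    ani = "numeric",
    sectionCounts = "integer",
    rsd = "numeric",
    identityHistogram = "numeric",
    twoClouds = "logical",
    cloudSummaries = "data.frame"
  )
)

setValidity("RecruitmentProfile", function(object) {
  msg <- character()
  if (length(object@sectionCounts) != 10L)
    msg <- c(msg, "sectionCounts must have length 10")
  else if (sum(object@sectionCounts) != object@nReads)
    msg <- c(msg, "sectionCounts must sum to nReads")
  if (any(object@sectionCounts < 0L))
    msg <- c(msg, "sectionCounts must be non-negative")
  if (object@nReads > 0L) {
    if (is.na(object@ani) || object@ani < 0 || object@ani > 100)
      msg <- c(msg, "ani must lie in [0,100] when reads are recruited")
    if (is.na(object@rsd) || object@rsd < 0)
      msg <- c(msg, "rsd must be a non-negative number when reads exist")
  } else {
    if (!is.na(object@ani)) msg <- c(msg, "ani must be NA when nReads == 0")
    if (!is.na(object@rsd)) msg <- c(msg, "rsd must be NA when nReads == 0")
  }
  if (sum(object@identityHistogram) != object@nReads)
    msg <- c(msg, "identityHistogram must sum to nReads")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RecruitmentProfile", function(object) {
  cat("RecruitmentProfile", object@genomeId, "\n",
      " reads:", object@nReads,
      " ANI:", if (is.na(object@ani)) "NA" else sprintf("%.2f", object@ani),
      " RSD:", if (is.na(object@rsd)) "NA" else sprintf("%.3f", object@rsd),
      " two clouds:", object@twoClouds, "\n",
      " sections:", paste(object@sectionCounts, collapse = " "), "\n")
})

#' PresenceCall: rule-based species presence decision
#'
#' The decision that a species is present in a sample, made from its
#' recruitment profile: at least \code{minReads} recruited reads and an RSD
#' below \code{maxRsd}. Carries the ANI band used for colour-coded
#' reporting, the two-cloud flag (reported as an asterisk), the relative
#' abundance as percent of the sample's quality-trimmed reads, and the
#' reasons a call failed.
#'
#' @slot species species name.
#' @slot genomeId reference genome identifier.
#' @slot present logical decision.
#' @slot aniBand one of "95-100", "90-95", "80-90", "70-80", "below-70".
#' @slot twoCloudFlag logical; TRUE when the profile shows two read clouds.
#' @slot relativeAbundance percent of sample reads recruited (NA if the
#'   sample total was not supplied).
#' @slot failReasons subset of \code{c("too_few_reads", "rsd_too_high")}.
#' @exportClass PresenceCall
setClass("PresenceCall",
  representation(
    species = "character",
    genomeId = "character",
    present = "logical",
    aniBand = "character",
    twoCloudFlag = "logical",
    relativeAbundance = "numeric",
    failReasons = "character"
  )
)

setValidity("PresenceCall", function(object) {
  msg <- character()
  if (object@present && length(object@failReasons) > 0L)
    msg <- c(msg, "a present call cannot carry fail reasons")
  if (!all(object@failReasons %in% c("too_few_reads", "rsd_too_high")))
    msg <- c(msg, "unknown fail reason")
  if (!is.na(object@relativeAbundance) && object@relativeAbundance < 0)
    msg <- c(msg, "relativeAbundance must be >= 0")
  bands <- c("95-100", "90-95", "80-90", "70-80", "below-70", NA_character_)
  if (!object@aniBand %in% bands) msg <- c(msg, "invalid ANI band")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PresenceCall", function(object) {
  cat("PresenceCall:", object@species, "[", object@genomeId, "]\n",
      " present:", object@present,
      " band:", object@aniBand,
      if (object@twoCloudFlag) " *two clouds*" else "", "\n")
  if (length(object@failReasons))
    cat("  fail reasons:", paste(object@failReasons, collapse = ", "), "\n")
})

#' AbundanceTable: samples-by-taxa relative abundances
#'
#' A samples x taxa matrix of relative percentages (of each sample's
#' quality-trimmed reads) at a stated taxonomic rank. Row sums may fall
#' below 100 because unassigned read mass is excluded.
#'
#' @slot values numeric matrix, samples in rows, taxa in columns.
#' @slot rank taxonomic rank of the columns ("species", "genus", "class").
#' @exportClass AbundanceTable
setClass("AbundanceTable",
  representation(values = "matrix", rank = "character")
)

setValidity("AbundanceTable", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  else {
    if (any(v < 0)) msg <- c(msg, "abundances must be non-negative")
    if (any(rowSums(v) > 100 + 0.01))
      msg <- c(msg, "row sums must not exceed 100 (+0.01 tolerance)")
  }
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must have sample row names and taxon column names")
  if (length(msg)) msg else TRUE
})

#' Construct an AbundanceTable
#'
#' @param values numeric matrix of relative percentages, samples in rows
#'   (named), taxa in columns (named).
#' @param rank taxonomic rank of the columns.
#' @return An [AbundanceTable-class] object.
#' @export
abundanceTable <- function(values, rank = "genus") {
  new("AbundanceTable", values = as.matrix(values), rank = rank)
}

setMethod("show", "AbundanceTable", function(object) {
  cat("AbundanceTable (", object@rank, "):", nrow(object@values),
      "samples x", ncol(object@values), "taxa\n")
  print(utils::head(object@values[, seq_len(min(5, ncol(object@values))),
                                  drop = FALSE], 4))
})

#' @describeIn AbundanceTable-class dimensions of the abundance matrix
#' @param x an AbundanceTable
#' @export
setMethod("dim", "AbundanceTable", function(x) dim(x@values))
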