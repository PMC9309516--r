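#' Accessors for frpkit S4 objects
#'
#' Small read-only accessors for the core data classes; slot access in user
#' code is discouraged.
#'
#' @param object an frpkit S4 object.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeId", function(object) standardGeneric("genomeId"))
#' @rdname accessors
#' @export
setGeneric("nReads", function(object) standardGeneric("nReads"))
#' @rdname accessors
#' @export
setGeneric("ani", function(object) standardGeneric("ani"))
#' @rdname accessors
#' @export
setGeneric("rsd", function(object) standardGeneric("rsd"))
#' @rdname accessors
#' @export
setGeneric("sections", function(object) standardGeneric("sections"))
#' @rdname accessors
#' @export
setGeneric("identityHistogram",
           function(object) standardGeneric("identityHistogram"))
#' @rdname accessors
#' @export
setGeneric("twoClouds", function(object) standardGeneric("twoClouds"))
#' @rdname accessors
#' @export
setGeneric("cloudSummaries",
           function(object) standardGeneric("cloudSummaries"))
#' @rdname accessors
#' @export
setGeneric("speciesName", function(object) standardGeneric("speciesName"))
#' @rdname accessors
#' @export
setGeneric("isPresent", function(object) standardGeneric("isPresent"))
#' @rdname accessors
#' @export
setGeneric("aniBand", function(object) standardGeneric("aniBand"))
#' @rdname accessors
#' @export
setGeneric("failReasons", function(object) standardGeneric("failReasons"))
#' @rdname accessors
#' @export
setGeneric("relativeAbundanceOf",
           function(object) standardGeneric("relativeAbundanceOf"))
#' @rdname accessors
#' @export
setGeneric("abundanceValues",
           function(object) standardGeneric("abundanceValues"))
#' @rdname accessors
#' @export
setGeneric("taxonRank", function(object) standardGeneric("taxonRank"))

#' @rdname accessors
#' @export
setMethod("genomeId", "GenomeSpec", function(object) object@genomeId)
#' @rdname accessors
#' @export
setMethod("genomeId", "RecruitmentProfile", function(object) object@genomeId)
#' @rdname accessors
#' @export
setMethod("genomeId", "PresenceCall", function(object) object@genomeId)
#' @rdname accessors
#' @export
setMethod("nReads", "RecruitmentProfile", function(object) object@nReads)
#' @rdname accessors
#' @export
setMethod("ani", "RecruitmentProfile", function(object) object@ani)
#' @rdname accessors
#' @export
setMethod("rsd", "RecruitmentProfile", function(object) object@rsd)
#' @rdname accessors
#' @export
setMethod("sections", "RecruitmentProfile",
          function(object) object@sectionCounts)
#' @rdname accessors
#' @export
setMethod("identityHistogram", "RecruitmentProfile",
          function(object) object@identityHistogram)
#' @rdname accessors
#' @export
setMethod("twoClouds", "RecruitmentProfile", function(object) object@twoClouds)
#' @rdname accessors
#' @export
setMethod("twoClouds", "PresenceCall", function(object) object@twoCloudFlag)
#' @rdname accessors
#' @export
setMethod("cloudSummaries", "RecruitmentProfile",
          function(object) object@cloudSummaries)
#' @rdname accessors
#' @export
setMethod("speciesName", "GenomeSpec", function(object) object@species)
#' @rdname accessors
#' @export
setMethod("speciesName", "PresenceCall", function(object) object@species)
#' @rdname accessors
#' @export
setMethod("isPresent", "PresenceCall", function(object) object@present)
#' @rdname accessors
#' @export
setMethod("aniBand", "PresenceCall", function(object) object@aniBand)
#' @rdname accessors
#' @export
setMethod("failReasons", "PresenceCall", function(object) object@failReasons)
#' @rdname accessors
#' @export
setMethod("relativeAbundanceOf", "PresenceCall",
          function(object) object@relativeAbundance)
#' @rdname accessors
#' @export
setMethod("abundanceValues", "AbundanceTable", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("taxonRank", "AbundanceTable", function(object) object@rank)
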