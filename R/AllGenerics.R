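#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small family of accessors for the core S4 containers: OTU identifiers,
#' per-sample library sizes, treatment-group labels, and the matrices held by
#' count, normalized-count and distance objects.
#'
#' @param object an object of one of the package's S4 classes.
#' @return `otuIds` a character vector; `sampleDepths` an integer vector named
#'   by sample; `sampleGroups` a character vector of `"A"`/`"B"` labels named
#'   by sample; `otuCounts` and `normValues` a samples-by-OTU matrix;
#'   `distValues` a symmetric sample-by-sample matrix.
#' @name accessors
#' @aliases otuIds sampleDepths sampleGroups otuCounts normValues distValues
#' @examples
#' pp <- makeSyntheticParents(nOtus = 20, seed = 1)
#' head(otuIds(pp))
NULL

#' @rdname accessors
#' @export
setGeneric("otuIds", function(object) standardGeneric("otuIds"))

#' @rdname accessors
#' @export
setGeneric("sampleDepths", function(object) standardGeneric("sampleDepths"))

#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(object) standardGeneric("sampleGroups"))

#' @rdname accessors
#' @export
setGeneric("otuCounts", function(object) standardGeneric("otuCounts"))

#' @rdname accessors
#' @export
setGeneric("normValues", function(object) standardGeneric("normValues"))

#' @rdname accessors
#' @export
setGeneric("distValues", function(object) standardGeneric("distValues"))
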