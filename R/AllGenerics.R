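#' Accessors for FragmentLibrary, ScaledTrack and GeneMarkTable
#'
#' Accessor generics for the package's core classes. Slot access via
#' \code{@} is not part of the API.
#'
#' @param x a [FragmentLibrary-class], [ScaledTrack-class] or
#'   [GeneMarkTable-class] object, as documented per method.
#' @return The slot contents: see the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))
#' @rdname accessors
#' @export
setGeneric("antibody", function(x) standardGeneric("antibody"))
#' @rdname accessors
#' @export
setGeneric("genotype", function(x) standardGeneric("genotype"))
#' @rdname accessors
#' @export
setGeneric("libraryId", function(x) standardGeneric("libraryId"))
#' @rdname accessors
#' @export
setGeneric("replicateId", function(x) standardGeneric("replicateId"))
#' @rdname accessors
#' @export
setGeneric("totalBaseCoverage", function(x) standardGeneric("totalBaseCoverage"))
#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @rdname accessors
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))
#' @rdname accessors
#' @export
setGeneric("seqLengths", function(x) standardGeneric("seqLengths"))
#' @rdname accessors
#' @export
setGeneric("trackLabel", function(x) standardGeneric("trackLabel"))
#' @rdname accessors
#' @export
setGeneric("markTable", function(x) standardGeneric("markTable"))

#' @rdname accessors
#' @export
setMethod("fragments", "FragmentLibrary", function(x) x@fragments)
#' @rdname accessors
#' @export
setMethod("antibody", "FragmentLibrary", function(x) x@antibody)
#' @rdname accessors
#' @export
setMethod("genotype", "FragmentLibrary", function(x) x@genotype)
#' @rdname accessors
#' @export
setMethod("libraryId", "FragmentLibrary", function(x) x@libraryId)
#' @rdname accessors
#' @export
setMethod("replicateId", "FragmentLibrary", function(x) x@replicate)
#' @rdname accessors
#' @export
setMethod("totalBaseCoverage", "FragmentLibrary", function(x) x@totalBaseCoverage)

#' @rdname accessors
#' @export
setMethod("binSize", "ScaledTrack", function(x) x@binSize)
#' @rdname accessors
#' @export
setMethod("trackValues", "ScaledTrack", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("seqLengths", "ScaledTrack", function(x) x@seqlengths)
#' @rdname accessors
#' @export
setMethod("trackLabel", "ScaledTrack", function(x) x@label)

#' @rdname accessors
#' @export
setMethod("markTable", "GeneMarkTable", function(x) x@table)
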