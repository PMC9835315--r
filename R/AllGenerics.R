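#' @rdname CompoundSet-accessors
#' @export
setGeneric("canonicalSmiles", function(x) standardGeneric("canonicalSmiles"))

#' @rdname CompoundSet-accessors
#' @export
setGeneric("compoundData", function(x) standardGeneric("compoundData"))

#' @rdname CompoundSet-accessors
#' @export
setGeneric("compoundData<-", function(x, value) standardGeneric("compoundData<-"))

#' @rdname CompoundSet-accessors
#' @export
setGeneric("activityLabels", function(x) standardGeneric("activityLabels"))

#' @rdname CompoundSet-accessors
#' @export
setGeneric("featureBlock", function(x, name) standardGeneric("featureBlock"))

#' @rdname CompoundSet-accessors
#' @export
setGeneric("featureBlocks", function(x) standardGeneric("featureBlocks"))

#' @rdname CompoundSet-accessors
#' @export
setGeneric("featureBlock<-", function(x, name, value) standardGeneric("featureBlock<-"))

#' @rdname CompoundSet-accessors
#' @export
setGeneric("tokenizedSmiles", function(x) standardGeneric("tokenizedSmiles"))

#' @rdname CompoundSet-accessors
#' @export
setGeneric("tokenizedSmiles<-", function(x, value) standardGeneric("tokenizedSmiles<-"))

#' @rdname CompoundSet-accessors
#' @export
setGeneric("partitions", function(x) standardGeneric("partitions"))

#' Accessors for CompoundSet
#'
#' @param x A [CompoundSet-class].
#' @param name Feature block name (`"descriptors"`, `"maccs"`, `"ecfp4"`,
#'   or a processed/fused block name).
#' @param value Replacement value.
#' @return The requested component, or the modified object for setters.
#' @name CompoundSet-accessors
NULL

#' @rdname CompoundSet-accessors
#' @export
setMethod("canonicalSmiles", "CompoundSet",
          function(x) x@compoundData$canonical_smiles)

#' @rdname CompoundSet-accessors
#' @export
setMethod("compoundData", "CompoundSet", function(x) x@compoundData)

#' @rdname CompoundSet-accessors
#' @export
setReplaceMethod("compoundData", "CompoundSet", function(x, value) {
  x@compoundData <- value; validObject(x); x
})

#' @rdname CompoundSet-accessors
#' @export
setMethod("activityLabels", "CompoundSet", function(x) x@compoundData$label)

#' @rdname CompoundSet-accessors
#' @export
setMethod("featureBlock", "CompoundSet", function(x, name) {
  if (!name %in% names(x@featureBlocks))
    stop(sprintf("no feature block '%s' (have: %s)", name,
                 paste(names(x@featureBlocks), collapse = ", ")))
  x@featureBlocks[[name]]
})

#' @rdname CompoundSet-accessors
#' @export
setMethod("featureBlocks", "CompoundSet", function(x) x@featureBlocks)

#' @rdname CompoundSet-accessors
#' @export
setReplaceMethod("featureBlock", "CompoundSet", function(x, name, value) {
  x@featureBlocks[[name]] <- value; validObject(x); x
})

#' @rdname CompoundSet-accessors
#' @export
setMethod("tokenizedSmiles", "CompoundSet", function(x) x@tokens)

#' @rdname CompoundSet-accessors
#' @export
setReplaceMethod("tokenizedSmiles", "CompoundSet", function(x, value) {
  x@tokens <- value; validObject(x); x
})

#' @rdname CompoundSet-accessors
#' @export
setMethod("partitions", "CompoundSet", function(x) x@compoundData$partition)
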