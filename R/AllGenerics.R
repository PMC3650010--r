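#' @rdname ProteinSet-class
#' @param x,object A `ProteinSet`, `AnnotationTrack`, `EdgeList` or
#'   `JointStats` object, as appropriate to the accessor.
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' @rdname ProteinSet-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname ProteinSet-class
#' @export
setGeneric("setLabels", function(x) standardGeneric("setLabels"))

#' @rdname ProteinSet-class
#' @export
setGeneric("isoformRanks", function(x) standardGeneric("isoformRanks"))

#' @rdname ProteinSet-class
#' @export
setGeneric("seqLengths", function(x) standardGeneric("seqLengths"))

#' @rdname ProteinSet-class
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname AnnotationTrack-class
#' @export
setGeneric("trackKind", function(x) standardGeneric("trackKind"))

#' @rdname AnnotationTrack-class
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' @rdname AnnotationTrack-class
#' @export
setGeneric("trackSource", function(x) standardGeneric("trackSource"))

#' @rdname AnnotationTrack-class
#' @export
setGeneric("trackScores", function(x) standardGeneric("trackScores"))

#' @rdname EdgeList-class
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname EdgeList-class
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname JointStats-class
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname JointStats-class
#' @export
setGeneric("jointCounts", function(x) standardGeneric("jointCounts"))

#' @rdname JointStats-class
#' @export
setGeneric("jointProbabilities", function(x) standardGeneric("jointProbabilities"))

#' @rdname JointStats-class
#' @export
setGeneric("propensityValue", function(x) standardGeneric("propensityValue"))
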