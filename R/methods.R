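## Accessors and show() methods for the S4 containers.

#' @rdname ProteinSet-class
#' @export
setMethod("proteinIds", "ProteinSet", function(x) names(x@sequences))

#' @rdname ProteinSet-class
#' @export
setMethod("geneIds", "ProteinSet", function(x)
    setNames(x@geneId, names(x@sequences)))

#' @rdname ProteinSet-class
#' @export
setMethod("setLabels", "ProteinSet", function(x)
    setNames(x@setLabel, names(x@sequences)))

#' @rdname ProteinSet-class
#' @export
setMethod("isoformRanks", "ProteinSet", function(x)
    setNames(x@isoformRank, names(x@sequences)))

#' @rdname ProteinSet-class
#' @export
setMethod("seqLengths", "ProteinSet", function(x)
    setNames(Biostrings::width(x@sequences), names(x@sequences)))

#' @rdname ProteinSet-class
#' @export
setMethod("sequences", "ProteinSet", function(x) x@sequences)

#' @rdname ProteinSet-class
#' @export
setMethod("length", "ProteinSet", function(x) length(x@sequences))

#' @rdname ProteinSet-class
#' @param i Index (numeric, logical or protein ids) for subsetting.
#' @param j,drop,... Ignored; present for generic compatibility.
#' @export
setMethod("[", "ProteinSet", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) i <- match(i, names(x@sequences))
    new("ProteinSet",
        sequences = x@sequences[i],
        geneId = x@geneId[i],
        setLabel = x@setLabel[i],
        isoformRank = x@isoformRank[i])
})

setMethod("show", "ProteinSet", function(object) {
    n <- length(object@sequences)
    cat(sprintf("ProteinSet with %d protein(s)\n", n))
    if (n > 0) {
        w <- Biostrings::width(object@sequences)
        cat(sprintf("  set label(s): %s\n",
                    paste(unique(object@setLabel), collapse = ", ")))
        cat(sprintf("  genes: %d | length range: %d-%d | mean length: %.1f\n",
                    length(unique(object@geneId)), min(w), max(w), mean(w)))
    }
    invisible(NULL)
})

#' @rdname AnnotationTrack-class
#' @export
setMethod("proteinIds", "AnnotationTrack", function(x) x@proteinId)

#' @rdname AnnotationTrack-class
#' @export
setMethod("trackKind", "AnnotationTrack", function(x) x@kind)

#' @rdname AnnotationTrack-class
#' @export
setMethod("trackValues", "AnnotationTrack", function(x) x@values)

#' @rdname AnnotationTrack-class
#' @export
setMethod("trackSource", "AnnotationTrack", function(x) x@source)

#' @rdname AnnotationTrack-class
#' @export
setMethod("trackScores", "AnnotationTrack", function(x)
    if (length(x@score)) x@score else NULL)

#' @rdname AnnotationTrack-class
#' @export
setMethod("length", "AnnotationTrack", function(x) length(x@values))

setMethod("show", "AnnotationTrack", function(object) {
    v <- object@values
    frac <- if (is.logical(v)) sprintf("%.1f%% positive", 100 * mean(v))
            else paste(sprintf("%s:%.0f%%", names(table(v)),
                               100 * table(v) / length(v)), collapse = " ")
    cat(sprintf("AnnotationTrack '%s' for %s (%d residues, %s): %s\n",
                object@kind, object@proteinId, length(v), object@source, frac))
    invisible(NULL)
})

#' @rdname EdgeList-class
#' @export
setMethod("edges", "EdgeList", function(x) x@edges)

#' @rdname EdgeList-class
#' @export
setMethod("nodes", "EdgeList", function(x) x@nodes)

#' @rdname EdgeList-class
#' @export
setMethod("length", "EdgeList", function(x) nrow(x@edges))

setMethod("show", "EdgeList", function(object) {
    cat(sprintf("EdgeList: %d undirected edge(s) over %d node(s)\n",
                nrow(object@edges), length(object@nodes)))
    invisible(NULL)
})

#' @rdname JointStats-class
#' @export
setMethod("nResidues", "JointStats", function(x) x@nResidues)

#' @rdname JointStats-class
#' @export
setMethod("jointCounts", "JointStats", function(x) {
    out <- list(disorder_coil = x@counts)
    if (length(x@ssCounts)) out$disorder_ss <- x@ssCounts
    out
})

#' @rdname JointStats-class
#' @export
setMethod("jointProbabilities", "JointStats", function(x)
    c(p_disorder = x@pDisorder,
      p_coil = x@pCoil,
      p_coil_and_disorder = x@pCoilAndDisorder,
      p_coil_not_disorder = x@pCoilNotDisorder))

#' @rdname JointStats-class
#' @export
setMethod("propensityValue", "JointStats", function(x) x@propensity)

setMethod("show", "JointStats", function(object) {
    cat(sprintf("JointStats over %d residues (tracks: %s)\n",
                object@nResidues, object@source))
    cat(sprintf("  P(disorder) = %.3f, P(coil) = %.3f\n",
                object@pDisorder, object@pCoil))
    cat(sprintf("  P(coil & disorder) = %.3f, P(coil & !disorder) = %.3f\n",
                object@pCoilAndDisorder, object@pCoilNotDisorder))
    cat(sprintf("  Prop(coil & disorder) = %s (natural-log units)\n",
                ifelse(is.na(object@propensity), "undefined",
                       sprintf("%.3f", object@propensity))))
    invisible(NULL)
})
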