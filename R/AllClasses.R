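#' @import methods
#' @importClassesFrom Biostrings AAStringSet
#' @importFrom stats quantile rbinom rlnorm rnorm runif sd setNames
#' @importFrom utils head read.table write.table
NULL

## Accepted amino-acid alphabet: the 20 standard residues plus 'X' for
## unknown. Sequences containing anything else are rejected at import.
.AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

.TRACK_KINDS <- c("disorder", "coil", "ss", "modeled")
.SS_CLASSES <- c("H", "E", "C")

#' ProteinSet: a set of protein sequences with gene and cohort metadata
#'
#' Wraps an [Biostrings::AAStringSet] together with per-protein gene
#' identifiers, a cohort label (`"study"` or `"control"`) and the isoform
#' rank within each gene (rank 1 = longest isoform, ties broken by
#' lexicographically smallest protein id).
#'
#' @slot sequences An `AAStringSet`; names are the protein ids.
#' @slot geneId Character vector, one gene id per protein.
#' @slot setLabel Character vector, `"study"` or `"control"` per protein.
#' @slot isoformRank Integer vector, rank by decreasing length within gene.
#'
#' @seealso [readProteinSet()], [selectLongestIsoform()]
#' @exportClass ProteinSet
setClass("ProteinSet",
         representation(sequences = "AAStringSet",
                        geneId = "character",
                        setLabel = "character",
                        isoformRank = "integer"))

setValidity("ProteinSet", function(object) {
    n <- length(object@sequences)
    msg <- character(0)
    ids <- names(object@sequences)
    if (is.null(ids) || any(!nzchar(ids)))
        msg <- c(msg, "all sequences must be named with protein ids")
    if (anyDuplicated(ids))
        msg <- c(msg, sprintf("duplicate protein id(s): %s",
                              paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (length(object@geneId) != n || length(object@setLabel) != n ||
        length(object@isoformRank) != n)
        msg <- c(msg, "metadata slots must have one entry per sequence")
    if (n > 0 && any(Biostrings::width(object@sequences) < 1L))
        msg <- c(msg, "all sequences must have length >= 1")
    if (!all(object@setLabel %in% c("study", "control")))
        msg <- c(msg, "setLabel must be 'study' or 'control'")
    if (length(msg)) msg else TRUE
})

#' AnnotationTrack: a per-residue annotation aligned to one protein
#'
#' Values are logical for `disorder`, `coil` and `modeled` tracks and one of
#' `H`/`E`/`C` for `ss` (secondary structure) tracks. The `source` field
#' records provenance (`"imported"` for external predictor output,
#' `"builtin"` for the package's own stand-in predictors or the synthetic
#' generator) and is carried into every report so that builtin and imported
#' tracks are never silently mixed.
#'
#' @slot proteinId Character scalar.
#' @slot kind One of `"disorder"`, `"coil"`, `"ss"`, `"modeled"`.
#' @slot values Logical vector, or character in `H`/`E`/`C` for `ss`.
#' @slot source `"imported"` or `"builtin"`.
#' @slot score Optional per-residue numeric score (length 0 or same as values).
#'
#' @seealso [importTrack()], [coilScoreTrack()], [disorderIndexTrack()]
#' @exportClass AnnotationTrack
setClass("AnnotationTrack",
         representation(proteinId = "character",
                        kind = "character",
                        values = "ANY",
                        source = "character",
                        score = "numeric"))

setValidity("AnnotationTrack", function(object) {
    msg <- character(0)
    if (length(object@proteinId) != 1L)
        msg <- c(msg, "proteinId must be a single string")
    if (length(object@kind) != 1L || !object@kind %in% .TRACK_KINDS)
        msg <- c(msg, sprintf("kind must be one of: %s",
                              paste(.TRACK_KINDS, collapse = ", ")))
    v <- object@values
    if (length(v) < 1L)
        msg <- c(msg, "values must have length >= 1")
    if (anyNA(v))
        msg <- c(msg, "values must not contain NA")
    if (identical(object@kind, "ss")) {
        if (!is.character(v) || !all(v %in% .SS_CLASSES))
            msg <- c(msg, "ss values must all be 'H', 'E' or 'C'")
    } else if (object@kind %in% c("disorder", "coil", "modeled")) {
        if (!is.logical(v))
            msg <- c(msg, sprintf("%s values must be logical", object@kind))
    }
    if (length(object@source) != 1L ||
        !object@source %in% c("imported", "builtin"))
        msg <- c(msg, "source must be 'imported' or 'builtin'")
    if (length(object@score) && length(object@score) != length(v))
        msg <- c(msg, "score must be empty or one value per residue")
    if (length(msg)) msg else TRUE
})

#' EdgeList: an undirected simple protein-interaction graph
#'
#' Stores deduplicated, self-loop-free undirected edges as a two-column
#' data.frame with each pair in canonical (sorted) order, plus the node set.
#'
#' @slot edges data.frame with columns `from`, `to` (character).
#' @slot nodes Character vector of node ids (a superset of ids in `edges`).
#'
#' @seealso [importEdgeList()], [graphMetrics()]
#' @exportClass EdgeList
setClass("EdgeList",
         representation(edges = "data.frame", nodes = "character"))

setValidity("EdgeList", function(object) {
    msg <- character(0)
    e <- object@edges
    if (!all(c("from", "to") %in% names(e)))
        msg <- c(msg, "edges must have columns 'from' and 'to'")
    else {
        if (any(e$from == e$to))
            msg <- c(msg, "self-loops are not allowed")
        if (any(e$from > e$to))
            msg <- c(msg, "edges must be stored with from <= to")
        if (anyDuplicated(paste(e$from, e$to, sep = "\r")))
            msg <- c(msg, "duplicate edges are not allowed")
        if (!all(c(e$from, e$to) %in% object@nodes))
            msg <- c(msg, "all edge endpoints must appear in the node set")
    }
    if (anyDuplicated(object@nodes))
        msg <- c(msg, "duplicate node ids")
    if (length(msg)) msg else TRUE
})

#' JointStats: pooled joint-annotation residue statistics for a protein set
#'
#' Residue-weighted counts over the joint disorder x coil partition (and,
#' when a secondary-structure track is present, the disorder x ss partition),
#' the derived probabilities, and the log-ratio propensity
#' `ln P(coil & disorder) - ln P(coil) - ln P(disorder)` measuring how much
#' more often a residue is predicted coiled-coil and disordered at the same
#' time than expected under independence.
#'
#' @slot nResidues Integer, total pooled residues.
#' @slot counts Named integer vector over the four disorder x coil cells.
#' @slot ssCounts Named integer vector over disorder x `{H,E,C}` (may be
#'   empty when no ss tracks were supplied).
#' @slot pDisorder,pCoil,pCoilAndDisorder,pCoilNotDisorder Numeric fractions.
#' @slot propensity Numeric, natural-log units (`NA` if undefined).
#' @slot source Track provenance: `"imported"`, `"builtin"` or `"mixed"`.
#'
#' @seealso [jointResidueCounts()], [propensity()]
#' @exportClass JointStats
setClass("JointStats",
         representation(nResidues = "integer",
                        counts = "integer",
                        ssCounts = "integer",
                        pDisorder = "numeric",
                        pCoil = "numeric",
                        pCoilAndDisorder = "numeric",
                        pCoilNotDisorder = "numeric",
                        propensity = "numeric",
                        source = "character"))

setValidity("JointStats", function(object) {
    msg <- character(0)
    if (length(object@counts) != 4L ||
        !setequal(names(object@counts),
                  c("d_and_c", "d_not_c", "c_not_d", "neither")))
        msg <- c(msg, "counts must cover the four disorder x coil cells")
    else if (sum(object@counts) != object@nResidues)
        msg <- c(msg, "disorder x coil counts must sum to nResidues")
    if (length(object@ssCounts) &&
        sum(object@ssCounts) != object@nResidues)
        msg <- c(msg, "disorder x ss counts must sum to nResidues")
    ps <- c(object@pDisorder, object@pCoil,
            object@pCoilAndDisorder, object@pCoilNotDisorder)
    if (any(ps < 0 | ps > 1))
        msg <- c(msg, "probabilities must lie in [0, 1]")
    if (abs(object@pCoil -
            (object@pCoilAndDisorder + object@pCoilNotDisorder)) > 1e-12)
        msg <- c(msg, "pCoil must equal pCoilAndDisorder + pCoilNotDisorder")
    if (length(msg)) msg else TRUE
})
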