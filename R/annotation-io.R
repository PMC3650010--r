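## annotation_io: sequence, track, table and edge-list input/output.
## Coordinates are 1-based inclusive throughout; every file written by the
## package states this in a '#' header line. All I/O is UTF-8 and '#'
## comment lines are ignored on input.

## isoform rank within each gene: 1 = longest; ties broken by
## lexicographically smallest protein id (radix order, locale-independent).
.isoformRank <- function(ids, geneId, lengths) {
    rank <- integer(length(ids))
    for (g in unique(geneId)) {
        i <- which(geneId == g)
        o <- order(-lengths[i], ids[i], method = "radix")
        rank[i[o]] <- seq_along(i)
    }
    rank
}

#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a [ProteinSet]. The protein id is the first
#' whitespace-delimited token of each header; the gene id defaults to the
#' protein id but can be taken from another whitespace-delimited header
#' field via `geneIdField`. Sequences are restricted to the 20 standard
#' amino acids plus `X`; any other character is an error that reports the
#' offending position.
#'
#' @param path Path to a FASTA file.
#' @param setLabel Cohort membership of every record: `"study"` (e.g. the
#'   centrosomal set) or `"control"`.
#' @param geneIdField Optional integer: which whitespace-delimited header
#'   token holds the gene id (1 = the protein id itself, the default).
#' @return A [ProteinSet] with isoform ranks computed per gene.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">P1 G1", "MKLV", ">P2 G1", "MKLVAE"), fa)
#' ps <- readProteinSet(fa, "study", geneIdField = 2)
#' seqLengths(ps)
#' @export
readProteinSet <- function(path, setLabel = c("study", "control"),
                           geneIdField = NULL) {
    setLabel <- match.arg(setLabel)
    if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
    seqs <- Biostrings::readAAStringSet(path)
    if (length(seqs) == 0L) .stopf("no sequences found in FASTA file: %s", path)
    toks <- strsplit(names(seqs), "\\s+")
    ids <- vapply(toks, `[`, "", 1L)
    if (anyDuplicated(ids))
        .stopf("duplicate sequence id(s): %s",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
    geneId <- if (is.null(geneIdField)) {
        ids
    } else {
        vapply(toks, function(t)
            if (length(t) >= geneIdField) t[[geneIdField]] else t[[1L]], "")
    }
    ## alphabet check with position-level reporting
    chars <- strsplit(as.character(seqs), "")
    for (i in seq_along(chars)) {
        bad <- which(!(chars[[i]] %in% .AA_ALPHABET))
        if (length(bad))
            .stopf("sequence '%s' contains non-standard character '%s' at position %d",
                   ids[i], chars[[i]][bad[1L]], bad[1L])
    }
    names(seqs) <- ids
    w <- Biostrings::width(seqs)
    new("ProteinSet", sequences = seqs, geneId = geneId,
        setLabel = rep(setLabel, length(seqs)),
        isoformRank = .isoformRank(ids, geneId, w))
}

#' Keep the longest isoform of each gene
#'
#' Retains exactly one protein per gene: the longest isoform, with length
#' ties broken by the lexicographically smallest protein id. Idempotent.
#'
#' @param proteins A [ProteinSet].
#' @return A [ProteinSet] with one record per gene (all isoform ranks 1).
#' @export
selectLongestIsoform <- function(proteins) {
    stopifnot(is(proteins, "ProteinSet"))
    rank <- .isoformRank(proteinIds(proteins), proteins@geneId,
                         seqLengths(proteins))
    proteins[rank == 1L]
}

#' Construct a per-residue annotation track
#'
#' @param proteinId Protein id the track is aligned to.
#' @param kind `"disorder"`, `"coil"`, `"ss"` or `"modeled"`.
#' @param values Logical vector (or `H`/`E`/`C` character vector for `ss`).
#' @param source Track provenance: `"imported"` or `"builtin"`.
#' @param score Optional per-residue numeric score.
#' @return An [AnnotationTrack].
#' @export
annotationTrack <- function(proteinId, kind, values, source = "imported",
                            score = numeric(0)) {
    new("AnnotationTrack", proteinId = proteinId, kind = kind,
        values = values, source = source, score = as.numeric(score))
}

## DSSP 8-class to 3-class collapse: H,G,I -> H; E,B -> E; all else -> C.
.collapseDssp <- function(x) {
    out <- rep("C", length(x))
    out[x %in% c("H", "G", "I")] <- "H"
    out[x %in% c("E", "B")] <- "E"
    out
}

.checkTrackAlignment <- function(resCol, protein, id, path) {
    seqc <- .seqChars(protein, id)
    n <- length(seqc)
    if (length(resCol) != n)
        .stopf("track file '%s' has %d residue rows but protein '%s' has %d residues",
               path, length(resCol), id, n)
    mism <- which(toupper(resCol) != seqc & toupper(resCol) != "X" & seqc != "X")
    if (length(mism))
        .stopf("residue mismatch at position %d: track file '%s' has '%s', protein '%s' has '%s'",
               mism[1L], path, resCol[mism[1L]], id, seqc[mism[1L]])
    invisible(n)
}

#' Import a per-residue predictor output file as an annotation track
#'
#' Supported dialects (all whitespace/tab-delimited, `#` comments ignored,
#' one row per residue in sequence order):
#' \describe{
#'   \item{`disopred`}{columns `index residue marker confidence`; a residue
#'     is disordered when `marker == "*"` (default) or, with
#'     `useConfidence = TRUE`, when `confidence >= disorderCutoff`.}
#'   \item{`psipred_ss2`}{columns `index residue state pC pH pE`; the state
#'     column is taken as-is unless `recomputeFromProbs = TRUE`, in which
#'     case the maximum-probability class is used.}
#'   \item{`coils`}{columns `index residue score probability`; a residue is
#'     coil when `probability >= coilCutoff`.}
#'   \item{`dssp`}{columns `index residue ss8`; the 8 DSSP classes are
#'     collapsed to 3 (`H,G,I -> H`; `E,B -> E`; else `C`).}
#'   \item{`generic_tsv`}{columns `index residue state [score]`; `state` is
#'     `0`/`1` for boolean kinds or `H`/`E`/`C` for `ss`; `kind` must be
#'     given.}
#' }
#' The file must align 1:1 with the protein: a row-count or residue-letter
#' mismatch is an error reporting the position.
#'
#' @param path Path to the predictor output file.
#' @param dialect One of `"disopred"`, `"psipred_ss2"`, `"coils"`, `"dssp"`,
#'   `"generic_tsv"`.
#' @param protein A single-protein [ProteinSet] (or a larger set together
#'   with `proteinId`).
#' @param proteinId Which protein of `protein` the file belongs to
#'   (defaults to the only protein present).
#' @param kind Track kind; required for `generic_tsv`, implied otherwise.
#' @param disorderCutoff Confidence threshold for `disopred` when
#'   `useConfidence = TRUE` (default 0.5; the decision threshold of the
#'   original predictor is not published, so it is configurable).
#' @param useConfidence Call disorder from the confidence column rather
#'   than the `*` marker (default `FALSE`).
#' @param coilCutoff Probability threshold for the `coils` dialect
#'   (default 0.5, configurable for the same reason).
#' @param recomputeFromProbs For `psipred_ss2`: recompute the state from the
#'   probability columns (default `FALSE`).
#' @return An [AnnotationTrack] with `source = "imported"`.
#' @export
importTrack <- function(path,
                        dialect = c("disopred", "psipred_ss2", "coils",
                                    "dssp", "generic_tsv"),
                        protein, proteinId = NULL, kind = NULL,
                        disorderCutoff = 0.5, useConfidence = FALSE,
                        coilCutoff = 0.5, recomputeFromProbs = FALSE) {
    dialect <- match.arg(dialect)
    stopifnot(is(protein, "ProteinSet"))
    if (is.null(proteinId)) {
        if (length(protein) != 1L)
            .stopf("proteinId must be given when 'protein' holds %d proteins",
                   length(protein))
        proteinId <- proteinIds(protein)
    }
    tl <- .readTokenLines(path)
    toks <- tl$tokens
    ncols <- c(disopred = 4L, psipred_ss2 = 6L, coils = 4L,
               dssp = 3L, generic_tsv = 3L)[[dialect]]
    short <- which(lengths(toks) < ncols)
    if (length(short))
        .stopf("malformed row at line %d of '%s': expected >= %d columns",
               tl$lineno[short[1L]], path, ncols)
    col <- function(j) vapply(toks, `[[`, "", j)
    resCol <- col(2L)
    .checkTrackAlignment(resCol, protein, proteinId, path)
    values <- switch(dialect,
        disopred = {
            kind <- "disorder"
            if (useConfidence) as.numeric(col(4L)) >= disorderCutoff
            else col(3L) == "*"
        },
        psipred_ss2 = {
            kind <- "ss"
            if (recomputeFromProbs) {
                p <- cbind(C = as.numeric(col(4L)), H = as.numeric(col(5L)),
                           E = as.numeric(col(6L)))
                colnames(p)[max.col(p, ties.method = "first")]
            } else {
                st <- col(3L)
                if (!all(st %in% .SS_CLASSES))
                    .stopf("unexpected secondary-structure state in '%s'", path)
                st
            }
        },
        coils = {
            kind <- "coil"
            as.numeric(col(4L)) >= coilCutoff
        },
        dssp = {
            kind <- "ss"
            .collapseDssp(col(3L))
        },
        generic_tsv = {
            if (is.null(kind))
                .stopf("kind must be given for the generic_tsv dialect")
            st <- col(3L)
            if (kind == "ss") {
                if (!all(st %in% .SS_CLASSES))
                    .stopf("unexpected secondary-structure state in '%s'", path)
                st
            } else {
                if (!all(st %in% c("0", "1")))
                    .stopf("generic_tsv state column must be 0/1 in '%s'", path)
                st == "1"
            }
        })
    score <- switch(dialect,
        disopred = as.numeric(col(4L)),
        coils = as.numeric(col(4L)),
        generic_tsv = if (all(lengths(toks) >= 4L)) as.numeric(col(4L))
                      else numeric(0),
        numeric(0))
    annotationTrack(proteinId, kind, values, source = "imported",
                    score = score)
}

#' Write an annotation track as a generic TSV file
#'
#' Writes the `generic_tsv` dialect (`index residue state [score]`), with a
#' header comment stating the 1-based inclusive coordinate convention and
#' the track provenance. Re-importing the file with
#' [importTrack()] reproduces the track exactly.
#'
#' @param track An [AnnotationTrack].
#' @param protein The matching [ProteinSet] (supplies the residue column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTrack <- function(track, protein, path) {
    stopifnot(is(track, "AnnotationTrack"), is(protein, "ProteinSet"))
    id <- proteinIds(track)
    seqc <- .seqChars(protein, id)
    if (length(seqc) != length(track))
        .stopf("track length %d does not match protein '%s' length %d",
               length(track), id, length(seqc))
    v <- trackValues(track)
    state <- if (is.logical(v)) as.integer(v) else v
    df <- data.frame(index = seq_along(v), residue = seqc, state = state)
    sc <- trackScores(track)
    if (!is.null(sc)) df$score <- format(sc, digits = 15)
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(c("# coordinates: 1-based inclusive",
                 sprintf("# protein_id: %s", id),
                 sprintf("# kind: %s", trackKind(track)),
                 sprintf("# source: %s", trackSource(track))), con)
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Import a SMART-style domain table
#'
#' Reads a tab-separated table with header columns `protein_id`,
#' `domain_name`, `start`, `end`, `significant` into a data.frame of
#' 1-based inclusive intervals of type `smart_domain`. Intervals extending
#' beyond the protein length are clipped with a warning (clipping is
#' counted, never silent); `start > end` or an unknown protein id is an
#' error.
#'
#' @param path Path to the TSV file.
#' @param proteins A [ProteinSet] used to validate ids and clip intervals.
#' @return data.frame with columns `protein_id`, `start`, `end`, `type`,
#'   `domain_name`, `significant`.
#' @export
importDomainTable <- function(path, proteins) {
    stopifnot(is(proteins, "ProteinSet"))
    if (!file.exists(path)) .stopf("domain table not found: %s", path)
    df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                     stringsAsFactors = FALSE, quote = "",
                     fileEncoding = "UTF-8")
    need <- c("protein_id", "domain_name", "start", "end", "significant")
    if (!all(need %in% names(df)))
        .stopf("domain table '%s' must have columns: %s", path,
               paste(need, collapse = ", "))
    if (nrow(df) == 0L)
        return(data.frame(protein_id = character(0), start = integer(0),
                          end = integer(0), type = character(0),
                          domain_name = character(0),
                          significant = logical(0)))
    unknown <- setdiff(df$protein_id, proteinIds(proteins))
    if (length(unknown))
        .stopf("domain table '%s' refers to unknown protein id(s): %s",
               path, paste(unknown, collapse = ", "))
    df$start <- as.integer(df$start)
    df$end <- as.integer(df$end)
    if (any(df$start > df$end))
        .stopf("domain table '%s': start > end at row %d", path,
               which(df$start > df$end)[1L])
    if (any(df$start < 1L))
        .stopf("domain table '%s': start < 1 at row %d", path,
               which(df$start < 1L)[1L])
    lens <- seqLengths(proteins)[df$protein_id]
    over <- df$end > lens
    if (any(over)) {
        .warnf("clipped %d domain interval(s) extending beyond the sequence length",
               sum(over))
        df$end[over] <- lens[over]
    }
    data.frame(protein_id = df$protein_id, start = df$start, end = df$end,
               type = "smart_domain", domain_name = df$domain_name,
               significant = as.logical(df$significant))
}

#' Import a protein-protein interaction edge list
#'
#' Reads a two-column tab/whitespace-separated edge list into an
#' undirected, simple [EdgeList]: duplicate edges (in either orientation)
#' are collapsed and self-loops are dropped, with counts reported via
#' `message()` so that nothing is removed silently.
#'
#' @param path Path to the edge-list file.
#' @return An [EdgeList].
#' @export
importEdgeList <- function(path) {
    tl <- .readTokenLines(path)
    toks <- tl$tokens
    if (length(toks) == 0L)
        return(new("EdgeList",
                   edges = data.frame(from = character(0), to = character(0)),
                   nodes = character(0)))
    bad <- which(lengths(toks) < 2L)
    if (length(bad))
        .stopf("malformed edge row at line %d of '%s': expected 2 columns",
               tl$lineno[bad[1L]], path)
    a <- vapply(toks, `[[`, "", 1L)
    b <- vapply(toks, `[[`, "", 2L)
    nodes <- sort(unique(c(a, b)), method = "radix")
    loop <- a == b
    if (any(loop))
        message(sprintf("importEdgeList: dropped %d self-loop(s)", sum(loop)))
    a2 <- pmin(a[!loop], b[!loop])
    b2 <- pmax(a[!loop], b[!loop])
    key <- paste(a2, b2, sep = "\r")
    dup <- duplicated(key)
    if (any(dup))
        message(sprintf("importEdgeList: collapsed %d duplicate edge(s)",
                        sum(dup)))
    o <- order(a2[!dup], b2[!dup], method = "radix")
    new("EdgeList",
        edges = data.frame(from = a2[!dup][o], to = b2[!dup][o]),
        nodes = nodes)
}
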