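## Internal helpers shared across modules.

## Read a whitespace/tab-delimited predictor or table file, dropping '#'
## comment lines and blank lines. Returns a list of character vectors
## (tokens per line) plus the original line numbers for error reporting.
.readTokenLines <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
    keep <- !grepl("^\\s*(#|$)", raw)
    lines <- raw[keep]
    list(tokens = strsplit(trimws(lines), "[ \t]+"),
         lineno = which(keep))
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

.assertFraction <- function(x, name, allowNA = FALSE) {
    ok <- is.numeric(x) & (allowNA | !is.na(x))
    if (!all(ok) || any(x < 0 | x > 1, na.rm = TRUE))
        .stopf("%s must lie in [0, 1]", name)
    invisible(x)
}

## round-half-up for non-negative values (base round() is round-half-even)
.roundHalfUp <- function(x) floor(x + 0.5)

## Split sequence characters of one protein.
.seqChars <- function(proteins, id) {
    strsplit(as.character(sequences(proteins)[[id]]), "")[[1]]
}

## Fetch a residue-index logical/character vector for id, checking presence.
.getTrack <- function(tracks, id, kind, required = TRUE) {
    tr <- tracks[[id]][[kind]]
    if (is.null(tr)) {
        if (required)
            .stopf("protein '%s' is missing its required '%s' track", id, kind)
        return(NULL)
    }
    tr
}

## Provenance of a collection of tracks: imported / builtin / mixed.
.poolSource <- function(trackObjs) {
    src <- unique(vapply(trackObjs, trackSource, ""))
    if (length(src) == 1L) src else "mixed"
}

## Convert logical run-length encoding to [start, end] rows for TRUE runs
## with length strictly greater than minRun.
.trueRuns <- function(values, minRun = 0L) {
    r <- rle(as.logical(values))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths > minRun
    data.frame(start = starts[keep], end = ends[keep])
}

## Deterministic sub-seed derivation: all module-level randomness flows from
## one top-level seed through fixed small offsets (documented in the methods
## vignette). Kept well below 2^31.
.subSeed <- function(seed, offset) (as.integer(seed) %% 1000000000L) + offset
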