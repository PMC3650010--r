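## Fixtures are built in code at test time; nothing is read from disk
## except files the helpers themselves write to tempdir().

## Write named sequences to a temporary FASTA and read them back as a
## ProteinSet (exercising the importer on the way).
proteinsFromStrings <- function(seqs, setLabel = "study",
                                geneIdField = NULL, headers = NULL) {
    fa <- tempfile(fileext = ".fasta")
    hdr <- if (is.null(headers)) names(seqs) else headers
    writeLines(as.vector(rbind(paste0(">", hdr), unname(seqs))), fa)
    readProteinSet(fa, setLabel, geneIdField = geneIdField)
}

## A random amino-acid sequence (standard alphabet, no X)
randomSequence <- function(n) {
    paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                   "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                 n, replace = TRUE), collapse = "")
}

## A random boolean track with segmental (run-length) structure
randomSegmentalTrack <- function(id, kind, n, pOn = 0.4, meanRun = 15) {
    v <- logical(0)
    state <- runif(1) < pOn
    while (length(v) < n) {
        run <- 1L + stats::rgeom(1L, 1 / meanRun)
        v <- c(v, rep(state, run))
        state <- !state
    }
    annotationTrack(id, kind, v[seq_len(n)], source = "builtin")
}

## A small bundle of generated tracks for nProteins proteins
randomBundle <- function(nProteins, lenRange = c(60L, 300L), withSS = FALSE) {
    ids <- sprintf("RB%03d", seq_len(nProteins))
    out <- lapply(ids, function(id) {
        n <- sample(lenRange[1]:lenRange[2], 1L)
        b <- list(disorder = randomSegmentalTrack(id, "disorder", n),
                  coil = randomSegmentalTrack(id, "coil", n, pOn = 0.2))
        if (withSS)
            b$ss <- annotationTrack(id, "ss",
                                    sample(c("H", "E", "C"), n, TRUE),
                                    source = "builtin")
        b
    })
    names(out) <- ids
    out
}
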