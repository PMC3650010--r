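test_that("FASTA import preserves entries and parses headers", {
    set.seed(101)
    ps <- proteinsFromStrings(
        c(P1 = randomSequence(100), P2 = randomSequence(250),
          P3 = randomSequence(80)))
    expect_s4_class(ps, "ProteinSet")
    expect_equal(unname(seqLengths(ps)), c(100L, 250L, 80L))
    expect_equal(proteinIds(ps), c("P1", "P2", "P3"))
    ## gene id from a configurable header field
    ps2 <- proteinsFromStrings(c(A = "MKLV", B = "MKLVAE"),
                               headers = c("A gene1", "B gene1"),
                               geneIdField = 2)
    expect_equal(unname(geneIds(ps2)), c("gene1", "gene1"))
})

test_that("FASTA import rejects bad input with informative errors", {
    fa <- tempfile(fileext = ".fasta")
    writeLines(c(">P1", paste0(strrep("A", 11), "B", strrep("A", 5))), fa)
    expect_error(readProteinSet(fa, "study"), "position 12")
    expect_error(readProteinSet(fa, "study"), "'B'")
    writeLines(c(">P1", "MKL", ">P1", "MKV"), fa)
    expect_error(readProteinSet(fa, "study"), "P1")
    writeLines(character(0), fa)
    expect_error(readProteinSet(fa, "study"), "no sequences")
    expect_error(readProteinSet(tempfile(), "study"), "not found")
})

test_that("longest-isoform selection keeps the longest, ties by smallest id", {
    ps <- proteinsFromStrings(
        c(I1 = randomSequence(300), I2 = randomSequence(500),
          S1 = randomSequence(120),
          B1 = randomSequence(400), A1 = randomSequence(400)),
        headers = c("I1 G1", "I2 G1", "S1 G2", "B1 G3", "A1 G3"),
        geneIdField = 2)
    sel <- selectLongestIsoform(ps)
    expect_setequal(proteinIds(sel), c("I2", "S1", "A1"))
    expect_true(all(isoformRanks(sel) == 1L))
    ## idempotent
    sel2 <- selectLongestIsoform(sel)
    expect_identical(proteinIds(sel2), proteinIds(sel))
})

test_that("track import handles each dialect and validates alignment", {
    ps <- proteinsFromStrings(c(P1 = strrep("A", 50)))
    ## psipred ss2: max-probability column is H everywhere, state says H
    f <- tempfile()
    writeLines(sprintf("%d A H 0.1 0.8 0.1", 1:50), f)
    tr <- importTrack(f, "psipred_ss2", ps)
    expect_equal(trackKind(tr), "ss")
    expect_true(all(trackValues(tr) == "H"))
    expect_equal(trackSource(tr), "imported")
    ## disopred: all rows starred -> all-true disorder
    writeLines(sprintf("%d A * 0.9", 1:50), f)
    trd <- importTrack(f, "disopred", ps)
    expect_true(all(trackValues(trd)))
    ## confidence-threshold alternative
    writeLines(sprintf("%d A . %.2f", 1:50, seq(0, 0.98, length.out = 50)), f)
    trc <- importTrack(f, "disopred", ps, useConfidence = TRUE,
                       disorderCutoff = 0.5)
    expect_equal(sum(trackValues(trc)),
                 sum(seq(0, 0.98, length.out = 50) >= 0.5))
    ## coils dialect thresholds on the probability column
    writeLines(sprintf("%d A 1.5 %.2f", 1:50,
                       rep(c(0.9, 0.1), each = 25)), f)
    trco <- importTrack(f, "coils", ps)
    expect_equal(sum(trackValues(trco)), 25L)
    ## dssp 8-class collapse
    ps8 <- proteinsFromStrings(c(P8 = strrep("A", 8)))
    writeLines(sprintf("%d A %s", 1:8,
                       c("H", "G", "I", "E", "B", "T", "S", "-")), f)
    trss <- importTrack(f, "dssp", ps8)
    expect_equal(trackValues(trss),
                 c("H", "H", "H", "E", "E", "C", "C", "C"))
    ## length mismatch reports both counts
    ps31 <- proteinsFromStrings(c(P31 = strrep("A", 31)))
    writeLines(sprintf("%d A 1", 1:30), f)
    expect_error(importTrack(f, "generic_tsv", ps31, kind = "disorder"),
                 "30.*31")
    ## residue mismatch reports the position
    writeLines(sprintf("%d %s 1", 1:31, c(rep("A", 10), "W", rep("A", 20))), f)
    expect_error(importTrack(f, "generic_tsv", ps31, kind = "disorder"),
                 "position 11")
})

test_that("generic_tsv round-trip reproduces a track exactly", {
    set.seed(77)
    ps <- proteinsFromStrings(c(RT1 = randomSequence(120)))
    for (kind in c("disorder", "ss")) {
        v <- if (kind == "ss") sample(c("H", "E", "C"), 120, TRUE)
             else runif(120) < 0.4
        tr <- annotationTrack("RT1", kind, v, source = "imported",
                              score = if (kind == "ss") numeric(0)
                                      else round(runif(120), 6))
        f <- tempfile()
        writeTrack(tr, ps, f)
        back <- importTrack(f, "generic_tsv", ps, kind = kind)
        expect_identical(trackValues(back), trackValues(tr))
        if (kind != "ss")
            expect_equal(trackScores(back), trackScores(tr))
    }
})

test_that("domain-table import validates, clips and counts", {
    ps <- proteinsFromStrings(c(P1 = randomSequence(500)))
    f <- tempfile()
    hdr <- "protein_id\tdomain_name\tstart\tend\tsignificant"
    writeLines(c(hdr, "P1\tWD40\t10\t60\tTRUE"), f)
    dom <- importDomainTable(f, ps)
    expect_equal(dom$start, 10L)
    expect_equal(dom$end, 60L)
    expect_equal(dom$type, "smart_domain")
    expect_equal(dom$domain_name, "WD40")
    expect_true(dom$significant)
    ## clipping past the sequence end warns and clips
    writeLines(c(hdr, "P1\tIQ\t490\t520\tTRUE"), f)
    expect_warning(dom2 <- importDomainTable(f, ps), "clipped")
    expect_equal(dom2$end, 500L)
    ## empty table -> empty collection
    writeLines(hdr, f)
    expect_equal(nrow(importDomainTable(f, ps)), 0L)
    ## start > end and unknown ids are errors
    writeLines(c(hdr, "P1\tX\t60\t10\tTRUE"), f)
    expect_error(importDomainTable(f, ps), "start > end")
    writeLines(c(hdr, "PX\tX\t1\t5\tTRUE"), f)
    expect_error(importDomainTable(f, ps), "PX")
})

test_that("edge-list import deduplicates, drops self-loops and reports counts", {
    f <- tempfile()
    writeLines(c("A\tB", "B\tA", "C\tC"), f)
    msgs <- capture_messages(el <- importEdgeList(f))
    expect_equal(length(el), 1L)
    expect_equal(edges(el), data.frame(from = "A", to = "B"))
    expect_true(any(grepl("1 self-loop", msgs)))
    expect_true(any(grepl("1 duplicate", msgs)))
    ## empty file -> empty edge list
    writeLines(character(0), f)
    expect_equal(length(importEdgeList(f)), 0L)
    ## malformed row cites the line number
    writeLines(c("A\tB", "Conly"), f)
    expect_error(importEdgeList(f), "line 2")
})
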