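test_that("spec validation rejects inconsistent targets before sampling", {
    expect_error(syntheticSpec(pCoilAndDisorder = 0.6, pDisorder = 0.5,
                               pDisorderHelical = 0.6, seed = 1),
                 "P\\(disorder\\)")
    expect_error(syntheticSpec(pDisorderHelical = 0.05, seed = 1),
                 "helical")
    expect_error(syntheticSpec(pDisorder = 0.98, pCoilNotDisorder = 0.05,
                               pDisorderHelical = 0.3, seed = 1),
                 "exceeds 1")
    expect_error(syntheticSpec(richFraction = 0.6, seed = 1),
                 "dual-rich")
    expect_error(syntheticSpec(), "seed")
})

test_that("a pure disordered-loop spec yields all-disorder, zero-coil tracks", {
    sp <- syntheticSpec(nProteins = 5, targetMeanLength = 200,
                        pDisorder = 1, pCoilAndDisorder = 0,
                        pCoilNotDisorder = 0, pDisorderHelical = 0,
                        richFraction = 0, seed = 11)
    sim <- sampleProteinSet(sp)
    for (id in names(sim$tracks)) {
        expect_true(all(trackValues(sim$tracks[[id]]$disorder)))
        expect_false(any(trackValues(sim$tracks[[id]]$coil)))
        expect_true(all(trackValues(sim$tracks[[id]]$ss) == "C"))
    }
})

test_that("the ground-truth ledger equals fractions recomputed from tracks", {
    sp <- syntheticSpec(nProteins = 40, targetMeanLength = 400, seed = 23)
    sim <- sampleProteinSet(sp)
    js <- jointResidueCounts(sim$tracks)
    p <- jointProbabilities(js)
    expect_identical(unname(p["p_disorder"]),
                     unname(sim$ledger$realized["p_disorder"]))
    expect_identical(unname(p["p_coil_and_disorder"]),
                     unname(sim$ledger$realized["p_coil_and_disorder"]))
    expect_identical(unname(p["p_coil_not_disorder"]),
                     unname(sim$ledger$realized["p_coil_not_disorder"]))
    dH <- jointCounts(js)$disorder_ss[["d_H"]] / nResidues(js)
    expect_identical(dH,
                     unname(sim$ledger$realized["p_disorder_and_helical"]))
    ## segment layout tiles each protein exactly
    for (id in head(names(sim$ledger$segments), 5)) {
        seg <- sim$ledger$segments[[id]]
        expect_equal(seg$start[1], 1L)
        expect_equal(seg$end[nrow(seg)],
                     unname(seqLengths(sim$proteins)[id]))
        if (nrow(seg) > 1)
            expect_true(all(seg$start[-1] == seg$end[-nrow(seg)] + 1L))
    }
})

test_that("generation is bit-identical under the same seed", {
    sp <- syntheticSpec(nProteins = 15, targetMeanLength = 300, seed = 77)
    a <- sampleProteinSet(sp)
    b <- sampleProteinSet(sp)
    expect_identical(as.character(sequences(a$proteins)),
                     as.character(sequences(b$proteins)))
    expect_identical(lapply(a$tracks, lapply, trackValues),
                     lapply(b$tracks, lapply, trackValues))
    ha <- sampleTemplateHits(sp, a)
    hb <- sampleTemplateHits(sp, b)
    expect_identical(ha$hits, hb$hits)
    expect_identical(edges(sampleNetwork(sp)), edges(sampleNetwork(sp)))
})

test_that("generated sequences are valid and lengths are heavy-tailed", {
    sp <- syntheticSpec(nProteins = 150, seed = 5)
    sim <- sampleProteinSet(sp)
    expect_true(validObject(sim$proteins))
    lens <- seqLengths(sim$proteins)
    ## mean near the 796-residue target, right tail present
    expect_lt(abs(mean(lens) - 796) / 796, 0.15)
    expect_gt(max(lens), 2 * stats::median(lens))
})

test_that("template-hit generation respects the filters and the mixture", {
    sp <- syntheticSpec(nProteins = 80, targetMeanLength = 500, seed = 13)
    sim <- sampleProteinSet(sp)
    th <- sampleTemplateHits(sp, sim)
    hits <- th$hits
    expect_gt(nrow(hits), 0)
    ## every generated hit survives the strict significance filters
    expect_identical(nrow(filterHits(hits)), nrow(hits))
    spans <- hits$q_end - hits$q_start + 1L
    expect_true(all(spans > 30L))
    ## bimodal identity: both modes populated, nothing in between
    expect_gt(sum(hits$identity < 0.30), 0)
    expect_gt(sum(hits$identity > 0.90), 0)
    expect_equal(sum(hits$identity > 0.35 & hits$identity < 0.65), 0L)
    ## zero coverage targets produce an empty table
    sp0 <- syntheticSpec(nProteins = 10, targetMeanLength = 300,
                         orderedCoverage = 0, disorderedCoverage = 0,
                         seed = 3)
    sim0 <- sampleProteinSet(sp0)
    th0 <- sampleTemplateHits(sp0, sim0)
    expect_equal(nrow(th0$hits), 0L)
})

test_that("network generation hits exact counts and degenerate cases", {
    sp <- syntheticSpec(nNodes = 167, nEdges = 354, seed = 8)
    el <- sampleNetwork(sp)
    expect_equal(length(nodes(el)), 167L)
    expect_equal(length(el), 354L)
    ## 3 nodes, 3 edges is necessarily a triangle
    sp3 <- syntheticSpec(nNodes = 3, nEdges = 3, seed = 8)
    el3 <- sampleNetwork(sp3)
    expect_equal(length(el3), 3L)
    expect_equal(sort(unique(c(edges(el3)$from, edges(el3)$to))),
                 nodes(el3))
    ## impossible edge counts are rejected
    expect_error(sampleNetwork(syntheticSpec(nNodes = 4, nEdges = 7,
                                             seed = 1)),
                 "cannot place")
    ## preferential-attachment model also honours exact counts
    spPa <- syntheticSpec(nNodes = 60, nEdges = 140,
                          networkModel = "pa", seed = 10)
    elPa <- sampleNetwork(spPa)
    expect_equal(length(elPa), 140L)
    expect_equal(length(nodes(elPa)), 60L)
})

test_that("a written simulation bundle is complete and readable", {
    dir <- file.path(tempdir(), "simbundle")
    unlink(dir, recursive = TRUE)
    sp <- syntheticSpec(nProteins = 8, targetMeanLength = 250, seed = 19)
    writeSimulation(sp, dir)
    expect_true(file.exists(file.path(dir, "proteins.fasta")))
    expect_true(file.exists(file.path(dir, "hits.tsv")))
    expect_true(file.exists(file.path(dir, "edges.tsv")))
    gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
    expect_equal(gt$seed, 19L)
    ps <- readProteinSet(file.path(dir, "proteins.fasta"), "study")
    expect_equal(length(ps), 8L)
    ## track files round-trip through the generic importer
    id <- proteinIds(ps)[1]
    tr <- importTrack(file.path(dir, "tracks",
                                sprintf("%s.disorder.tsv", id)),
                      "generic_tsv", ps, proteinId = id, kind = "disorder")
    expect_equal(length(tr), unname(seqLengths(ps)[id]))
})
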