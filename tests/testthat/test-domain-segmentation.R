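mkTracksFor <- function(id, n, coilRuns = NULL, disRuns = NULL) {
    cv <- logical(n); dv <- logical(n)
    if (!is.null(coilRuns))
        for (k in seq_len(nrow(coilRuns)))
            cv[coilRuns$start[k]:coilRuns$end[k]] <- TRUE
    if (!is.null(disRuns))
        for (k in seq_len(nrow(disRuns)))
            dv[disRuns$start[k]:disRuns$end[k]] <- TRUE
    list(coil = annotationTrack(id, "coil", cv),
         disorder = annotationTrack(id, "disorder", dv))
}

test_that("priority partition reproduces the hand-traced layout", {
    ps <- proteinsFromStrings(c(P1 = strrep("A", 500)))
    tr <- mkTracksFor("P1", 500, coilRuns = data.frame(start = 130, end = 200),
                      disRuns = data.frame(start = 70, end = 120))
    smart <- data.frame(protein_id = "P1", start = 10L, end = 60L,
                        type = "smart_domain", domain_name = "D",
                        significant = TRUE)
    part <- partitionSequence(ps, smart, tr$coil, tr$disorder)
    expect_equal(part$start, c(1L, 10L, 61L, 70L, 121L, 130L, 201L))
    expect_equal(part$end, c(9L, 60L, 69L, 120L, 129L, 200L, 500L))
    expect_equal(part$type,
                 c("residual", "smart_domain", "residual", "disorder_stretch",
                   "residual", "coil_stretch", "residual"))
})

test_that("stretches truncated by SMART are re-tested against the run rule", {
    ps <- proteinsFromStrings(c(P1 = strrep("A", 200)))
    smart <- data.frame(protein_id = "P1", start = 10L, end = 60L,
                        type = "smart_domain", domain_name = "D",
                        significant = TRUE)
    ## coil run 50..80 overlaps SMART; surviving piece 61..80 has exactly
    ## 20 residues, which is not > 20, so it reverts to residual
    tr <- mkTracksFor("P1", 200, coilRuns = data.frame(start = 50, end = 80))
    part <- partitionSequence(ps, smart, tr$coil, tr$disorder)
    expect_false("coil_stretch" %in% part$type)
    ## one residue more and the piece survives
    tr2 <- mkTracksFor("P1", 200, coilRuns = data.frame(start = 50, end = 81))
    part2 <- partitionSequence(ps, smart, tr2$coil, tr2$disorder)
    cs <- part2[part2$type == "coil_stretch", ]
    expect_equal(c(cs$start, cs$end), c(61L, 81L))
})

test_that("a sequence without annotations is a single residual interval", {
    ps <- proteinsFromStrings(c(P1 = strrep("A", 77)))
    tr <- mkTracksFor("P1", 77)
    part <- partitionSequence(ps, NULL, tr$coil, tr$disorder)
    expect_equal(nrow(part), 1L)
    expect_equal(part$type, "residual")
    expect_equal(c(part$start, part$end), c(1L, 77L))
})

test_that("partition covers every residue exactly once and matches the painting oracle", {
    set.seed(404)
    for (rep in 1:40) {
        n <- sample(80:400, 1)
        id <- "PP1"
        ps <- proteinsFromStrings(setNames(strrep("A", n), id))
        cv <- trackValues(randomSegmentalTrack(id, "coil", n, meanRun = 18))
        dv <- trackValues(randomSegmentalTrack(id, "disorder", n,
                                               meanRun = 25, pOn = 0.5))
        nSmart <- sample(0:2, 1)
        smart <- NULL
        if (nSmart > 0) {
            s <- sort(sample.int(n, 2 * nSmart))
            smart <- data.frame(protein_id = id,
                                start = s[seq(1, 2 * nSmart, 2)],
                                end = s[seq(2, 2 * nSmart, 2)],
                                type = "smart_domain", domain_name = "D",
                                significant = TRUE)
        }
        part <- suppressWarnings(partitionSequence(
            ps, smart,
            annotationTrack(id, "coil", cv),
            annotationTrack(id, "disorder", dv)))
        ## exact tiling of [1, n]
        expect_equal(part$start[1], 1L)
        expect_equal(part$end[nrow(part)], n)
        if (nrow(part) > 1)
            expect_true(all(part$start[-1] == part$end[-nrow(part)] + 1L))
        ## agreement with the independent painting oracle
        lab <- brutePartitionLabels(n, smart, cv, dv)
        labImpl <- rep(part$type, part$end - part$start + 1L)
        expect_equal(labImpl, lab)
    }
})

test_that("raising the run threshold only shrinks stretch coverage", {
    set.seed(21)
    n <- 300
    ps <- proteinsFromStrings(c(P1 = strrep("A", n)))
    cv <- trackValues(randomSegmentalTrack("P1", "coil", n, meanRun = 25))
    dv <- trackValues(randomSegmentalTrack("P1", "disorder", n, meanRun = 30))
    cover <- function(minRun) {
        part <- partitionSequence(ps, NULL,
                                  annotationTrack("P1", "coil", cv),
                                  annotationTrack("P1", "disorder", dv),
                                  minRun = minRun)
        stretch <- part$type %in% c("coil_stretch", "disorder_stretch")
        sum((part$end - part$start + 1L)[stretch])
    }
    covs <- vapply(c(5L, 10L, 20L, 40L), cover, 0L)
    expect_true(all(diff(covs) <= 0))
})

test_that("globular calls follow the two printed conditions strictly", {
    n <- 400
    ps <- proteinsFromStrings(c(P1 = strrep("A", n)))
    dv <- logical(n); cv <- logical(n)
    dTr <- annotationTrack("P1", "disorder", dv)
    cTr <- annotationTrack("P1", "coil", cv)
    ## condition 1: significant SMART spanning >= 30 residues
    smart <- data.frame(protein_id = "P1", start = 50L, end = 100L,
                        type = "smart_domain", domain_name = "D",
                        significant = TRUE)
    part <- partitionSequence(ps, smart, cTr, dTr)
    calls <- callGlobular(part, dTr, cTr,
                          zscores = data.frame(protein_id = "P1",
                                               start = 101L, end = 400L,
                                               z = 3.5))
    expect_equal(calls$verdict[calls$type == "smart_domain"],
                 "globular_condition1")
    ## condition 2 on the 300-residue residual with z = 3.5, low disorder
    expect_equal(calls$verdict[calls$start == 101L], "globular_condition2")
    ## a short SMART match is too_short
    smart2 <- data.frame(protein_id = "P1", start = 50L, end = 78L,
                         type = "smart_domain", domain_name = "D",
                         significant = TRUE)
    part2 <- partitionSequence(ps, smart2, cTr, dTr)
    calls2 <- suppressMessages(callGlobular(part2, dTr, cTr))
    expect_equal(calls2$reason[calls2$type == "smart_domain"], "too_short")
})

test_that("the 30% disorder-plus-coil bound is strict and mode-aware", {
    n <- 300
    ps <- proteinsFromStrings(c(P1 = strrep("A", n)))
    ## 90 of 300 residual residues disordered = exactly 30%
    dv <- c(rep(TRUE, 90), rep(FALSE, n - 90))
    dTr <- annotationTrack("P1", "disorder", dv)
    cTr <- annotationTrack("P1", "coil", logical(n))
    ## keep the disorder run below stretch length by breaking it up? No:
    ## use minRun large enough that no disorder stretch forms
    part <- partitionSequence(ps, NULL, cTr, dTr, minRun = 100L)
    expect_equal(part$type, "residual")
    zs <- data.frame(protein_id = "P1", start = 1L, end = n, z = 3.5)
    calls <- callGlobular(part, dTr, cTr, zscores = zs)
    expect_equal(calls$verdict, "rejected")
    expect_equal(calls$reason, "too_disordered")
    ## one disordered residue fewer: strictly below 30% -> accepted
    dv2 <- c(rep(TRUE, 89), rep(FALSE, n - 89))
    calls2 <- callGlobular(part, annotationTrack("P1", "disorder", dv2),
                           cTr, zscores = zs)
    expect_equal(calls2$verdict, "globular_condition2")
    ## additive mode double-counts dual residues
    cv3 <- dv2  # coil exactly where disordered: union 89, sum 178
    calls3 <- callGlobular(part, annotationTrack("P1", "disorder", dv2),
                           annotationTrack("P1", "coil", cv3),
                           zscores = zs, dcMode = "sum")
    expect_equal(calls3$reason, "too_disordered")
})

test_that("eligible residual regions without alignment records are logged, not fatal", {
    n <- 200
    ps <- proteinsFromStrings(c(P1 = strrep("A", n)))
    dTr <- annotationTrack("P1", "disorder", logical(n))
    cTr <- annotationTrack("P1", "coil", logical(n))
    part <- partitionSequence(ps, NULL, cTr, dTr)
    expect_message(calls <- callGlobular(part, dTr, cTr),
                   "missing_evidence")
    expect_equal(calls$reason, "missing_evidence")
})

test_that("identity filter discards strictly above 40% and keeps the rest", {
    calls <- data.frame(protein_id = "P1", start = c(1L, 101L, 201L),
                        end = c(100L, 200L, 300L), type = "smart_domain",
                        verdict = "globular_condition1", reason = "none")
    out <- identityFilter(calls, c(0.45, 0.40, NA))
    expect_equal(out$verdict, c("rejected", "globular_condition1",
                                "globular_condition1"))
    expect_equal(out$reason[1], "high_identity")
    expect_error(identityFilter(calls, c(0.2, 1.4, NA)), "\\[0, 1\\]")
})
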