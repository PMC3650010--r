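twoProteinBundle <- function() {
    list(P1 = list(disorder = annotationTrack("P1", "disorder", rep(TRUE, 10)),
                   coil = annotationTrack("P1", "coil",
                                          c(rep(TRUE, 5), rep(FALSE, 5)))),
         P2 = list(disorder = annotationTrack("P2", "disorder", rep(TRUE, 10)),
                   coil = annotationTrack("P2", "coil", rep(FALSE, 10))))
}

test_that("joint residue counts pool residues across proteins", {
    js <- jointResidueCounts(twoProteinBundle())
    expect_equal(nResidues(js), 20L)
    p <- jointProbabilities(js)
    expect_equal(unname(p["p_disorder"]), 1.0)
    expect_equal(unname(p["p_coil_and_disorder"]), 0.25)
    expect_equal(unname(p["p_coil_not_disorder"]), 0)
    ## all-false tracks: all probabilities zero, propensity undefined
    bundle0 <- list(Z = list(
        disorder = annotationTrack("Z", "disorder", rep(FALSE, 30)),
        coil = annotationTrack("Z", "coil", rep(FALSE, 30))))
    js0 <- jointResidueCounts(bundle0)
    expect_true(all(jointProbabilities(js0) == 0))
    expect_true(is.na(propensityValue(js0)))
    ## missing required track names the protein
    broken <- twoProteinBundle()
    broken$P2$coil <- NULL
    expect_error(jointResidueCounts(broken), "P2")
})

test_that("joint counts are additive over disjoint protein sets", {
    set.seed(31)
    b1 <- randomBundle(4)
    b2 <- randomBundle(3)
    names(b2) <- paste0("X", names(b2))
    for (id in names(b2))
        for (k in names(b2[[id]]))
            b2[[id]][[k]]@proteinId <- id
    jsU <- jointResidueCounts(c(b1, b2))
    js1 <- jointResidueCounts(b1)
    js2 <- jointResidueCounts(b2)
    expect_equal(jointCounts(jsU)$disorder_coil,
                 jointCounts(js1)$disorder_coil +
                     jointCounts(js2)$disorder_coil)
})

test_that("propensity is the natural-log ratio and rejects bad input", {
    ## exact independence for random marginals
    set.seed(99)
    for (i in 1:100) {
        p <- runif(1, 0.01, 1); q <- runif(1, 0.01, 1)
        expect_lt(abs(propensity(p * q, p, q)), 1e-12)
    }
    expect_error(propensity(0, 0.5, 0.5), "pJoint")
    expect_error(propensity(0.1, -0.2, 0.5), "pCoil")
    expect_error(propensity(0.1, 0.5, 1.2), "pDisorder")
})

test_that("stretch extraction uses a strict run-length threshold", {
    mk <- function(v) annotationTrack("S1", "coil", v)
    ## exactly 20 true residues: not a stretch under the default threshold
    v20 <- c(rep(FALSE, 4), rep(TRUE, 20), rep(FALSE, 10))
    expect_equal(nrow(extractStretches(mk(v20))), 0L)
    ## 21 true residues at positions 5..25 qualify
    v21 <- c(rep(FALSE, 4), rep(TRUE, 21), rep(FALSE, 9))
    st <- extractStretches(mk(v21))
    expect_equal(st$start, 5L)
    expect_equal(st$end, 25L)
    expect_equal(st$type, "coil_stretch")
    ## alternating values never form a run of length > 1
    alt <- rep(c(TRUE, FALSE), 25)
    expect_equal(nrow(extractStretches(mk(alt), minRun = 1L)), 0L)
})

test_that("stretches plus their complement tile the sequence exactly", {
    set.seed(17)
    for (i in 1:20) {
        n <- sample(30:200, 1)
        tr <- randomSegmentalTrack("T1", "disorder", n, meanRun = 8)
        minRun <- sample(1:15, 1)
        st <- extractStretches(tr, minRun)
        covered <- logical(n)
        if (nrow(st))
            for (k in seq_len(nrow(st))) {
                idx <- st$start[k]:st$end[k]
                expect_false(any(covered[idx]))  # no overlap
                covered[idx] <- TRUE
                expect_true(all(trackValues(tr)[idx]))
                expect_gt(length(idx), minRun)
            }
        ## every uncovered TRUE run must be short enough
        leftover <- rle(trackValues(tr) & !covered)
        expect_true(all(leftover$lengths[leftover$values] <= minRun))
    }
})

test_that("per-protein fractions and the strict dual-coverage count", {
    mkP <- function(id, n, dual) {
        dv <- rep(FALSE, n); dv[seq_len(dual)] <- TRUE
        list(disorder = annotationTrack(id, "disorder", dv),
             coil = annotationTrack(id, "coil", dv))
    }
    bundle <- list(A = mkP("A", 100, 30),   # 30% dual -> counted
                   B = mkP("B", 100, 20),   # exactly 20% -> NOT counted
                   C = mkP("C", 100, 0))
    pf <- perProteinFractions(bundle)
    fr <- pf$fractions
    expect_equal(fr$f_disorder_and_coil[fr$protein_id == "A"], 0.30)
    expect_equal(pf$nDualAboveThreshold, 1L)
    expect_true(all(is.na(fr$f_modeled)))
})

test_that("secondary-structure fractions and disorder conditionals", {
    allH <- list(P = list(
        disorder = annotationTrack("P", "disorder", rep(TRUE, 50)),
        coil = annotationTrack("P", "coil", rep(FALSE, 50)),
        ss = annotationTrack("P", "ss", rep("H", 50))))
    s <- ssClassFractions(allH)
    expect_equal(unname(s$pDisorderAnd["H"]), 1)
    expect_equal(unname(s$conditionalGivenDisorder["H"]), 1)
    ## no disordered residues: conditionals absent (NA), not zero
    noD <- list(P = list(
        disorder = annotationTrack("P", "disorder", rep(FALSE, 50)),
        coil = annotationTrack("P", "coil", rep(FALSE, 50)),
        ss = annotationTrack("P", "ss", rep("E", 50))))
    s2 <- ssClassFractions(noD)
    expect_true(all(is.na(s2$conditionalGivenDisorder)))
    ## missing ss track is an error
    expect_error(ssClassFractions(twoProteinBundle()), "ss")
})

test_that("set comparison bootstraps at the protein level, reproducibly", {
    set.seed(55)
    b <- randomBundle(12)
    cmp <- compareSets(b, b, nBoot = 50, seed = 7)
    expect_true(all(cmp$difference == 0))
    expect_true(all(cmp$study_se > 0))
    expect_false(any(cmp$unreliable))
    ## same seed -> bit-identical result
    cmp2 <- compareSets(b, b, nBoot = 50, seed = 7)
    expect_identical(cmp, cmp2)
    expect_error(compareSets(b, b, nBoot = 1, seed = 1), "nBoot")
    expect_error(compareSets(b, b, nBoot = 10), "seed")
    ## single-protein set is flagged unreliable
    expect_message(cmp1 <- compareSets(b[1], b, nBoot = 20, seed = 3),
                   "unreliable")
    expect_true(all(cmp1$unreliable))
})

test_that("two generated cohorts with different disorder levels separate", {
    spS <- syntheticSpec(nProteins = 120, targetMeanLength = 600,
                         pDisorder = 0.57, seed = 301)
    spC <- syntheticSpec(nProteins = 120, targetMeanLength = 600,
                         pDisorder = 0.39, pDisorderHelical = 0.20,
                         pCoilAndDisorder = 0.033, richFraction = 0.05,
                         seed = 302)
    simS <- sampleProteinSet(spS)
    simC <- sampleProteinSet(spC, setLabel = "control")
    cmp <- compareSets(simS$tracks, simC$tracks, nBoot = 200, seed = 9)
    row <- cmp[cmp$metric == "p_disorder", ]
    expect_lt(abs(row$difference - (0.57 - 0.39)), 3 * row$combined_se + 1e-3)
    expect_true(all(cmp$combined_se < 0.02))
})
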