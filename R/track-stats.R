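## track_stats: joint-annotation residue statistics over protein sets.
##
## A "track bundle" is a named list keyed by protein id; each element is a
## named list of AnnotationTracks keyed by kind ("disorder", "coil", "ss",
## "modeled"). All set-level fractions are residue-weighted (pooled counts
## over all residues of the set), matching how proteome-composition numbers
## such as "57% of the residues are disordered" are defined; per-protein
## (length-fraction) views are provided by perProteinFractions().

## per-protein joint counts used by pooling and by the protein-level
## bootstrap; returns one row per protein.
.proteinJointCounts <- function(tracks, needSS = FALSE) {
    ids <- names(tracks)
    if (is.null(ids) || length(ids) == 0L)
        .stopf("empty track bundle")
    rows <- lapply(ids, function(id) {
        d <- .getTrack(tracks, id, "disorder")
        co <- .getTrack(tracks, id, "coil")
        dv <- trackValues(d)
        cv <- trackValues(co)
        if (length(dv) != length(cv))
            .stopf("protein '%s': disorder and coil tracks have different lengths",
                   id)
        ss <- .getTrack(tracks, id, "ss", required = needSS)
        out <- c(n = length(dv), d = sum(dv), coil = sum(cv),
                 dc = sum(dv & cv), c_not_d = sum(cv & !dv),
                 dH = NA_real_, dE = NA_real_, dC = NA_real_,
                 H = NA_real_, E = NA_real_, C = NA_real_)
        if (!is.null(ss)) {
            sv <- trackValues(ss)
            if (length(sv) != length(dv))
                .stopf("protein '%s': ss track has a different length", id)
            out[c("dH", "dE", "dC")] <-
                c(sum(dv & sv == "H"), sum(dv & sv == "E"), sum(dv & sv == "C"))
            out[c("H", "E", "C")] <-
                c(sum(sv == "H"), sum(sv == "E"), sum(sv == "C"))
        }
        out
    })
    m <- do.call(rbind, rows)
    rownames(m) <- ids
    m
}

.bundleSource <- function(tracks) {
    .poolSource(unlist(lapply(tracks, function(x) unname(x)),
                       recursive = FALSE))
}

#' Pooled joint disorder/coil (and disorder/ss) residue counts
#'
#' Pools residues over all proteins of a set and tabulates the joint
#' disorder x coil categories (plus disorder x secondary-structure when ss
#' tracks are present). Fractions are counts divided by total residues; the
#' log-ratio propensity is computed when all marginals are positive.
#'
#' @param tracks A track bundle: named list (protein id) of named lists of
#'   [AnnotationTrack]s with at least `disorder` and `coil` entries per
#'   protein (`ss` optional).
#' @return A [JointStats] object.
#' @examples
#' t1 <- list(P1 = list(
#'   disorder = annotationTrack("P1", "disorder", rep(TRUE, 10)),
#'   coil = annotationTrack("P1", "coil", rep(c(TRUE, FALSE), 5))))
#' jointResidueCounts(t1)
#' @export
jointResidueCounts <- function(tracks) {
    m <- .proteinJointCounts(tracks)
    n <- sum(m[, "n"])
    d <- sum(m[, "d"])
    dc <- sum(m[, "dc"])
    cnd <- sum(m[, "c_not_d"])
    counts <- c(d_and_c = dc, d_not_c = d - dc, c_not_d = cnd,
                neither = n - d - cnd)
    ssCounts <- integer(0)
    if (!anyNA(m[, "dH"])) {
        dH <- sum(m[, "dH"]); dE <- sum(m[, "dE"]); dC <- sum(m[, "dC"])
        oH <- sum(m[, "H"]) - dH; oE <- sum(m[, "E"]) - dE
        oC <- sum(m[, "C"]) - dC
        ssCounts <- as.integer(c(d_H = dH, d_E = dE, d_C = dC,
                                 o_H = oH, o_E = oE, o_C = oC))
        names(ssCounts) <- c("d_H", "d_E", "d_C", "o_H", "o_E", "o_C")
    }
    pD <- d / n; pC <- (dc + cnd) / n; pDC <- dc / n
    prop <- if (pD > 0 && pC > 0 && pDC > 0)
        propensity(pDC, pC, pD) else NA_real_
    countsInt <- as.integer(counts)
    names(countsInt) <- names(counts)
    new("JointStats", nResidues = as.integer(n),
        counts = countsInt,
        ssCounts = ssCounts,
        pDisorder = pD, pCoil = pC, pCoilAndDisorder = pDC,
        pCoilNotDisorder = cnd / n, propensity = prop,
        source = .bundleSource(tracks))
}

#' Log-ratio propensity for a joint annotation
#'
#' `propensity(pJoint, pCoil, pDisorder)` returns
#' `ln(pJoint) - ln(pCoil) - ln(pDisorder)`: the natural-log over-
#' representation of the joint annotation relative to independence of the
#' two marginals. `P(coil)` here is the full coil marginal, i.e. dual
#' (coil-and-disordered) plus coil-only residues. Positive values mean the
#' two annotations co-occur more often than expected by chance; 0 means
#' exact independence.
#'
#' @param pJoint,pCoil,pDisorder Fractions in `(0, 1]`; any argument
#'   outside that range is an error (the statistic is undefined at 0 and
#'   is never returned as `-Inf` silently).
#' @return The propensity in natural-log units.
#' @examples
#' propensity(0.124, 0.124 + 0.007, 0.57)  # ~0.51
#' propensity(0.033, 0.033 + 0.007, 0.39)  # ~0.75
#' @export
propensity <- function(pJoint, pCoil, pDisorder) {
    for (nm in c("pJoint", "pCoil", "pDisorder")) {
        v <- get(nm)
        if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v > 1)
            .stopf("%s must be a single value in (0, 1]; got %s", nm,
                   format(v))
    }
    log(pJoint) - log(pCoil) - log(pDisorder)
}

#' Extract annotation stretches (maximal runs above a length threshold)
#'
#' Returns the maximal runs of `TRUE` values whose length is strictly
#' greater than `minRun` (the "more than 20 consecutive residues"
#' convention: with the default `minRun = 20`, runs of 21 or more qualify
#' and a run of exactly 20 does not).
#'
#' @param track A boolean [AnnotationTrack].
#' @param minRun Strict lower bound on run length (default 20).
#' @return data.frame with columns `protein_id`, `start`, `end`, `type`
#'   (`"<kind>_stretch"`), 1-based inclusive.
#' @export
extractStretches <- function(track, minRun = 20L) {
    stopifnot(is(track, "AnnotationTrack"))
    if (!is.logical(trackValues(track)))
        .stopf("extractStretches requires a boolean track")
    minRun <- as.integer(minRun)
    if (minRun < 1L) .stopf("minRun must be >= 1")
    runs <- .trueRuns(trackValues(track), minRun)
    if (nrow(runs) == 0L)
        return(data.frame(protein_id = character(0), start = integer(0),
                          end = integer(0), type = character(0)))
    data.frame(protein_id = proteinIds(track), start = runs$start,
               end = runs$end, type = paste0(trackKind(track), "_stretch"))
}

#' Per-protein annotation fractions and their distributions
#'
#' For every protein computes the fraction of its length that is (a)
#' disordered and coiled-coil at the same time, (b) disordered but not
#' coiled-coil, (c) modeled (when a `modeled` track is present), and (d)
#' in regular secondary structure (H or E) while neither disordered, nor
#' coiled-coil, nor modeled (when `ss` and `modeled` tracks are present).
#' Also returns binned histograms of each fraction and the number of
#' proteins whose dual disorder-and-coil fraction strictly exceeds
#' `dualThreshold` (default 20% of length, strict).
#'
#' @param tracks A track bundle (see [jointResidueCounts()]).
#' @param binWidth Histogram bin width on the fraction scale (default 0.05).
#' @param dualThreshold Strict threshold for the dual-coverage protein
#'   count (default 0.20).
#' @return A list with elements `fractions` (data.frame), `histograms`
#'   (named list of binned counts) and `nDualAboveThreshold`.
#' @export
perProteinFractions <- function(tracks, binWidth = 0.05,
                                dualThreshold = 0.20) {
    ids <- names(tracks)
    rows <- lapply(ids, function(id) {
        dv <- trackValues(.getTrack(tracks, id, "disorder"))
        cv <- trackValues(.getTrack(tracks, id, "coil"))
        n <- length(dv)
        mTr <- .getTrack(tracks, id, "modeled", required = FALSE)
        sTr <- .getTrack(tracks, id, "ss", required = FALSE)
        mv <- if (!is.null(mTr)) trackValues(mTr) else NULL
        sv <- if (!is.null(sTr)) trackValues(sTr) else NULL
        data.frame(
            protein_id = id,
            length = n,
            f_disorder_and_coil = sum(dv & cv) / n,
            f_disorder_not_coil = sum(dv & !cv) / n,
            f_modeled = if (!is.null(mv)) sum(mv) / n else NA_real_,
            f_ss_not_d_not_c_not_modeled =
                if (!is.null(mv) && !is.null(sv))
                    sum(sv %in% c("H", "E") & !dv & !cv & !mv) / n
                else NA_real_)
    })
    fr <- do.call(rbind, rows)
    breaks <- seq(0, 1, by = binWidth)
    if (max(breaks) < 1) breaks <- c(breaks, 1)
    histOf <- function(x) {
        x <- x[!is.na(x)]
        if (!length(x)) return(NULL)
        table(cut(x, breaks = breaks, include.lowest = TRUE, right = FALSE))
    }
    hists <- lapply(fr[, -(1:2)], histOf)
    list(fractions = fr,
         histograms = hists[!vapply(hists, is.null, TRUE)],
         nDualAboveThreshold =
             sum(fr$f_disorder_and_coil > dualThreshold))
}

#' Secondary-structure class fractions and their overlap with disorder
#'
#' Residue-weighted fractions of the three secondary-structure classes over
#' a protein set, the joint fractions `P(disorder & class)`, and the class
#' composition conditional on being disordered. When the set contains no
#' disordered residues the conditional fractions are reported as `NA`
#' (absent), not 0.
#'
#' @param tracks A track bundle with `ss` and `disorder` tracks per protein.
#' @return A list with `classFractions`, `pDisorderAnd`,
#'   `conditionalGivenDisorder` (each named by `H`, `E`, `C`), `nResidues`,
#'   `nDisordered` and `source`.
#' @export
ssClassFractions <- function(tracks) {
    m <- .proteinJointCounts(tracks, needSS = TRUE)
    n <- sum(m[, "n"])
    tot <- c(H = sum(m[, "H"]), E = sum(m[, "E"]), C = sum(m[, "C"]))
    dJoint <- c(H = sum(m[, "dH"]), E = sum(m[, "dE"]), C = sum(m[, "dC"]))
    nD <- sum(m[, "d"])
    list(classFractions = tot / n,
         pDisorderAnd = dJoint / n,
         conditionalGivenDisorder =
             if (nD > 0) dJoint / nD else setNames(rep(NA_real_, 3),
                                                   c("H", "E", "C")),
         nResidues = n, nDisordered = nD,
         source = .bundleSource(tracks))
}

## pooled metric vector from a per-protein count matrix
.pooledMetrics <- function(m) {
    n <- sum(m[, "n"])
    out <- c(p_disorder = sum(m[, "d"]) / n,
             p_coil = (sum(m[, "dc"]) + sum(m[, "c_not_d"])) / n,
             p_coil_and_disorder = sum(m[, "dc"]) / n,
             p_coil_not_disorder = sum(m[, "c_not_d"]) / n)
    if (!anyNA(m[, "dH"]))
        out <- c(out, p_disorder_and_helical = sum(m[, "dH"]) / n)
    out
}

#' Compare pooled annotation fractions between two protein sets
#'
#' Computes residue-weighted fractions for each set and attaches standard
#' errors from a protein-level bootstrap: proteins (not residues) are
#' resampled with replacement, because residues within one protein are
#' strongly correlated through its segmental annotation structure. With
#' several hundred proteins of typical proteome lengths the resulting
#' standard errors are of order 1 percentage point.
#'
#' @param study,control Track bundles for the two sets.
#' @param nBoot Bootstrap replicates (default 1000; must be >= 2).
#' @param seed Mandatory integer seed for the bootstrap.
#' @return data.frame with one row per metric: the two set values, their
#'   bootstrap SEs, the difference (study - control), the combined SE and
#'   an `unreliable` flag set when either set has fewer than 2 proteins.
#' @export
compareSets <- function(study, control, nBoot = 1000L, seed) {
    if (missing(seed)) .stopf("seed is mandatory for the bootstrap")
    nBoot <- as.integer(nBoot)
    if (nBoot < 2L) .stopf("nBoot must be >= 2")
    if (!length(study) || !length(control))
        .stopf("both sets must be non-empty")
    mS <- .proteinJointCounts(study)
    mC <- .proteinJointCounts(control)
    vS <- .pooledMetrics(mS)
    vC <- .pooledMetrics(mC)
    metrics <- intersect(names(vS), names(vC))
    bootSE <- function(m, sub) {
        k <- nrow(m)
        reps <- vapply(seq_len(nBoot), function(b) {
            idx <- sample.int(k, k, replace = TRUE)
            .pooledMetrics(m[idx, , drop = FALSE])[metrics]
        }, numeric(length(metrics)))
        if (length(metrics) == 1L) reps <- matrix(reps, nrow = 1L)
        apply(reps, 1L, sd)
    }
    oldSeed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(oldSeed))
        assign(".Random.seed", oldSeed, envir = globalenv()))
    set.seed(.subSeed(seed, 0L))
    seS <- bootSE(mS)
    seC <- bootSE(mC)
    unreliable <- nrow(mS) < 2L || nrow(mC) < 2L
    if (unreliable)
        message("compareSets: a set has fewer than 2 proteins; bootstrap SEs are unreliable")
    data.frame(metric = metrics,
               study_value = unname(vS[metrics]),
               control_value = unname(vC[metrics]),
               study_se = unname(seS),
               control_se = unname(seC),
               difference = unname(vS[metrics] - vC[metrics]),
               combined_se = sqrt(unname(seS)^2 + unname(seC)^2),
               unreliable = unreliable)
}
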