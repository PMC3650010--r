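## baseline_predictors: deterministic stand-in predictors so the pipeline
## can be exercised end-to-end without any external tool. These are NOT
## reimplementations of the published coiled-coil or disorder predictors
## whose outputs the import functions expect; tracks they produce carry
## source = "builtin" and are never silently mixed with imported tracks.

## Heptad position groups: core (a, d), edge (e, g), other (b, c, f).
.HEPTAD_GROUP <- c(a = "core", b = "other", c = "other", d = "core",
                   e = "edge", f = "other", g = "edge")

.defaultPropensities <- function() {
    aa <- setdiff(.AA_ALPHABET, "X")
    core <- setNames(rep(0.3, length(aa)), aa)
    core[c("L")] <- 4.0
    core[c("I")] <- 3.5
    core[c("M", "V")] <- 3.0
    core[c("A")] <- 1.5
    core[c("F")] <- 1.2
    edge <- setNames(rep(0.5, length(aa)), aa)
    edge[c("E", "K")] <- 3.0
    edge[c("Q")] <- 2.5
    edge[c("R")] <- 2.0
    edge[c("D")] <- 1.2
    other <- setNames(rep(0.8, length(aa)), aa)
    other[c("A", "E", "K", "Q", "R", "S", "N", "D")] <- 1.5
    other["L"] <- 1.0
    ## 'X' is neutral at every position
    list(core = c(core, X = 1.0), edge = c(edge, X = 1.0),
         other = c(other, X = 1.0))
}

#' Parameters for the built-in heptad coiled-coil scorer
#'
#' A sliding window of length `window` is scored at each of the 7 heptad
#' register offsets as the geometric mean of position-weighted residue
#' propensities; each residue receives the maximum score over all
#' window/register placements covering it and is called coil when that
#' score reaches `scoreThreshold`. The default propensity table favours
#' L/M/I/V at the hydrophobic core positions (a, d) and E/K/Q/R at the
#' flanking charged positions (e, g), so idealized leucine-zipper repeats
#' score far above threshold while low-complexity non-coil sequence scores
#' below it.
#'
#' @param window Window length in residues (default 21; must be >= 7).
#' @param positionWeights Numeric length-7 multiplier per heptad position
#'   a-g (default all 1).
#' @param residuePropensities List with elements `core`, `edge`, `other`,
#'   each a named positive numeric vector over the alphabet (incl. `X`).
#' @param scoreThreshold Score at or above which a residue is called coil
#'   (default 1, i.e. geometric-mean propensity above neutral).
#' @return A list of class `HeptadParams`.
#' @export
heptadParams <- function(window = 21L, positionWeights = rep(1, 7),
                         residuePropensities = .defaultPropensities(),
                         scoreThreshold = 1.0) {
    window <- as.integer(window)
    if (window < 7L) .stopf("window must be >= 7 residues")
    if (length(positionWeights) != 7L || any(positionWeights <= 0))
        .stopf("positionWeights must be 7 strictly positive values")
    for (g in c("core", "edge", "other")) {
        p <- residuePropensities[[g]]
        if (is.null(p) || any(p <= 0) || !all(.AA_ALPHABET %in% names(p)))
            .stopf("residuePropensities$%s must be strictly positive and cover the alphabet",
                   g)
    }
    structure(list(window = window, positionWeights = positionWeights,
                   residuePropensities = residuePropensities,
                   scoreThreshold = scoreThreshold),
              class = "HeptadParams")
}

#' Score coiled-coil propensity with the built-in heptad scorer
#'
#' Pure function of (sequence, params): for every window placement and
#' every heptad register, the score is the geometric mean over the window
#' of `positionWeight[p] * propensity[residue, group(p)]`; each residue is
#' assigned the maximum score among placements covering it.
#'
#' @param protein A single-protein [ProteinSet] (or larger set plus
#'   `proteinId`).
#' @param params A `HeptadParams` object from [heptadParams()].
#' @param proteinId Protein to score (defaults to the only one present).
#' @return An [AnnotationTrack] of kind `coil`, `source = "builtin"`, with
#'   the per-residue scores attached. Sequences shorter than the window
#'   give an all-`FALSE` track with a warning.
#' @export
coilScoreTrack <- function(protein, params = heptadParams(),
                           proteinId = NULL) {
    stopifnot(is(protein, "ProteinSet"), inherits(params, "HeptadParams"))
    if (is.null(proteinId)) {
        stopifnot(length(protein) == 1L)
        proteinId <- proteinIds(protein)
    }
    seqc <- .seqChars(protein, proteinId)
    n <- length(seqc)
    w <- params$window
    if (n < w) {
        .warnf("sequence '%s' (%d residues) is shorter than the window (%d): all-FALSE coil track",
               proteinId, n, w)
        return(annotationTrack(proteinId, "coil", rep(FALSE, n),
                               source = "builtin", score = rep(0, n)))
    }
    groups <- .HEPTAD_GROUP  # position 1..7 -> group
    prop <- params$residuePropensities
    logw <- log(params$positionWeights)
    ## precompute, per register r (0..6), the per-residue log contribution
    best <- rep(-Inf, n)
    for (r in 0:6) {
        pos <- ((seq_len(n) - 1L + r) %% 7L) + 1L
        contrib <- logw[pos]
        for (g in c("core", "edge", "other")) {
            sel <- groups[pos] == g
            contrib[sel] <- contrib[sel] + log(prop[[g]][seqc[sel]])
        }
        cs <- c(0, cumsum(contrib))
        winMean <- (cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]) / w
        ## residue i is covered by windows starting in [i-w+1, i]
        for (s in seq_len(n - w + 1L)) {
            idx <- s:(s + w - 1L)
            best[idx] <- pmax(best[idx], winMean[s])
        }
    }
    score <- exp(best)
    annotationTrack(proteinId, "coil", score >= params$scoreThreshold,
                    source = "builtin", score = score)
}

## Kyte-Doolittle hydropathy, rescaled to [0, 1] via (h + 4.5) / 9.
.kdRescaled <- function() {
    kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
            E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
            M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
            Y = -1.3, V = 4.2)
    c((kd + 4.5) / 9, X = 0.5)
}

.defaultCharge <- function() {
    q <- setNames(rep(0, length(.AA_ALPHABET)), .AA_ALPHABET)
    q[c("K", "R")] <- 1
    q[c("D", "E")] <- -1
    q
}

#' Parameters for the built-in charge-hydropathy disorder index
#'
#' The index follows the classical charge-hydropathy functional form
#' `a * <H> - |<q>| - b` with `<H>` the mean rescaled Kyte-Doolittle
#' hydropathy and `<q>` the mean net charge, evaluated over the whole
#' sequence or over a sliding window; a residue is called disordered when
#' its index is negative (low hydropathy and/or high net charge).
#'
#' @param hydropathyScale Named numeric, residue to hydropathy in `[0, 1]`
#'   (`X` maps to the midpoint 0.5).
#' @param charge Named numeric, residue to charge in `{-1, 0, +1}`
#'   (`X` maps to 0).
#' @param coefficients Numeric `c(a, b)`; defaults `a = 2.785`,
#'   `b = 1.151`.
#' @param window `NULL` for whole-sequence evaluation (default) or an odd
#'   integer window length; near the ends the window shrinks symmetrically.
#' @return A list of class `ChargeHydropathyParams`.
#' @export
chargeHydropathyParams <- function(hydropathyScale = .kdRescaled(),
                                   charge = .defaultCharge(),
                                   coefficients = c(a = 2.785, b = 1.151),
                                   window = NULL) {
    if (!all(.AA_ALPHABET %in% names(hydropathyScale)) ||
        any(hydropathyScale < 0 | hydropathyScale > 1))
        .stopf("hydropathyScale must cover the alphabet with values in [0, 1]")
    if (!all(.AA_ALPHABET %in% names(charge)) ||
        !all(charge %in% c(-1, 0, 1)))
        .stopf("charge must cover the alphabet with values in {-1, 0, +1}")
    if (length(coefficients) != 2L)
        .stopf("coefficients must be c(a, b)")
    if (!is.null(window)) {
        window <- as.integer(window)
        if (window < 1L || window %% 2L == 0L)
            .stopf("window must be NULL or an odd positive integer")
    }
    structure(list(hydropathyScale = hydropathyScale, charge = charge,
                   a = as.numeric(coefficients[[1]]),
                   b = as.numeric(coefficients[[2]]), window = window),
              class = "ChargeHydropathyParams")
}

#' Call disorder with the built-in charge-hydropathy index
#'
#' Pure function of (sequence, params). In whole-sequence mode every
#' residue receives the same index (permutation invariant); in windowed
#' mode each residue's index is computed from the centred window around it
#' (shrunk at the termini).
#'
#' @param protein A single-protein [ProteinSet] (or larger set plus
#'   `proteinId`).
#' @param params A `ChargeHydropathyParams` object.
#' @param proteinId Protein to score (defaults to the only one present).
#' @return An [AnnotationTrack] of kind `disorder`, `source = "builtin"`,
#'   with the per-residue index attached as score; disordered iff index < 0.
#' @export
disorderIndexTrack <- function(protein, params = chargeHydropathyParams(),
                               proteinId = NULL) {
    stopifnot(is(protein, "ProteinSet"),
              inherits(params, "ChargeHydropathyParams"))
    if (is.null(proteinId)) {
        stopifnot(length(protein) == 1L)
        proteinId <- proteinIds(protein)
    }
    seqc <- .seqChars(protein, proteinId)
    n <- length(seqc)
    h <- unname(params$hydropathyScale[seqc])
    q <- unname(params$charge[seqc])
    idx <- if (is.null(params$window)) {
        rep(params$a * mean(h) - abs(mean(q)) - params$b, n)
    } else {
        half <- (params$window - 1L) %/% 2L
        vapply(seq_len(n), function(i) {
            lo <- max(1L, i - half)
            hi <- min(n, i + half)
            params$a * mean(h[lo:hi]) - abs(mean(q[lo:hi])) - params$b
        }, 0)
    }
    annotationTrack(proteinId, "disorder", idx < 0,
                    source = "builtin", score = idx)
}
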