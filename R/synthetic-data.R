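## synthetic_data: seeded generators for protein sets, annotation tracks,
## template-hit tables and interaction graphs with known ground truth.
##
## Proteins are assembled segment by segment from a five-type grammar
## (globular, disordered_loop, disordered_helical, coil_disordered,
## coil_ordered). The generator is quota-based: each protein receives
## integer residue budgets per segment type, drawn around the set-level
## target fractions with controlled per-protein heterogeneity (a
## configurable share of "dual-rich" proteins emulating the subset whose
## disordered coiled-coil fragments cover more than 20% of their length),
## and a final correction pass pins the pooled joint fractions to the
## targets up to integer rounding. Tracks are emitted from the generating
## segment labels (ground truth), never from the built-in predictors.

.SEGMENT_TYPES <- c("globular", "disordered_loop", "disordered_helical",
                    "coil_disordered", "coil_ordered")

#' Specification for the synthetic-data generator
#'
#' Defaults emulate the headline composition of the centrosomal proteome:
#' heavy-tailed log-normal lengths with mean ~796 residues, 57% disordered
#' residues, 12.4% dual disordered-and-coiled-coil, 0.7% coil-only, 30%
#' disordered-and-helical, ~15% of proteins with dual fragments covering
#' more than 20% of their length, a bimodal template-identity mixture with
#' weights 99 (low, ~25%) : 174 (high, ~92%), modeled coverage of 57.2% of
#' ordered (globular) residues and 5.4% of disordered-or-coil residues,
#' and a sparse interaction graph of 354 edges over 167 nodes.
#'
#' @param nProteins Number of proteins (default 500).
#' @param targetMeanLength Target mean sequence length (default 796; use
#'   599 for a control-like cohort).
#' @param lengthSdLog Log-scale SD of the log-normal length distribution
#'   (default 0.7, giving the heavy right tail).
#' @param minLength Minimum sequence length (default 80).
#' @param pDisorder,pCoilAndDisorder,pCoilNotDisorder,pDisorderHelical
#'   Target pooled residue fractions (defaults 0.57, 0.124, 0.007, 0.30).
#'   Must satisfy `pCoilAndDisorder <= pDisorderHelical <= pDisorder`
#'   (dual segments are helical in the grammar) and
#'   `pDisorder + pCoilNotDisorder <= 1`.
#' @param richFraction Share of proteins drawn as dual-rich (default 0.15).
#' @param richDualRange Range of the dual fraction for rich proteins
#'   (default `c(0.22, 0.38)`, i.e. all strictly above 20% of length).
#' @param segmentMeanLengths Named mean segment lengths in residues.
#' @param orderedCoverage,disorderedCoverage Target modeled fraction of
#'   ordered (globular) and of disordered-or-coil residues (defaults
#'   0.572 and 0.054, jointly implying ~27.6% modeled overall).
#' @param identityWeights Mixture weights of the low/high identity modes
#'   (default `c(low = 99, high = 174)`).
#' @param identityLow,identityHigh `c(mean, sd)` of each identity mode.
#' @param minSpan Minimum template span in residues (default 31, so every
#'   generated hit passes the strict `> 30` span filter).
#' @param nNodes,nEdges Interaction-graph size (defaults 167, 354).
#' @param networkModel `"gnm"` (uniform random simple graph, default) or
#'   `"pa"` (preferential attachment).
#' @param seed Mandatory integer seed; all randomness of the generator
#'   flows from it through fixed sub-seed offsets.
#' @return A list of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(nProteins = 500L,
                          targetMeanLength = 796,
                          lengthSdLog = 0.7,
                          minLength = 80L,
                          pDisorder = 0.57,
                          pCoilAndDisorder = 0.124,
                          pCoilNotDisorder = 0.007,
                          pDisorderHelical = 0.30,
                          richFraction = 0.15,
                          richDualRange = c(0.22, 0.38),
                          segmentMeanLengths = c(globular = 150,
                                                 disordered_loop = 40,
                                                 disordered_helical = 25,
                                                 coil_disordered = 60,
                                                 coil_ordered = 30),
                          orderedCoverage = 0.572,
                          disorderedCoverage = 0.054,
                          identityWeights = c(low = 99, high = 174),
                          identityLow = c(mean = 0.25, sd = 0.03),
                          identityHigh = c(mean = 0.92, sd = 0.04),
                          minSpan = 31L,
                          nNodes = 167L,
                          nEdges = 354L,
                          networkModel = c("gnm", "pa"),
                          seed) {
    if (missing(seed)) .stopf("seed is mandatory in a SyntheticSpec")
    networkModel <- match.arg(networkModel)
    .assertFraction(c(pDisorder, pCoilAndDisorder, pCoilNotDisorder,
                      pDisorderHelical, richFraction,
                      orderedCoverage, disorderedCoverage),
                    "target probabilities")
    if (pCoilAndDisorder > pDisorder)
        .stopf("inconsistent targets: P(coil & disorder) exceeds P(disorder)")
    if (pCoilAndDisorder > pDisorderHelical)
        .stopf("inconsistent targets: P(coil & disorder) exceeds P(disorder & helical) (dual segments are helical)")
    if (pDisorderHelical > pDisorder)
        .stopf("inconsistent targets: P(disorder & helical) exceeds P(disorder)")
    if (pDisorder + pCoilNotDisorder > 1)
        .stopf("inconsistent targets: P(disorder) + P(coil & !disorder) exceeds 1")
    if (!all(.SEGMENT_TYPES %in% names(segmentMeanLengths)))
        .stopf("segmentMeanLengths must name all five segment types")
    if (richFraction > 0 &&
        richFraction * mean(richDualRange) >= pCoilAndDisorder)
        .stopf("inconsistent targets: dual-rich proteins alone would exceed the pooled dual target")
    structure(list(nProteins = as.integer(nProteins),
                   targetMeanLength = targetMeanLength,
                   lengthMeanLog = log(targetMeanLength) - lengthSdLog^2 / 2,
                   lengthSdLog = lengthSdLog,
                   minLength = as.integer(minLength),
                   pDisorder = pDisorder,
                   pCoilAndDisorder = pCoilAndDisorder,
                   pCoilNotDisorder = pCoilNotDisorder,
                   pDisorderHelical = pDisorderHelical,
                   richFraction = richFraction,
                   richDualRange = richDualRange,
                   segmentMeanLengths = segmentMeanLengths,
                   orderedCoverage = orderedCoverage,
                   disorderedCoverage = disorderedCoverage,
                   identityWeights = identityWeights,
                   identityLow = identityLow,
                   identityHigh = identityHigh,
                   minSpan = as.integer(minSpan),
                   nNodes = as.integer(nNodes),
                   nEdges = as.integer(nEdges),
                   networkModel = networkModel,
                   seed = as.integer(seed)),
              class = "SyntheticSpec")
}

## residue composition tables per segment type
.segmentComposition <- function(type) {
    switch(type,
        disordered_loop = c(P = 0.14, E = 0.14, S = 0.14, K = 0.12,
                            G = 0.12, Q = 0.10, A = 0.08, D = 0.08,
                            R = 0.05, T = 0.03),
        disordered_helical = c(A = 0.18, E = 0.20, K = 0.16, Q = 0.12,
                               L = 0.10, R = 0.10, S = 0.08, D = 0.06),
        globular = c(A = 0.08, C = 0.02, D = 0.06, E = 0.06, F = 0.04,
                     G = 0.07, H = 0.02, I = 0.06, K = 0.06, L = 0.09,
                     M = 0.02, N = 0.04, P = 0.05, Q = 0.04, R = 0.05,
                     S = 0.07, T = 0.06, V = 0.07, W = 0.01, Y = 0.03),
        .stopf("no composition for segment type '%s'", type))
}

## heptad-patterned residues for coil segments
.sampleCoilResidues <- function(len) {
    reg <- sample.int(7L, 1L)
    pos <- ((seq_len(len) - 1L + reg - 1L) %% 7L) + 1L
    out <- character(len)
    core <- pos %in% c(1L, 4L)
    edge <- pos %in% c(5L, 7L)
    other <- !core & !edge
    out[core] <- sample(c("L", "I", "V", "M"), sum(core), replace = TRUE,
                        prob = c(0.45, 0.20, 0.20, 0.15))
    out[edge] <- sample(c("E", "K", "Q", "R"), sum(edge), replace = TRUE,
                        prob = c(0.35, 0.35, 0.20, 0.10))
    out[other] <- sample(c("A", "S", "N", "D", "E", "K", "Q", "T"),
                         sum(other), replace = TRUE)
    out
}

.sampleSegmentResidues <- function(type, len) {
    if (type %in% c("coil_disordered", "coil_ordered"))
        return(.sampleCoilResidues(len))
    comp <- .segmentComposition(type)
    sample(names(comp), len, replace = TRUE, prob = comp)
}

## secondary structure inside a globular segment: runs of H/E/C
.globularSS <- function(len) {
    out <- character(0)
    while (length(out) < len) {
        cls <- sample(c("H", "E", "C"), 1L, prob = c(0.45, 0.18, 0.37))
        run <- 1L + stats::rgeom(1L, prob = 1 / 8)
        out <- c(out, rep(cls, run))
    }
    out[seq_len(len)]
}

## split a count into k parts, each >= 1, uniformly at random
.randomComposition <- function(total, k) {
    if (k <= 1L) return(total)
    cuts <- sort(sample.int(total - 1L, k - 1L))
    diff(c(0L, cuts, total))
}

## move `delta` residues between column `type` and the globular reservoir,
## one residue at a time over randomly ordered proteins with capacity
.adjustBudget <- function(budget, type, delta) {
    while (delta != 0L) {
        if (delta > 0L) {
            cand <- which(budget[, "globular"] > 1L)
            if (!length(cand)) break
            take <- cand[sample.int(length(cand),
                                    min(length(cand), delta))]
            budget[take, type] <- budget[take, type] + 1L
            budget[take, "globular"] <- budget[take, "globular"] - 1L
            delta <- delta - length(take)
        } else {
            cand <- which(budget[, type] > 0L)
            if (!length(cand)) break
            take <- cand[sample.int(length(cand),
                                    min(length(cand), -delta))]
            budget[take, type] <- budget[take, type] - 1L
            budget[take, "globular"] <- budget[take, "globular"] + 1L
            delta <- delta + length(take)
        }
    }
    budget
}

#' Generate a synthetic protein set with ground-truth annotation tracks
#'
#' See [syntheticSpec()] for the generative model. The returned ledger
#' stores the exact realized pooled fractions (recomputable from the
#' emitted tracks), the per-protein residue budgets, the segment layout of
#' every protein and the ids of the dual-rich proteins.
#'
#' @param spec A `SyntheticSpec`.
#' @param setLabel Cohort label for the generated proteins.
#' @param idPrefix Prefix for generated protein ids (default `"SYN"`).
#' @return A list with `proteins` (a [ProteinSet]), `tracks` (a track
#'   bundle of ground-truth `disorder`, `coil` and `ss`
#'   [AnnotationTrack]s, `source = "builtin"`) and `ledger`.
#' @export
sampleProteinSet <- function(spec, setLabel = "study", idPrefix = "SYN") {
    stopifnot(inherits(spec, "SyntheticSpec"))
    oldSeed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(oldSeed))
        assign(".Random.seed", oldSeed, envir = globalenv()))
    set.seed(.subSeed(spec$seed, 1L))

    n <- spec$nProteins
    L <- pmax(spec$minLength,
              as.integer(.roundHalfUp(rlnorm(n, spec$lengthMeanLog,
                                             spec$lengthSdLog))))
    total <- sum(L)
    ids <- sprintf("%s%04d", idPrefix, seq_len(n))

    ## dual (coil & disorder) fraction per protein: a rich subset with
    ## > 20% coverage, the rest rebalanced so the pooled target is met
    nRich <- round(spec$richFraction * n)
    rich <- if (nRich > 0) sample.int(n, nRich) else integer(0)
    fDual <- numeric(n)
    if (nRich > 0)
        fDual[rich] <- runif(nRich, spec$richDualRange[1],
                             spec$richDualRange[2])
    poor <- setdiff(seq_len(n), rich)
    poolDual <- spec$pCoilAndDisorder * total
    remainder <- poolDual - sum(fDual[rich] * L[rich])
    if (remainder < 0)
        .stopf("inconsistent spec: rich proteins alone exceed the pooled dual target")
    if (length(poor)) fDual[poor] <- remainder / sum(L[poor])

    ## integer residue budgets per type, globular as the reservoir
    cd <- as.integer(.roundHalfUp(fDual * L))
    dh <- pmax(0L, as.integer(.roundHalfUp(spec$pDisorderHelical * L)) - cd)
    dl <- pmax(0L, as.integer(.roundHalfUp(spec$pDisorder * L)) - cd - dh)
    co <- as.integer(.roundHalfUp(spec$pCoilNotDisorder * L))
    gl <- L - cd - dh - dl - co
    short <- which(gl < 0L)
    for (i in short) {  # take the deficit out of the loop budget
        need <- -gl[i]
        give <- min(need, dl[i]); dl[i] <- dl[i] - give; need <- need - give
        if (need > 0L) { give <- min(need, dh[i]); dh[i] <- dh[i] - give }
        gl[i] <- L[i] - cd[i] - dh[i] - dl[i] - co[i]
    }
    budget <- cbind(globular = gl, disordered_loop = dl,
                    disordered_helical = dh, coil_disordered = cd,
                    coil_ordered = co)

    ## correction pass: pin pooled counts to the targets (rounding-exact)
    budget <- .adjustBudget(budget, "coil_disordered",
                            as.integer(.roundHalfUp(spec$pCoilAndDisorder * total)) -
                                sum(budget[, "coil_disordered"]))
    budget <- .adjustBudget(budget, "disordered_helical",
                            as.integer(.roundHalfUp(spec$pDisorderHelical * total)) -
                                sum(budget[, "coil_disordered"]) -
                                sum(budget[, "disordered_helical"]))
    budget <- .adjustBudget(budget, "disordered_loop",
                            as.integer(.roundHalfUp(spec$pDisorder * total)) -
                                sum(budget[, c("coil_disordered",
                                               "disordered_helical",
                                               "disordered_loop")]))
    budget <- .adjustBudget(budget, "coil_ordered",
                            as.integer(.roundHalfUp(spec$pCoilNotDisorder * total)) -
                                sum(budget[, "coil_ordered"]))

    ## segment layout, sequence and tracks per protein
    m <- spec$segmentMeanLengths
    seqs <- character(n)
    tracks <- vector("list", n)
    segments <- vector("list", n)
    for (i in seq_len(n)) {
        segTypes <- character(0)
        segLens <- integer(0)
        for (t in .SEGMENT_TYPES) {
            ct <- budget[i, t]
            if (ct == 0L) next
            k <- max(1L, as.integer(.roundHalfUp(ct / m[[t]])))
            k <- min(k, ct)
            parts <- .randomComposition(ct, k)
            segTypes <- c(segTypes, rep(t, k))
            segLens <- c(segLens, parts)
        }
        o <- sample.int(length(segTypes))
        segTypes <- segTypes[o]; segLens <- segLens[o]
        resid <- unlist(lapply(seq_along(segTypes), function(j)
            .sampleSegmentResidues(segTypes[j], segLens[j])),
            use.names = FALSE)
        typePer <- rep(segTypes, segLens)
        dv <- typePer %in% c("disordered_loop", "disordered_helical",
                             "coil_disordered")
        cv <- typePer %in% c("coil_disordered", "coil_ordered")
        sv <- character(L[i])
        sv[typePer %in% c("disordered_helical", "coil_disordered",
                          "coil_ordered")] <- "H"
        sv[typePer == "disordered_loop"] <- "C"
        glob <- which(typePer == "globular")
        if (length(glob)) {
            r <- rle(typePer == "globular")
            ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
            for (k in which(r$values))
                sv[starts[k]:ends[k]] <- .globularSS(r$lengths[k])
        }
        seqs[i] <- paste(resid, collapse = "")
        segEnds <- cumsum(segLens)
        segments[[i]] <- data.frame(protein_id = ids[i],
                                    start = segEnds - segLens + 1L,
                                    end = segEnds, type = segTypes)
        tracks[[i]] <- list(
            disorder = annotationTrack(ids[i], "disorder", dv, "builtin"),
            coil = annotationTrack(ids[i], "coil", cv, "builtin"),
            ss = annotationTrack(ids[i], "ss", sv, "builtin"))
    }
    names(tracks) <- ids
    names(segments) <- ids

    aa <- Biostrings::AAStringSet(seqs)
    names(aa) <- ids
    proteins <- new("ProteinSet", sequences = aa, geneId = ids,
                    setLabel = rep(setLabel, n),
                    isoformRank = rep(1L, n))

    realized <- c(
        p_disorder = sum(budget[, c("disordered_loop", "disordered_helical",
                                    "coil_disordered")]) / total,
        p_coil = sum(budget[, c("coil_disordered", "coil_ordered")]) / total,
        p_coil_and_disorder = sum(budget[, "coil_disordered"]) / total,
        p_coil_not_disorder = sum(budget[, "coil_ordered"]) / total,
        p_disorder_and_helical = sum(budget[, c("coil_disordered",
                                                "disordered_helical")]) / total)
    ledger <- list(targets = c(p_disorder = spec$pDisorder,
                               p_coil_and_disorder = spec$pCoilAndDisorder,
                               p_coil_not_disorder = spec$pCoilNotDisorder,
                               p_disorder_and_helical = spec$pDisorderHelical),
                   realized = realized,
                   nResidues = total,
                   perProtein = data.frame(protein_id = ids, length = L,
                                           budget),
                   segments = segments,
                   richIds = ids[rich])
    list(proteins = proteins, tracks = tracks, ledger = ledger)
}

## truncated-normal draw by clamping (keeps the mode sharp and bounded)
.clampNorm <- function(k, mean, sd, lo, hi) pmin(hi, pmax(lo, rnorm(k, mean, sd)))

#' Generate a synthetic template-hit table with known modeled coverage
#'
#' Places template hits preferentially on globular segments, calibrating
#' the hit probability and covered fraction against the realized segment
#' layout so that the expected modeled fraction of ordered residues equals
#' `spec$orderedCoverage` and that of disordered-or-coil residues equals
#' `spec$disorderedCoverage`. Sequence identity is drawn from the bimodal
#' low/high mixture; all generated hits satisfy the strict significance
#' filters (probability > 0.95, span > 30, identity > 0.20, or identity
#' > 0.70 in the high-identity channel), mirroring hits that survived an
#' upstream search.
#'
#' @param spec The `SyntheticSpec` used to generate the proteins.
#' @param sim Output of [sampleProteinSet()].
#' @return A list with `hits` (a data.frame usable with [filterHits()] /
#'   [greedySelect()]) and `impliedModeledFraction` (the exact union
#'   coverage of the generated hits over the whole set).
#' @export
sampleTemplateHits <- function(spec, sim) {
    stopifnot(inherits(spec, "SyntheticSpec"))
    oldSeed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(oldSeed))
        assign(".Random.seed", oldSeed, envir = globalenv()))
    set.seed(.subSeed(spec$seed, 2L))

    segAll <- do.call(rbind, sim$ledger$segments)
    segAll$len <- segAll$end - segAll$start + 1L
    isGlob <- segAll$type == "globular"
    elig <- segAll$len >= spec$minSpan
    gTotal <- sum(segAll$len[isGlob])
    dTotal <- sum(segAll$len[!isGlob])
    gElig <- sum(segAll$len[isGlob & elig])
    dElig <- sum(segAll$len[!isGlob & elig])
    pG <- 0.8; pD <- 0.15
    mfG <- if (gElig > 0)
        min(0.95, max(0.05, spec$orderedCoverage * gTotal / (pG * gElig)))
    else 0
    mfD <- if (dElig > 0)
        min(0.95, max(0.02, spec$disorderedCoverage * dTotal / (pD * dElig)))
    else 0
    ## re-calibrate the hit probabilities against the expected per-segment
    ## coverage (the minimum-span floor inflates short-segment coverage,
    ## which would otherwise bias the disordered-region target upwards)
    expCov <- function(p, mf, lens) {
        lo <- pmax(mf - 0.12, spec$minSpan / lens)
        hi <- pmin(mf + 0.12, 0.98)
        meanf <- ifelse(lo >= hi, lo, (lo + hi) / 2)
        p * sum(pmax(spec$minSpan, meanf * lens))
    }
    gLens <- segAll$len[isGlob & elig]
    dLens <- segAll$len[!isGlob & elig]
    if (gElig > 0 && expCov(pG, mfG, gLens) > 0)
        pG <- min(1, pG * spec$orderedCoverage * gTotal /
                         expCov(pG, mfG, gLens))
    if (dElig > 0 && expCov(pD, mfD, dLens) > 0)
        pD <- min(1, pD * spec$disorderedCoverage * dTotal /
                         expCov(pD, mfD, dLens))

    wLow <- spec$identityWeights[["low"]] / sum(spec$identityWeights)
    drawIdentity <- function(k) {
        low <- runif(k) < wLow
        out <- numeric(k)
        out[low] <- .clampNorm(sum(low), spec$identityLow[["mean"]],
                               spec$identityLow[["sd"]], 0.205, 0.295)
        out[!low] <- .clampNorm(sum(!low), spec$identityHigh[["mean"]],
                                spec$identityHigh[["sd"]], 0.705, 0.99)
        out
    }

    rows <- list()
    cnt <- 0L
    for (j in which(elig)) {
        glob <- isGlob[j]
        pHit <- if (glob) pG else pD
        if (runif(1) > pHit) next
        mf <- if (glob) mfG else mfD
        len <- segAll$len[j]
        lo <- max(mf - 0.12, spec$minSpan / len)
        hi <- min(mf + 0.12, 0.98)
        f <- if (lo >= hi) lo else runif(1, lo, hi)
        span <- min(len, max(spec$minSpan, as.integer(.roundHalfUp(f * len))))
        offset <- sample.int(len - span + 1L, 1L) - 1L
        cnt <- cnt + 1L
        idv <- drawIdentity(1L)
        rows[[cnt]] <- data.frame(
            query_id = segAll$protein_id[j],
            template_id = sprintf("T%05d", cnt),
            q_start = segAll$start[j] + offset,
            q_end = segAll$start[j] + offset + span - 1L,
            identity = idv,
            probability = runif(1, 0.955, 0.999),
            channel = if (idv > 0.70) "high_identity" else "hmm")
    }
    hits <- if (cnt > 0) do.call(rbind, rows) else
        data.frame(query_id = character(0), template_id = character(0),
                   q_start = integer(0), q_end = integer(0),
                   identity = numeric(0), probability = numeric(0),
                   channel = character(0))
    covered <- 0L
    if (nrow(hits)) {
        for (id in unique(hits$query_id)) {
            h <- hits[hits$query_id == id, ]
            covered <- covered + sum(IRanges::width(IRanges::reduce(
                IRanges::IRanges(h$q_start, h$q_end))))
        }
    }
    list(hits = hits,
         impliedModeledFraction = covered / sum(seqLengths(sim$proteins)))
}

#' Generate a random interaction graph with exact node and edge counts
#'
#' @param spec A `SyntheticSpec` (uses `nNodes`, `nEdges`, `networkModel`,
#'   `seed`).
#' @param nodeIds Optional character vector of node ids (length `nNodes`);
#'   defaults to `N001`, `N002`, ...
#' @return An [EdgeList] with exactly `nEdges` edges over `nNodes` nodes.
#' @export
sampleNetwork <- function(spec, nodeIds = NULL) {
    stopifnot(inherits(spec, "SyntheticSpec"))
    n <- spec$nNodes; mEdges <- spec$nEdges
    if (mEdges > n * (n - 1) / 2)
        .stopf("cannot place %d edges on %d nodes (max %d)",
               mEdges, n, n * (n - 1) / 2)
    if (is.null(nodeIds))
        nodeIds <- sprintf("N%03d", seq_len(n))
    if (length(nodeIds) != n)
        .stopf("nodeIds must have length %d", n)
    oldSeed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(oldSeed))
        assign(".Random.seed", oldSeed, envir = globalenv()))
    set.seed(.subSeed(spec$seed, 3L))
    g <- if (spec$networkModel == "gnm") {
        igraph::sample_gnm(n, mEdges, directed = FALSE)
    } else {
        g0 <- igraph::sample_pa(n, m = max(1L, floor(mEdges / n)),
                                directed = FALSE)
        ## adjust to the exact edge count
        cur <- igraph::gsize(g0)
        if (cur > mEdges) {
            drop <- sample.int(cur, cur - mEdges)
            g0 <- igraph::delete_edges(g0, drop)
        } else if (cur < mEdges) {
            need <- mEdges - cur
            while (need > 0L) {
                a <- sample.int(n, 1L); b <- sample.int(n, 1L)
                if (a != b && !igraph::are_adjacent(g0, a, b)) {
                    g0 <- igraph::add_edges(g0, c(a, b))
                    need <- need - 1L
                }
            }
        }
        g0
    }
    em <- igraph::as_edgelist(g, names = FALSE)
    a <- nodeIds[pmin(em[, 1], em[, 2])]
    b <- nodeIds[pmax(em[, 1], em[, 2])]
    o <- order(a, b, method = "radix")
    new("EdgeList", edges = data.frame(from = a[o], to = b[o]),
        nodes = nodeIds)
}

#' Write a complete synthetic bundle to a directory
#'
#' Emits everything a full pipeline run consumes: `proteins.fasta`, one
#' `tracks/<id>.<kind>.tsv` per ground-truth track, `hits.tsv`,
#' `edges.tsv` and `ground_truth.json` with the generator's exact realized
#' fractions.
#'
#' @param spec A `SyntheticSpec`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; the component objects are attached as
#'   attributes `sim`, `hits`, `network`.
#' @export
writeSimulation <- function(spec, dir) {
    stopifnot(inherits(spec, "SyntheticSpec"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sim <- sampleProteinSet(spec)
    th <- sampleTemplateHits(spec, sim)
    net <- sampleNetwork(spec)
    fa <- file.path(dir, "proteins.fasta")
    Biostrings::writeXStringSet(sequences(sim$proteins), fa)
    trackDir <- file.path(dir, "tracks")
    dir.create(trackDir, showWarnings = FALSE)
    for (id in names(sim$tracks))
        for (kind in names(sim$tracks[[id]]))
            writeTrack(sim$tracks[[id]][[kind]], sim$proteins,
                       file.path(trackDir, sprintf("%s.%s.tsv", id, kind)))
    write.table(th$hits, file.path(dir, "hits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(edges(net), file.path(dir, "edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    gt <- list(targets = as.list(sim$ledger$targets),
               realized = as.list(sim$ledger$realized),
               n_residues = sim$ledger$nResidues,
               implied_modeled_fraction = th$impliedModeledFraction,
               n_nodes = length(nodes(net)), n_edges = length(net),
               seed = spec$seed)
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out <- invisible(dir)
    attr(out, "sim") <- sim
    attr(out, "hits") <- th
    attr(out, "network") <- net
    out
}
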