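## template_coverage: template-hit filtering, greedy maximum-identical-
## residues selection with the 30-new-residue overlap allowance, and
## modeled-coverage accounting.

.checkHitFrame <- function(hits) {
    need <- c("query_id", "template_id", "q_start", "q_end",
              "identity", "probability", "channel")
    if (!all(need %in% names(hits)))
        .stopf("hit table must have columns: %s", paste(need, collapse = ", "))
    if (nrow(hits)) {
        if (any(hits$q_start > hits$q_end))
            .stopf("hit table: q_start > q_end at row %d",
                   which(hits$q_start > hits$q_end)[1L])
        .assertFraction(hits$identity, "identity")
        .assertFraction(hits$probability, "probability")
        if (!all(hits$channel %in% c("hmm", "high_identity")))
            .stopf("channel must be 'hmm' or 'high_identity'")
    }
    invisible(hits)
}

#' Number of identical residues of a template hit
#'
#' `round-half-up(identity * span)`; used as the greedy selection's ranking
#' criterion when the hit table does not carry an explicit count.
#'
#' @param identity Identity fraction(s) in `[0, 1]`.
#' @param spanLength Aligned query span length(s) in residues.
#' @return Integer vector of identical-residue counts.
#' @export
identicalResidues <- function(identity, spanLength) {
    .assertFraction(identity, "identity")
    as.integer(.roundHalfUp(identity * spanLength))
}

#' Filter template hits by channel-specific significance thresholds
#'
#' The profile-HMM search channel (`hmm`) keeps hits with true-positive
#' probability strictly above `probMin` (default 0.95), query span strictly
#' longer than `spanMin` residues (default 30) and sequence identity
#' strictly above `idMin` (default 20%, the conventional floor for
#' reliable homology models). The complementary high-identity channel
#' (`high_identity`, a BLAST-style search against the unclustered PDB)
#' keeps hits with identity strictly above `highIdMin` (default 70%).
#'
#' @param hits data.frame with columns `query_id`, `template_id`,
#'   `q_start`, `q_end`, `identity`, `probability`, `channel` (and
#'   optionally `identical_residues`).
#' @param probMin,spanMin,idMin,highIdMin Thresholds as above; all strict.
#' @return The retained rows of `hits`.
#' @export
filterHits <- function(hits, probMin = 0.95, spanMin = 30L, idMin = 0.20,
                       highIdMin = 0.70) {
    .checkHitFrame(hits)
    if (!nrow(hits)) return(hits)
    span <- hits$q_end - hits$q_start + 1L
    keep <- ifelse(hits$channel == "hmm",
                   hits$probability > probMin & span > spanMin &
                       hits$identity > idMin,
                   hits$identity > highIdMin)
    hits[keep, , drop = FALSE]
}

#' Greedy template selection maximizing identical residues
#'
#' For one query protein, hits are ranked by identical-residue count
#' (explicit `identical_residues` column when present, otherwise
#' `round-half-up(identity * span)`), with ties broken by longer span,
#' then lexicographic template id, then query start, making the order
#' total and the result invariant to input permutation. The top hit is
#' accepted; every later hit is accepted iff it contributes at least
#' `minNew` query residues (default 30) not covered by previously
#' accepted hits. Accepted fragments with identity at or above 95% are
#' flagged `retrieve_only` (an existing structure would be fetched rather
#' than modeled); the maximum template-free gap length bridged during
#' modeling is recorded as metadata.
#'
#' @param hits data.frame of (already filtered) hits for a single query.
#' @param minNew Minimum number of new residues an overlapping template
#'   must contribute (default 30, inclusive).
#' @return The accepted rows, in acceptance order, with added columns
#'   `identical_residues`, `new_residues` (contributed at acceptance
#'   time), `retrieve_only`, `max_gap_modeled`; the union coverage is
#'   attached as `attr(, "coverage")` (an [IRanges::IRanges]).
#' @export
greedySelect <- function(hits, minNew = 30L) {
    .checkHitFrame(hits)
    if (!nrow(hits)) {
        hits$identical_residues <- integer(0)
        hits$new_residues <- integer(0)
        hits$retrieve_only <- logical(0)
        hits$max_gap_modeled <- integer(0)
        attr(hits, "coverage") <- IRanges::IRanges()
        return(hits)
    }
    if (length(unique(hits$query_id)) != 1L)
        .stopf("greedySelect expects hits for a single query protein")
    span <- hits$q_end - hits$q_start + 1L
    ident <- if ("identical_residues" %in% names(hits) &&
                 !all(is.na(hits$identical_residues))) {
        given <- hits$identical_residues
        derived <- identicalResidues(hits$identity, span)
        ifelse(is.na(given), derived, as.integer(given))
    } else {
        identicalResidues(hits$identity, span)
    }
    o <- order(-ident, -span, hits$template_id, hits$q_start,
               method = "radix")
    hits <- hits[o, , drop = FALSE]
    ident <- ident[o]
    maxEnd <- max(hits$q_end)
    covered <- rep(FALSE, maxEnd)
    accept <- logical(nrow(hits))
    newRes <- integer(nrow(hits))
    for (i in seq_len(nrow(hits))) {
        idx <- hits$q_start[i]:hits$q_end[i]
        contrib <- sum(!covered[idx])
        if (i == 1L || contrib >= minNew) {
            accept[i] <- TRUE
            newRes[i] <- contrib
            covered[idx] <- TRUE
        }
    }
    out <- hits[accept, , drop = FALSE]
    out$identical_residues <- ident[accept]
    out$new_residues <- newRes[accept]
    out$retrieve_only <- out$identity >= 0.95
    out$max_gap_modeled <- 6L
    rownames(out) <- NULL
    attr(out, "coverage") <- IRanges::reduce(
        IRanges::IRanges(start = out$q_start, end = out$q_end))
    out
}

#' Modeled-coverage accounting over a protein set
#'
#' Derives a `modeled` track per protein from accepted template spans and
#' summarises: per-protein modeled fraction and fragment count; the
#' set-level modeled residue fraction; the 2x2 residue cross-tabulation of
#' modeled status against disordered-or-coiled-coil status with its
#' conditional fractions (e.g. the fraction of ordered-region residues
#' that could be modeled, and the fraction of unmodeled residues that are
#' disordered or coil); and the identity histogram of accepted fragments
#' with the counts below 30% and above 90% identity. Degenerate
#' cross-tabulation cells (empty denominators) are reported as `NA`.
#'
#' @param accepted Named list (protein id) of accepted-hit data.frames
#'   from [greedySelect()]; proteins without hits may be missing or empty.
#' @param tracks A track bundle with `disorder` and `coil` tracks.
#' @param lengths Named integer vector of protein lengths (e.g.
#'   `seqLengths(proteins)`).
#' @param identityBinWidth Histogram bin width on the identity scale
#'   (default 0.10).
#' @return A list with `perProtein` (data.frame), `modeledFraction`,
#'   `crossTab` (2x2 counts), `conditionals` (named fractions),
#'   `identityHistogram`, `nBelow30`, `nAbove90`, and `modeledTracks`
#'   (a list of `modeled` [AnnotationTrack]s keyed by protein id).
#' @export
coverageSummary <- function(accepted, tracks, lengths,
                            identityBinWidth = 0.10) {
    ids <- names(lengths)
    if (is.null(ids)) .stopf("lengths must be a named vector")
    modeledTracks <- list()
    per <- lapply(ids, function(id) {
        n <- lengths[[id]]
        mv <- rep(FALSE, n)
        hits <- accepted[[id]]
        k <- 0L
        if (!is.null(hits) && nrow(hits)) {
            for (i in seq_len(nrow(hits)))
                mv[hits$q_start[i]:min(hits$q_end[i], n)] <- TRUE
            k <- nrow(hits)
        }
        modeledTracks[[id]] <<- annotationTrack(id, "modeled", mv,
                                                source = "builtin")
        data.frame(protein_id = id, length = n, n_models = k,
                   modeled_fraction = sum(mv) / n)
    })
    per <- do.call(rbind, per)
    ## residue-level cross-tab modeled x (disorder | coil)
    tab <- matrix(0, 2, 2,
                  dimnames = list(modeled = c("modeled", "unmodeled"),
                                  region = c("d_or_c", "ordered")))
    for (id in ids) {
        dv <- trackValues(.getTrack(tracks, id, "disorder"))
        cv <- trackValues(.getTrack(tracks, id, "coil"))
        mv <- trackValues(modeledTracks[[id]])
        dc <- dv | cv
        tab["modeled", "d_or_c"] <- tab["modeled", "d_or_c"] + sum(mv & dc)
        tab["modeled", "ordered"] <- tab["modeled", "ordered"] + sum(mv & !dc)
        tab["unmodeled", "d_or_c"] <- tab["unmodeled", "d_or_c"] + sum(!mv & dc)
        tab["unmodeled", "ordered"] <- tab["unmodeled", "ordered"] +
            sum(!mv & !dc)
    }
    n <- sum(tab)
    safeDiv <- function(a, b) if (b > 0) a / b else NA_real_
    conditionals <- c(
        p_modeled = safeDiv(sum(tab["modeled", ]), n),
        p_d_or_c = safeDiv(sum(tab[, "d_or_c"]), n),
        p_modeled_given_ordered = safeDiv(tab["modeled", "ordered"],
                                          sum(tab[, "ordered"])),
        p_modeled_given_d_or_c = safeDiv(tab["modeled", "d_or_c"],
                                         sum(tab[, "d_or_c"])),
        p_d_or_c_given_unmodeled = safeDiv(tab["unmodeled", "d_or_c"],
                                           sum(tab["unmodeled", ])),
        p_ordered_given_modeled = safeDiv(tab["modeled", "ordered"],
                                          sum(tab["modeled", ])))
    allHits <- do.call(rbind, lapply(accepted, function(h)
        if (!is.null(h) && nrow(h)) h[, c("identity"), drop = FALSE]))
    breaks <- seq(0, 1, by = identityBinWidth)
    if (max(breaks) < 1) breaks <- c(breaks, 1)
    idHist <- if (!is.null(allHits) && nrow(allHits))
        table(cut(allHits$identity, breaks = breaks,
                  include.lowest = TRUE, right = FALSE))
    else NULL
    list(perProtein = per,
         modeledFraction = safeDiv(sum(tab["modeled", ]), n),
         crossTab = tab,
         conditionals = conditionals,
         identityHistogram = idHist,
         nBelow30 = if (!is.null(allHits)) sum(allHits$identity < 0.30) else 0L,
         nAbove90 = if (!is.null(allHits)) sum(allHits$identity > 0.90) else 0L,
         modeledTracks = modeledTracks)
}
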