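## domain_segmentation: the putative-globular-domain selection procedure.
## A sequence is partitioned, with decreasing priority, into merged SMART
## domains, coiled-coil stretches (maximal runs of more than `minRun`
## predicted coil residues), disordered stretches (same rule on the
## disorder track) and residual regions. When a higher-priority interval
## truncates a stretch, the "more than `minRun` residues" test is
## re-applied to every surviving piece, so a truncated remnant of 20 or
## fewer residues reverts to residual.

.maskToIntervals <- function(mask) .trueRuns(mask, 0L)

#' Partition a protein sequence by annotation priority
#'
#' Produces an ordered, non-overlapping partition of `[1, L]` into
#' `smart_domain` (overlapping SMART rows merged into their union, with a
#' warning), `coil_stretch`, `disorder_stretch` and `residual` intervals,
#' applying the priority SMART > coil > disorder > residual and re-testing
#' the strict `> minRun` run-length rule on truncated stretch pieces.
#'
#' @param protein A single-protein [ProteinSet] (or larger set plus
#'   `proteinId`).
#' @param smart data.frame of SMART intervals for this protein (as from
#'   [importDomainTable()]); may be empty or `NULL`.
#' @param coilTrack,disorderTrack Boolean [AnnotationTrack]s aligned to the
#'   protein.
#' @param minRun Strict run-length threshold for stretches (default 20).
#' @param proteinId Protein to partition (defaults to the only one present).
#' @return data.frame with columns `protein_id`, `start`, `end`, `type`,
#'   covering every residue exactly once, in sequence order.
#' @export
partitionSequence <- function(protein, smart = NULL, coilTrack,
                              disorderTrack, minRun = 20L,
                              proteinId = NULL) {
    stopifnot(is(protein, "ProteinSet"))
    if (is.null(proteinId)) {
        stopifnot(length(protein) == 1L)
        proteinId <- proteinIds(protein)
    }
    n <- unname(seqLengths(protein)[proteinId])
    cv <- trackValues(coilTrack)
    dv <- trackValues(disorderTrack)
    if (length(cv) != n || length(dv) != n)
        .stopf("tracks must align with protein '%s' (%d residues)",
               proteinId, n)
    minRun <- as.integer(minRun)

    smartMask <- rep(FALSE, n)
    if (!is.null(smart) && nrow(smart)) {
        smart <- smart[smart$protein_id == proteinId, , drop = FALSE]
        if (nrow(smart)) {
            ir <- IRanges::IRanges(start = smart$start, end = smart$end)
            red <- IRanges::reduce(ir)
            if (length(red) < length(ir))
                .warnf("merged %d overlapping/adjacent SMART interval(s) for '%s'",
                       length(ir) - length(red), proteinId)
            for (k in seq_along(red))
                smartMask[IRanges::start(red)[k]:IRanges::end(red)[k]] <- TRUE
        }
    }

    ## coil stretches: runs > minRun on the raw track, truncated by SMART,
    ## surviving pieces re-tested against > minRun
    stretchMask <- function(values, higher) {
        cand <- rep(FALSE, n)
        runs <- .trueRuns(values, minRun)
        for (k in seq_len(nrow(runs)))
            cand[runs$start[k]:runs$end[k]] <- TRUE
        cand[higher] <- FALSE
        out <- rep(FALSE, n)
        pieces <- .trueRuns(cand, minRun)
        for (k in seq_len(nrow(pieces)))
            out[pieces$start[k]:pieces$end[k]] <- TRUE
        out
    }
    coilMask <- stretchMask(cv, smartMask)
    disMask <- stretchMask(dv, smartMask | coilMask)

    label <- rep("residual", n)
    label[disMask] <- "disorder_stretch"
    label[coilMask] <- "coil_stretch"
    label[smartMask] <- "smart_domain"
    r <- rle(label)
    ends <- cumsum(r$lengths)
    data.frame(protein_id = proteinId,
               start = ends - r$lengths + 1L, end = ends,
               type = r$values)
}

#' Call putative globular domains on a partitioned sequence
#'
#' Applies the two globular-domain conditions to a partition from
#' [partitionSequence()]:
#' \enumerate{
#'   \item a `smart_domain` interval with significant evidence spanning at
#'     least `smartMinLen` residues (inclusive, default 30);
#'   \item a `residual` interval strictly longer than `regionMin` residues
#'     (default 40) whose structure-alignment Z score exceeds `zCut`
#'     (default 3) and whose local disordered-or-coiled-coil residue
#'     fraction is strictly below `dcMax` (default 30%).
#' }
#' Everything else is rejected with a reason: `not_candidate` (coil or
#' disorder stretches), `too_short`, `low_Z`, `too_disordered`, or
#' `missing_evidence` when an eligible residual region has no alignment
#' record (logged via `message()`, never an exception).
#'
#' @param partition data.frame from [partitionSequence()].
#' @param disorderTrack,coilTrack The tracks used for the local
#'   disorder/coil fraction of residual regions.
#' @param zscores Optional data.frame with columns `protein_id`, `start`,
#'   `end`, `z` (and optionally `match_length`, carried as evidence),
#'   matched to residual intervals by exact coordinates.
#' @param smart Optional data.frame of SMART rows (as imported) used to
#'   look up domain-name/significance evidence for `smart_domain`
#'   intervals; when absent, merged SMART intervals are treated as
#'   significant.
#' @param smartMinLen Inclusive minimum SMART match length (default 30).
#' @param zCut Strict Z-score threshold (default 3).
#' @param regionMin Strict minimum residual-region length for condition 2
#'   eligibility (default 40).
#' @param dcMax Strict upper bound on the local disorder/coil fraction
#'   (default 0.30).
#' @param dcMode `"union"` (default: a residue counts once if disordered
#'   or coil) or `"sum"` (disordered and coil residues counted
#'   additively, possibly double-counting).
#' @return data.frame with columns `protein_id`, `start`, `end`, `type`,
#'   `verdict` (`globular_condition1`, `globular_condition2`, `rejected`),
#'   `reason`, `z`, `dc_fraction`.
#' @export
callGlobular <- function(partition, disorderTrack, coilTrack,
                         zscores = NULL, smart = NULL,
                         smartMinLen = 30L, zCut = 3, regionMin = 40L,
                         dcMax = 0.30, dcMode = c("union", "sum")) {
    dcMode <- match.arg(dcMode)
    dv <- trackValues(disorderTrack)
    cv <- trackValues(coilTrack)
    nMissing <- 0L
    out <- lapply(seq_len(nrow(partition)), function(i) {
        p <- partition[i, ]
        len <- p$end - p$start + 1L
        verdict <- "rejected"; reason <- "not_candidate"
        z <- NA_real_; dcf <- NA_real_
        if (p$type == "smart_domain") {
            sig <- TRUE
            if (!is.null(smart) && nrow(smart)) {
                rows <- smart[smart$protein_id == p$protein_id &
                              smart$start <= p$end & smart$end >= p$start, ,
                              drop = FALSE]
                if (nrow(rows)) sig <- any(rows$significant)
            }
            if (!sig) {
                reason <- "missing_evidence"
            } else if (len >= smartMinLen) {
                verdict <- "globular_condition1"; reason <- "none"
            } else reason <- "too_short"
        } else if (p$type == "residual") {
            if (len <= regionMin) {
                reason <- "too_short"
            } else {
                zrow <- NULL
                if (!is.null(zscores) && nrow(zscores)) {
                    zrow <- zscores[zscores$protein_id == p$protein_id &
                                    zscores$start == p$start &
                                    zscores$end == p$end, , drop = FALSE]
                }
                if (is.null(zrow) || nrow(zrow) == 0L) {
                    reason <- "missing_evidence"
                    nMissing <<- nMissing + 1L
                } else {
                    z <- max(zrow$z)
                    idx <- p$start:p$end
                    dcf <- if (dcMode == "union")
                        mean(dv[idx] | cv[idx])
                    else (sum(dv[idx]) + sum(cv[idx])) / len
                    if (z <= zCut) {
                        reason <- "low_Z"
                    } else if (dcf >= dcMax) {
                        reason <- "too_disordered"
                    } else {
                        verdict <- "globular_condition2"; reason <- "none"
                    }
                }
            }
        }
        data.frame(protein_id = p$protein_id, start = p$start, end = p$end,
                   type = p$type, verdict = verdict, reason = reason,
                   z = z, dc_fraction = dcf)
    })
    if (nMissing > 0L)
        message(sprintf("callGlobular: %d eligible residual region(s) had no alignment record (rejected as missing_evidence)",
                        nMissing))
    do.call(rbind, out)
}

#' Discard domain calls with high identity to known structures
#'
#' Calls whose best PDB sequence identity strictly exceeds `maxIdentity`
#' (default 40%) are re-flagged `rejected` with reason `high_identity`;
#' calls with no identity record are retained unchanged.
#'
#' @param calls data.frame from [callGlobular()].
#' @param pdbIdentity Numeric vector of identity fractions in `[0, 1]`
#'   (NA = no record), one per call row.
#' @param maxIdentity Strict discard threshold (default 0.40).
#' @return `calls` with an added `pdb_identity` column and updated
#'   `verdict`/`reason`.
#' @export
identityFilter <- function(calls, pdbIdentity, maxIdentity = 0.40) {
    if (length(pdbIdentity) != nrow(calls))
        .stopf("pdbIdentity must have one value per call")
    .assertFraction(pdbIdentity[!is.na(pdbIdentity)], "pdbIdentity")
    calls$pdb_identity <- pdbIdentity
    drop <- !is.na(pdbIdentity) & pdbIdentity > maxIdentity &
        calls$verdict != "rejected"
    calls$verdict[drop] <- "rejected"
    calls$reason[drop] <- "high_identity"
    calls
}
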