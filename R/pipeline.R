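## pipeline: end-to-end orchestration from a single structured config
## (YAML file or R list) to per-protein tables, set-level summaries and a
## machine-readable JSON report. Every decision threshold defaults to the
## value used throughout the package's decision rules, so an empty
## override reproduces them exactly.

.defaultConfig <- function() {
    list(fasta = NULL, set_label = "study", tracks_dir = NULL,
         smart = NULL, zscores = NULL, hits = NULL, edges = NULL,
         out_dir = NULL,
         thresholds = list(min_run = 20L, dual_coverage = 0.20,
                           smart_min = 30L, region_min = 40L, z_cut = 3,
                           dc_max = 0.30, identity_discard = 0.40,
                           prob_min = 0.95, span_min = 30L, id_min = 0.20,
                           high_id_min = 0.70, overlap_new = 30L,
                           disorder_cutoff = 0.5, coil_cutoff = 0.5),
         n_boot = 1000L, seed = 1L)
}

.mergeConfig <- function(user) {
    cfg <- .defaultConfig()
    for (nm in names(user)) {
        if (nm == "thresholds") {
            for (t in names(user$thresholds))
                cfg$thresholds[[t]] <- user$thresholds[[t]]
        } else cfg[[nm]] <- user[[nm]]
    }
    cfg
}

## import one protein's tracks from a directory of <id>.<kind>.tsv files
.importTrackDir <- function(dir, proteins) {
    tracks <- list()
    for (id in proteinIds(proteins)) {
        bundle <- list()
        for (kind in c("disorder", "coil", "ss", "modeled")) {
            f <- file.path(dir, sprintf("%s.%s.tsv", id, kind))
            if (file.exists(f))
                bundle[[kind]] <- importTrack(f, "generic_tsv", proteins,
                                              proteinId = id, kind = kind)
        }
        if (length(bundle)) tracks[[id]] <- bundle
    }
    tracks
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes import, track acquisition, joint-annotation statistics, domain
#' segmentation, template-coverage accounting and network analysis,
#' skipping (with a log entry) any stage whose optional inputs are absent.
#' The FASTA input is required and checked before any stage runs; the
#' longest-isoform convention is applied on import. When no track
#' directory is given, the built-in predictors supply disorder and coil
#' tracks (flagged `source = "builtin"` throughout the report).
#'
#' @param config A YAML file path or a named list. Recognised fields:
#'   `fasta` (required), `set_label`, `tracks_dir`, `smart`, `zscores`,
#'   `hits`, `edges`, `out_dir`, `thresholds` (named overrides), `n_boot`,
#'   `seed`.
#' @return A list with the `report` (also written as `report.json` when
#'   `out_dir` is set), the computed objects (`stats`, `fractions`,
#'   `calls`, `coverage`, `network`) and the paths written.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) {
        if (!file.exists(config)) .stopf("config file not found: %s", config)
        config <- yaml::read_yaml(config)
    }
    cfg <- .mergeConfig(config)
    th <- cfg$thresholds
    if (is.null(cfg$fasta) || !file.exists(cfg$fasta))
        .stopf("required input missing: fasta (%s)",
               if (is.null(cfg$fasta)) "not set" else cfg$fasta)
    for (nm in c("smart", "zscores", "hits", "edges")) {
        if (!is.null(cfg[[nm]]) && !file.exists(cfg[[nm]]))
            .stopf("configured input '%s' does not exist: %s", nm, cfg[[nm]])
    }

    proteins <- selectLongestIsoform(
        readProteinSet(cfg$fasta, cfg$set_label))
    lens <- seqLengths(proteins)
    log <- character(0)
    note <- function(msg) {
        message("runPipeline: ", msg)
        log <<- c(log, msg)
    }
    note(sprintf("imported %d protein(s) (longest isoform per gene) from %s",
                 length(proteins), cfg$fasta))

    ## tracks
    if (!is.null(cfg$tracks_dir)) {
        tracks <- .importTrackDir(cfg$tracks_dir, proteins)
        note(sprintf("imported tracks for %d protein(s) from %s",
                     length(tracks), cfg$tracks_dir))
    } else {
        note("no tracks_dir configured: using builtin predictor tracks (disorder + coil only)")
        hp <- heptadParams()
        cp <- chargeHydropathyParams()
        tracks <- lapply(proteinIds(proteins), function(id)
            list(disorder = disorderIndexTrack(proteins, cp, proteinId = id),
                 coil = suppressWarnings(
                     coilScoreTrack(proteins, hp, proteinId = id))))
        names(tracks) <- proteinIds(proteins)
    }
    haveSS <- all(vapply(tracks, function(x) !is.null(x$ss), TRUE))

    ## joint statistics
    stats <- jointResidueCounts(tracks)
    fractions <- perProteinFractions(tracks, dualThreshold = th$dual_coverage)
    ssStats <- if (haveSS) ssClassFractions(tracks) else NULL
    if (!haveSS) note("no ss tracks: secondary-structure statistics skipped")

    ## segmentation
    smart <- if (!is.null(cfg$smart))
        importDomainTable(cfg$smart, proteins) else NULL
    zs <- if (!is.null(cfg$zscores))
        read.table(cfg$zscores, header = TRUE, sep = "\t",
                   comment.char = "#", stringsAsFactors = FALSE) else NULL
    calls <- do.call(rbind, lapply(proteinIds(proteins), function(id) {
        part <- partitionSequence(proteins, smart,
                                  tracks[[id]]$coil, tracks[[id]]$disorder,
                                  minRun = th$min_run, proteinId = id)
        callGlobular(part, tracks[[id]]$disorder, tracks[[id]]$coil,
                     zscores = zs, smart = smart,
                     smartMinLen = th$smart_min, zCut = th$z_cut,
                     regionMin = th$region_min, dcMax = th$dc_max)
    }))

    ## template coverage
    coverage <- NULL
    if (!is.null(cfg$hits)) {
        hits <- read.table(cfg$hits, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
        ok <- tryCatch(.checkHitFrame(hits), error = function(e)
            .stopf("coverage stage failed on hit table '%s': %s",
                   cfg$hits, conditionMessage(e)))
        kept <- filterHits(hits, probMin = th$prob_min,
                           spanMin = th$span_min, idMin = th$id_min,
                           highIdMin = th$high_id_min)
        accepted <- lapply(split(kept, kept$query_id), greedySelect,
                           minNew = th$overlap_new)
        coverage <- coverageSummary(accepted, tracks, lens)
        note(sprintf("coverage: %d/%d hits retained, set-level modeled fraction %.3f",
                     nrow(kept), nrow(hits), coverage$modeledFraction))
    } else note("no hit table configured: coverage stage skipped")

    ## network
    network <- NULL
    if (!is.null(cfg$edges)) {
        el <- importEdgeList(cfg$edges)
        gm <- graphMetrics(el, totalNodes = length(proteins))
        disFrac <- setNames(fractions$fractions$f_disorder_and_coil +
                            fractions$fractions$f_disorder_not_coil,
                            fractions$fractions$protein_id)
        network <- list(metrics = gm,
                        report = centralityReport(gm, disFrac))
    } else note("no edge list configured: network stage skipped")

    report <- list(
        config = cfg,
        package_version = as.character(utils::packageVersion("centroshape")),
        n_proteins = length(proteins),
        track_source = stats@source,
        joint_stats = c(list(n_residues = nResidues(stats)),
                        as.list(jointProbabilities(stats)),
                        list(propensity = propensityValue(stats))),
        n_dual_above_threshold = fractions$nDualAboveThreshold,
        ss_stats = if (!is.null(ssStats))
            list(class_fractions = as.list(ssStats$classFractions),
                 p_disorder_and = as.list(ssStats$pDisorderAnd),
                 conditional_given_disorder =
                     as.list(ssStats$conditionalGivenDisorder)) else NULL,
        domain_calls = list(
            n_intervals = nrow(calls),
            n_globular = sum(calls$verdict != "rejected"),
            by_verdict = as.list(table(calls$verdict))),
        coverage = if (!is.null(coverage))
            list(modeled_fraction = coverage$modeledFraction,
                 conditionals = as.list(coverage$conditionals),
                 n_below_30 = coverage$nBelow30,
                 n_above_90 = coverage$nAbove90) else NULL,
        network = if (!is.null(network))
            list(n_nodes = network$metrics$nNodes,
                 n_edges = network$metrics$nEdges,
                 avg_degree = network$metrics$avgDegree,
                 avg_degree_full_set = network$metrics$avgDegreeFullSet,
                 avg_clustering = network$metrics$avgClustering,
                 top_nodes = head(network$report$id, 10L)) else NULL,
        log = log)

    paths <- character(0)
    if (!is.null(cfg$out_dir)) {
        dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
        wtsv <- function(df, name) {
            p <- file.path(cfg$out_dir, name)
            write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
            p
        }
        paths <- c(wtsv(fractions$fractions, "per_protein_fractions.tsv"),
                   wtsv(calls, "domain_calls.tsv"))
        if (!is.null(coverage))
            paths <- c(paths, wtsv(coverage$perProtein, "coverage.tsv"))
        if (!is.null(network))
            paths <- c(paths, wtsv(network$report, "network.tsv"))
        rp <- file.path(cfg$out_dir, "report.json")
        jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = 10,
                             pretty = TRUE, null = "null")
        paths <- c(paths, rp)
    }
    list(report = report, stats = stats, fractions = fractions,
         ssStats = ssStats, calls = calls, coverage = coverage,
         network = network, paths = paths)
}
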