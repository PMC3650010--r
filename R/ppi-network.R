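## ppi_network: undirected interaction-graph metrics. The graph machinery
## (degree, local clustering, betweenness) is delegated to igraph; this
## module fixes the conventions: betweenness is the unnormalized count of
## shortest paths over unordered node pairs excluding endpoints, with
## fractional credit when several shortest paths exist, computed within
## connected components; the average clustering coefficient is the mean of
## local coefficients with degree < 2 nodes contributing 0.

#' Compute degree, clustering and betweenness centrality for a network
#'
#' @param edgeList An [EdgeList] (e.g. from [importEdgeList()] or
#'   [sampleNetwork()]).
#' @param normalized Also report betweenness divided by
#'   `(n-1)(n-2)/2` (default `FALSE` adds only the raw values).
#' @param totalNodes Optional size of the full protein set (e.g. 361 when
#'   only 167 proteins interact); when given, `avgDegreeFullSet`
#'   (`2E / totalNodes`) is reported alongside the interacting-subset
#'   average degree `2E / V`. The two conventions can differ substantially
#'   and both are reported.
#' @return A list with `perNode` (data.frame: `id`, `degree`,
#'   `clustering`, `betweenness`[, `betweenness_normalized`]), `nNodes`,
#'   `nEdges`, `avgDegree`, `avgClustering` and optionally
#'   `avgDegreeFullSet`.
#' @export
graphMetrics <- function(edgeList, normalized = FALSE, totalNodes = NULL) {
    stopifnot(is(edgeList, "EdgeList"))
    e <- edges(edgeList)
    nds <- nodes(edgeList)
    if (length(nds) == 0L) .stopf("empty graph")
    g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                       vertices = data.frame(name = nds))
    deg <- igraph::degree(g)
    btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
    clu <- igraph::transitivity(g, type = "local", isolates = "zero")
    names(clu) <- igraph::V(g)$name
    clu[deg < 2] <- 0
    per <- data.frame(id = igraph::V(g)$name,
                      degree = unname(deg),
                      clustering = unname(clu),
                      betweenness = unname(btw))
    if (normalized) {
        nn <- length(nds)
        denom <- if (nn > 2) (nn - 1) * (nn - 2) / 2 else NA_real_
        per$betweenness_normalized <- per$betweenness / denom
    }
    out <- list(perNode = per,
                nNodes = length(nds),
                nEdges = nrow(e),
                avgDegree = 2 * nrow(e) / length(nds),
                avgClustering = mean(clu))
    if (!is.null(totalNodes))
        out$avgDegreeFullSet <- 2 * nrow(e) / totalNodes
    out
}

#' Rank network nodes by betweenness centrality
#'
#' Nodes are ordered by decreasing betweenness, ties broken by decreasing
#' degree and then by id; each row is annotated with the protein's
#' disorder fraction where available (`NA` when absent).
#'
#' @param metrics Output of [graphMetrics()].
#' @param disorderFractions Optional named numeric vector: fraction of
#'   each protein's length predicted disordered.
#' @return data.frame `id`, `degree`, `betweenness`, `clustering`,
#'   `disorder_fraction`, in rank order.
#' @export
centralityReport <- function(metrics, disorderFractions = NULL) {
    per <- metrics$perNode
    o <- order(-per$betweenness, -per$degree, per$id, method = "radix")
    per <- per[o, c("id", "degree", "betweenness", "clustering")]
    per$disorder_fraction <- if (is.null(disorderFractions)) NA_real_
        else unname(disorderFractions[per$id])
    rownames(per) <- NULL
    per
}
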