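## Independent brute-force oracles. These re-derive expected results by the
## most direct possible route (explicit enumeration / per-residue painting)
## and deliberately share no code with the package implementation.

## --- coiled-coil heptad scoring: enumerate every window x register ------
bruteCoilScores <- function(seqChars, params) {
    n <- length(seqChars)
    w <- params$window
    groupOf <- c("core", "other", "other", "core", "edge", "other", "edge")
    best <- rep(-Inf, n)
    if (n < w) return(rep(0, n))
    for (s in 1:(n - w + 1)) {
        for (r in 0:6) {
            vals <- numeric(w)
            for (k in 1:w) {
                pos <- ((s + k - 1 - 1 + r) %% 7) + 1
                res <- seqChars[s + k - 1]
                vals[k] <- params$positionWeights[pos] *
                    params$residuePropensities[[groupOf[pos]]][[res]]
            }
            sc <- exp(mean(log(vals)))
            idx <- s:(s + w - 1)
            best[idx] <- pmax(best[idx], sc)
        }
    }
    best
}

## --- priority partition: paint labels residue by residue ----------------
brutePartitionLabels <- function(L, smartRows, coilVals, disVals,
                                 minRun = 20L) {
    lab <- rep("residual", L)
    smartPos <- integer(0)
    if (!is.null(smartRows) && nrow(smartRows))
        for (k in seq_len(nrow(smartRows)))
            smartPos <- union(smartPos, smartRows$start[k]:smartRows$end[k])
    paintStretches <- function(vals, blocked, label) {
        ## raw runs of > minRun, then re-test each piece left after
        ## removing blocked positions
        i <- 1L
        while (i <= L) {
            if (!vals[i]) { i <- i + 1L; next }
            j <- i
            while (j < L && vals[j + 1L]) j <- j + 1L
            if (j - i + 1L > minRun) {
                free <- setdiff(i:j, blocked)
                if (length(free)) {
                    ## maximal contiguous pieces of the free positions
                    brk <- c(0L, which(diff(free) != 1L), length(free))
                    for (b in seq_len(length(brk) - 1L)) {
                        piece <- free[(brk[b] + 1L):brk[b + 1L]]
                        if (length(piece) > minRun)
                            lab[piece] <<- label
                    }
                }
            }
            i <- j + 1L
        }
    }
    environment(paintStretches) <- environment()
    paintStretches(coilVals, smartPos, "coil_stretch")
    coilPos <- which(lab == "coil_stretch")
    paintStretches(disVals, union(smartPos, coilPos), "disorder_stretch")
    lab[smartPos] <- "smart_domain"
    lab
}

## --- globular-call rules, re-stated verbatim -----------------------------
bruteGlobularVerdict <- function(type, len, significant, z, dcFraction,
                                 smartMinLen = 30, zCut = 3,
                                 regionMin = 40, dcMax = 0.30) {
    if (type == "smart_domain") {
        if (significant && len >= smartMinLen) return("globular_condition1")
        return("rejected")
    }
    if (type == "residual") {
        if (len > regionMin && !is.na(z) && z > zCut &&
            !is.na(dcFraction) && dcFraction < dcMax)
            return("globular_condition2")
        return("rejected")
    }
    "rejected"
}

## --- betweenness: enumerate every shortest path explicitly --------------
## adj: n x n logical adjacency matrix (undirected, no loops)
bruteBetweenness <- function(adj) {
    n <- nrow(adj)
    btw <- rep(0, n)
    dist <- function(s) {  # BFS distances
        d <- rep(Inf, n); d[s] <- 0
        q <- s
        while (length(q)) {
            v <- q[1]; q <- q[-1]
            for (u in which(adj[v, ]))
                if (d[u] > d[v] + 1) { d[u] <- d[v] + 1; q <- c(q, u) }
        }
        d
    }
    allShortestPaths <- function(s, t, d) {
        ## DFS over the shortest-path DAG, collecting full paths
        paths <- list()
        walk <- function(v, path) {
            if (v == t) { paths[[length(paths) + 1L]] <<- path; return() }
            for (u in which(adj[v, ]))
                if (d[u] == d[v] + 1 && d[u] <= d[t])
                    walk(u, c(path, u))
        }
        walk(s, s)
        paths
    }
    for (s in 1:(n - 1)) {
        d <- dist(s)
        for (t in (s + 1):n) {
            if (!is.finite(d[t]) || d[t] < 2) next
            paths <- allShortestPaths(s, t, d)
            npath <- length(paths)
            for (p in paths) {
                interior <- p[-c(1, length(p))]
                btw[interior] <- btw[interior] + 1 / npath
            }
        }
    }
    btw
}

## random adjacency matrix on n nodes with edge probability p
randomAdjacency <- function(n, p) {
    adj <- matrix(FALSE, n, n)
    for (i in 1:(n - 1))
        for (j in (i + 1):n)
            if (runif(1) < p) adj[i, j] <- adj[j, i] <- TRUE
    adj
}

adjacencyToEdgeList <- function(adj) {
    ids <- sprintf("V%02d", seq_len(nrow(adj)))
    rows <- which(upper.tri(adj) & adj, arr.ind = TRUE)
    new("EdgeList",
        edges = data.frame(from = ids[rows[, 1]], to = ids[rows[, 2]]),
        nodes = ids)
}
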