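#' Gene-gene Pearson correlations within a condition group
#'
#' Correlates every pair of genes across the samples of one condition
#' group (e.g. the twelve shock arrays or the twelve control arrays of
#' the reference design).  Genes with zero variance across the group are
#' dropped with a message.
#'
#' @param x a [StateExpressionSet-class].
#' @param states state labels defining the group; default all states.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
geneCorrelations <- function(x, states = NULL) {
    st <- stateLabels(x)
    if (is.null(states)) states <- unique(st)
    unknown <- setdiff(states, st)
    if (length(unknown))
        stop("unknown state label(s): ", paste(unknown, collapse = ", "))
    cols <- st %in% states
    if (sum(cols) < 3)
        stop("correlation needs >= 3 samples; group has ", sum(cols))
    if (sum(cols) < 4)
        warning("only ", sum(cols), " samples in group; ",
                "correlations will be unstable")
    v <- log2Values(x)[, cols, drop = FALSE]
    sds <- apply(v, 1, stats::sd)
    if (any(sds == 0)) {
        message(sum(sds == 0), " zero-variance gene(s) dropped")
        v <- v[sds > 0, , drop = FALSE]
    }
    stats::cor(t(v))
}

#' Build a thresholded co-expression network
#'
#' Edges connect gene pairs with `|r| >= threshold` and carry the
#' correlation and its sign; genes left without any edge are excluded
#' from the node set.
#'
#' @param cm symmetric correlation matrix with gene dimnames.
#' @param threshold absolute-correlation cutoff in (0, 1]; the reference
#'   analysis used 0.98 (see also [rmtThreshold()]).
#' @return a [CoexNetwork-class].
#' @export
buildNetwork <- function(cm, threshold = 0.98) {
    cm <- as.matrix(cm)
    if (threshold <= 0 || threshold > 1)
        stop("threshold must lie in (0, 1]")
    if (is.null(rownames(cm)))
        rownames(cm) <- colnames(cm) <- paste0("g", seq_len(nrow(cm)))
    adj <- abs(cm) >= threshold
    diag(adj) <- FALSE
    idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
    edges <- data.frame(from = rownames(cm)[idx[, 1]],
                        to = colnames(cm)[idx[, 2]],
                        r = cm[idx])
    edges$sign <- ifelse(edges$r >= 0, "positive", "negative")
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    new("CoexNetwork", graph = g, threshold = threshold)
}

#' Detect network modules by fast-greedy modularity optimisation
#'
#' Agglomerative greedy modularity maximisation on the unweighted,
#' undirected edge set.  Modules below `minSize` stay in the partition
#' but are flagged as "small" ([smallModules()]) rather than dropped.
#'
#' @param net a [CoexNetwork-class].
#' @param minSize minimum module size to count as a full module (the
#'   reference analysis reported modules of at least five nodes).
#' @return a [ModulePartition-class].
#' @export
detectModules <- function(net, minSize = 5L) {
    g <- networkGraph(net)
    if (igraph::vcount(g) == 0) stop("empty network")
    comm <- igraph::cluster_fast_greedy(igraph::simplify(g))
    ## cut the merge path exactly at the modularity maximum
    membership <- as.integer(igraph::cut_at(
        comm, steps = which.max(comm$modularity) - 1L))
    names(membership) <- igraph::V(g)$name
    new("ModulePartition", membership = membership,
        modularity = max(comm$modularity), minSize = as.integer(minSize))
}

#' Node-accounting arithmetic for a two-network comparison
#'
#' @param nA,nB node counts of networks A and B.
#' @param nShared number of nodes present in both.
#' @return list with `aSpecific`, `bSpecific`, `shrinkagePercent`
#'   (`(nB - nA) / nB * 100`, i.e. how much smaller A is than B).
#' @examples
#' networkAccounting(216, 283, 186)   # 30 A-specific, 97 B-specific, 23.7%
#' @export
networkAccounting <- function(nA, nB, nShared) {
    if (nShared > min(nA, nB)) stop("shared count exceeds a network size")
    list(aSpecific = nA - nShared, bSpecific = nB - nShared,
         shrinkagePercent = (nB - nA) / nB * 100)
}

#' Compare two co-expression networks
#'
#' Set algebra on node labels, shrinkage of A relative to B, the top-k
#' degree hubs of each network, and - when module partitions are supplied
#' - the module assignment of every shared node in both networks (module
#' rewiring table).
#'
#' @param a,b [CoexNetwork-class] objects (e.g. shock and control).
#' @param k number of hub nodes to report per network.
#' @param modulesA,modulesB optional [ModulePartition-class] objects.
#' @return list with `shared`, `aSpecific`, `bSpecific`,
#'   `shrinkagePercent`, `hubsA`, `hubsB`, and (if partitions are given)
#'   `moduleOverlap`.
#' @export
compareNetworks <- function(a, b, k = 20L, modulesA = NULL,
                            modulesB = NULL) {
    na <- networkNodes(a)
    nb <- networkNodes(b)
    shared <- intersect(na, nb)
    acc <- networkAccounting(length(na), length(nb), length(shared))
    hubs <- function(net, k) {
        deg <- sort(igraph::degree(networkGraph(net)), decreasing = TRUE)
        data.frame(node = names(deg), degree = as.integer(deg),
                   row.names = NULL)[seq_len(min(k, length(deg))), ]
    }
    out <- list(shared = shared,
                aSpecific = setdiff(na, shared),
                bSpecific = setdiff(nb, shared),
                shrinkagePercent = acc$shrinkagePercent,
                hubsA = hubs(a, k), hubsB = hubs(b, k))
    if (!is.null(modulesA) && !is.null(modulesB)) {
        ma <- moduleMembership(modulesA)
        mb <- moduleMembership(modulesB)
        out$moduleOverlap <- data.frame(
            node = shared,
            moduleA = unname(ma[shared]),
            moduleB = unname(mb[shared]))
    }
    out
}

#' First-neighbour subnetwork around seed genes
#'
#' Induced subgraph on the seed genes and every gene directly connected
#' to at least one of them (e.g. the first neighbours of the V-type
#' ATPase genes in the shock network).  Seeds absent from the network are
#' reported with a warning; if none are present, an error is raised.
#'
#' @param net a [CoexNetwork-class].
#' @param seeds character vector of seed gene ids.
#' @return an [igraph::igraph] induced subgraph.
#' @export
firstNeighbors <- function(net, seeds) {
    g <- networkGraph(net)
    present <- intersect(seeds, igraph::V(g)$name)
    if (length(present) == 0)
        stop("none of the seed genes is present in the network")
    missing <- setdiff(seeds, present)
    if (length(missing))
        warning("seed(s) absent from network: ",
                paste(missing, collapse = ", "))
    nbrs <- unique(unlist(lapply(present, function(s)
        igraph::neighbors(g, s)$name)))
    igraph::induced_subgraph(g, union(present, nbrs))
}
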