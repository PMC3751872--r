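#' Replicate-averaged absolute state profiles
#'
#' @param x a [StateExpressionSet-class].
#' @return numeric matrix, genes x states, of replicate-mean log2 values.
#' @export
absoluteStates <- function(x) {
    st <- stateLabels(x)
    states <- unique(st)
    if (any(table(st)[states] < 1)) stop("empty state")
    v <- log2Values(x)
    profiles <- matrix(NA_real_, nrow(v), length(states),
                       dimnames = list(rownames(v), states))
    for (s in states)
        profiles[, s] <- rowMeans(v[, st == s, drop = FALSE])
    profiles
}

#' Relative state profiles (contrast vectors) with fold-change filtering
#'
#' Builds one profile per contrast from the per-gene mean log2 ratio, then
#' restricts all profiles to the genes whose maximum absolute mean log2
#' ratio over the contrasts strictly exceeds `log2(foldFilter)` ("more
#' than `foldFilter`-fold" in at least one contrast).
#'
#' @param x a [StateExpressionSet-class].
#' @param contrasts list of `c(treatment, control)` pairs; default the
#'   eight contrasts of the reference design ([defaultContrasts()]).
#' @param foldFilter fold-change filter (> 1); default 2.
#' @return numeric matrix, retained genes x contrasts, with columns
#'   labelled `"treatment vs control"`.
#' @export
relativeStates <- function(x, contrasts = defaultContrasts(),
                           foldFilter = 2.0) {
    if (foldFilter <= 1) stop("foldFilter must be > 1")
    means <- vapply(contrasts, function(p)
        rowMeans(contrastLogRatios(x, p[1], p[2])),
        numeric(nrow(x)))
    colnames(means) <- vapply(contrasts, function(p) relLabel(p[1], p[2]), "")
    keep <- apply(abs(means), 1, max) > log2(foldFilter)
    if (!any(keep))
        stop("no gene exceeds the ", foldFilter,
             "-fold filter; relax 'foldFilter'")
    means[keep, , drop = FALSE]
}

#' Pearson-correlation distances among state profiles
#'
#' `d(a, b) = 1 - r(a, b)` with `r` the Pearson correlation of the two
#' per-gene profiles, giving distances in `[0, 2]`.
#'
#' @param profiles genes x states matrix ([absoluteStates()] or
#'   [relativeStates()]).
#' @param type `"absolute"` or `"relative"` (bookkeeping label).
#' @return a [StateDistanceMatrix-class].
#' @examples
#' p <- cbind(a = c(1, 2, 3), b = c(1, 2, 4))
#' as.matrix(stateDistances(p))    # d ~ 0.018
#' @export
stateDistances <- function(profiles, type = c("absolute", "relative")) {
    type <- match.arg(type)
    if (ncol(profiles) < 2) stop("need >= 2 profiles")
    sds <- apply(profiles, 2, stats::sd)
    if (any(sds == 0))
        stop("zero-variance profile(s): ",
             paste(colnames(profiles)[sds == 0], collapse = ", "))
    d <- 1 - stats::cor(profiles)
    diag(d) <- 0
    new("StateDistanceMatrix", distances = d, type = type)
}

#' Bootstrap-supported average-linkage clustering of state profiles
#'
#' Clusters states by average linkage on the Pearson-correlation distance
#' and attaches to every internal node the percentage of gene-resampled
#' (rows with replacement) trees containing the same clade.
#'
#' @param profiles genes x states matrix.
#' @param nBoot number of bootstrap resamples (the reference analysis
#'   used 1000).
#' @param seed integer seed.
#' @return a [BootstrapTree-class].
#' @export
bootstrapTree <- function(profiles, nBoot = 1000L, seed = 1L) {
    if (ncol(profiles) < 3) stop("need >= 3 profiles")
    if (nBoot < 1) stop("nBoot must be >= 1")
    corDist <- function(m) {
        r <- suppressWarnings(stats::cor(m))
        r[is.na(r)] <- 0            # degenerate resample: treat as unrelated
        stats::as.dist(1 - r)
    }
    buildTree <- function(m)
        ape::as.phylo(stats::hclust(corDist(m), method = "average"))
    tree <- buildTree(profiles)
    set.seed(seed)
    bootTrees <- vector("list", nBoot)
    for (b in seq_len(nBoot)) {
        idx <- sample(nrow(profiles), replace = TRUE)
        bootTrees[[b]] <- buildTree(profiles[idx, , drop = FALSE])
    }
    class(bootTrees) <- "multiPhylo"
    counts <- ape::prop.clades(tree, bootTrees, rooted = TRUE)
    counts[is.na(counts)] <- 0
    support <- 100 * counts / nBoot
    tree$node.label <- formatC(support, format = "f", digits = 1)
    new("BootstrapTree", tree = tree, support = support,
        nBoot = as.integer(nBoot))
}

offDiagonalPairs <- function(labels) {
    pairs <- utils::combn(sort(labels), 2)
    data.frame(a = pairs[1, ], b = pairs[2, ])
}

#' Quantitative microevolution metrics over state-space distances
#'
#' Summarises the transcriptome state space with five metrics:
#' \describe{
#'   \item{distinctness}{for a stated two-group labelling of absolute
#'     states, the minimum inter-group and maximum intra-group distance,
#'     and whether the groups separate (min inter > max intra).}
#'   \item{discreteness}{the distance from a designated state to its
#'     nearest neighbour.}
#'   \item{resilience}{distances of every trajectory state to the first
#'     one, and whether the final state has returned closer to the origin
#'     than all intermediate states.}
#'   \item{memory}{designated relative-state pairs ranked by increasing
#'     distance (most similar first).}
#'   \item{convergence}{the globally closest pair of relative states and
#'     its distance (ties broken lexicographically on the label pair).}
#' }
#'
#' @param dmAbs [StateDistanceMatrix-class] over absolute states.
#' @param dmRel [StateDistanceMatrix-class] over relative states.
#' @param groups list of two character vectors partitioning (a subset of)
#'   the absolute-state labels.
#' @param trajectory ordered character vector (>= 3) of absolute-state
#'   labels along a temporal trajectory.
#' @param discreteState absolute-state label whose isolation is measured;
#'   default the last trajectory state.
#' @param memoryPairs optional list of `c(labelA, labelB)` relative-state
#'   pairs to rank; default all pairs.
#' @return list with elements `distinctness`, `discreteness`,
#'   `resilience`, `memory`, `convergence`.
#' @export
microevolutionMetrics <- function(dmAbs, dmRel, groups, trajectory,
                                  discreteState = NULL,
                                  memoryPairs = NULL) {
    A <- as.matrix(dmAbs)
    R <- as.matrix(dmRel)
    labsA <- rownames(A)
    labsR <- rownames(R)
    checkLabels <- function(x, pool, what)
        if (!all(x %in% pool))
            stop("unknown ", what, " label(s): ",
                 paste(setdiff(x, pool), collapse = ", "))
    checkLabels(unlist(groups), labsA, "absolute-state")
    checkLabels(trajectory, labsA, "absolute-state")
    if (length(trajectory) < 3) stop("trajectory needs >= 3 states")
    if (is.null(discreteState))
        discreteState <- trajectory[length(trajectory)]
    checkLabels(discreteState, labsA, "absolute-state")

    g1 <- groups[[1]]; g2 <- groups[[2]]
    inter <- A[g1, g2, drop = FALSE]
    intra <- c(A[g1, g1][upper.tri(diag(length(g1)))],
               A[g2, g2][upper.tri(diag(length(g2)))])
    distinctness <- list(minInter = min(inter),
                         maxIntra = if (length(intra)) max(intra) else NA_real_,
                         separated = length(intra) > 0 &&
                             min(inter) > max(intra))

    others <- setdiff(labsA, discreteState)
    discreteness <- list(state = discreteState,
                         nearest = others[which.min(A[discreteState, others])],
                         distance = min(A[discreteState, others]))

    first <- trajectory[1]
    rest <- trajectory[-1]
    dToFirst <- A[first, rest]
    resilience <- list(trajectory = trajectory, distanceToFirst = dToFirst,
                       returned = dToFirst[length(dToFirst)] <
                           min(dToFirst[-length(dToFirst)]))

    if (is.null(memoryPairs)) {
        op <- offDiagonalPairs(labsR)
        memoryPairs <- Map(c, op$a, op$b)
    }
    for (p in memoryPairs) checkLabels(p, labsR, "relative-state")
    md <- vapply(memoryPairs, function(p) R[p[1], p[2]], 0)
    ord <- order(md)
    memory <- data.frame(
        a = vapply(memoryPairs, `[`, "", 1)[ord],
        b = vapply(memoryPairs, `[`, "", 2)[ord],
        distance = md[ord], row.names = NULL)

    op <- offDiagonalPairs(labsR)      # lexicographic order by construction
    dAll <- unname(mapply(function(a, b) R[a, b], op$a, op$b))
    best <- which(dAll == min(dAll))[1]
    convergence <- list(pair = c(op$a[best], op$b[best]),
                        distance = dAll[best])

    list(distinctness = distinctness, discreteness = discreteness,
         resilience = resilience, memory = memory,
         convergence = convergence)
}
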