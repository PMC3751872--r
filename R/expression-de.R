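#' Replicate-wise log2 ratios between two cellular states
#'
#' Computes, per gene, the vector of replicate-paired log2 differences
#' treatment - control (equivalently the log2 of the expression ratio R).
#' Replicates are paired by their replicate index.  Genes with a missing
#' value in any replicate of either state are excluded from the contrast
#' (a message reports how many).
#'
#' @param x a [StateExpressionSet-class].
#' @param treatment,control state labels.
#' @return numeric matrix, genes x replicates, of log2 ratios.
#' @examples
#' m <- matrix(c(3, 3, 2, 2), 1, 4,
#'             dimnames = list("g1", paste0("s", 1:4)))
#' ses <- stateExpressionSet(m, state = c("T", "T", "C", "C"),
#'                           replicate = c(1, 2, 1, 2))
#' contrastLogRatios(ses, "T", "C")   # both replicates: log2R = 1
#' @export
contrastLogRatios <- function(x, treatment, control) {
    st <- stateLabels(x)
    for (lab in c(treatment, control))
        if (!lab %in% st) stop("unknown state label: ", lab)
    it <- which(st == treatment)
    ic <- which(st == control)
    if (length(it) < 2 || length(ic) < 2)
        stop("both states need >= 2 replicates (",
             treatment, ": ", length(it), ", ",
             control, ": ", length(ic), ")")
    if (length(it) != length(ic))
        stop("replicate counts differ between '", treatment, "' (",
             length(it), ") and '", control, "' (", length(ic), ")")
    rt <- replicateIndex(x)[it]
    rc <- replicateIndex(x)[ic]
    it <- it[order(rt)]
    ic <- ic[order(rc)]
    v <- log2Values(x)
    ratios <- v[, it, drop = FALSE] - v[, ic, drop = FALSE]
    colnames(ratios) <- paste0("rep", sort(rt))
    keep <- stats::complete.cases(ratios)
    if (!all(keep))
        message(sum(!keep), " gene(s) with missing replicates excluded ",
                "from contrast ", relLabel(treatment, control))
    ratios[keep, , drop = FALSE]
}

#' Call differential expression with joint ratio and Z-score cutoffs
#'
#' A gene is significant when both `|mean log2R| >= ratioCutoff` and
#' `|Z| >= zCutoff` (inclusive thresholds).  The Z score is the one-sample
#' statistic over replicates, `mean / (SD / sqrt(n))`.  Zero-variance
#' ratio vectors get an infinite-Z sentinel, so their significance is
#' decided by the ratio cutoff alone.
#'
#' @param ratios genes x replicates matrix from [contrastLogRatios()].
#' @param ratioCutoff minimum absolute mean log2 ratio (default 1.0, i.e.
#'   two-fold).
#' @param zCutoff minimum absolute Z score (default 2.0).
#' @return a [S4Vectors::DataFrame] with columns `meanLog2R`, `z`,
#'   `significant`, `direction` (`up`/`down`/`none`), gene ids as
#'   rownames, and the cutoffs in `metadata()`.
#' @examples
#' r <- rbind(g1 = c(1.2, 1.3, 1.1), g2 = c(0.2, -0.1, 0))
#' callDE(r)
#' @export
callDE <- function(ratios, ratioCutoff = 1.0, zCutoff = 2.0) {
    ratios <- as.matrix(ratios)
    if (ncol(ratios) < 2) stop("need >= 2 replicates per gene")
    m <- unname(rowMeans(ratios))
    s <- unname(apply(ratios, 1, stats::sd))
    n <- ncol(ratios)
    z <- ifelse(s == 0, sign(m) * Inf, m / (s / sqrt(n)))
    z[s == 0 & m == 0] <- 0
    sig <- abs(m) >= ratioCutoff & abs(z) >= zCutoff
    res <- DataFrame(
        meanLog2R = m, z = z, significant = sig,
        direction = ifelse(!sig, "none", ifelse(m > 0, "up", "down")),
        row.names = rownames(ratios))
    metadata(res) <- list(ratioCutoff = ratioCutoff, zCutoff = zCutoff,
                          nReplicates = n)
    res
}

#' Cluster temporal expression patterns with K-means
#'
#' Partitions significant genes by their mean log2-ratio trajectory over
#' time points, using Euclidean K-means with multiple restarts under a
#' fixed seed.  If K-means leaves some of the `k` requested clusters empty
#' (e.g. all trajectories identical), the empty clusters are reported in
#' the result.
#'
#' @param deMatrix genes x time points matrix of mean log2 ratios,
#'   restricted to genes significant in at least one time point.
#' @param k number of clusters (the reference analysis used 10).
#' @param seed integer seed.
#' @param nstart K-means restarts.
#' @return list with `assignments` (named integer), `centroids`
#'   (k x time points), `k`, and `emptyClusters`.
#' @export
temporalClusters <- function(deMatrix, k = 10L, seed = 1L, nstart = 10L) {
    deMatrix <- as.matrix(deMatrix)
    if (nrow(deMatrix) == 0) stop("empty matrix: no genes to cluster")
    if (k < 1) stop("k must be >= 1")
    if (k > nrow(deMatrix))
        stop("k (", k, ") exceeds the number of genes (", nrow(deMatrix), ")")
    set.seed(seed)
    nUnique <- nrow(unique(deMatrix))
    kEff <- min(k, nUnique)
    km <- stats::kmeans(deMatrix, centers = kEff, nstart = nstart,
                        iter.max = 100)
    assignments <- km$cluster
    names(assignments) <- rownames(deMatrix)
    centroids <- km$centers
    if (kEff < k) {
        pad <- matrix(NA_real_, k - kEff, ncol(centroids))
        centroids <- rbind(centroids, pad)
    }
    rownames(centroids) <- paste0("cluster", seq_len(k))
    list(assignments = assignments, centroids = centroids, k = k,
         emptyClusters = if (kEff < k) seq(kEff + 1L, k) else integer(0))
}
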