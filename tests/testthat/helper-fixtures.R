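## tiny expression set: one state pair, values chosen by hand
makeTinySet <- function(treat, ctrl, genes = paste0("g", seq_len(nrow(treat)))) {
    stopifnot(ncol(treat) == ncol(ctrl))
    m <- cbind(treat, ctrl)
    rownames(m) <- genes
    colnames(m) <- c(paste0("T.r", seq_len(ncol(treat))),
                     paste0("C.r", seq_len(ncol(ctrl))))
    stateExpressionSet(m,
                       state = rep(c("T", "C"), each = ncol(treat)),
                       replicate = rep(seq_len(ncol(treat)), 2))
}

## all set partitions of n items as membership vectors (restricted
## growth strings), memoised per n
.partitionCache <- new.env(parent = emptyenv())
allPartitions <- function(n) {
    key <- as.character(n)
    if (!is.null(.partitionCache[[key]])) return(.partitionCache[[key]])
    res <- list()
    a <- integer(n)
    rec <- function(i, maxv) {
        if (i > n) {
            res[[length(res) + 1L]] <<- a
            return(invisible())
        }
        for (v in seq_len(maxv + 1L)) {
            a[i] <<- v
            rec(i + 1L, max(maxv, v))
        }
    }
    rec(1L, 0L)
    .partitionCache[[key]] <- res
    res
}

## exhaustive maximal-modularity oracle for tiny graphs
exactMaxModularity <- function(g) {
    parts <- allPartitions(igraph::vcount(g))
    max(vapply(parts, function(m) igraph::modularity(g, m), 0))
}

## correlation matrix with two planted blocks (within ~0.99, between ~0)
plantedTwoBlockMatrix <- function(blockSize = 15, nNoise = 30,
                                  seed = 1) {
    set.seed(seed)
    n <- 2 * blockSize + nNoise
    cm <- matrix(stats::rnorm(n * n, 0, 0.05), n, n)
    cm <- (cm + t(cm)) / 2
    b1 <- seq_len(blockSize)
    b2 <- blockSize + seq_len(blockSize)
    cm[b1, b1] <- 0.99 + stats::rnorm(blockSize^2, 0, 0.003)
    cm[b2, b2] <- 0.99 + stats::rnorm(blockSize^2, 0, 0.003)
    cm[b1, b1] <- (cm[b1, b1] + t(cm[b1, b1])) / 2
    cm[b2, b2] <- (cm[b2, b2] + t(cm[b2, b2])) / 2
    cm <- pmin(pmax(cm, -1), 1)
    diag(cm) <- 1
    rownames(cm) <- colnames(cm) <- paste0("g", seq_len(n))
    attr(cm, "blocks") <- list(b1 = rownames(cm)[b1], b2 = rownames(cm)[b2])
    cm
}

## per-gene coverage table for one condition from simulated tracks
coverageTable <- function(reads, condition, annotation, minDepth = 5) {
    do.call(rbind, lapply(seq_along(reads$coverage[[condition]]),
                          function(r) {
        s <- summarizeCoverage(reads$coverage[[condition]][[r]],
                               annotation, minDepth)
        s$replicate <- r
        s
    }))
}
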