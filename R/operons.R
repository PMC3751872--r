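#' Mean per-gene read depth from a coverage track
#'
#' Averages per-base depth over each gene's coding interval (1-based
#' inclusive annotation coordinates) and flags genes as expressed when
#' the mean reaches `minDepth`.
#'
#' @param track per-base coverage as an `RleList` named by chromosome
#'   (from [simulateOperonReads()] or [readCoverage()]).
#' @param annotation [GenomicRanges::GRanges] of genes with `gene_id`.
#' @param minDepth minimum mean depth for the expressed flag.
#' @return data.frame `gene_id, meanDepth, expressed`.
#' @export
summarizeCoverage <- function(track, annotation, minDepth = 5) {
    chrs <- as.character(GenomicRanges::seqnames(annotation))
    starts <- GenomicRanges::start(annotation)
    ends <- GenomicRanges::end(annotation)
    md <- numeric(length(annotation))
    for (i in seq_along(annotation)) {
        if (!chrs[i] %in% names(track))
            stop("gene ", annotation$gene_id[i],
                 " on chromosome absent from track: ", chrs[i])
        rle <- track[[chrs[i]]]
        if (ends[i] > length(rle))
            stop("gene ", annotation$gene_id[i],
                 " extends beyond the coverage track")
        md[i] <- mean(as.numeric(rle[starts[i]:ends[i]]))
    }
    data.frame(gene_id = annotation$gene_id, meanDepth = md,
               expressed = md >= minDepth)
}

#' Call condition-specific suboperons of a predicted polycistron
#'
#' Applies the two-requirement rule for splitting a predicted polycistron
#' into suboperons, evaluated in every replicate of the condition:
#' \enumerate{
#'   \item a boundary between adjacent genes is a split point when the
#'     ratio of their mean depths (larger over smaller) is strictly
#'     greater than `fold` in each replicate;
#'   \item operon co-membership additionally requires uniquely mapped
#'     bridging read pairs: within every multi-gene suboperon, each
#'     adjacent gene pair must be bridged by at least `minPairs` pairs in
#'     each replicate, otherwise the unit is split there too and
#'     unsupported genes fall out as monocistrons.
#' }
#' Genes whose mean depth stays below `minDepth` in any replicate are
#' flagged unexpressed, excluded from suboperon membership, and break
#' contiguity.  With `boundaryMode = "across"` the pair-support
#' requirement is read the other way: a depth split is confirmed only
#' when bridging pairs across that boundary are absent in each replicate.
#'
#' @param polycistron list with `id` and ordered `genes`.
#' @param coverage data.frame `gene_id, replicate, meanDepth` for one
#'   condition (bind [summarizeCoverage()] outputs over replicates).
#' @param links data.frame `gene_i, gene_j, replicate, n_pairs` for the
#'   same condition.
#' @param fold depth-ratio threshold (strict; the reference rule is
#'   "greater than two-fold").
#' @param minDepth expressed-flag threshold (mean reads).
#' @param minPairs minimum bridging read pairs per replicate.
#' @param condition condition label recorded on the model.
#' @param replicates expected replicate count (the reference design is
#'   triplicate); a different observed count is an error unless this
#'   argument is changed to match.
#' @param boundaryMode `"within"` (default) or `"across"`, see above.
#' @return an [OperonModel-class].
#' @examples
#' cov <- data.frame(gene_id = rep(c("a", "b", "c"), each = 3),
#'                   replicate = rep(1:3, 3),
#'                   meanDepth = c(100, 95, 105, 40, 38, 41, 38, 40, 37))
#' lk <- data.frame(gene_i = "b", gene_j = "c", replicate = 1:3,
#'                  n_pairs = 5)
#' callSuboperons(list(id = "p1", genes = c("a", "b", "c")), cov, lk)
#' @export
callSuboperons <- function(polycistron, coverage, links, fold = 2.0,
                           minDepth = 5, minPairs = 1L,
                           condition = "c1", replicates = 3L,
                           boundaryMode = c("within", "across")) {
    boundaryMode <- match.arg(boundaryMode)
    genes <- polycistron$genes
    reps <- sort(unique(coverage$replicate))
    if (length(reps) != replicates)
        stop("expected ", replicates, " replicates, found ", length(reps),
             "; set 'replicates' to override")
    depth <- matrix(NA_real_, length(genes), length(reps),
                    dimnames = list(genes, paste0("rep", reps)))
    for (r in seq_along(reps)) {
        sub <- coverage[coverage$replicate == reps[r], ]
        idx <- match(genes, sub$gene_id)
        if (anyNA(idx))
            stop("no coverage for gene(s): ",
                 paste(genes[is.na(idx)], collapse = ", "))
        depth[, r] <- sub$meanDepth[idx]
    }
    expressed <- apply(depth >= minDepth, 1, all)
    unexpressed <- genes[!expressed]

    pairSupport <- function(i) {     # >= minPairs in every replicate?
        all(vapply(reps, function(r) {
            row <- links[links$gene_i == genes[i] &
                         links$gene_j == genes[i + 1] &
                         links$replicate == r, ]
            nrow(row) > 0 && row$n_pairs[1] >= minPairs
        }, TRUE))
    }
    depthSplit <- function(i) {
        d1 <- depth[i, ]; d2 <- depth[i + 1, ]
        ratios <- ifelse(pmin(d1, d2) == 0, Inf,
                         pmax(d1, d2) / pmin(d1, d2))
        all(ratios > fold)
    }

    splits <- integer(0)
    boundaries <- which(expressed[-length(genes)] & expressed[-1])
    for (i in boundaries) {
        isSplit <- depthSplit(i)
        if (boundaryMode == "across") {
            if (isSplit && pairSupport(i)) isSplit <- FALSE
        }
        if (isSplit) splits <- c(splits, i)
    }
    if (boundaryMode == "within") {
        for (i in setdiff(boundaries, splits))
            if (!pairSupport(i)) splits <- c(splits, i)
    }
    splits <- sort(splits)

    ## assemble suboperons: runs of expressed genes cut at split points
    suboperons <- list()
    current <- character(0)
    for (i in seq_along(genes)) {
        if (!expressed[i]) {
            if (length(current)) suboperons <- c(suboperons, list(current))
            current <- character(0)
            next
        }
        current <- c(current, genes[i])
        if (i %in% splits) {
            suboperons <- c(suboperons, list(current))
            current <- character(0)
        }
    }
    if (length(current)) suboperons <- c(suboperons, list(current))

    new("OperonModel", polycistron = polycistron$id, genes = genes,
        condition = condition, suboperons = suboperons,
        splits = as.integer(splits), unexpressed = unexpressed)
}

#' Dynamic-operon calls between two conditions
#'
#' For each polycistron present in both model sets, takes the symmetric
#' difference of the split-point sets of the two conditions; a call is
#' emitted only when the difference is non-empty (the operon structure
#' changed between conditions).
#'
#' @param modelsA,modelsB lists of [OperonModel-class] objects over the
#'   same polycistron ids (one condition each).
#' @return data.frame `polycistron, conditionA, conditionB, boundary,
#'   presentIn` with one row per differing boundary; zero rows when the
#'   structures agree everywhere.
#' @export
compareOperons <- function(modelsA, modelsB) {
    idsA <- vapply(modelsA, function(m) m@polycistron, "")
    idsB <- vapply(modelsB, function(m) m@polycistron, "")
    if (!setequal(idsA, idsB))
        stop("polycistron ids differ between the two model sets")
    out <- list()
    for (id in idsA) {
        a <- modelsA[[which(idsA == id)]]
        b <- modelsB[[which(idsB == id)]]
        onlyA <- setdiff(a@splits, b@splits)
        onlyB <- setdiff(b@splits, a@splits)
        if (length(onlyA) + length(onlyB) == 0) next
        out[[length(out) + 1L]] <- data.frame(
            polycistron = id, conditionA = a@condition,
            conditionB = b@condition,
            boundary = c(onlyA, onlyB),
            presentIn = c(rep(a@condition, length(onlyA)),
                          rep(b@condition, length(onlyB))))
    }
    if (length(out)) do.call(rbind, out) else
        data.frame(polycistron = character(), conditionA = character(),
                   conditionB = character(), boundary = integer(),
                   presentIn = character())
}
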