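#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData
NULL

setOldClass("phylo")
setOldClass("igraph")

#' Replicated log2 expression measurements across cellular states
#'
#' `StateExpressionSet` extends
#' [SummarizedExperiment::SummarizedExperiment] with the constraint that
#' every sample (column) carries a cellular-state label and a replicate
#' index in its `colData`.  The single assay, `"log2"`, holds gene-level
#' log2 measurements (two-channel log-ratios against a common reference,
#' or log intensities); all downstream arithmetic is done in log2 space.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @seealso [stateExpressionSet()] for construction from a matrix,
#'   [readExpression()] for construction from TSV files.
#' @export
setClass("StateExpressionSet", contains = "SummarizedExperiment")

setValidity("StateExpressionSet", function(object) {
    msg <- character()
    if (!"log2" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'log2' is required")
    cd <- colData(object)
    if (!all(c("state", "replicate") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'state' and 'replicate'")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene ids are not allowed")
    if (is.null(rownames(object)))
        msg <- c(msg, "gene ids (rownames) are required")
    if (length(msg)) msg else TRUE
})

#' Construct a StateExpressionSet
#'
#' @param values numeric matrix of log2 measurements, genes x samples, with
#'   gene ids as rownames.
#' @param state character vector of cellular-state labels, one per column.
#' @param replicate integer vector of replicate indices, one per column.
#'   Replicates are paired across states by this index.
#' @return A [StateExpressionSet-class] object.
#' @examples
#' m <- matrix(rnorm(20), 5, 4,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' ses <- stateExpressionSet(m, state = rep(c("A", "B"), each = 2),
#'                           replicate = rep(1:2, 2))
#' stateLabels(ses)
#' @export
stateExpressionSet <- function(values, state, replicate) {
    values <- as.matrix(values)
    if (length(state) != ncol(values))
        stop("'state' must have one entry per column of 'values'")
    if (length(replicate) != ncol(values))
        stop("'replicate' must have one entry per column of 'values'")
    if (is.null(colnames(values)))
        colnames(values) <- paste(state, replicate, sep = ".r")
    se <- SummarizedExperiment(
        assays = list(log2 = values),
        colData = DataFrame(state = as.character(state),
                            replicate = as.integer(replicate),
                            row.names = colnames(values)))
    new("StateExpressionSet", se)
}

#' Pearson-correlation distance matrix among transcriptome states
#'
#' Symmetric matrix of distances `d = 1 - r` between replicate-averaged
#' state profiles (`type = "absolute"`) or between contrast vectors
#' (`type = "relative"`).  Entries lie in `[0, 2]`; the diagonal is zero.
#'
#' @slot distances symmetric numeric matrix with state labels as dimnames.
#' @slot type `"absolute"` or `"relative"`.
#' @export
setClass("StateDistanceMatrix",
         representation(distances = "matrix", type = "character"))

setValidity("StateDistanceMatrix", function(object) {
    d <- object@distances
    msg <- character()
    if (nrow(d) != ncol(d) || is.null(rownames(d)) ||
        !identical(rownames(d), colnames(d)))
        msg <- c(msg, "distances must be square with matching dimnames")
    else {
        if (max(abs(d - t(d))) > 1e-8) msg <- c(msg, "matrix must be symmetric")
        if (max(abs(diag(d))) > 1e-8) msg <- c(msg, "diagonal must be zero")
        if (min(d) < -1e-8 || max(d) > 2 + 1e-8)
            msg <- c(msg, "distances must lie in [0, 2]")
    }
    if (!object@type %in% c("absolute", "relative"))
        msg <- c(msg, "type must be 'absolute' or 'relative'")
    if (length(msg)) msg else TRUE
})

#' Bootstrap-supported hierarchical clustering of state profiles
#'
#' An average-linkage tree over Pearson-correlation distances, with
#' per-internal-node support computed as the percentage of gene-resampled
#' trees that contain the same bipartition.
#'
#' @slot tree an [ape::phylo] tree whose `node.label` carries the supports.
#' @slot support numeric vector of supports (percent, 0-100), one per
#'   internal node in `tree` node order.
#' @slot nBoot number of bootstrap resamples used.
#' @export
setClass("BootstrapTree",
         representation(tree = "phylo", support = "numeric",
                        nBoot = "integer"))

setValidity("BootstrapTree", function(object) {
    if (any(object@support < 0 | object@support > 100))
        return("supports must lie in [0, 100]")
    if (object@nBoot < 1L) return("nBoot must be >= 1")
    TRUE
})

#' Thresholded gene co-expression network
#'
#' An undirected graph whose nodes are genes retained after correlation
#' thresholding and whose edges connect gene pairs with `|r| >= threshold`.
#' Each edge carries the correlation `r` and its `sign`
#' (`"positive"`/`"negative"`).  Genes left with no edge are excluded.
#'
#' @slot graph an [igraph::igraph] object.
#' @slot threshold the absolute-correlation cutoff used.
#' @export
setClass("CoexNetwork",
         representation(graph = "igraph", threshold = "numeric"))

setValidity("CoexNetwork", function(object) {
    if (object@threshold <= 0 || object@threshold > 1)
        return("threshold must lie in (0, 1]")
    if (igraph::vcount(object@graph) > 0 &&
        any(igraph::degree(object@graph) == 0))
        return("isolated nodes must be excluded from the network")
    TRUE
})

#' Module partition of a co-expression network
#'
#' Result of fast-greedy modularity optimisation.  Modules smaller than
#' `minSize` are retained in the partition but flagged as "small" rather
#' than silently dropped.
#'
#' @slot membership named integer vector, gene -> module id.
#' @slot modularity the modularity Q of the partition.
#' @slot minSize minimum size for a module to count as a full module.
#' @export
setClass("ModulePartition",
         representation(membership = "integer", modularity = "numeric",
                        minSize = "integer"))

setValidity("ModulePartition", function(object) {
    if (is.null(names(object@membership)))
        return("membership must be named by gene")
    if (object@modularity < -0.5 - 1e-8 || object@modularity > 1 + 1e-8)
        return("modularity must lie in [-0.5, 1]")
    TRUE
})

#' Condition-specific suboperon structure of a predicted polycistron
#'
#' Ordered genes of one predicted polycistron together with the suboperons
#' (ordered, contiguous, disjoint runs of expressed genes) called for one
#' condition.  `splits` are boundary indices: a split at `i` separates
#' `genes[i]` from `genes[i + 1]`.  Unexpressed genes are excluded from
#' suboperon membership and break contiguity.
#'
#' @slot polycistron polycistron identifier.
#' @slot genes ordered gene ids of the predicted polycistron.
#' @slot condition condition label the call applies to.
#' @slot suboperons list of character vectors, each an ordered run of
#'   expressed genes.
#' @slot splits integer boundary indices (into `genes`).
#' @slot unexpressed gene ids excluded for insufficient coverage.
#' @export
setClass("OperonModel",
         representation(polycistron = "character", genes = "character",
                        condition = "character", suboperons = "list",
                        splits = "integer", unexpressed = "character"))

setValidity("OperonModel", function(object) {
    sub <- unlist(object@suboperons, use.names = FALSE)
    msg <- character()
    if (anyDuplicated(sub))
        msg <- c(msg, "a gene cannot belong to two suboperons")
    if (!all(sub %in% object@genes))
        msg <- c(msg, "suboperon genes must come from the polycistron")
    idx <- match(sub, object@genes)
    if (length(idx) > 1 && any(diff(idx) < 1))
        msg <- c(msg, "suboperons must preserve gene order")
    if (any(object@unexpressed %in% sub))
        msg <- c(msg, "unexpressed genes cannot be suboperon members")
    if (length(msg)) msg else TRUE
})

#' Synthetic-study configuration
#'
#' Parameters of the synthetic data generators.  The defaults encode the
#' study design the pipeline targets: nine cellular states (wild type
#' unshocked, four ethanol-shock time points, and two adapted strains each
#' with and without ethanol), three biological replicates per state, and a
#' pooled-population sequencing depth of 140x.
#'
#' @slot nGenes number of genes simulated.
#' @slot states cellular-state labels.
#' @slot replicates biological replicates per state.
#' @slot noiseSd per-measurement Gaussian noise SD, log2 units.
#' @slot deFraction fraction of genes planted as differential.
#' @slot deEffect planted effect size, log2 units.
#' @slot deStates states in which planted DE genes are shifted.
#' @slot moduleSpec list of `list(size =, rho =)` planted co-expression
#'   blocks (single shared latent factor per block).
#' @slot memorySpec list of planted shared-signature constraints, each
#'   `list(pair = list(c(t1, c1), c(t2, c2)), nGenes =, sd =)`.
#' @slot operonSpec list of planted polycistrons, each
#'   `list(id =, genes =, splits =, depthMult =)`.
#' @slot poolSpec data.frame with columns `pos` and `freq` (true pooled
#'   allele frequencies).
#' @slot depth mean sequencing depth for coverage and pooled reads.
#' @slot seed integer master seed; generator substreams are derived from
#'   it, so identical config + seed gives identical output.
#' @export
setClass("SimulationConfig",
         representation(nGenes = "integer", states = "character",
                        replicates = "integer", noiseSd = "numeric",
                        deFraction = "numeric", deEffect = "numeric",
                        deStates = "character", moduleSpec = "list",
                        memorySpec = "list", operonSpec = "list",
                        poolSpec = "data.frame", depth = "numeric",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@nGenes < 1L) msg <- c(msg, "nGenes must be positive")
    if (object@replicates < 1L) msg <- c(msg, "replicates must be positive")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@deFraction < 0 || object@deFraction > 1)
        msg <- c(msg, "deFraction must lie in [0, 1]")
    if (length(object@states) < 1) msg <- c(msg, "at least one state required")
    if (!all(object@deStates %in% object@states))
        msg <- c(msg, "deStates must be a subset of states")
    if (object@depth < 0) msg <- c(msg, "depth must be >= 0")
    sizes <- vapply(object@moduleSpec, function(m) as.numeric(m$size), 0)
    if (length(sizes) && sum(sizes) > object@nGenes)
        msg <- c(msg, "module sizes must not sum to more than nGenes")
    if (nrow(object@poolSpec)) {
        if (!all(c("pos", "freq") %in% colnames(object@poolSpec)))
            msg <- c(msg, "poolSpec needs columns 'pos' and 'freq'")
        else if (any(object@poolSpec$freq < 0 | object@poolSpec$freq > 1))
            msg <- c(msg, "pool frequencies must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})
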