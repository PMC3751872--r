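#' The nine cellular states of the reference study design
#'
#' Wild type without ethanol, the wild type at four time points of 0.15%
#' ethanol shock, and two adapted strains (2%- and 6%-tolerant) each grown
#' without and with their ethanol dose.
#'
#' @return character vector of nine state labels.
#' @export
defaultStates <- function() {
    c("X-0%", "X-0.15%-0.5h", "X-0.15%-1h", "X-0.15%-2h", "X-0.15%-4h",
      "XI-0%", "XI-2%", "XII-0%", "XII-6%")
}

#' The eight relative states (contrasts) of the reference study design
#'
#' Six contrasts isolate environmental perturbation (shock time points vs
#' unshocked wild type; each adapted strain with vs without ethanol) and
#' two isolate genetic change (each adapted strain without ethanol vs the
#' wild type).
#'
#' @return list of `c(treatment, control)` pairs.
#' @export
defaultContrasts <- function() {
    list(c("X-0.15%-0.5h", "X-0%"),
         c("X-0.15%-1h",   "X-0%"),
         c("X-0.15%-2h",   "X-0%"),
         c("X-0.15%-4h",   "X-0%"),
         c("XI-0%",  "X-0%"),
         c("XI-2%",  "XI-0%"),
         c("XII-0%", "X-0%"),
         c("XII-6%", "XII-0%"))
}

#' @describeIn stateExpressionSet state label of every sample.
#' @param x a `StateExpressionSet`.
#' @export
stateLabels <- function(x) as.character(colData(x)$state)

#' @describeIn stateExpressionSet replicate index of every sample.
#' @export
replicateIndex <- function(x) as.integer(colData(x)$replicate)

#' @describeIn stateExpressionSet the log2 measurement matrix.
#' @export
log2Values <- function(x) assay(x, "log2")

#' Coerce a StateDistanceMatrix to a plain matrix
#'
#' @param x a `StateDistanceMatrix`.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "StateDistanceMatrix", function(x, ...) x@distances)

#' @describeIn StateDistanceMatrix-class whether the matrix is over
#'   absolute or relative states.
#' @param object,x a `StateDistanceMatrix`.
#' @export
distType <- function(x) x@type

#' @describeIn CoexNetwork-class the underlying igraph object.
#' @param x a `CoexNetwork`.
#' @export
networkGraph <- function(x) x@graph

#' @describeIn CoexNetwork-class the absolute-correlation threshold used.
#' @export
networkThreshold <- function(x) x@threshold

#' @describeIn CoexNetwork-class node (gene) labels of the network.
#' @export
networkNodes <- function(x) igraph::V(x@graph)$name

#' @describeIn CoexNetwork-class edge table with correlation and sign.
#' @export
networkEdges <- function(x) {
    g <- x@graph
    if (igraph::ecount(g) == 0)
        return(data.frame(from = character(), to = character(),
                          r = numeric(), sign = character()))
    el <- igraph::as_edgelist(g)
    data.frame(from = el[, 1], to = el[, 2],
               r = igraph::E(g)$r, sign = igraph::E(g)$sign)
}

#' @describeIn ModulePartition-class gene -> module assignment.
#' @param x a `ModulePartition`.
#' @export
moduleMembership <- function(x) x@membership

#' @describeIn ModulePartition-class module sizes, largest first.
#' @export
moduleSizes <- function(x) sort(table(x@membership), decreasing = TRUE)

#' @describeIn ModulePartition-class modularity Q of the partition.
#' @export
modularityQ <- function(x) x@modularity

#' @describeIn ModulePartition-class ids of modules at or above the
#'   minimum size; the rest are reported as "small".
#' @export
fullModules <- function(x) {
    sz <- table(x@membership)
    as.integer(names(sz)[sz >= x@minSize])
}

#' @describeIn ModulePartition-class ids of modules below the minimum size.
#' @export
smallModules <- function(x) {
    sz <- table(x@membership)
    as.integer(names(sz)[sz < x@minSize])
}

#' @describeIn OperonModel-class the called suboperons.
#' @param x an `OperonModel`.
#' @export
suboperons <- function(x) x@suboperons

#' @describeIn OperonModel-class split-point indices (a split at `i`
#'   separates gene `i` from gene `i + 1`).
#' @export
splitPoints <- function(x) x@splits

#' @describeIn BootstrapTree-class the tree with node-label supports.
#' @param x a `BootstrapTree`.
#' @export
supportTree <- function(x) x@tree

#' @describeIn BootstrapTree-class per-internal-node supports (percent).
#' @export
supportValues <- function(x) x@support

setMethod("show", "StateExpressionSet", function(object) {
    cat("StateExpressionSet:", nrow(object), "genes x", ncol(object),
        "samples\n")
    st <- stateLabels(object)
    cat(" ", length(unique(st)), "states;",
        paste0(utils::head(unique(st), 4), collapse = ", "),
        if (length(unique(st)) > 4) "..." else "", "\n")
})

setMethod("show", "StateDistanceMatrix", function(object) {
    cat("StateDistanceMatrix (", object@type, "): ",
        nrow(object@distances), " states, ",
        choose(nrow(object@distances), 2), " pairwise distances\n", sep = "")
})

setMethod("show", "CoexNetwork", function(object) {
    cat("CoexNetwork: ", igraph::vcount(object@graph), " nodes, ",
        igraph::ecount(object@graph), " edges at |r| >= ",
        object@threshold, "\n", sep = "")
})

setMethod("show", "ModulePartition", function(object) {
    sz <- moduleSizes(object)
    cat("ModulePartition: ", length(sz), " modules (",
        length(fullModules(object)), " with >= ", object@minSize,
        " nodes), Q = ", round(object@modularity, 4), "\n", sep = "")
})

setMethod("show", "OperonModel", function(object) {
    cat("OperonModel ", object@polycistron, " [", object@condition, "]: ",
        length(object@genes), " genes -> ", length(object@suboperons),
        " suboperon(s)\n", sep = "")
})

setMethod("show", "BootstrapTree", function(object) {
    cat("BootstrapTree: ", length(object@tree$tip.label), " states, ",
        object@nBoot, " resamples, median support ",
        round(stats::median(object@support), 1), "%\n", sep = "")
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig: ", object@nGenes, " genes, ",
        length(object@states), " states x ", object@replicates,
        " replicates, seed ", object@seed, "\n", sep = "")
})
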