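test_that("gene correlations behave like Pearson r", {
    set.seed(41)
    m <- matrix(rnorm(60), 5, 12,
                dimnames = list(paste0("g", 1:5), NULL))
    m[2, ] <- -m[1, ]                     # exact negation
    ses <- stateExpressionSet(m, state = rep(paste0("s", 1:4), each = 3),
                              replicate = rep(1:3, 4))
    cm <- geneCorrelations(ses)
    expect_equal(unname(diag(cm)), rep(1, 5))
    expect_equal(cm["g1", "g2"], -1)
    expect_error(geneCorrelations(ses, "nope"), "unknown state")
})

test_that("zero-variance genes are dropped and tiny groups rejected", {
    m <- matrix(rnorm(40), 4, 10,
                dimnames = list(paste0("g", 1:4), NULL))
    m[3, ] <- 7
    ses <- stateExpressionSet(m, state = rep(c("a", "b"), each = 5),
                              replicate = rep(1:5, 2))
    expect_message(cm <- geneCorrelations(ses), "zero-variance")
    expect_false("g3" %in% rownames(cm))
    tiny <- stateExpressionSet(m[, 1:2], state = c("a", "a"),
                               replicate = 1:2)
    expect_error(geneCorrelations(tiny), ">= 3 samples")
})

test_that("planted high-loading gene pairs correlate strongly", {
    sim <- simulateExpression(simConfig(
        nGenes = 40, states = paste0("s", 1:4), deStates = character(0),
        moduleSpec = list(list(size = 8, rho = 0.99)), seed = 19))
    cm <- geneCorrelations(sim$expression)
    block <- names(sim$truth$moduleMembership)
    within <- cm[block, block][upper.tri(diag(length(block)))]
    expect_gte(mean(within), 0.95)
})

test_that("network edges obey the threshold and sign contract", {
    cm <- plantedTwoBlockMatrix(blockSize = 5, nNoise = 5, seed = 2)
    cm["g1", "g11"] <- cm["g11", "g1"] <- -0.995
    net <- buildNetwork(cm, 0.98)
    ed <- networkEdges(net)
    expect_true(all(abs(ed$r) >= 0.98))
    expect_true(all(ed$sign[ed$r < 0] == "negative"))
    neg <- ed[ed$from %in% c("g1", "g11") & ed$to %in% c("g1", "g11"), ]
    expect_equal(neg$sign, "negative")
    ## a planted block at r ~ 0.99 is a complete subgraph at 0.98
    b1 <- attr(cm, "blocks")$b1
    sub <- igraph::induced_subgraph(networkGraph(net), b1)
    expect_equal(igraph::ecount(sub), choose(length(b1), 2))
    ## no isolated nodes; noise genes are absent
    expect_true(all(igraph::degree(networkGraph(net)) > 0))
})

test_that("edge sets are monotone along a threshold ladder", {
    set.seed(43)
    m <- matrix(rnorm(240), 20, 12,
                dimnames = list(paste0("g", 1:20), NULL))
    cm <- cor(t(m))
    edgeKey <- function(net) {
        ed <- networkEdges(net)
        paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
    }
    ladder <- c(0.3, 0.5, 0.7, 0.9)
    keys <- lapply(ladder, function(th) edgeKey(buildNetwork(cm, th)))
    for (i in seq_len(length(ladder) - 1))
        expect_true(all(keys[[i + 1]] %in% keys[[i]]))
    ## threshold 1.0 on a noisy matrix gives an empty network
    empty <- buildNetwork(cm, 1.0)
    expect_length(networkNodes(empty), 0)
    expect_error(buildNetwork(cm, 0), "threshold")
})

test_that("fast-greedy modules match structure on canonical graphs", {
    ## two disjoint 5-cliques: exactly two modules, matching brute force
    cm <- diag(10)
    cm[1:5, 1:5] <- 0.99
    cm[6:10, 6:10] <- 0.99
    diag(cm) <- 1
    rownames(cm) <- colnames(cm) <- paste0("g", 1:10)
    net <- buildNetwork(cm, 0.98)
    mp <- detectModules(net)
    expect_length(unique(moduleMembership(mp)), 2)
    expect_length(unique(moduleMembership(mp)[paste0("g", 1:5)]), 1)
    expect_equal(modularityQ(mp),
                 exactMaxModularity(networkGraph(net)), tolerance = 1e-10)
    expect_equal(sort(as.integer(moduleSizes(mp))), c(5L, 5L))
    expect_length(smallModules(mp), 0)

    ## complete graph: one module
    cmFull <- matrix(0.99, 6, 6,
                     dimnames = list(paste0("g", 1:6), paste0("g", 1:6)))
    diag(cmFull) <- 1
    mpFull <- detectModules(buildNetwork(cmFull, 0.98))
    expect_length(unique(moduleMembership(mpFull)), 1)

    ## single edge: both nodes in one (small) module
    cm2 <- diag(2)
    cm2[1, 2] <- cm2[2, 1] <- 0.99
    rownames(cm2) <- colnames(cm2) <- c("a", "b")
    mp2 <- detectModules(buildNetwork(cm2, 0.98))
    expect_length(unique(moduleMembership(mp2)), 1)
    expect_equal(smallModules(mp2), unique(moduleMembership(mp2)))

    emptyNet <- buildNetwork(diag(3), 1.0)
    expect_error(detectModules(emptyNet), "empty")
})

test_that("planted co-expression blocks are recovered as modules", {
    sim <- simulateExpression(simConfig(
        nGenes = 60, states = paste0("s", 1:4), deStates = character(0),
        moduleSpec = rep(list(list(size = 10, rho = 0.97)), 4),
        seed = 23))
    cm <- geneCorrelations(sim$expression)
    net <- buildNetwork(cm, 0.9)
    mp <- detectModules(net)
    truth <- sim$truth$moduleMembership
    common <- intersect(names(truth), names(moduleMembership(mp)))
    expect_gte(length(common) / length(truth), 0.9)
    ari <- mclust::adjustedRandIndex(truth[common],
                                     moduleMembership(mp)[common])
    expect_gte(ari, 0.9)
})

test_that("network comparison accounting identities always hold", {
    acc <- networkAccounting(216, 283, 186)
    expect_equal(acc$aSpecific, 30)
    expect_equal(acc$bSpecific, 97)
    expect_equal(round(acc$shrinkagePercent, 1), 23.7)
    expect_error(networkAccounting(5, 5, 6), "exceeds")

    cmA <- plantedTwoBlockMatrix(blockSize = 6, nNoise = 0, seed = 3)
    cmB <- cmA[1:9, 1:9]
    netA <- buildNetwork(cmA, 0.98)
    netB <- buildNetwork(cmB, 0.98)
    cmp <- compareNetworks(netA, netB, k = 3)
    expect_equal(length(cmp$shared) + length(cmp$aSpecific),
                 length(networkNodes(netA)))
    expect_equal(length(cmp$shared) + length(cmp$bSpecific),
                 length(networkNodes(netB)))
    expect_lte(nrow(cmp$hubsA), 3)

    same <- compareNetworks(netA, netA)
    expect_equal(same$shrinkagePercent, 0)
    expect_length(same$aSpecific, 0)
    expect_setequal(same$shared, networkNodes(netA))

    ## disjoint node sets share nothing
    cmC <- cmB
    rownames(cmC) <- colnames(cmC) <- paste0("h", 1:9)
    cmpD <- compareNetworks(netB, buildNetwork(cmC, 0.98))
    expect_length(cmpD$shared, 0)

    ## module-overlap table covers every shared node
    mpA <- detectModules(netA); mpB <- detectModules(netB)
    cmpM <- compareNetworks(netA, netB, modulesA = mpA, modulesB = mpB)
    expect_setequal(cmpM$moduleOverlap$node, cmp$shared)
})

test_that("first neighbours induce the expected subgraphs", {
    ## star: the centre as seed returns the whole star
    star <- matrix(0, 5, 5, dimnames = list(paste0("g", 1:5),
                                            paste0("g", 1:5)))
    star[1, 2:5] <- star[2:5, 1] <- 0.99
    diag(star) <- 1
    net <- buildNetwork(star, 0.98)
    sub <- firstNeighbors(net, "g1")
    expect_setequal(igraph::V(sub)$name, paste0("g", 1:5))
    ## a leaf as seed returns only centre + leaf
    leaf <- firstNeighbors(net, "g2")
    expect_setequal(igraph::V(leaf)$name, c("g1", "g2"))
    ## seed inside a clique returns the clique
    cm <- diag(6)
    cm[1:5, 1:5] <- 0.99
    diag(cm) <- 1
    rownames(cm) <- colnames(cm) <- paste0("g", 1:6)
    clique <- buildNetwork(cm, 0.98)
    subc <- firstNeighbors(clique, "g3")
    expect_setequal(igraph::V(subc)$name, paste0("g", 1:5))
    expect_warning(firstNeighbors(net, c("g1", "zz")), "absent")
    expect_error(firstNeighbors(net, "zz"), "none of the seed")
})

test_that("RMT threshold selection degrades gracefully", {
    set.seed(47)
    m <- matrix(rnorm(180), 15, 12,
                dimnames = list(paste0("g", 1:15), NULL))
    cm <- cor(t(m))
    expect_warning(res <- rmtThreshold(cm, grid = 1.0), "grid maximum")
    expect_equal(res$threshold, 1.0)
    expect_error(rmtThreshold(cm[1:5, 1:5]), "10 x 10")
    expect_error(rmtThreshold(cm, grid = c(0.9, 0.5)), "ascending")
})

test_that("RMT separates planted correlation blocks", {
    cm <- plantedTwoBlockMatrix(blockSize = 15, nNoise = 30, seed = 7)
    ## the degenerate block spectrum may fall through to the grid
    ## maximum, which is a valid (separating) selection
    res <- suppressWarnings(
        rmtThreshold(cm, grid = seq(0.30, 0.99, by = 0.01)))
    blocks <- attr(cm, "blocks")
    between <- abs(cm[blocks$b1, blocks$b2])
    expect_gt(res$threshold, max(between))   # no between-block edge
    net <- buildNetwork(cm, res$threshold)
    ed <- networkEdges(net)
    crossing <- (ed$from %in% blocks$b1 & ed$to %in% blocks$b2) |
        (ed$from %in% blocks$b2 & ed$to %in% blocks$b1)
    expect_equal(sum(crossing), 0)
})
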