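test_that("absolute profiles are replicate means, invariant to order", {
    m <- matrix(c(1, 2, 3, 10, 20, 30), 1, 6,
                dimnames = list("g1", paste0("s", 1:6)))
    ses <- stateExpressionSet(m, state = rep(c("A", "B"), each = 3),
                              replicate = rep(1:3, 2))
    prof <- absoluteStates(ses)
    expect_equal(prof["g1", "A"], 2)
    expect_equal(prof["g1", "B"], 20)
    ## permuting replicate columns leaves profiles unchanged
    perm <- c(3, 1, 2, 5, 6, 4)
    ses2 <- stateExpressionSet(m[, perm, drop = FALSE],
                               state = rep(c("A", "B"), each = 3),
                               replicate = c(3, 1, 2, 2, 3, 1))
    expect_equal(absoluteStates(ses2), prof)
})

test_that("relative states apply the strict more-than-k-fold filter", {
    ## g1 sits exactly at log2 ratio 1.0 (excluded), g2 at 1.1 (included)
    treat <- rbind(g1 = c(1, 1, 1), g2 = c(1.1, 1.1, 1.1))
    ses <- makeTinySet(treat, ctrl = matrix(0, 2, 3),
                       genes = c("g1", "g2"))
    rel <- relativeStates(ses, contrasts = list(c("T", "C")))
    expect_equal(rownames(rel), "g2")
    expect_equal(colnames(rel), "T vs C")
    expect_error(relativeStates(ses, contrasts = list(c("T", "C")),
                                foldFilter = 10), "relax")
    expect_error(relativeStates(ses, contrasts = list(c("T", "C")),
                                foldFilter = 1), "> 1")
})

test_that("eight contrasts give 28 pairwise relative-state distances", {
    sim <- simulateExpression(simConfig(nGenes = 200, deFraction = 0.2,
                                        seed = 2))
    rel <- relativeStates(sim$expression)
    expect_equal(ncol(rel), 8)
    dm <- stateDistances(rel, "relative")
    d <- as.matrix(dm)
    expect_equal(sum(upper.tri(d)), 28)
})

test_that("Pearson distances match the long-hand definition", {
    ## identical profiles -> 0; negated -> 2
    p <- cbind(a = c(1, 2, 3, 1), b = c(1, 2, 3, 1), c = -c(1, 2, 3, 1))
    d <- as.matrix(stateDistances(p))
    expect_equal(d["a", "b"], 0)
    expect_equal(d["a", "c"], 2)
    ## long-hand Pearson for (1,2,3) vs (1,2,4)
    x <- c(1, 2, 3); y <- c(1, 2, 4)
    r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    d2 <- as.matrix(stateDistances(cbind(a = x, b = y)))
    expect_equal(d2["a", "b"], 1 - r, tolerance = 1e-12)
    expect_equal(round(d2["a", "b"], 4), 0.0180)
    expect_error(stateDistances(cbind(a = c(1, 1, 1), b = 1:3)),
                 "zero-variance.*a")
})

test_that("distance matrices are metric-shaped and affine-invariant", {
    set.seed(13)
    p <- matrix(rnorm(400), 50, 8,
                dimnames = list(NULL, paste0("s", 1:8)))
    d <- as.matrix(stateDistances(p))
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 8))
    expect_true(all(d >= 0 & d <= 2))
    ## positive-slope affine rescaling of any profile leaves d unchanged
    p2 <- p
    p2[, 3] <- 5 + 2.7 * p2[, 3]
    expect_equal(as.matrix(stateDistances(p2)), d, tolerance = 1e-12)
})

test_that("bootstrap trees are deterministic and support planted groups", {
    set.seed(31)
    base1 <- rnorm(150); base2 <- rnorm(150)
    prof <- cbind(a1 = base1 + rnorm(150, 0, 0.1),
                  a2 = base1 + rnorm(150, 0, 0.1),
                  a3 = base1 + rnorm(150, 0, 0.1),
                  b1 = base2 + rnorm(150, 0, 0.1),
                  b2 = base2 + rnorm(150, 0, 0.1),
                  b3 = base2 + rnorm(150, 0, 0.1))
    bt1 <- bootstrapTree(prof, nBoot = 200, seed = 5)
    bt2 <- bootstrapTree(prof, nBoot = 200, seed = 5)
    expect_identical(supportValues(bt1), supportValues(bt2))
    tree <- supportTree(bt1)
    node <- ape::getMRCA(tree, c("a1", "a2", "a3"))
    support <- supportValues(bt1)[node - length(tree$tip.label)]
    expect_gte(support, 99)
    expect_true(all(supportValues(bt1) >= 0 & supportValues(bt1) <= 100))
    ## three profiles: a single internal node besides the root
    bt3 <- bootstrapTree(prof[, 1:3], nBoot = 50, seed = 1)
    expect_lte(length(supportValues(bt3)), 2)
    expect_error(bootstrapTree(prof, nBoot = 0), "nBoot")
    expect_error(bootstrapTree(prof[, 1:2]), ">= 3")
})

test_that("convergence equals the brute-force off-diagonal minimum", {
    set.seed(17)
    for (trial in 1:5) {
        p <- matrix(rnorm(300), 50, 6,
                    dimnames = list(NULL, paste0("r", 1:6)))
        dm <- stateDistances(p, "relative")
        d <- as.matrix(dm)
        mm <- microevolutionMetrics(dm, dm,
                                    groups = list(c("r1", "r2"),
                                                  c("r3", "r4")),
                                    trajectory = c("r1", "r2", "r3"))
        expect_equal(mm$convergence$distance,
                     min(d[upper.tri(d)]), tolerance = 1e-12)
        expect_equal(unname(d[mm$convergence$pair[1],
                              mm$convergence$pair[2]]),
                     mm$convergence$distance)
    }
})

test_that("microevolution metrics match their definitions", {
    labs <- c("t0", "t1", "t2", "t3")
    d <- matrix(0, 4, 4, dimnames = list(labs, labs))
    d["t0", "t1"] <- d["t1", "t0"] <- 0.5
    d["t0", "t2"] <- d["t2", "t0"] <- 0.4
    d["t0", "t3"] <- d["t3", "t0"] <- 0.1   # returns toward the origin
    d["t1", "t2"] <- d["t2", "t1"] <- 0.05
    d["t1", "t3"] <- d["t3", "t1"] <- 0.45
    d["t2", "t3"] <- d["t3", "t2"] <- 0.35
    dm <- new("StateDistanceMatrix", distances = d, type = "absolute")
    dmr <- new("StateDistanceMatrix", distances = d, type = "relative")
    mm <- microevolutionMetrics(dm, dmr,
                                groups = list(c("t0", "t3"),
                                              c("t1", "t2")),
                                trajectory = labs)
    expect_true(mm$resilience$returned)
    expect_equal(mm$distinctness$minInter, 0.35)
    expect_equal(mm$distinctness$maxIntra, 0.1)
    expect_true(mm$distinctness$separated)
    expect_equal(mm$discreteness$state, "t3")
    expect_equal(mm$discreteness$distance, 0.1)
    ## memory table is ranked most-similar first
    expect_equal(mm$memory$distance, sort(mm$memory$distance))
    expect_equal(c(mm$memory$a[1], mm$memory$b[1]), c("t1", "t2"))
    expect_error(microevolutionMetrics(dm, dmr,
                                       groups = list("t0", "zz"),
                                       trajectory = labs), "unknown")
})

test_that("equal distances break convergence ties lexicographically", {
    labs <- c("b", "a", "c")
    d <- matrix(0.3, 3, 3, dimnames = list(labs, labs))
    diag(d) <- 0
    dm <- new("StateDistanceMatrix", distances = d, type = "relative")
    mm <- microevolutionMetrics(dm, dm,
                                groups = list("a", "b"),
                                trajectory = labs)
    expect_equal(mm$convergence$pair, c("a", "b"))
    expect_false(mm$distinctness$separated)
})
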