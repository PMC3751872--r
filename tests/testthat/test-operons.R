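## hand-built coverage/link tables for one polycistron
covTab <- function(depths, reps = 3) {
    ## depths: named list gene -> per-replicate mean depth (recycled)
    do.call(rbind, lapply(seq_len(reps), function(r)
        data.frame(gene_id = names(depths),
                   replicate = r,
                   meanDepth = vapply(depths, function(d)
                       if (length(d) >= r) d[r] else d[1], 0))))
}
linkTab <- function(pairs, reps = 3, n = 5) {
    if (length(pairs) == 0)
        return(data.frame(gene_i = character(), gene_j = character(),
                          replicate = integer(), n_pairs = integer()))
    do.call(rbind, lapply(seq_len(reps), function(r)
        data.frame(gene_i = vapply(pairs, `[`, "", 1),
                   gene_j = vapply(pairs, `[`, "", 2),
                   replicate = r, n_pairs = n)))
}

test_that("coverage summaries average per-base depth over the gene", {
    rle <- S4Vectors::Rle(c(0, 10, 10, 10, 10, 0, 0, 5, 0, 0),
                          c(10, 10, 10, 10, 10, 10, 5, 5, 10, 30))
    track <- methods::as(list(chr1 = rle), "RleList")
    genes <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(c(11, 61, 91), c(50, 70, 100)),
        gene_id = c("a", "b", "c"))
    sc <- summarizeCoverage(track, genes)
    expect_equal(sc$meanDepth, c(10, 2.5, 0))
    expect_equal(sc$expressed, c(TRUE, FALSE, FALSE))
    outside <- GenomicRanges::GRanges("chr1",
                                      IRanges::IRanges(100, 200),
                                      gene_id = "z")
    expect_error(summarizeCoverage(track, outside), "z")
})

test_that("the two-requirement split rule is applied per replicate", {
    poly <- list(id = "p", genes = c("g1", "g2", "g3"))
    ## depths (100, 40, 38): ratio 2.5 > 2 between g1 and g2
    cov <- covTab(list(g1 = 100, g2 = 40, g3 = 38))
    links <- linkTab(list(c("g2", "g3")))
    om <- callSuboperons(poly, cov, links)
    expect_equal(suboperons(om), list("g1", c("g2", "g3")))
    expect_equal(splitPoints(om), 1L)

    ## no ratio exceeds 2: a single operon
    cov2 <- covTab(list(g1 = 50, g2 = 50, g3 = 49))
    links2 <- linkTab(list(c("g1", "g2"), c("g2", "g3")))
    om2 <- callSuboperons(poly, cov2, links2)
    expect_equal(suboperons(om2), list(c("g1", "g2", "g3")))

    ## ratio exactly 2.0 is NOT a split (strictly greater than)
    cov3 <- covTab(list(g1 = 100, g2 = 50, g3 = 50))
    om3 <- callSuboperons(poly, cov3, links2)
    expect_equal(splitPoints(om3), integer(0))

    ## a ratio above 2 in only some replicates is not a split
    cov4 <- covTab(list(g1 = c(100, 100, 100), g2 = c(40, 60, 40),
                        g3 = c(40, 60, 40)))
    om4 <- callSuboperons(poly, cov4, links2)
    expect_equal(splitPoints(om4), integer(0))
})

test_that("missing pair support splits units into monocistrons", {
    poly <- list(id = "p", genes = c("g1", "g2", "g3"))
    cov <- covTab(list(g1 = 50, g2 = 50, g3 = 50))
    ## no bridging pairs anywhere: all monocistrons
    om <- callSuboperons(poly, cov, linkTab(list()))
    expect_equal(suboperons(om), list("g1", "g2", "g3"))
    ## support only between g1-g2
    om2 <- callSuboperons(poly, cov, linkTab(list(c("g1", "g2"))))
    expect_equal(suboperons(om2), list(c("g1", "g2"), "g3"))
    ## pair support missing in one replicate is not support
    partial <- linkTab(list(c("g1", "g2"), c("g2", "g3")))
    partial <- partial[!(partial$gene_i == "g2" & partial$replicate == 2), ]
    om3 <- callSuboperons(poly, cov, partial)
    expect_equal(suboperons(om3), list(c("g1", "g2"), "g3"))
})

test_that("unexpressed genes are excluded and break contiguity", {
    poly <- list(id = "p", genes = c("g1", "g2", "g3"))
    cov <- covTab(list(g1 = 50, g2 = 0, g3 = 50))
    links <- linkTab(list(c("g1", "g2"), c("g2", "g3")))
    om <- callSuboperons(poly, cov, links)
    expect_equal(om@unexpressed, "g2")
    expect_equal(suboperons(om), list("g1", "g3"))
})

test_that("split decisions are invariant to uniform depth scaling", {
    poly <- list(id = "p", genes = c("g1", "g2", "g3", "g4"))
    links <- linkTab(list(c("g1", "g2"), c("g2", "g3"), c("g3", "g4")))
    base <- list(g1 = 90, g2 = 30, g3 = 28, g4 = 80)
    om <- callSuboperons(poly, covTab(base), links)
    scaled <- covTab(lapply(base, function(d) d * 7.3))
    omS <- callSuboperons(poly, scaled, links)
    expect_equal(splitPoints(om), splitPoints(omS))
    expect_equal(suboperons(om), suboperons(omS))
})

test_that("replicate structure is validated", {
    poly <- list(id = "p", genes = c("g1", "g2"))
    cov <- covTab(list(g1 = 50, g2 = 50), reps = 2)
    links <- linkTab(list(c("g1", "g2")), reps = 2)
    expect_error(callSuboperons(poly, cov, links), "3 replicates")
    om <- callSuboperons(poly, cov, links, replicates = 2L)
    expect_equal(suboperons(om), list(c("g1", "g2")))
})

test_that("suboperons partition the expressed genes on random inputs", {
    set.seed(53)
    for (trial in 1:20) {
        n <- sample(3:7, 1)
        genes <- paste0("g", seq_len(n))
        depths <- as.list(stats::runif(n, 0, 100))
        names(depths) <- genes
        pairs <- Filter(function(p) stats::runif(1) < 0.7,
                        lapply(seq_len(n - 1),
                               function(i) genes[c(i, i + 1)]))
        om <- callSuboperons(list(id = "p", genes = genes),
                             covTab(depths), linkTab(pairs))
        members <- unlist(suboperons(om))
        expect_setequal(members, setdiff(genes, om@unexpressed))
        expect_equal(match(members, genes), sort(match(members, genes)))
    }
})

test_that("dynamic-operon calls are symmetric differences of splits", {
    poly <- list(id = "p", genes = paste0("g", 1:4))
    links <- linkTab(list(c("g1", "g2"), c("g2", "g3"), c("g3", "g4")))
    one <- callSuboperons(poly, covTab(list(g1 = 50, g2 = 50, g3 = 50,
                                            g4 = 50)),
                          links, condition = "A")
    three <- callSuboperons(poly, covTab(list(g1 = 90, g2 = 20, g3 = 90,
                                              g4 = 85)),
                            links, condition = "B")
    expect_length(suboperons(one), 1)
    expect_length(suboperons(three), 3)
    calls <- compareOperons(list(one), list(three))
    expect_equal(nrow(calls), 2)            # two boundary differences
    expect_setequal(calls$boundary, c(1L, 2L))
    expect_true(all(calls$presentIn == "B"))
    ## identical models: no calls
    expect_equal(nrow(compareOperons(list(one), list(one))), 0)
    bad <- callSuboperons(list(id = "q", genes = paste0("g", 1:4)),
                          covTab(list(g1 = 50, g2 = 50, g3 = 50,
                                      g4 = 50)), links)
    expect_error(compareOperons(list(one), list(bad)), "ids differ")
})

test_that("planted condition-specific splits are recovered end to end", {
    g <- simulateGenome(nGenes = 4, seed = 61)
    genes <- g$genes$gene_id
    specA <- list(list(id = "p1", genes = genes, splits = 2L,
                       depthMult = c(3, 3, 1, 1)))
    specB <- list(list(id = "p1", genes = genes, splits = integer(0),
                       depthMult = rep(1, 4)))
    readsA <- simulateOperonReads(g$genes, specA, depth = 80, seed = 61,
                                  conditions = "A")
    readsB <- simulateOperonReads(g$genes, specB, depth = 80, seed = 61,
                                  conditions = "B")
    modelA <- callSuboperons(list(id = "p1", genes = genes),
                             coverageTable(readsA, "A", g$genes),
                             readsA$links, condition = "A")
    modelB <- callSuboperons(list(id = "p1", genes = genes),
                             coverageTable(readsB, "B", g$genes),
                             readsB$links, condition = "B")
    expect_equal(splitPoints(modelA), 2L)
    expect_equal(splitPoints(modelB), integer(0))
    calls <- compareOperons(list(modelA), list(modelB))
    expect_equal(nrow(calls), 1)
    expect_equal(calls$boundary, 2L)
    expect_equal(calls$presentIn, "A")
})
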