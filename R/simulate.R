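#' Build a synthetic-study configuration
#'
#' Defaults mirror the reference study design: nine cellular states in
#' biological triplicate, Gaussian log2 noise, and 140x pooled sequencing
#' depth.  All planted structure (differential genes, co-expression
#' blocks, shared "memory" signatures, operon splits, pooled allele
#' frequencies) is optional and off by default.
#'
#' @param nGenes number of genes.
#' @param states state labels; default [defaultStates()].
#' @param replicates replicates per state.
#' @param noiseSd per-measurement Gaussian noise SD (log2 units).
#' @param deFraction fraction of genes planted as differential.
#' @param deEffect planted shift (log2 units) applied in `deStates`.
#' @param deStates states receiving the planted shift; default all states
#'   except the first (the reference/control state).
#' @param moduleSpec list of `list(size =, rho =)` co-expression blocks.
#' @param memorySpec list of `list(pair = list(c(t1, c1), c(t2, c2)),
#'   nGenes =, sd =)` shared-signature constraints between two contrasts.
#' @param operonSpec list of `list(id =, genes =, splits =, depthMult =)`
#'   planted polycistrons (see [simulateOperonReads()]).
#' @param poolSpec data.frame with columns `pos`, `freq`.
#' @param depth mean sequencing depth.
#' @param seed master integer seed.
#' @return a [SimulationConfig-class] object.
#' @export
simConfig <- function(nGenes = 500L, states = defaultStates(),
                      replicates = 3L, noiseSd = 0.25,
                      deFraction = 0, deEffect = 2.0,
                      deStates = states[-1],
                      moduleSpec = list(), memorySpec = list(),
                      operonSpec = list(),
                      poolSpec = data.frame(pos = integer(),
                                            freq = numeric()),
                      depth = 140, seed = 1L) {
    new("SimulationConfig", nGenes = as.integer(nGenes),
        states = as.character(states), replicates = as.integer(replicates),
        noiseSd = noiseSd, deFraction = deFraction, deEffect = deEffect,
        deStates = as.character(deStates), moduleSpec = moduleSpec,
        memorySpec = memorySpec, operonSpec = operonSpec,
        poolSpec = poolSpec, depth = depth, seed = as.integer(seed))
}

relLabel <- function(treatment, control) paste(treatment, "vs", control)

## Derived substream seeds keep the three generators reproducible yet
## decoupled; offsets are arbitrary small constants.
substreamSeed <- function(seed, k) (as.integer(seed) + 97L * k) %% 2147483647L

#' Simulate a replicated multi-state expression experiment
#'
#' Generates a gene x sample matrix of log2 ratios against a common
#' reference with planted structure, together with the ground truth needed
#' for recovery testing.  Planted elements:
#' \itemize{
#'   \item differential genes: `deFraction` of genes shifted by
#'     `+/- deEffect` in every state of `deStates`;
#'   \item co-expression blocks: each block shares one latent factor with
#'     loading chosen so the expected within-block Pearson correlation is
#'     the requested `rho`;
#'   \item memory signatures: a common random contrast signature added to
#'     the treatment state of both contrasts of each `memorySpec` pair,
#'     which makes those two relative states the most similar pair.
#' }
#' Noise is homoscedastic Gaussian in log2 space.
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements `expression` (a
#'   [StateExpressionSet-class]) and `truth` (list: `deGenes`, per-contrast
#'   `dePerContrast`, `moduleMembership`, `plantedNearestPair`).
#' @examples
#' sim <- simulateExpression(simConfig(nGenes = 100, deFraction = 0.1,
#'                                     seed = 7))
#' sim$expression
#' length(sim$truth$deGenes)
#' @export
simulateExpression <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    set.seed(substreamSeed(config@seed, 1L))
    nG <- config@nGenes
    states <- config@states
    reps <- config@replicates
    genes <- sprintf("gene%04d", seq_len(nG))

    ## state-level mean log2 ratios
    M <- matrix(0, nG, length(states), dimnames = list(genes, states))

    ## planted differential genes
    nDE <- round(config@deFraction * nG)
    deGenes <- character(0)
    if (nDE > 0) {
        deGenes <- sample(genes, nDE)
        sign <- sample(c(-1, 1), nDE, replace = TRUE)
        M[deGenes, config@deStates] <-
            M[deGenes, config@deStates] + sign * config@deEffect
    }

    ## planted memory signatures (shared contrast shift between two pairs)
    plantedNearestPair <- NULL
    bestStrength <- -Inf
    for (ms in config@memorySpec) {
        nMem <- if (is.null(ms$nGenes)) max(10L, round(0.1 * nG)) else ms$nGenes
        sdMem <- if (is.null(ms$sd)) 1.5 else ms$sd
        memGenes <- sample(genes, nMem)
        sig <- stats::rnorm(nMem, 0, sdMem)
        for (pr in ms$pair) {
            t <- pr[1]; c <- pr[2]
            if (!all(c(t, c) %in% states))
                stop("memorySpec pair references unknown state")
            M[memGenes, t] <- M[memGenes, t] + sig
        }
        strength <- nMem * sdMem^2
        if (strength > bestStrength) {
            bestStrength <- strength
            plantedNearestPair <- vapply(ms$pair,
                function(pr) relLabel(pr[1], pr[2]), "")
        }
    }

    ## sample matrix: replicate columns with block latent factors + noise
    nS <- length(states) * reps
    state <- rep(states, each = reps)
    replicate <- rep(seq_len(reps), times = length(states))
    vals <- M[, state, drop = FALSE] +
        matrix(stats::rnorm(nG * nS, 0, config@noiseSd), nG, nS)

    moduleMembership <- integer(0)
    if (length(config@moduleSpec)) {
        pool <- sample(genes)          # disjoint block members
        off <- 0L
        for (b in seq_along(config@moduleSpec)) {
            spec <- config@moduleSpec[[b]]
            blockGenes <- pool[(off + 1L):(off + spec$size)]
            off <- off + spec$size
            rho <- spec$rho
            loading <- config@noiseSd * sqrt(rho / (1 - rho))
            f <- stats::rnorm(nS)
            vals[blockGenes, ] <- vals[blockGenes, ] +
                loading * matrix(f, length(blockGenes), nS, byrow = TRUE)
            mm <- rep(b, spec$size); names(mm) <- blockGenes
            moduleMembership <- c(moduleMembership, mm)
        }
    }

    colnames(vals) <- paste0(state, ".r", replicate)
    expr <- stateExpressionSet(vals, state = state, replicate = replicate)

    ## per-contrast planted-DE truth for the default contrast design
    contrasts <- Filter(function(p) all(p %in% states), defaultContrasts())
    dePerContrast <- lapply(contrasts, function(p) {
        tIn <- p[1] %in% config@deStates
        cIn <- p[2] %in% config@deStates
        if (xor(tIn, cIn)) deGenes else character(0)
    })
    names(dePerContrast) <- vapply(contrasts,
                                   function(p) relLabel(p[1], p[2]), "")

    list(expression = expr,
         truth = list(deGenes = deGenes, dePerContrast = dePerContrast,
                      moduleMembership = moduleMembership,
                      plantedNearestPair = plantedNearestPair,
                      stateMeans = M))
}

#' Simulate RNA-seq coverage and paired-end links over polycistrons
#'
#' For each condition and replicate, per-base read depths are drawn
#' Poisson around each gene's planted mean (`depth` times the gene's
#' `depthMult`), and bridging read-pair counts are drawn positive for
#' adjacent gene pairs within a planted transcription unit and set to zero
#' across planted split boundaries.  Genes with `depthMult = 0` receive no
#' coverage (unexpressed).
#'
#' @param annotation a [GenomicRanges::GRanges] of genes with a `gene_id`
#'   metadata column (e.g. from [simulateGenome()] or [readAnnotation()]).
#' @param operonSpec list of planted polycistrons:
#'   `list(id =, genes = <ordered ids>, splits = <boundary indices>,
#'   depthMult = <per-gene multiplier>)`.
#' @param depth mean per-base depth for a multiplier of 1.
#' @param seed integer seed.
#' @param conditions condition labels to simulate.
#' @param replicates replicates per condition.
#' @return list with `coverage` (nested list
#'   `coverage[[condition]][[replicate]]`, each an [S4Vectors::Rle] of
#'   per-base depth per chromosome in an `RleList`), `links` (data.frame
#'   `gene_i, gene_j, condition, replicate, n_pairs`) and `truth`
#'   (per-polycistron planted split indices).
#' @export
simulateOperonReads <- function(annotation, operonSpec, depth = 140,
                                seed = 1L, conditions = "c1",
                                replicates = 3L) {
    if (depth < 0) stop("depth must be >= 0")
    gid <- annotation$gene_id
    for (op in operonSpec) {
        missing <- setdiff(op$genes, gid)
        if (length(missing))
            stop("polycistron gene(s) not in annotation: ",
                 paste(missing, collapse = ", "))
    }
    set.seed(substreamSeed(seed, 2L))
    chroms <- GenomeInfoDb::seqlevels(annotation)
    chromLen <- vapply(chroms, function(ch)
        max(GenomicRanges::end(annotation[
            GenomicRanges::seqnames(annotation) == ch])) + 100L, 0)

    coverage <- list()
    links <- list()
    for (cond in conditions) {
        coverage[[cond]] <- list()
        for (r in seq_len(replicates)) {
            depths <- lapply(chromLen, function(L) integer(L))
            for (op in operonSpec) {
                mult <- op$depthMult
                if (is.null(mult)) mult <- rep(1, length(op$genes))
                for (k in seq_along(op$genes)) {
                    g <- annotation[match(op$genes[k], gid)]
                    ch <- as.character(GenomicRanges::seqnames(g))
                    span <- GenomicRanges::start(g):GenomicRanges::end(g)
                    lam <- depth * mult[k]
                    depths[[ch]][span] <- depths[[ch]][span] +
                        if (lam > 0) stats::rpois(length(span), lam) else 0L
                }
            }
            coverage[[cond]][[r]] <- methods::as(
                lapply(depths, S4Vectors::Rle), "RleList")
            for (op in operonSpec) {
                mult <- op$depthMult
                if (is.null(mult)) mult <- rep(1, length(op$genes))
                nGenes <- length(op$genes)
                if (nGenes < 2) next
                for (k in seq_len(nGenes - 1)) {
                    crossesSplit <- k %in% op$splits
                    eitherOff <- mult[k] == 0 || mult[k + 1] == 0
                    n <- if (crossesSplit || eitherOff) 0L else
                        1L + stats::rpois(1, max(depth, 1) / 10)
                    links[[length(links) + 1L]] <- data.frame(
                        gene_i = op$genes[k], gene_j = op$genes[k + 1],
                        condition = cond, replicate = r, n_pairs = n)
                }
            }
        }
    }
    truth <- lapply(operonSpec, function(op) op$splits)
    names(truth) <- vapply(operonSpec, function(op) op$id, "")
    list(coverage = coverage,
         links = if (length(links)) do.call(rbind, links) else
             data.frame(gene_i = character(), gene_j = character(),
                        condition = character(), replicate = integer(),
                        n_pairs = integer()),
         truth = truth)
}

#' Simulate pooled-population read counts at mutated loci
#'
#' Per-locus total depth is Poisson around `depth` (at least one read) and
#' the alternate-read count is binomial at the locus's true allele
#' frequency, matching the "fraction of mutated reads" estimand of
#' pooled-population sequencing.
#'
#' @param poolSpec data.frame with columns `pos` and `freq` (and
#'   optionally `chrom`, `ref`, `alt`).
#' @param depth mean depth (the reference design uses 140x).
#' @param seed integer seed.
#' @return data.frame `chrom, pos, ref, alt, ref_reads, alt_reads`.
#' @export
simulatePoolReads <- function(poolSpec, depth = 140, seed = 1L) {
    if (depth < 1) stop("depth must be >= 1")
    if (any(poolSpec$freq < 0 | poolSpec$freq > 1))
        stop("frequencies must lie in [0, 1]")
    set.seed(substreamSeed(seed, 3L))
    n <- nrow(poolSpec)
    total <- pmax(1L, stats::rpois(n, depth))
    alt <- stats::rbinom(n, total, poolSpec$freq)
    data.frame(
        chrom = if ("chrom" %in% names(poolSpec)) poolSpec$chrom else "chr1",
        pos = poolSpec$pos,
        ref = if ("ref" %in% names(poolSpec)) poolSpec$ref else "A",
        alt = if ("alt" %in% names(poolSpec)) poolSpec$alt else "G",
        ref_reads = total - alt,
        alt_reads = alt)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulate a toy annotated bacterial genome
#'
#' Builds one circular-free chromosome of alternating intergenic spacers
#' and complete ORFs (ATG ... stop, bacterial code), on randomly chosen
#' strands, for exercising coordinate- and strand-aware annotation.
#'
#' @param nGenes number of genes.
#' @param geneLength CDS length in bp (multiple of 3, >= 9).
#' @param intergenic spacer length between genes.
#' @param seed integer seed.
#' @return list with `genome` (a [Biostrings::DNAStringSet] named "chr1")
#'   and `genes` (a [GenomicRanges::GRanges] with `gene_id`).
#' @export
simulateGenome <- function(nGenes = 10L, geneLength = 300L,
                           intergenic = 100L, seed = 1L) {
    stopifnot(geneLength %% 3 == 0, geneLength >= 9)
    set.seed(substreamSeed(seed, 4L))
    nCodons <- geneLength / 3 - 2L
    bases <- c("A", "C", "G", "T")
    randCodons <- function(n) {
        out <- character(n)
        for (i in seq_len(n)) {
            repeat {
                cd <- paste0(sample(bases, 3, replace = TRUE), collapse = "")
                if (!cd %in% STOP_CODONS && cd != "ATG") break
            }
            out[i] <- cd
        }
        out
    }
    pieces <- character(0)
    starts <- integer(nGenes); ends <- integer(nGenes)
    strands <- character(nGenes)
    pos <- 0L
    for (i in seq_len(nGenes)) {
        spacer <- paste0(sample(bases, intergenic, replace = TRUE),
                         collapse = "")
        orf <- paste0("ATG", paste0(randCodons(nCodons), collapse = ""),
                      sample(STOP_CODONS, 1))
        strands[i] <- sample(c("+", "-"), 1)
        if (strands[i] == "-")
            orf <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(orf)))
        pieces <- c(pieces, spacer, orf)
        starts[i] <- pos + intergenic + 1L
        ends[i] <- starts[i] + geneLength - 1L
        pos <- ends[i]
    }
    tail <- paste0(sample(bases, intergenic, replace = TRUE), collapse = "")
    chrom <- paste0(paste0(pieces, collapse = ""), tail)
    genome <- Biostrings::DNAStringSet(chrom)
    names(genome) <- "chr1"
    genes <- GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(starts, ends), strand = strands,
        gene_id = sprintf("orf%03d", seq_len(nGenes)))
    list(genome = genome, genes = genes)
}

#' Plant mutations of known functional effect in a toy genome
#'
#' For each requested effect class a mutation is drawn at random and its
#' effect verified independently of the annotation machinery: coding
#' effects are established by translating the entire mutant CDS (bacterial
#' translation table) and comparing it to the wild-type protein, so the
#' planted truth does not share code with [annotateEffects()].
#'
#' @param genomeSim output of [simulateGenome()].
#' @param effects character vector drawn from `synonymous`, `missense`,
#'   `nonsense`, `frameshift`, `intergenic` (repeats allowed).
#' @param seed integer seed.
#' @return data.frame `chrom, pos, ref, alt, truth, gene` with 1-based VCF
#'   positions (indels anchored on the preceding base).
#' @export
plantMutations <- function(genomeSim, effects, seed = 1L) {
    set.seed(substreamSeed(seed, 5L))
    genome <- genomeSim$genome
    genes <- genomeSim$genes
    chromSeq <- genome[[1]]
    bases <- c("A", "C", "G", "T")
    code <- Biostrings::getGeneticCode("11")

    cdsProtein <- function(g, seqStr) {
        cds <- Biostrings::subseq(seqStr, GenomicRanges::start(g),
                                  GenomicRanges::end(g))
        if (as.character(GenomicRanges::strand(g)) == "-")
            cds <- Biostrings::reverseComplement(cds)
        as.character(Biostrings::translate(cds, genetic.code = code,
                                           if.fuzzy.codon = "solve"))
    }
    classifySnp <- function(g, pos, alt) {
        mutant <- Biostrings::replaceLetterAt(chromSeq, pos, alt)
        p0 <- cdsProtein(g, chromSeq); p1 <- cdsProtein(g, mutant)
        if (p0 == p1) return("synonymous")
        d <- which(strsplit(p0, "")[[1]] != strsplit(p1, "")[[1]])[1]
        if (substr(p1, d, d) == "*") "nonsense" else "missense"
    }

    out <- list()
    for (eff in effects) {
        if (eff == "intergenic") {
            repeat {
                pos <- sample(length(chromSeq), 1)
                hit <- GenomicRanges::findOverlaps(
                    GenomicRanges::GRanges("chr1",
                                           IRanges::IRanges(pos, pos)),
                    genes)
                if (length(hit) == 0) break
            }
            ref <- as.character(Biostrings::subseq(chromSeq, pos, pos))
            alt <- sample(setdiff(bases, ref), 1)
            out[[length(out) + 1L]] <- data.frame(
                chrom = "chr1", pos = pos, ref = ref, alt = alt,
                truth = "intergenic", gene = NA_character_)
        } else if (eff == "frameshift") {
            gi <- sample(length(genes), 1)
            g <- genes[gi]
            ## single-base deletion inside the CDS, VCF-anchored
            pos <- sample((GenomicRanges::start(g) + 3):
                          (GenomicRanges::end(g) - 4), 1)
            ref <- as.character(Biostrings::subseq(chromSeq, pos, pos + 1))
            alt <- substr(ref, 1, 1)
            out[[length(out) + 1L]] <- data.frame(
                chrom = "chr1", pos = pos, ref = ref, alt = alt,
                truth = "frameshift", gene = g$gene_id)
        } else {
            found <- FALSE
            while (!found) {
                gi <- sample(length(genes), 1)
                g <- genes[gi]
                ## avoid start/stop codons so classes stay clean
                pos <- sample((GenomicRanges::start(g) + 3):
                              (GenomicRanges::end(g) - 3), 1)
                ref <- as.character(Biostrings::subseq(chromSeq, pos, pos))
                for (alt in sample(setdiff(bases, ref))) {
                    if (classifySnp(g, pos, alt) == eff) {
                        out[[length(out) + 1L]] <- data.frame(
                            chrom = "chr1", pos = pos, ref = ref,
                            alt = alt, truth = eff, gene = g$gene_id)
                        found <- TRUE
                        break
                    }
                }
            }
        }
    }
    do.call(rbind, out)
}
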