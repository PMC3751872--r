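callKey <- function(calls)
    paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")

#' Consensus mutation calls across variant callers
#'
#' Intersects the call sets of two or more callers on the key
#' (chrom, pos, ref, alt) - the same position with a different alternate
#' allele is a different call.  Calls not shared by every caller go to a
#' machine-readable side report with their per-caller support.
#'
#' @param callSets named list (>= 2) of data.frames with columns
#'   `chrom, pos, ref, alt`.
#' @return list with `consensus` (data.frame plus a `callerSupport`
#'   column) and `nonConsensus` (side report with `callerSupport`).
#' @examples
#' m1 <- data.frame(chrom = "c", pos = c(5, 9), ref = "A", alt = "G")
#' consensusCalls(list(maq = m1, gatk = m1[1, ]))$consensus
#' @export
consensusCalls <- function(callSets) {
    if (length(callSets) == 0) stop("no call sets given")
    if (length(callSets) < 2)
        warning("only one call set: consensus equals the input")
    if (is.null(names(callSets)))
        names(callSets) <- paste0("caller", seq_along(callSets))
    keys <- lapply(callSets, callKey)
    allCalls <- unique(do.call(rbind, lapply(callSets, function(s)
        s[, c("chrom", "pos", "ref", "alt")])))
    allCalls <- allCalls[order(allCalls$chrom, allCalls$pos,
                               allCalls$ref, allCalls$alt), , drop = FALSE]
    rownames(allCalls) <- NULL
    k <- callKey(allCalls)
    supportMat <- vapply(keys, function(kk) k %in% kk,
                         logical(length(k)))
    if (is.null(dim(supportMat)))
        supportMat <- matrix(supportMat, nrow = length(k))
    nSupport <- rowSums(supportMat)
    allCalls$callerSupport <- apply(supportMat, 1, function(row)
        paste(names(callSets)[row], collapse = ","))
    shared <- nSupport == length(callSets)
    cons <- allCalls[shared, , drop = FALSE]
    rest <- allCalls[!shared, , drop = FALSE]
    rownames(cons) <- rownames(rest) <- NULL
    list(consensus = cons, nonConsensus = rest)
}

#' Annotate mutation calls with region and codon-level effect
#'
#' Classifies each call as coding or non-coding by overlap with the gene
#' annotation; for coding SNPs the affected codon is retrieved respecting
#' strand, translated with the bacterial genetic code (translation table
#' 11) before and after the substitution, and classified as synonymous,
#' missense, or nonsense (stop gain).  Single-base indels inside a coding
#' interval are frameshifts.  A reference allele that disagrees with the
#' genome sequence is an error.
#'
#' @param calls data.frame `chrom, pos, ref, alt` (1-based VCF
#'   convention; indels anchored on the preceding base).
#' @param annotation [GenomicRanges::GRanges] of genes with `gene_id`,
#'   strand-aware.
#' @param genome [Biostrings::DNAStringSet] named by chromosome.
#' @return the calls with columns `type` (`SNP`/`insertion`/`deletion`),
#'   `region` (`coding`/`non-coding`), `gene`, `effect` (`synonymous`,
#'   `missense`, `nonsense`, `frameshift`, `intergenic`).
#' @export
annotateEffects <- function(calls, annotation, genome) {
    code <- Biostrings::getGeneticCode("11")
    n <- nrow(calls)
    type <- character(n); region <- character(n)
    gene <- rep(NA_character_, n); effect <- character(n)
    bad <- character(0)
    for (i in seq_len(n)) {
        chrom <- calls$chrom[i]; pos <- calls$pos[i]
        ref <- calls$ref[i]; alt <- calls$alt[i]
        if (!chrom %in% names(genome))
            stop("unknown chromosome: ", chrom)
        seqChr <- genome[[chrom]]
        if (pos + nchar(ref) - 1 > length(seqChr))
            stop("position beyond chromosome end: ", chrom, ":", pos)
        obs <- as.character(Biostrings::subseq(seqChr, pos,
                                               pos + nchar(ref) - 1))
        if (obs != ref) {
            bad <- c(bad, paste0(chrom, ":", pos, " (expected ", ref,
                                 ", genome has ", obs, ")"))
            next
        }
        isSnp <- nchar(ref) == 1 && nchar(alt) == 1
        type[i] <- if (isSnp) "SNP" else
            if (nchar(ref) > nchar(alt)) "deletion" else "insertion"
        ## the varied base: for anchored indels, the base after the anchor
        varPos <- if (isSnp) pos else pos + 1L
        hit <- GenomicRanges::findOverlaps(
            GenomicRanges::GRanges(chrom, IRanges::IRanges(varPos, varPos)),
            annotation, ignore.strand = TRUE)
        if (length(hit) == 0) {
            region[i] <- "non-coding"
            effect[i] <- "intergenic"
            next
        }
        g <- annotation[S4Vectors::subjectHits(hit)[1]]
        region[i] <- "coding"
        gene[i] <- g$gene_id
        if (!isSnp) {
            effect[i] <- "frameshift"
            next
        }
        minus <- as.character(GenomicRanges::strand(g)) == "-"
        offset <- if (minus) GenomicRanges::end(g) - pos else
            pos - GenomicRanges::start(g)
        codonIdx <- offset %/% 3L
        inCodon <- offset %% 3L           # 0-based position within codon
        if (minus) {
            cEnd <- GenomicRanges::end(g) - 3L * codonIdx
            codon <- Biostrings::reverseComplement(
                Biostrings::subseq(seqChr, cEnd - 2L, cEnd))
            altBase <- as.character(Biostrings::complement(
                Biostrings::DNAString(alt)))
        } else {
            cStart <- GenomicRanges::start(g) + 3L * codonIdx
            codon <- Biostrings::subseq(seqChr, cStart, cStart + 2L)
            altBase <- alt
        }
        refCodon <- as.character(codon)
        mutCodon <- refCodon
        substr(mutCodon, inCodon + 1L, inCodon + 1L) <- altBase
        aaRef <- code[[refCodon]]
        aaMut <- code[[mutCodon]]
        effect[i] <- if (aaRef == aaMut) "synonymous" else
            if (aaMut == "*") "nonsense" else "missense"
    }
    if (length(bad))
        stop("reference allele mismatch at: ", paste(bad, collapse = "; "))
    calls$type <- type; calls$region <- region
    calls$gene <- gene; calls$effect <- effect
    calls
}

#' Pooled-population allele frequencies
#'
#' The pooled mutation frequency of a locus is the fraction of reads
#' carrying the alternate allele, `alt / (ref + alt)`.  Loci with zero
#' depth get `NA` and are flagged.
#'
#' @param pool data.frame with columns `ref_reads` and `alt_reads` (e.g.
#'   from [simulatePoolReads()] or [readPoolCounts()]).
#' @return the input with columns `freq` and `undefined`.
#' @export
pooledFrequency <- function(pool) {
    depth <- pool$ref_reads + pool$alt_reads
    pool$freq <- ifelse(depth > 0, pool$alt_reads / depth, NA_real_)
    pool$undefined <- depth == 0
    pool
}

#' Flag candidate beneficial mutations
#'
#' A consensus mutation is a beneficial candidate when its effect is
#' non-synonymous (missense, nonsense or frameshift) and its pooled
#' frequency strictly exceeds the threshold (the reference rule is
#' "> 80%").
#'
#' @param calls annotated calls carrying `effect` and `pooledFreq`
#'   columns (see [attachPoolFrequencies()]).
#' @param threshold strict frequency threshold, default 0.80.
#' @return the calls with a logical `beneficial` column.
#' @export
beneficialCalls <- function(calls, threshold = 0.80) {
    nonSyn <- calls$effect %in% c("missense", "nonsense", "frameshift")
    calls$beneficial <- nonSyn & !is.na(calls$pooledFreq) &
        calls$pooledFreq > threshold
    calls
}

#' Attach pooled frequencies to mutation calls by locus
#'
#' @param calls data.frame with `chrom` and `pos`.
#' @param pool output of [pooledFrequency()].
#' @return calls with a `pooledFreq` column (`NA` where the locus is not
#'   in the pool table).
#' @export
attachPoolFrequencies <- function(calls, pool) {
    idx <- match(paste(calls$chrom, calls$pos),
                 paste(pool$chrom, pool$pos))
    calls$pooledFreq <- pool$freq[idx]
    calls
}

#' Spontaneous mutation rate per genome per generation
#'
#' `mu_g = n_mutations / generations`, reported to two significant
#' figures.  All consensus mutations (SNPs and single-base indels) count.
#'
#' @param nMutations number of fixed mutations.
#' @param generations generations elapsed (> 0).
#' @return mutation rate (dimensionless, per genome per generation).
#' @examples
#' mutationRate(20, 440)   # 0.045
#' @export
mutationRate <- function(nMutations, generations) {
    if (generations <= 0) stop("generations must be > 0")
    if (nMutations < 0) stop("nMutations must be >= 0")
    signif(nMutations / generations, 2)
}

#' Summarise an annotated mutation call set
#'
#' Tallies calls by type and effect, computes the non-coding to coding
#' ratio as a percentage (one decimal), and lists beneficial candidates
#' when the `beneficial` column is present.
#'
#' @param calls annotated calls ([annotateEffects()]).
#' @return list with `total`, `byType`, `byEffect`, `nCoding`,
#'   `nNonCoding`, `nonCodingCodingPercent`, `beneficial`.
#' @examples
#' calls <- data.frame(type = rep("SNP", 20),
#'                     region = rep(c("coding", "non-coding"), c(17, 3)),
#'                     effect = rep(c("missense", "intergenic"), c(17, 3)))
#' mutationProfile(calls)$nonCodingCodingPercent   # 17.6
#' @export
mutationProfile <- function(calls) {
    if (!all(c("type", "region", "effect") %in% colnames(calls)) ||
        anyNA(calls$region) || anyNA(calls$effect))
        stop("calls must be annotated (type/region/effect) first")
    nCoding <- sum(calls$region == "coding")
    nNonCoding <- sum(calls$region == "non-coding")
    ratio <- if (nCoding > 0) round(nNonCoding / nCoding * 100, 1) else
        NA_real_
    list(total = nrow(calls),
         byType = table(calls$type),
         byEffect = table(calls$effect),
         nCoding = nCoding, nNonCoding = nNonCoding,
         nonCodingCodingPercent = ratio,
         beneficial = if ("beneficial" %in% colnames(calls))
             calls[which(calls$beneficial), , drop = FALSE] else NULL)
}
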