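#' Read an expression matrix and sample metadata from TSV
#'
#' The expression TSV has gene ids in the first column and one column per
#' sample; the metadata TSV maps sample id to state label and replicate
#' index (columns `sample`, `state`, `replicate`).  Missing-value tokens
#' (`NA`, empty) are kept as `NA` and handled downstream by the
#' differential-expression policy (genes with missing replicates are
#' excluded from the affected contrast).
#'
#' @param path expression TSV path.
#' @param metaPath sample-metadata TSV path.
#' @return a [StateExpressionSet-class].
#' @export
readExpression <- function(path, metaPath) {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (anyDuplicated(tab[[1]]))
        stop("duplicate gene id(s) in ", path, ": ",
             paste(unique(tab[[1]][duplicated(tab[[1]])]), collapse = ", "))
    values <- as.matrix(tab[, -1, drop = FALSE])
    rownames(values) <- tab[[1]]
    meta <- utils::read.delim(metaPath, stringsAsFactors = FALSE)
    if (!all(c("sample", "state", "replicate") %in% colnames(meta)))
        stop("metadata needs columns sample, state, replicate")
    missing <- setdiff(colnames(values), meta$sample)
    if (length(missing))
        stop("sample(s) absent from metadata: ",
             paste(missing, collapse = ", "))
    idx <- match(colnames(values), meta$sample)
    stateExpressionSet(values, state = meta$state[idx],
                       replicate = meta$replicate[idx])
}

#' Write a StateExpressionSet to expression + metadata TSV
#'
#' @param x a [StateExpressionSet-class].
#' @param path expression TSV path.
#' @param metaPath metadata TSV path.
#' @return invisibly, the two paths.
#' @export
writeExpression <- function(x, path, metaPath) {
    tab <- data.frame(gene_id = rownames(x), log2Values(x),
                      check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    meta <- data.frame(sample = colnames(x), state = stateLabels(x),
                       replicate = replicateIndex(x))
    utils::write.table(meta, metaPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(path, metaPath))
}

#' Read gene annotation from GFF3
#'
#' Returns gene records with 1-based inclusive coordinates, strand and
#' locus tag (`gene_id`, taken from the `locus_tag` or `ID` attribute).
#' An empty file yields an empty range set with a warning.  Overlapping
#' genes (e.g. on opposite strands) are all retained.
#'
#' @param path GFF3 path.
#' @param feature feature type(s) to keep; default `gene` and `CDS`.
#' @return [GenomicRanges::GRanges] with a `gene_id` column.
#' @export
readAnnotation <- function(path, feature = c("gene", "CDS")) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) %in% feature]
    if (length(gr) == 0) {
        warning("no ", paste(feature, collapse = "/"),
                " records in ", path)
        return(GenomicRanges::GRanges(gene_id = character(0)))
    }
    ids <- if (!is.null(gr$locus_tag)) gr$locus_tag else gr$ID
    if (is.null(ids)) ids <- paste0("feature", seq_along(gr))
    out <- GenomicRanges::granges(gr)
    out$gene_id <- as.character(ids)
    out
}

#' Write gene annotation to GFF3
#'
#' @param genes [GenomicRanges::GRanges] with `gene_id`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeAnnotation <- function(genes, path) {
    gr <- genes
    gr$type <- "gene"
    gr$source <- "EvoShock"
    gr$locus_tag <- genes$gene_id
    gr$ID <- genes$gene_id
    rtracklayer::export(gr, path, format = "gff3")
    invisible(path)
}

#' Read a per-base coverage track from bedGraph
#'
#' bedGraph intervals are 0-based half-open on disk and are expanded to a
#' 1-based per-base run-length encoding per chromosome.
#'
#' @param path bedGraph path.
#' @param chromLengths optional named vector to pad chromosomes to full
#'   length (uncovered tail bases get depth 0).
#' @return `RleList` of per-base depths named by chromosome.
#' @export
readCoverage <- function(path, chromLengths = NULL) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (!is.null(chromLengths))
        GenomeInfoDb::seqlengths(gr) <-
            chromLengths[GenomeInfoDb::seqlevels(gr)]
    GenomicRanges::coverage(gr, weight = "score")
}

#' Write a coverage track to bedGraph
#'
#' @param track `RleList` of per-base depths named by chromosome.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeCoverage <- function(track, path) {
    gr <- methods::as(track, "GRanges")
    gr <- gr[gr$score != 0]
    rtracklayer::export(gr, path, format = "bedGraph")
    invisible(path)
}

#' Read a paired-end gene-link table
#'
#' @param path TSV with columns `gene_i, gene_j, condition, replicate,
#'   n_pairs`.
#' @return data.frame.
#' @export
readLinks <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_i", "gene_j", "condition", "replicate", "n_pairs")
    if (!all(need %in% colnames(tab)))
        stop("link table needs columns: ", paste(need, collapse = ", "))
    tab
}

#' Write a paired-end gene-link table
#'
#' @param links data.frame from [simulateOperonReads()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeLinks <- function(links, path) {
    utils::write.table(links, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read simple variant calls from a VCF file
#'
#' Reads `CHROM, POS, REF, ALT` from a (possibly caller-specific) VCF
#' into the call-set data.frame used by [consensusCalls()].  Positions
#' stay 1-based per the VCF standard.
#'
#' @param path VCF path (plain text).
#' @return data.frame `chrom, pos, ref, alt`.
#' @export
readVcfCalls <- function(path) {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (length(body) == 0)
        return(data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character()))
    fields <- strsplit(body, "\t")
    bad <- which(vapply(fields, length, 0L) < 5)
    if (length(bad))
        stop("malformed VCF line ", bad[1] + sum(startsWith(lines, "#")),
             " in ", path)
    data.frame(chrom = vapply(fields, `[`, "", 1),
               pos = as.integer(vapply(fields, `[`, "", 2)),
               ref = vapply(fields, `[`, "", 4),
               alt = vapply(fields, `[`, "", 5))
}

#' Write annotated mutation calls to VCF
#'
#' Emits a minimal VCF 4.2 file; annotation columns present on the calls
#' (caller support, region, effect, pooled frequency, beneficial flag)
#' become `INFO` fields `SUPPORT`, `REGION`, `EFFECT`, `POOLFREQ`,
#' `BENEFICIAL`.
#'
#' @param calls data.frame of (annotated) calls.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeVcfCalls <- function(calls, path) {
    hdr <- c("##fileformat=VCFv4.2",
             "##source=EvoShock",
             "##INFO=<ID=SUPPORT,Number=1,Type=String,Description=\"Supporting callers\">",
             "##INFO=<ID=REGION,Number=1,Type=String,Description=\"coding or non-coding\">",
             "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Predicted effect\">",
             "##INFO=<ID=POOLFREQ,Number=1,Type=Float,Description=\"Pooled allele frequency\">",
             "##INFO=<ID=BENEFICIAL,Number=0,Type=Flag,Description=\"Candidate beneficial mutation\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    info <- vapply(seq_len(nrow(calls)), function(i) {
        parts <- character(0)
        if (!is.null(calls$callerSupport))
            parts <- c(parts, paste0("SUPPORT=", calls$callerSupport[i]))
        if (!is.null(calls$region))
            parts <- c(parts, paste0("REGION=", calls$region[i]))
        if (!is.null(calls$effect))
            parts <- c(parts, paste0("EFFECT=", calls$effect[i]))
        if (!is.null(calls$pooledFreq) && !is.na(calls$pooledFreq[i]))
            parts <- c(parts, paste0("POOLFREQ=",
                                     format(calls$pooledFreq[i], digits = 4)))
        if (!is.null(calls$beneficial) && isTRUE(calls$beneficial[i]))
            parts <- c(parts, "BENEFICIAL")
        if (length(parts)) paste(parts, collapse = ";") else "."
    }, "")
    body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt,
                  ".", "PASS", info, sep = "\t")
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Read pooled per-locus read counts
#'
#' @param path TSV with columns `chrom, pos, ref, alt, ref_reads,
#'   alt_reads`.
#' @return data.frame.
#' @export
readPoolCounts <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt", "ref_reads", "alt_reads")
    if (!all(need %in% colnames(tab)))
        stop("pool table needs columns: ", paste(need, collapse = ", "))
    if (any(tab$ref_reads < 0 | tab$alt_reads < 0))
        stop("read counts must be >= 0")
    tab
}

#' Write pooled per-locus read counts
#'
#' @param pool data.frame from [simulatePoolReads()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writePoolCounts <- function(pool, path) {
    utils::write.table(pool, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write a distance matrix as TSV
#'
#' @param dm a [StateDistanceMatrix-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeDistances <- function(dm, path) {
    m <- as.matrix(dm)
    utils::write.table(data.frame(state = rownames(m), m,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a bootstrap tree as Newick with support annotations
#'
#' @param bt a [BootstrapTree-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSupportTree <- function(bt, path) {
    ape::write.tree(supportTree(bt), file = path)
    invisible(path)
}

#' Write a co-expression network as edge-list TSV and GraphML
#'
#' @param net a [CoexNetwork-class].
#' @param path edge-list TSV path.
#' @param graphmlPath optional GraphML path.
#' @return invisibly, the path(s).
#' @export
writeNetwork <- function(net, path, graphmlPath = NULL) {
    utils::write.table(networkEdges(net), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(graphmlPath))
        igraph::write_graph(networkGraph(net), graphmlPath,
                            format = "graphml")
    invisible(c(path, graphmlPath))
}

#' Write a genome as FASTA
#'
#' @param genome [Biostrings::DNAStringSet].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeGenome <- function(genome, path) {
    Biostrings::writeXStringSet(genome, path)
    invisible(path)
}
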