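## Readers/writers for the plain-text formats every stage touches.
## Internal convention: GRanges (1-based, closed). File dialects declare their
## own convention at the boundary: BED is 0-based half-open (rtracklayer
## converts), the coverage and cytosine-report TSVs are 1-based.

#' Read per-base methylation calls
#'
#' Reads bismark-style methylation call tables into a
#' [MethylomeTable-class]. Two dialects are supported:
#' \describe{
#'   \item{`coverage`}{`chrom, start, end, pct, countM, countU` with 1-based
#'     positions; one row per strand-merged CpG.}
#'   \item{`cytosine_report`}{`chrom, pos, strand, countM, countU, context`
#'     with 1-based per-strand rows. CpG-context rows are strand-merged onto
#'     the forward-strand C position; non-CpG (CHG/CHH) rows are retained in
#'     `S4Vectors::metadata(sites(x))$nonCpG` for conversion-rate
#'     estimation.}
#' }
#' Counts are authoritative: if a coverage-dialect percentage disagrees with
#' its counts by more than 0.1, a warning is raised and the counts win.
#' Zero-coverage rows are dropped with a warning.
#'
#' @param path file path.
#' @param dialect `"coverage"` or `"cytosine_report"`.
#' @param sampleId sample identifier for the returned table.
#' @return A [MethylomeTable-class], sorted and unique by (chrom, pos).
#' @export
readMethylationCalls <- function(path, dialect = c("coverage", "cytosine_report"),
                                 sampleId = basename(path)) {
    dialect <- match.arg(dialect)
    stopifnot(file.exists(path))
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines))
        return(MethylomeTable(character(), integer(), integer(), integer(),
                              sampleId))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    want <- if (dialect == "coverage") 6L else 6L
    bad <- which(nf != want)
    if (length(bad))
        stop("malformed ", dialect, " line ", bad[1L], ": expected ", want,
             " tab-separated fields, got ", nf[bad[1L]])
    m <- matrix(unlist(fields), ncol = want, byrow = TRUE)
    if (dialect == "coverage") {
        pos <- suppressWarnings(as.integer(m[, 2L]))
        pct <- suppressWarnings(as.numeric(m[, 4L]))
        cm <- suppressWarnings(as.integer(m[, 5L]))
        cu <- suppressWarnings(as.integer(m[, 6L]))
        bad <- which(is.na(pos) | is.na(cm) | is.na(cu))
        if (length(bad))
            stop("malformed coverage line ", bad[1L], ": non-numeric field")
        cov <- cm + cu
        zero <- cov == 0L
        if (any(zero)) {
            warning(sum(zero), " zero-coverage row(s) dropped")
            m <- m[!zero, , drop = FALSE]; pos <- pos[!zero]
            pct <- pct[!zero]; cm <- cm[!zero]; cu <- cu[!zero]
            cov <- cov[!zero]
        }
        if (length(cm)) {
            derived <- 100 * cm / cov
            off <- which(!is.na(pct) & abs(pct - derived) > 0.1)
            if (length(off))
                warning(length(off), " row(s) with printed percentage ",
                        "inconsistent with counts (> 0.1); counts win")
        }
        tab <- MethylomeTable(m[, 1L], pos, cm, cu, sampleId)
    } else {
        df <- data.frame(chrom = m[, 1L],
                         pos = suppressWarnings(as.integer(m[, 2L])),
                         strand = m[, 3L],
                         countM = suppressWarnings(as.integer(m[, 4L])),
                         countU = suppressWarnings(as.integer(m[, 5L])),
                         context = m[, 6L], stringsAsFactors = FALSE)
        bad <- which(is.na(df$pos) | is.na(df$countM) | is.na(df$countU) |
                     !(df$strand %in% c("+", "-")))
        if (length(bad))
            stop("malformed cytosine_report line ", bad[1L])
        tab <- mergeCpGStrands(df[df$context == "CpG", , drop = FALSE],
                               sampleId = sampleId)
        nonCpG <- df[df$context != "CpG", , drop = FALSE]
        md <- tab@sites
        S4Vectors::metadata(md)$nonCpG <- nonCpG
        tab@sites <- md
    }
    tab
}

#' Write per-base methylation calls
#'
#' Inverse of [readMethylationCalls()] for the coverage dialect (1-based
#' positions, percentage printed to one decimal). Output is bit-stable for a
#' fixed table. Zero-coverage sites have no defined percentage and are
#' excluded with a warning.
#'
#' @param table a [MethylomeTable-class].
#' @param path output file path.
#' @param dialect only `"coverage"` is written.
#' @return `path`, invisibly.
#' @export
writeMethylationCalls <- function(table, path, dialect = "coverage") {
    stopifnot(is(table, "MethylomeTable"), dialect == "coverage")
    cov <- siteCoverage(table)
    keep <- cov > 0L
    if (any(!keep))
        warning(sum(!keep), " zero-coverage site(s) excluded from coverage output")
    s <- table@sites[keep]
    cm <- S4Vectors::mcols(s)$countM
    cu <- S4Vectors::mcols(s)$countU
    lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d",
        as.character(GenomeInfoDb::seqnames(s)), BiocGenerics::start(s),
        BiocGenerics::start(s),
        formatC(100 * cm / (cm + cu), format = "f", digits = 6), cm, cu)
    writeLines(lines, path)
    invisible(path)
}

#' Read genomic intervals from BED
#'
#' BED3+ via [rtracklayer::import()]; 0-based half-open coordinates are
#' converted to the 1-based closed GRanges convention. Optional name/strand
#' columns are kept. Output is sorted by (chrom, start); zero- or
#' negative-width records are a parse error.
#'
#' @param path BED file path.
#' @param format only `"BED"`.
#' @return A sorted [GenomicRanges::GRanges].
#' @export
readIntervals <- function(path, format = "BED") {
    stopifnot(file.exists(path), toupper(format) == "BED")
    info <- file.info(path)
    if (info$size == 0) return(GenomicRanges::GRanges())
    gr <- rtracklayer::import(path, format = "bed")
    if (any(BiocGenerics::width(gr) < 1L))
        stop("BED record with start >= end in ", path)
    gr[order(as.character(GenomeInfoDb::seqnames(gr)), BiocGenerics::start(gr))]
}

#' Write genomic intervals to BED
#'
#' @param gr a GRanges.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeIntervals <- function(gr, path) {
    rtracklayer::export(gr, path, format = "bed")
    invisible(path)
}

#' Construct a GeneModelSet
#'
#' @param txId,gene,chrom,strand per-transcript vectors.
#' @param txStart,txEnd 1-based closed transcript spans.
#' @param exonStarts,exonEnds lists of 1-based closed exon coordinates, one
#'   vector per transcript; exons must be non-overlapping within a transcript.
#' @return A [GeneModelSet-class] with TSS (strand-aware) and introns derived.
#' @export
geneModelSet <- function(txId, gene, chrom, strand, txStart, txEnd,
                         exonStarts, exonEnds) {
    n <- length(txId)
    stopifnot(length(exonStarts) == n, length(exonEnds) == n)
    exGr <- vector("list", n)
    inGr <- vector("list", n)
    for (i in seq_len(n)) {
        es <- as.integer(exonStarts[[i]]); ee <- as.integer(exonEnds[[i]])
        if (length(es) != length(ee))
            stop("exon count mismatch for transcript ", txId[i])
        o <- order(es); es <- es[o]; ee <- ee[o]
        ir <- IRanges::IRanges(es, ee)
        if (length(ir) > 1L && any(IRanges::start(ir)[-1L] <=
                                   IRanges::end(ir)[-length(ir)]))
            stop("overlapping exons in transcript ", txId[i])
        exGr[[i]] <- GenomicRanges::GRanges(chrom[i], ir, strand = strand[i])
        gaps <- if (length(ir) > 1L)
            IRanges::IRanges(IRanges::end(ir)[-length(ir)] + 1L,
                             IRanges::start(ir)[-1L] - 1L)
        else IRanges::IRanges()
        inGr[[i]] <- GenomicRanges::GRanges(rep(chrom[i], length(gaps)), gaps,
                                            strand = rep(strand[i],
                                                         length(gaps)))
    }
    tss <- ifelse(strand == "+", as.integer(txStart), as.integer(txEnd))
    tx <- GenomicRanges::GRanges(chrom, IRanges::IRanges(txStart, txEnd),
        strand = strand, txId = txId, gene = gene, tss = tss)
    new("GeneModelSet", transcripts = tx,
        exons = stats::setNames(GenomicRanges::GRangesList(exGr), txId),
        introns = stats::setNames(GenomicRanges::GRangesList(inGr), txId))
}

#' Read gene models from a refFlat-like TSV
#'
#' Standard 11-column refFlat (geneName, name, chrom, strand, txStart, txEnd,
#' cdsStart, cdsEnd, exonCount, exonStarts, exonEnds; 0-based half-open
#' coordinates, comma-terminated exon lists). The TSS is derived per strand
#' (leftmost base for `+`, rightmost for `-`) and introns as inter-exon gaps.
#'
#' @param path refFlat file path.
#' @return A [GeneModelSet-class].
#' @export
readGeneModels <- function(path) {
    stopifnot(file.exists(path))
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE,
                            col.names = c("gene", "txId", "chrom", "strand",
                                          "txStart", "txEnd", "cdsStart",
                                          "cdsEnd", "exonCount", "exonStarts",
                                          "exonEnds"))
    parseList <- function(x) lapply(strsplit(x, ",", fixed = TRUE), as.integer)
    es0 <- parseList(df$exonStarts)
    ee0 <- parseList(df$exonEnds)
    nEx <- lengths(es0)
    bad <- which(nEx != df$exonCount | nEx != lengths(ee0))
    if (length(bad))
        stop("exon count mismatch at refFlat line ", bad[1L])
    geneModelSet(df$txId, df$gene, df$chrom, df$strand,
                 df$txStart + 1L, df$txEnd,
                 lapply(es0, function(x) x + 1L), ee0)
}

#' Write gene models to refFlat
#'
#' @param models a [GeneModelSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(models, path) {
    tx <- models@transcripts
    lines <- vapply(seq_along(tx), function(i) {
        id <- S4Vectors::mcols(tx)$txId[i]
        ex <- models@exons[[id]]
        s0 <- BiocGenerics::start(ex) - 1L
        e0 <- BiocGenerics::end(ex)
        paste(S4Vectors::mcols(tx)$gene[i], id,
              as.character(GenomeInfoDb::seqnames(tx))[i],
              as.character(BiocGenerics::strand(tx))[i],
              BiocGenerics::start(tx)[i] - 1L, BiocGenerics::end(tx)[i],
              BiocGenerics::start(tx)[i] - 1L, BiocGenerics::end(tx)[i],
              length(ex),
              paste0(paste(s0, collapse = ","), ","),
              paste0(paste(e0, collapse = ","), ","),
              sep = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read/write per-transcript expression tables
#'
#' Two-column TSV with header: `transcript`, `value` (array-scale units).
#'
#' @param path file path.
#' @return `readExpression`: data.frame with columns `transcript`, `value`.
#' @export
readExpression <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
}

#' @rdname readExpression
#' @param expr data.frame with columns `transcript`, `value`.
#' @export
writeExpression <- function(expr, path) {
    utils::write.table(expr[, c("transcript", "value")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
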