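## CpG island shores, genome partition, promoter CpG classes, TSS distances.

#' Build CpG shores from islands
#'
#' A shore is the `shoreWidth` bp flank on each side of a CpG island. If a
#' shore would overlap another island it is clipped so that its last base
#' falls before that island's start (and symmetrically after its end);
#' overlapping shores are merged into a single shore. Shores are also clipped
#' at chromosome ends. The result is sorted, internally disjoint, and
#' disjoint from the islands.
#'
#' @param islands non-overlapping GRanges (pre-merge overlapping islands;
#'   overlap is an error).
#' @param shoreWidth flank width in bp (default 2000).
#' @param seqlengths optional named chromosome lengths for end clipping.
#' @return GRanges of shores.
#' @examples
#' isl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5001, 5800))
#' buildShores(isl)  # [3001, 5000] and [5801, 7800]
#' @export
buildShores <- function(islands, shoreWidth = 2000L, seqlengths = NULL) {
    if (!length(islands)) return(GenomicRanges::GRanges())
    isl <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(islands),
                                  IRanges::ranges(islands))
    if (!rangesDisjoint(isl))
        stop("islands overlap; merge them (e.g. GenomicRanges::reduce) first")
    up <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(isl),
        IRanges::IRanges(pmax(1L, BiocGenerics::start(isl) - shoreWidth),
                         BiocGenerics::start(isl) - 1L))
    dn <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(isl),
        IRanges::IRanges(BiocGenerics::end(isl) + 1L,
                         BiocGenerics::end(isl) + shoreWidth))
    up <- up[BiocGenerics::width(up) > 0L]
    flanks <- c(up, dn)
    if (!is.null(seqlengths)) {
        lens <- seqlengths[as.character(GenomeInfoDb::seqnames(flanks))]
        IRanges::end(flanks) <- pmin(BiocGenerics::end(flanks),
                                     as.integer(lens))
        flanks <- flanks[BiocGenerics::width(flanks) > 0L]
    }
    shores <- GenomicRanges::reduce(GenomicRanges::setdiff(flanks, isl))
    shores[order(as.character(GenomeInfoDb::seqnames(shores)),
                 BiocGenerics::start(shores))]
}

rangesDisjoint <- function(gr) {
    if (length(gr) < 2L) return(TRUE)
    o <- order(as.character(GenomeInfoDb::seqnames(gr)),
               BiocGenerics::start(gr))
    gr <- gr[o]
    same <- as.character(GenomeInfoDb::seqnames(gr))[-1L] ==
            as.character(GenomeInfoDb::seqnames(gr))[-length(gr)]
    !any(same & BiocGenerics::start(gr)[-1L] <=
               BiocGenerics::end(gr)[-length(gr)])
}

#' Assemble all annotation layers for CpG classification
#'
#' Derives promoter windows (`tss +/- promoterHalfwidth`, clipped to the
#' chromosome), shores ([buildShores()]), exon/intron unions, and the
#' intergenic complement over the supplied chromosome lengths.
#'
#' @param islands CpG island GRanges (non-overlapping).
#' @param genes a [GeneModelSet-class].
#' @param repeats repeat GRanges, optionally with a `name`/`family` mcol.
#' @param seqlengths named integer chromosome lengths.
#' @param promoterHalfwidth half the promoter window (default 1000 bp).
#' @param shoreWidth shore flank width (default 2000 bp).
#' @return An [AnnotationBundle-class].
#' @export
buildAnnotationBundle <- function(islands, genes, repeats = GenomicRanges::GRanges(),
        seqlengths, promoterHalfwidth = 1000L, shoreWidth = 2000L) {
    stopifnot(is(genes, "GeneModelSet"), !is.null(names(seqlengths)))
    seqlengths <- stats::setNames(as.integer(seqlengths), names(seqlengths))
    tx <- genes@transcripts
    tss <- S4Vectors::mcols(tx)$tss
    chr <- as.character(GenomeInfoDb::seqnames(tx))
    prom <- GenomicRanges::GRanges(chr,
        IRanges::IRanges(pmax(1L, tss - promoterHalfwidth),
                         pmin(seqlengths[chr], tss + promoterHalfwidth - 1L)),
        txId = S4Vectors::mcols(tx)$txId)
    exons <- GenomicRanges::reduce(unlist(genes@exons, use.names = FALSE),
                                   ignore.strand = TRUE)
    introns <- GenomicRanges::reduce(unlist(genes@introns, use.names = FALSE),
                                     ignore.strand = TRUE)
    genic <- GenomicRanges::reduce(c(
        GenomicRanges::granges(prom), GenomicRanges::granges(exons),
        GenomicRanges::granges(introns)), ignore.strand = TRUE)
    genome <- GenomicRanges::GRanges(names(seqlengths),
        IRanges::IRanges(1L, seqlengths))
    intergenic <- GenomicRanges::setdiff(genome, genic, ignore.strand = TRUE)
    new("AnnotationBundle",
        islands = GenomicRanges::granges(islands, use.mcols = TRUE),
        shores = buildShores(islands, shoreWidth, seqlengths),
        promoters = prom, exons = exons, introns = introns,
        intergenic = intergenic,
        repeats = repeats, genes = genes, seqlengths = seqlengths)
}

#' Classify positions by gene feature
#'
#' Assigns each position exactly one label with precedence
#' promoter > exon > intron > intergenic (promoter-centric analyses require
#' promoter to win; each CpG gets exactly one class).
#'
#' @param pos width-1 GRanges of positions.
#' @param bundle an [AnnotationBundle-class].
#' @return factor with levels promoter, exon, intron, intergenic.
#' @export
classifyFeature <- function(pos, bundle) {
    chroms <- as.character(unique(GenomeInfoDb::seqnames(pos)))
    missing <- setdiff(chroms, names(bundle@seqlengths))
    if (length(missing))
        stop("chromosome(s) not in annotation bundle: ",
             paste(missing, collapse = ", "))
    out <- rep("intergenic", length(pos))
    out[IRanges::overlapsAny(pos, bundle@introns, ignore.strand = TRUE)] <- "intron"
    out[IRanges::overlapsAny(pos, bundle@exons, ignore.strand = TRUE)] <- "exon"
    out[IRanges::overlapsAny(pos, bundle@promoters, ignore.strand = TRUE)] <- "promoter"
    factor(out, levels = c("promoter", "exon", "intron", "intergenic"))
}

#' Classify positions by CpG island context
#'
#' Mutually exclusive labels with island taking precedence over shore;
#' positions beyond the shores get `beyond-shore`.
#'
#' @param pos width-1 GRanges.
#' @param islands,shores GRanges (shores from [buildShores()]).
#' @return factor with levels island, shore, beyond-shore.
#' @export
classifyIslandContext <- function(pos, islands, shores) {
    out <- rep("beyond-shore", length(pos))
    out[IRanges::overlapsAny(pos, shores, ignore.strand = TRUE)] <- "shore"
    out[IRanges::overlapsAny(pos, islands, ignore.strand = TRUE)] <- "island"
    factor(out, levels = c("island", "shore", "beyond-shore"))
}

#' Signed distance to the nearest transcription start site
#'
#' For each position, the minimal absolute distance over all TSSs; the sign
#' is negative when the position lies upstream of the TSS in the gene's
#' orientation (for a `+` transcript, upstream means a smaller coordinate).
#' Ties are broken by lexicographic transcript id.
#'
#' @param pos width-1 GRanges.
#' @param genes a [GeneModelSet-class] with at least one transcript.
#' @return data.frame with `distance` (signed bp) and `txId`.
#' @export
distanceToTss <- function(pos, genes) {
    tx <- genes@transcripts
    if (!length(tx)) stop("empty gene model set")
    tssChr <- as.character(GenomeInfoDb::seqnames(tx))
    tssPos <- S4Vectors::mcols(tx)$tss
    tssStr <- as.character(BiocGenerics::strand(tx))
    tssId <- S4Vectors::mcols(tx)$txId
    n <- length(pos)
    dist <- rep(NA_real_, n); id <- rep(NA_character_, n)
    posChr <- as.character(GenomeInfoDb::seqnames(pos))
    posPos <- BiocGenerics::start(pos)
    for (chrom in unique(posChr)) {
        sel <- which(tssChr == chrom)
        if (!length(sel)) sel <- seq_along(tssPos)  # fall back to any TSS
        ## per unique TSS position keep the lexicographically smallest txId
        o <- order(tssPos[sel], tssId[sel])
        tp <- tssPos[sel][o]; ti <- tssId[sel][o]; ts <- tssStr[sel][o]
        keep <- !duplicated(tp)
        tp <- tp[keep]; ti <- ti[keep]; ts <- ts[keep]
        qi <- which(posChr == chrom)
        q <- posPos[qi]
        idx <- findInterval(q, tp)
        lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(tp))
        dLo <- abs(q - tp[lo]); dHi <- abs(q - tp[hi])
        dLo[idx < 1L] <- Inf
        useLo <- dLo < dHi | (dLo == dHi & ti[lo] <= ti[hi])
        best <- ifelse(useLo, lo, hi)
        bp <- tp[best]; bs <- ts[best]
        signed <- ifelse(bs == "+", q - bp, bp - q)
        dist[qi] <- signed
        id[qi] <- ti[best]
    }
    data.frame(distance = dist, txId = id, stringsAsFactors = FALSE)
}

#' Promoter CpG-content class (HCP / ICP / LCP)
#'
#' Slides 500-bp windows (step 5 bp) over the promoter sequence and computes
#' per window the GC fraction and the CpG observed/expected ratio
#' `(#CpG * N) / (#C * #G)`. High-CpG promoters (HCP) have some window with
#' obs/exp >= 0.75 and GC >= 55 percent; low-CpG promoters (LCP) have no
#' window reaching obs/exp >= 0.48; the rest are intermediate (ICP).
#' Sequences shorter than the window are evaluated on a single full-length
#' window with a warning.
#'
#' @param sequence promoter sequence (character or DNAString).
#' @param windowWidth,step sliding window size and step in bp.
#' @param hcpObsExp,hcpGC,lcpObsExp class thresholds.
#' @return list with `class` (`"HCP"`, `"ICP"` or `"LCP"`), `maxGC` (percent)
#'   and `maxObsExp` over windows.
#' @export
promoterCpGClass <- function(sequence, windowWidth = 500L, step = 5L,
                             hcpObsExp = 0.75, hcpGC = 55, lcpObsExp = 0.48) {
    s <- toupper(as.character(sequence))
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    L <- length(chars)
    if (L < windowWidth) {
        warning("sequence shorter than ", windowWidth,
                " bp; evaluated on a single full-length window")
        windowWidth <- L
    }
    isC <- cumsum(c(0L, chars == "C"))
    isG <- cumsum(c(0L, chars == "G"))
    cgStart <- chars[-L] == "C" & chars[-1L] == "G"
    nCG <- cumsum(c(0L, cgStart))
    starts <- seq(1L, L - windowWidth + 1L, by = step)
    ends <- starts + windowWidth - 1L
    wC <- isC[ends + 1L] - isC[starts]
    wG <- isG[ends + 1L] - isG[starts]
    ## a CpG belongs to a window when the full dinucleotide fits inside it
    wCG <- nCG[ends] - nCG[starts]
    gc <- 100 * (wC + wG) / windowWidth
    oe <- ifelse(wC * wG > 0, wCG * windowWidth / (wC * wG), 0)
    cls <- if (any(oe >= hcpObsExp & gc >= hcpGC)) "HCP"
           else if (all(oe < lcpObsExp)) "LCP"
           else "ICP"
    list(class = cls, maxGC = max(gc), maxObsExp = max(oe))
}

#' Annotate CpG positions with every classification layer
#'
#' @param pos width-1 GRanges of CpG positions.
#' @param bundle an [AnnotationBundle-class].
#' @return data.frame with chrom, pos, feature class, island context, repeat
#'   overlap flag and family, signed TSS distance and nearest transcript.
#' @export
annotateCpGs <- function(pos, bundle) {
    feature <- classifyFeature(pos, bundle)
    ctx <- classifyIslandContext(pos, bundle@islands, bundle@shores)
    repHit <- IRanges::findOverlaps(pos, bundle@repeats, ignore.strand = TRUE,
                                    select = "first")
    fam <- rep(NA_character_, length(pos))
    mc <- S4Vectors::mcols(bundle@repeats)
    famCol <- intersect(c("family", "name"), colnames(mc))[1L]
    if (length(bundle@repeats) && !is.na(famCol))
        fam[!is.na(repHit)] <- mc[[famCol]][repHit[!is.na(repHit)]]
    tssd <- distanceToTss(pos, bundle@genes)
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(pos)),
               pos = BiocGenerics::start(pos),
               feature = feature, islandContext = ctx,
               inRepeat = !is.na(repHit), repeatFamily = fam,
               distTss = tssd$distance, nearestTx = tssd$txId,
               stringsAsFactors = FALSE)
}
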