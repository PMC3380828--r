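## In-silico MspI digestion and fragment size selection. MspI cuts C^CGG
## irrespective of CpG methylation, so cut coordinates sit at site start + 1;
## CCGG is its own reverse complement, making forward-strand coordinates
## sufficient for CpG accounting.

#' Digest a genome at a restriction site
#'
#' Cuts every chromosome at each occurrence of `site` (case-insensitive),
#' placing the cut `cutOffset` bases into the site (MspI: C^CGG, offset 1).
#' The returned fragments tile each chromosome exactly: they abut, do not
#' overlap, and their lengths sum to the chromosome length. Terminal
#' fragments are flagged as not enzyme-flanked on their outer side; a
#' chromosome without any site yields a single unflanked fragment.
#'
#' @param genome a [Biostrings::DNAStringSet] (or named character vector).
#' @param site recognition sequence (default `"CCGG"`).
#' @param cutOffset bases between site start and the cut (default 1).
#' @return [GenomicRanges::GRanges] of fragments, ordered along each
#'   chromosome, with mcols `cutLeft`, `cutRight` (logical: boundary is an
#'   enzyme cut).
#' @examples
#' frags <- digestGenome(Biostrings::DNAStringSet(c(chr1 = "AACCGGTTCCGGAA")))
#' BiocGenerics::width(frags)  # 3 6 5
#' @export
digestGenome <- function(genome, site = "CCGG", cutOffset = 1L) {
    if (is.character(genome))
        genome <- Biostrings::DNAStringSet(toupper(genome))
    stopifnot(is(genome, "DNAStringSet"), length(genome) > 0,
              !is.null(names(genome)))
    out <- lapply(names(genome), function(chrom) {
        sq <- genome[[chrom]]
        len <- length(sq)
        hits <- Biostrings::matchPattern(Biostrings::DNAString(site), sq)
        cuts <- BiocGenerics::start(hits) + cutOffset - 1L  # last base before cut
        cuts <- cuts[cuts >= 1L & cuts < len]
        starts <- c(1L, cuts + 1L)
        ends <- c(cuts, len)
        GenomicRanges::GRanges(factor(chrom, levels = names(genome)),
            IRanges::IRanges(starts, ends),
            cutLeft = c(FALSE, rep(TRUE, length(cuts))),
            cutRight = c(rep(TRUE, length(cuts)), FALSE))
    })
    frags <- do.call(c, out)
    GenomeInfoDb::seqlengths(frags) <-
        stats::setNames(BiocGenerics::width(genome), names(genome))
    frags
}

#' Size-select digestion fragments
#'
#' Retains fragments with `minLen <= length <= maxLen` (inclusive bounds, as
#' the protocol's size windows 40-220 bp and 70-320 bp are read). With
#' `requireBothCuts`, terminal fragments lacking an enzyme cut on either side
#' are excluded. Idempotent, and monotone in the window.
#'
#' @param fragments GRanges from [digestGenome()].
#' @param minLen,maxLen inclusive length bounds in bp.
#' @param requireBothCuts exclude fragments not enzyme-flanked on both sides.
#' @return The retained subset, in input order.
#' @export
selectFragments <- function(fragments, minLen, maxLen = Inf,
                            requireBothCuts = FALSE) {
    stopifnot(minLen <= maxLen)
    w <- BiocGenerics::width(fragments)
    keep <- w >= minLen & w <= maxLen
    if (requireBothCuts)
        keep <- keep & S4Vectors::mcols(fragments)$cutLeft &
                       S4Vectors::mcols(fragments)$cutRight
    fragments[keep]
}

#' CpG and feature coverage of retained fragments
#'
#' Counts CG dinucleotides whose C falls inside a retained fragment, and for
#' each annotation class (island, shore, promoter, exon, intron) the number
#' and percentage of features overlapped by at least one retained fragment by
#' at least 1 bp.
#'
#' @param retained GRanges of size-selected fragments.
#' @param bundle an [AnnotationBundle-class].
#' @param genome the [Biostrings::DNAStringSet] the fragments came from.
#' @return list with `nCpG` (CpGs inside retained fragments) and `features`
#'   (data.frame `feature`, `total`, `covered`, `pctCovered`).
#' @export
coverageReport <- function(retained, bundle, genome) {
    if (is.character(genome))
        genome <- Biostrings::DNAStringSet(toupper(genome))
    feats <- list(island = bundle@islands, shore = bundle@shores,
                  promoter = bundle@promoters, exon = bundle@exons,
                  intron = bundle@introns)
    featChroms <- unique(unlist(lapply(feats, function(g)
        as.character(unique(GenomeInfoDb::seqnames(g))))))
    missing <- setdiff(featChroms, names(genome))
    if (length(missing))
        stop("annotation chromosome(s) absent from genome: ",
             paste(missing, collapse = ", "))
    cpg <- cpgPositions(genome)
    nCpG <- sum(IRanges::overlapsAny(cpg, retained, ignore.strand = TRUE))
    rows <- lapply(names(feats), function(nm) {
        g <- feats[[nm]]
        cov <- sum(IRanges::overlapsAny(g, retained, ignore.strand = TRUE))
        data.frame(feature = nm, total = length(g), covered = cov,
                   pctCovered = if (length(g)) 100 * cov / length(g) else 0,
                   stringsAsFactors = FALSE)
    })
    list(nCpG = nCpG, features = do.call(rbind, rows))
}

#' Side-by-side coverage report for two size windows
#'
#' Runs [selectFragments()] and [coverageReport()] for each window (by
#' default the 40-220 bp RRBS and 70-320 bp ERRBS designs) on the same
#' digestion, for direct comparison of protocol designs.
#'
#' @param fragments GRanges from [digestGenome()].
#' @param bundle an [AnnotationBundle-class].
#' @param genome the digested genome.
#' @param windows named list of `c(min, max)` length windows.
#' @return Named list of [coverageReport()] results.
#' @export
compareCoverageWindows <- function(fragments, bundle, genome,
        windows = list(rrbs = c(40, 220), errbs = c(70, 320))) {
    lapply(windows, function(w)
        coverageReport(selectFragments(fragments, w[1], w[2]), bundle, genome))
}

#' Positions of CG dinucleotides in a genome
#'
#' @param genome a DNAStringSet.
#' @return Width-1 GRanges at the C of every CG dinucleotide.
#' @export
cpgPositions <- function(genome) {
    if (is.character(genome))
        genome <- Biostrings::DNAStringSet(toupper(genome))
    out <- lapply(names(genome), function(chrom) {
        hits <- Biostrings::matchPattern("CG", genome[[chrom]])
        GenomicRanges::GRanges(factor(chrom, levels = names(genome)),
            IRanges::IRanges(BiocGenerics::start(hits), width = 1L))
    })
    gr <- do.call(c, out)
    GenomeInfoDb::seqlengths(gr) <-
        stats::setNames(BiocGenerics::width(genome), names(genome))
    gr
}
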