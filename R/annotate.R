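#' Find CCCGGG (SmaI/XmaI) sites in a genome
#'
#' Scans every sequence for occurrences of the palindromic CCCGGG
#' hexamer. Because the site is palindromic each genomic occurrence is
#' recorded once, with no strand. Matching is exact and
#' case-insensitive; ambiguous bases (N) never match. Site ids are
#' \code{"chrom:start"} with a 0-based start.
#'
#' @param genome a \code{DNAStringSet}, a named character vector of
#'   sequences, or the path to a FASTA file.
#' @return sorted \code{GRanges} of width-6 sites with mcol
#'   \code{site_id}.
#' @examples
#' findCCCGGGSites(c(chr1 = "AACCCGGGTT"))   # one site at start 2
#' @export
findCCCGGGSites <- function(genome) {
    if (is.character(genome) && length(genome) == 1L &&
        file.exists(genome))
        genome <- Biostrings::readDNAStringSet(genome)
    if (is.character(genome))
        genome <- Biostrings::DNAStringSet(genome)
    if (is.null(names(genome)) || anyNA(names(genome)))
        stop("genome sequences must be named")
    names(genome) <- sub("\\s.*$", "", names(genome))
    hits <- Biostrings::vmatchPattern("CCCGGG", genome, fixed = TRUE)
    gr <- GRanges(rep(names(genome), lengths(hits)),
                  unlist(hits, use.names = FALSE))
    gr <- sort(gr, ignore.strand = TRUE)
    mcols(gr)$site_id <- paste0(as.character(seqnames(gr)), ":",
                                start(gr) - 1L)
    gr
}

#' Classify sites as CpG island, shore or other
#'
#' A site is an \emph{island} site if its hexamer start base lies inside
#' a CGI interval, a \emph{shore} site if it is outside every island but
#' within 2,000 bp (inclusive) of the nearest island edge, and
#' \emph{other} beyond that. Distance is measured from the hexamer start
#' base to the nearest covered island base.
#'
#' @param sites \code{GRanges} of sites (from
#'   \code{\link{findCCCGGGSites}} or \code{\link{siteIdToGRanges}}).
#' @param cgi \code{GRanges} of CpG island intervals (e.g. read from a
#'   BED track); intervals with non-positive width are a format error.
#' @param shoreWidth maximum island distance for a shore call
#'   (default 2000, inclusive).
#' @return character vector over \{island, shore, other\}, parallel to
#'   \code{sites}.
#' @examples
#' s <- siteIdToGRanges(c("chr1:500", "chr1:5000"))
#' cgi <- GenomicRanges::GRanges("chr1", IRanges::IRanges(401, 600))
#' classifyCGI(s, cgi)
#' @export
classifyCGI <- function(sites, cgi, shoreWidth = 2000L) {
    if (any(width(cgi) <= 0L))
        stop("CGI interval with end <= start")
    pos <- GRanges(seqnames(sites), IRanges(start(sites), width = 1L))
    cls <- rep("other", length(sites))
    inIsle <- IRanges::overlapsAny(pos, cgi, ignore.strand = TRUE)
    cls[inIsle] <- "island"
    d <- GenomicRanges::distanceToNearest(pos, cgi, ignore.strand = TRUE)
    gap <- rep(NA_integer_, length(sites))
    gap[S4Vectors::queryHits(d)] <- mcols(d)$distance
    # distance() counts bases strictly between ranges; the edge distance
    # (hexamer start base to nearest island base) is that plus one
    shore <- !inIsle & !is.na(gap) & (gap + 1L) <= shoreWidth
    cls[shore] <- "shore"
    cls
}

#' Map CCCGGG sites into promoter windows
#'
#' Two window conventions around the annotated TSS are supported, both
#' inclusive of their endpoints and oriented by strand:
#' \describe{
#'   \item{\code{symmetric_1500}}{TSS +/- 1,500 bases (3,001-base span),
#'     as used for pathway-style promoter calling.}
#'   \item{\code{tcga}}{-1,500 to +500 relative to transcription
#'     direction (2,001-base span), as used when matching array-based
#'     tumour/normal promoter methylation.}
#' }
#' Each promoter's \emph{representative} site is the member whose
#' hexamer start is closest to the TSS, ties broken toward the lower
#' genomic coordinate.
#'
#' @param sites \code{GRanges} of sites with mcol \code{site_id}.
#' @param tss data.frame(gene, chrom, strand, tss) with a 1-based TSS
#'   coordinate; duplicate gene symbols are kept with a warning.
#' @param mode \code{"symmetric_1500"} or \code{"tcga"}.
#' @return data.frame(gene, chrom, strand, tss, site_id, position,
#'   distance, representative) with one row per (promoter, member
#'   site); genes with no member sites are absent.
#' @examples
#' s <- siteIdToGRanges(c("chr1:8599", "chr1:9799"))
#' tss <- data.frame(gene = "g", chrom = "chr1", strand = "+",
#'                   tss = 10000)
#' mapPromoters(s, tss, "symmetric_1500")
#' @export
mapPromoters <- function(sites, tss,
                         mode = c("symmetric_1500", "tcga")) {
    mode <- match.arg(mode)
    need <- c("gene", "chrom", "strand", "tss")
    if (!all(need %in% names(tss)))
        stop("tss table needs columns gene, chrom, strand, tss")
    if (anyDuplicated(tss$gene))
        warning("duplicate gene symbols in TSS table; all kept")
    up <- 1500L
    down <- if (mode == "symmetric_1500") 1500L else 500L
    plus <- tss$strand != "-"
    wstart <- ifelse(plus, tss$tss - up, tss$tss - down)
    wend <- ifelse(plus, tss$tss + down, tss$tss + up)
    prom <- GRanges(tss$chrom, IRanges(pmax(1L, wstart), wend))
    pos <- GRanges(seqnames(sites), IRanges(start(sites), width = 1L))
    ov <- GenomicRanges::findOverlaps(prom, pos, ignore.strand = TRUE)
    if (length(ov) == 0L)
        return(data.frame(gene = character(0), chrom = character(0),
                          strand = character(0), tss = integer(0),
                          site_id = character(0), position = integer(0),
                          distance = integer(0),
                          representative = logical(0)))
    qi <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    out <- data.frame(
        gene = tss$gene[qi], chrom = tss$chrom[qi],
        strand = tss$strand[qi], tss = tss$tss[qi],
        site_id = granges_site_id(sites)[si],
        position = start(sites)[si],
        stringsAsFactors = FALSE)
    out$distance <- abs(out$position - out$tss)
    # representative site: minimal |position - tss| per promoter row,
    # ties toward the lower coordinate
    o <- order(qi, out$distance, out$position)
    out <- out[o, , drop = FALSE]
    out$representative <- !duplicated(qi[o])
    out <- out[order(out$gene, out$distance, out$position), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Baseline methylation compartment of each site
#'
#' Averages methylation over a reference sample set (typically the
#' germ-free wild-type group) and assigns each site to a baseline
#' compartment: \code{high} above 80\%, \code{low} below 20\%,
#' \code{mid} otherwise (the 20 and 80 boundaries fall in \code{mid}).
#' Sites with no unmasked reference value are \code{NA} and drop out of
#' stratified summaries.
#'
#' @param x a \code{\linkS4class{DreamSet}}.
#' @param referenceSamples column names (or indices) of the reference
#'   group.
#' @return character vector over \{low, mid, high\} (or \code{NA}),
#'   parallel to rows, named by site id.
#' @examples
#' m <- matrix(c(10, 50, 95), 3, 1,
#'             dimnames = list(paste0("chr1:", 0:2), "ref"))
#' baselineCompartment(DreamSet(m, matrix(200L, 3, 1,
#'   dimnames = dimnames(m)), rownames(m)), "ref")
#' @export
baselineCompartment <- function(x, referenceSamples) {
    m <- methPercent(x)[, referenceSamples, drop = FALSE]
    if (ncol(m) == 0L) stop("empty reference group")
    mu <- rowMeans(m, na.rm = TRUE)
    mu[is.nan(mu)] <- NA_real_
    comp <- ifelse(mu > 80, "high", ifelse(mu < 20, "low", "mid"))
    names(comp) <- rownames(methPercent(x))
    comp
}
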