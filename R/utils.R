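#' Convert site ids to GRanges
#'
#' Site ids are \code{"chrom:start"} with a 0-based start of the CCCGGG
#' hexamer (BED convention); the returned ranges are 1-based, width 6.
#'
#' @param site_id character vector of ids.
#' @return \code{GRanges} with an mcol \code{site_id}.
#' @examples
#' siteIdToGRanges("chr1:99")   # spans bases 100..105
#' @export
siteIdToGRanges <- function(site_id) {
    parts <- strsplit(site_id, ":", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad))
        stop("malformed site_id: ", site_id[which(bad)[1L]])
    chrom <- vapply(parts, `[`, "", 1L)
    start0 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
    if (anyNA(start0))
        stop("non-numeric start in site_id")
    gr <- GRanges(chrom, IRanges(start = start0 + 1L, width = 6L))
    mcols(gr)$site_id <- site_id
    gr
}

#' @noRd
granges_site_id <- function(gr) {
    id <- mcols(gr)$site_id
    if (is.null(id))
        id <- paste0(as.character(seqnames(gr)), ":", start(gr) - 1L)
    id
}

# derive a reproducible sub-seed below 2^31 from a base seed and a tag
substream_seed <- function(seed, k) {
    (as.integer(seed) %% 1000000L) * 1000L + as.integer(k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
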