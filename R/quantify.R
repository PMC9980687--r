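#' Count SmaI/XmaI restriction signatures
#'
#' DREAM leaves two read-start signatures at each CCCGGG site: reads
#' beginning \code{CCGGG} come from XmaI cuts at methylated sites, reads
#' beginning \code{GGG} (and not \code{CCGGG}) from SmaI cuts at
#' unmethylated sites. Any other 5' start matches neither enzyme and is
#' discarded (tallied in the \code{discarded} attribute). Matching is
#' case-insensitive. Reads are assumed already assigned to sites by the
#' upstream aligner.
#'
#' @param readStarts data.frame with columns \code{site_id},
#'   \code{sample_id}, \code{seq} (5'-end sequence of each read).
#' @return data.frame(site_id, sample_id, n_meth, n_unmeth), one row per
#'   (site, sample) with at least one signature read; attributes
#'   \code{discarded} (reads matching neither signature) and
#'   \code{malformed} (records with empty/NA sequence, skipped with a
#'   warning).
#' @examples
#' r <- data.frame(site_id = "chr1:10", sample_id = "s1",
#'                 seq = c("CCGGGAT", "GGGTTAA", "CCGGGCC"))
#' countSignatures(r)
#' @export
countSignatures <- function(readStarts) {
    need <- c("site_id", "sample_id", "seq")
    if (!all(need %in% names(readStarts)))
        stop("readStarts needs columns site_id, sample_id, seq")
    if (nrow(readStarts) == 0L) {
        out <- data.frame(site_id = character(0),
                          sample_id = character(0),
                          n_meth = integer(0), n_unmeth = integer(0))
        attr(out, "discarded") <- 0L
        attr(out, "malformed") <- 0L
        return(out)
    }
    s <- toupper(as.character(readStarts$seq))
    malformed <- is.na(s) | s == ""
    if (any(malformed))
        warning(sum(malformed), " malformed read record(s) skipped")
    meth <- !malformed & startsWith(s, "CCGGG")
    unmeth <- !malformed & !meth & startsWith(s, "GGG")
    discarded <- sum(!malformed & !meth & !unmeth)

    keep <- meth | unmeth
    key <- paste(readStarts$site_id[keep], readStarts$sample_id[keep],
                 sep = "\t")
    nm <- rowsum(as.integer(meth[keep]), key)
    nu <- rowsum(as.integer(unmeth[keep]), key)
    lab <- strsplit(rownames(nm), "\t", fixed = TRUE)
    out <- data.frame(
        site_id = vapply(lab, `[`, "", 1L),
        sample_id = vapply(lab, `[`, "", 2L),
        n_meth = as.integer(nm), n_unmeth = as.integer(nu),
        stringsAsFactors = FALSE)
    out <- out[order(out$site_id, out$sample_id), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "discarded") <- discarded
    attr(out, "malformed") <- sum(malformed)
    out
}

#' Calibrated percent methylation from signature counts
#'
#' The DREAM methylation estimate at a site is
#' \deqn{100 \cdot \frac{c\,(X + 0.5)}{c\,(X + 0.5) + S + 0.5}}
#' where \eqn{X} is the methylated (XmaI) read count, \eqn{S} the
#' unmethylated (SmaI) count and \eqn{c} the per-sample digestion
#' correction factor (1 = no correction). The 0.5 pseudocounts keep the
#' value strictly inside (0, 100); the estimate is increasing in
#' \eqn{X} and decreasing in \eqn{S}.
#'
#' @param nMeth,nUnmeth non-negative counts (vectorised).
#' @param c positive correction factor (scalar or per-element).
#' @return percent methylation in (0, 100).
#' @examples
#' methylationValue(0, 0, 1)        # 50
#' methylationValue(10, 10, 2)      # 100 * 21 / 31.5
#' @export
methylationValue <- function(nMeth, nUnmeth, c = 1) {
    if (any(c <= 0)) stop("correction factor c must be > 0")
    if (any(nMeth < 0, na.rm = TRUE) || any(nUnmeth < 0, na.rm = TRUE))
        stop("counts must be non-negative")
    100 * c * (nMeth + 0.5) / (c * (nMeth + 0.5) + nUnmeth + 0.5)
}

#' Estimate the digestion correction factor from spike-in standards
#'
#' Finds the \code{c} minimising the sum of squared differences between
#' the calibrated methylation of each spike-in standard and its known
#' expected level, by bounded 1-D minimisation over log(c) in
#' [log 0.05, log 20]. A sample is accepted when the estimate falls in
#' [0.5, 2.0]; outside that range the digestion is considered too far
#' from nominal to correct reliably.
#'
#' @param spikes data.frame(standard_id, expected_meth, n_meth,
#'   n_unmeth, sample_id) for one sample, or for many samples (then one
#'   row per sample is returned).
#' @param cAccept acceptance interval for \code{c}.
#' @return data.frame(sample_id, c, accepted).
#' @examples
#' sp <- data.frame(standard_id = c("a", "b"), expected_meth = c(25, 75),
#'                  n_meth = c(250, 750), n_unmeth = c(750, 250),
#'                  sample_id = "s1")
#' estimateCorrectionFactor(sp)
#' @export
estimateCorrectionFactor <- function(spikes, cAccept = c(0.5, 2.0)) {
    one <- function(sp) {
        lev <- unique(sp$expected_meth)
        if (nrow(sp) < 2L || length(lev) < 2L)
            stop("calibration needs >= 2 standards at distinct expected levels")
        obj <- function(logc) {
            obs <- methylationValue(sp$n_meth, sp$n_unmeth, exp(logc))
            sum((obs - sp$expected_meth)^2)
        }
        opt <- optimize(obj, interval = c(log(0.05), log(20)),
                        tol = 1e-10)
        exp(opt$minimum)
    }
    chat <- vapply(split(spikes, spikes$sample_id), one, 0)
    data.frame(sample_id = names(chat), c = unname(chat),
               accepted = unname(chat >= cAccept[1L] &
                                 chat <= cAccept[2L]),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble a calibrated DreamSet from counts
#'
#' Applies \code{\link{methylationValue}} with each sample's correction
#' factor to every (site, sample) cell and packs the result, with
#' coverage, into a \code{\linkS4class{DreamSet}}. Samples whose
#' calibration was rejected (c outside [0.5, 2.0]) are excluded and
#' reported in a message; a sample present in \code{counts} but absent
#' from \code{calibration} is an error.
#'
#' @param counts data.frame(site_id, sample_id, n_meth, n_unmeth).
#' @param calibration data.frame(sample_id, c, accepted) from
#'   \code{\link{estimateCorrectionFactor}}.
#' @param colData optional per-sample metadata (e.g. the design table),
#'   with a \code{sample_id} column; matched and carried into the
#'   object's \code{colData}.
#' @return a \code{\linkS4class{DreamSet}}; cells with no reads get
#'   coverage 0 and \code{NA} methylation.
#' @examples
#' cts <- data.frame(site_id = "chr1:5", sample_id = "s1",
#'                   n_meth = 10L, n_unmeth = 10L)
#' cal <- data.frame(sample_id = "s1", c = 1, accepted = TRUE)
#' methPercent(buildDreamSet(cts, cal))
#' @export
buildDreamSet <- function(counts, calibration, colData = NULL) {
    missing_cal <- setdiff(unique(counts$sample_id),
                           calibration$sample_id)
    if (length(missing_cal))
        stop("no calibration for sample(s): ",
             paste(missing_cal, collapse = ", "))
    dropped <- calibration$sample_id[!calibration$accepted]
    if (length(dropped))
        message("excluding ", length(dropped),
                " sample(s) with rejected calibration: ",
                paste(dropped, collapse = ", "))
    keep <- calibration[calibration$accepted, , drop = FALSE]
    counts <- counts[counts$sample_id %in% keep$sample_id, ,
                     drop = FALSE]
    sites <- sort(unique(counts$site_id))
    samples <- keep$sample_id
    i <- match(counts$site_id, sites)
    j <- match(counts$sample_id, samples)
    cov <- matrix(0L, length(sites), length(samples),
                  dimnames = list(sites, samples))
    nm <- cov
    cov[cbind(i, j)] <- counts$n_meth + counts$n_unmeth
    nm[cbind(i, j)] <- counts$n_meth
    cvec <- keep$c[match(samples, keep$sample_id)]
    meth <- methylationValue(nm, cov - nm,
                             matrix(rep(cvec, each = length(sites)),
                                    nrow = length(sites)))
    meth[cov == 0L] <- NA_real_

    cd <- DataFrame(sample_id = samples, c = cvec,
                    row.names = samples)
    if (!is.null(colData)) {
        m <- match(samples, colData$sample_id)
        extra <- colData[m, setdiff(names(colData), "sample_id"),
                         drop = FALSE]
        rownames(extra) <- samples
        cd <- cbind(cd, as(extra, "DataFrame"))
    }
    DreamSet(meth, cov, sites, cd)
}

#' Depth, autosome and sample-fraction site filter
#'
#' Keeps autosomal sites whose coverage reaches \code{minDepth} in at
#' least \code{ceiling(minFraction * group size)} samples of every
#' group being compared, and masks (sets to \code{NA}) methylation in
#' any remaining cell below \code{minDepth} so sub-threshold
#' measurements never enter downstream statistics. The depth bound is
#' inclusive (depth exactly \code{minDepth} passes). Idempotent.
#'
#' @param x a \code{\linkS4class{DreamSet}}.
#' @param minDepth minimum reads per cell (default 100).
#' @param minFraction minimum fraction of each group's samples at depth
#'   (default 0.75).
#' @param autosomes chromosomes retained (default chr1-chr19, mouse).
#' @param groups per-sample grouping factor for the fraction rule;
#'   defaults to \code{colData(x)$group}, or a single pooled group if
#'   absent. Comparison-specific filtering is obtained by subsetting
#'   the object to the compared groups first.
#' @return the filtered \code{DreamSet}; numbers of sites and cells
#'   removed are reported via \code{message}.
#' @examples
#' m <- matrix(50, 2, 2, dimnames = list(c("chr1:0", "chrX:0"),
#'                                       c("a", "b")))
#' cv <- matrix(200L, 2, 2, dimnames = dimnames(m))
#' d <- filterSites(DreamSet(m, cv, rownames(m)))
#' nrow(d)   # chrX site removed
#' @export
filterSites <- function(x, minDepth = 100, minFraction = 0.75,
                        autosomes = paste0("chr", 1:19),
                        groups = NULL) {
    if (is.null(groups)) {
        groups <- colData(x)$group
        if (is.null(groups)) groups <- rep("all", ncol(x))
    }
    groups <- as.character(groups)
    if (length(groups) != ncol(x))
        stop("groups must have one entry per sample")
    if (any(table(groups) == 0L)) stop("empty group")

    auto <- as.character(seqnames(rowRanges(x))) %in% autosomes
    deep <- readDepth(x) >= minDepth
    okAll <- rep(TRUE, nrow(x))
    for (g in unique(groups)) {
        jj <- groups == g
        need <- ceiling(minFraction * sum(jj))
        okAll <- okAll & rowSums(deep[, jj, drop = FALSE]) >= need
    }
    keep <- auto & okAll
    message("filterSites: keeping ", sum(keep), "/", nrow(x),
            " sites (", sum(!auto), " non-autosomal)")
    out <- x[keep, ]
    m <- assay(out, "meth")
    m[readDepth(out) < minDepth] <- NA_real_
    assays(out)$meth <- m
    out
}
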