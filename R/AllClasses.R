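#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assays<- assayNames rowRanges rowData colData colData<-
#' @importFrom GenomicRanges GRanges seqnames start end width mcols mcols<-
#' @importFrom IRanges IRanges
NULL

#' DreamSet: calibrated DREAM methylation container
#'
#' A \code{DreamSet} holds per-site, per-sample DREAM measurements as a
#' \linkS4class{RangedSummarizedExperiment} with two assays:
#' \describe{
#'   \item{\code{meth}}{calibrated percent methylation, strictly inside
#'     (0, 100) where observed (the +0.5 pseudocounts of the methylation
#'     formula keep it off the boundaries); \code{NA} marks cells masked
#'     by the depth filter.}
#'   \item{\code{coverage}}{sequencing depth, i.e. the sum of methylated
#'     (XmaI-signature) and unmethylated (SmaI-signature) read counts the
#'     cell was computed from.}
#' }
#' Rows are CCCGGG sites (a \code{GRanges} of the 6-base recognition
#' hexamer); row metadata may carry \code{site_id}, \code{cgi_class} and
#' \code{compartment}. Columns are samples; \code{colData} carries the
#' per-sample correction factor \code{c}, its acceptance flag and any
#' design covariates (\code{group}, \code{microbiota}, \code{il10ko},
#' \code{aom}, \code{age_class}).
#'
#' @aliases DreamSet-class
#' @seealso \code{\link{buildDreamSet}}, \code{\link{filterSites}},
#'   \code{\link{methPercent}}, \code{\link{readDepth}}
#' @exportClass DreamSet
setClass("DreamSet", contains = "RangedSummarizedExperiment")

setValidity("DreamSet", function(object) {
    msg <- character(0)
    an <- assayNames(object)
    if (!all(c("meth", "coverage") %in% an))
        msg <- c(msg, "assays must include 'meth' and 'coverage'")
    else {
        m <- assay(object, "meth")
        cv <- assay(object, "coverage")
        if (!identical(dim(m), dim(cv)))
            msg <- c(msg, "'meth' and 'coverage' dimensions differ")
        mm <- m[!is.na(m)]
        if (length(mm) && (any(mm <= 0) || any(mm >= 100)))
            msg <- c(msg, "observed methylation must lie strictly in (0, 100)")
        if (any(cv[!is.na(cv)] < 0))
            msg <- c(msg, "coverage must be non-negative")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a DreamSet
#'
#' @param meth numeric matrix of percent methylation (sites x samples),
#'   values in (0, 100) or \code{NA} for masked cells.
#' @param coverage integer matrix of read depth, same dimensions.
#' @param rowRanges \code{GRanges} of CCCGGG sites (one row per site) or
#'   a character vector of site ids of the form \code{"chrom:start0"}
#'   from which ranges are reconstructed.
#' @param colData \code{DataFrame}/\code{data.frame} of per-sample
#'   metadata (rownames = sample ids).
#'
#' @return A \code{DreamSet}.
#' @examples
#' m <- matrix(c(50, 25), 1, 2, dimnames = list("chr1:100", c("a", "b")))
#' d <- DreamSet(m, matrix(200L, 1, 2, dimnames = dimnames(m)), "chr1:100")
#' methPercent(d)
#' @export
DreamSet <- function(meth, coverage, rowRanges, colData = NULL) {
    if (is.character(rowRanges))
        rowRanges <- siteIdToGRanges(rowRanges)
    if (is.null(colData))
        colData <- DataFrame(row.names = colnames(meth))
    colData <- as(colData, "DataFrame")
    if (is.null(rownames(colData)) && !is.null(colnames(meth)))
        rownames(colData) <- colnames(meth)
    se <- SummarizedExperiment(
        assays = list(meth = meth, coverage = coverage),
        rowRanges = rowRanges, colData = colData)
    new("DreamSet", se)
}

#' Simulation configuration for the synthetic DREAM study
#'
#' Bundles every knob of the synthetic-data generator: the site census
#' (count, compartment mixture, per-compartment baseline Beta laws, the
#' fraction placed on the sex chromosome to exercise the autosome
#' filter), the exposure design (groups x factor covariates), the
#' additive effect table, the read-depth law, the per-sample digestion
#' efficiency, the spike-in panel and the seed. Defaults emulate a
#' germ-free/SPF colonic methylome study: ~22,000 detectable CCCGGG
#' sites, CGI sites mostly unmethylated, intergenic sites mostly
#' high/intermediate, six mice per exposure group plus small young/old
#' ageing groups, nine spike-in standards per sample.
#'
#' @slot nSites number of CCCGGG sites to simulate.
#' @slot compartmentFractions named proportions over island/shore/other,
#'   summing to 1.
#' @slot baselineShapes list of Beta(a, b) shape pairs per compartment
#'   for the true baseline methylation fraction.
#' @slot effectTable data.frame(factor, compartment, shift, fraction):
#'   additive shift in percentage points applied to a random
#'   \code{fraction} of the compartment's sites when the factor is on.
#' @slot design data.frame(group, n, microbiota, il10ko, aom,
#'   age_class) describing the animal groups.
#' @slot depthMean,depthDispersion negative-binomial depth law (mean,
#'   size).
#' @slot cTrue per-sample digestion-efficiency factors; empty means draw
#'   log-uniformly from \code{cRange}.
#' @slot cRange range for drawn digestion efficiencies.
#' @slot mouseSd per-mouse biological jitter of true methylation
#'   (percentage points, Gaussian, truncated to [0, 100]).
#' @slot labileFraction fraction of sites (per direction) forming the
#'   loss-prone and gain-prone pools that different factors
#'   preferentially converge on; 0 makes factor effects independent.
#' @slot labileBias share of each factor's effect budget allocated to
#'   its direction's labile pool.
#' @slot spikeLevels the nine known spike-in methylation percentages.
#' @slot spikeDepth fixed spike-in sequencing depth.
#' @slot sexFraction fraction of sites placed on chrX.
#' @slot seed integer seed.
#' @aliases DreamSimConfig-class
#' @seealso \code{\link{DreamSimConfig}}, \code{\link{simulateSites}},
#'   \code{\link{simulateCounts}}
#' @exportClass DreamSimConfig
setClass("DreamSimConfig", representation(
    nSites = "integer",
    compartmentFractions = "numeric",
    baselineShapes = "list",
    effectTable = "data.frame",
    design = "data.frame",
    depthMean = "numeric",
    depthDispersion = "numeric",
    cTrue = "numeric",
    cRange = "numeric",
    mouseSd = "numeric",
    labileFraction = "numeric",
    labileBias = "numeric",
    spikeLevels = "numeric",
    spikeDepth = "numeric",
    sexFraction = "numeric",
    seed = "integer"
))

setValidity("DreamSimConfig", function(object) {
    msg <- character(0)
    f <- object@compartmentFractions
    if (!identical(sort(names(f)), c("island", "other", "shore")))
        msg <- c(msg, "compartmentFractions must be named island/shore/other")
    else if (abs(sum(f) - 1) > 1e-9 || any(f < 0))
        msg <- c(msg, "compartmentFractions must be non-negative and sum to 1")
    if (object@nSites < 1L)
        msg <- c(msg, "nSites must be positive")
    if (any(object@design$n < 2L))
        msg <- c(msg, "every design group needs n >= 2")
    need <- c("group", "n", "microbiota", "il10ko", "aom", "age_class")
    if (!all(need %in% names(object@design)))
        msg <- c(msg, paste("design must have columns:",
                            paste(need, collapse = ", ")))
    if (length(object@cTrue) && any(object@cTrue <= 0))
        msg <- c(msg, "all cTrue must be > 0")
    if (length(object@spikeLevels) != 9L)
        msg <- c(msg, "spikeLevels must have exactly 9 entries")
    if (any(object@spikeLevels < 0) || any(object@spikeLevels > 100))
        msg <- c(msg, "spikeLevels must lie in [0, 100]")
    if (object@sexFraction < 0 || object@sexFraction >= 1)
        msg <- c(msg, "sexFraction must be in [0, 1)")
    if (object@depthMean <= 0 || object@depthDispersion <= 0)
        msg <- c(msg, "depth parameters must be positive")
    if (object@labileFraction < 0 || object@labileFraction > 0.45)
        msg <- c(msg, "labileFraction must be in [0, 0.45]")
    if (object@labileBias < 0 || object@labileBias > 1)
        msg <- c(msg, "labileBias must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

setMethod("show", "DreamSet", function(object) {
    cat("DreamSet with", nrow(object), "sites x", ncol(object), "samples\n")
    callNextMethod()
})

setMethod("show", "DreamSimConfig", function(object) {
    cat("DreamSimConfig:", object@nSites, "sites;",
        sum(object@design$n), "samples in", nrow(object@design),
        "groups; seed", object@seed, "\n")
    cat("  compartments:",
        paste(sprintf("%s=%.2f", names(object@compartmentFractions),
                      object@compartmentFractions), collapse = " "), "\n")
    cat("  depth ~ NB(mean=", object@depthMean, ", size=",
        object@depthDispersion, "); spike depth ", object@spikeDepth,
        "\n", sep = "")
})
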