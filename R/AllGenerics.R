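#' Accessors for DreamSet assays
#'
#' \code{methPercent} returns the calibrated percent-methylation matrix
#' (\code{NA} for depth-masked cells); \code{readDepth} returns the
#' coverage matrix.
#'
#' @param x a \code{\linkS4class{DreamSet}}.
#' @return A numeric (or integer) sites x samples matrix.
#' @examples
#' m <- matrix(50, 1, 1, dimnames = list("chr1:0", "s1"))
#' d <- DreamSet(m, matrix(100L, 1, 1, dimnames = dimnames(m)), "chr1:0")
#' readDepth(d)
#' @export
setGeneric("methPercent", function(x) standardGeneric("methPercent"))

#' @rdname methPercent
#' @export
setGeneric("readDepth", function(x) standardGeneric("readDepth"))

#' @rdname methPercent
setMethod("methPercent", "DreamSet", function(x) assay(x, "meth"))

#' @rdname methPercent
setMethod("readDepth", "DreamSet", function(x) assay(x, "coverage"))
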