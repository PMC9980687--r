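#' Per-site multivariate linear model of exposure effects
#'
#' Fits, at every site, the ordinary-least-squares model
#' \deqn{y = b_m x_m + b_i x_i + b_a x_a + b_0 + \varepsilon}
#' where \eqn{y} is calibrated percent methylation across samples and
#' \eqn{x_m, x_i, x_a} are the binary microbiota, Il10-knockout and AOM
#' covariates, so each slope is directly the percent-methylation change
#' attributed to that exposure. Masked cells are handled by per-site
#' row deletion; sites are batched by missingness pattern and solved by
#' QR in groups. A site is skipped (with a counted reason) when fewer
#' than \code{p + 2} unmasked observations remain (p = number of
#' parameters) or the reduced design loses full column rank.
#' Per-coefficient two-sided p-values use the t distribution with
#' n - p degrees of freedom; q-values are Benjamini-Hochberg adjusted
#' separately for each coefficient across sites.
#'
#' @param x a filtered \code{\linkS4class{DreamSet}} whose
#'   \code{colData} carries the binary covariates.
#' @param covariates covariate column names (default microbiota,
#'   il10ko, aom). Age class is deliberately not a covariate: the
#'   ageing animals are a separate strain analysed by the pairwise
#'   route.
#' @return data.frame with site_id, b0, one \code{b_<cov>},
#'   \code{p_<cov>} and \code{q_<cov>} per covariate, and \code{n}
#'   (observations used).
#' @examples
#' cd <- data.frame(sample_id = c("a", "b", "c", "d", "e", "f"),
#'                  microbiota = c(0, 0, 0, 1, 1, 1),
#'                  il10ko = 0, aom = 0)
#' m <- matrix(c(30, 31, 29, 35, 36, 34), 1, 6,
#'             dimnames = list("chr1:0", cd$sample_id))
#' d <- DreamSet(m, matrix(200L, 1, 6, dimnames = dimnames(m)),
#'               "chr1:0", cd)
#' fitFactorModel(d, "microbiota")
#' @export
fitFactorModel <- function(x, covariates = c("microbiota", "il10ko",
                                             "aom")) {
    cd <- as.data.frame(colData(x))
    if (!all(covariates %in% names(cd)))
        stop("colData lacks covariate(s): ",
             paste(setdiff(covariates, names(cd)), collapse = ", "))
    Z <- as.matrix(cd[, covariates, drop = FALSE])
    storage.mode(Z) <- "double"
    if (!all(Z %in% c(0, 1))) stop("covariates must be binary 0/1")
    m <- methPercent(x)
    p <- length(covariates) + 1L
    obs <- !is.na(m)
    pattern <- do.call(paste0, as.data.frame(obs + 0L))
    out <- vector("list", 0L)
    skipped <- 0L
    for (pat in unique(pattern)) {
        rows <- which(pattern == pat)
        use <- obs[rows[1L], ]
        n <- sum(use)
        if (n < p + 2L) { skipped <- skipped + length(rows); next }
        X <- cbind(`(Intercept)` = 1, Z[use, , drop = FALSE])
        qrX <- qr(X)
        if (qrX$rank < p) { skipped <- skipped + length(rows); next }
        Y <- t(m[rows, use, drop = FALSE])
        coef <- qr.coef(qrX, Y)                      # p x k
        res <- Y - X %*% coef
        dfres <- n - p
        sigma2 <- colSums(res^2) / dfres
        dinv <- diag(solve(crossprod(X)))            # p
        se <- sqrt(outer(dinv, sigma2))              # p x k
        tstat <- coef / se
        pval <- 2 * pt(-abs(tstat), dfres)
        zero <- se == 0
        if (any(zero)) pval[zero] <- ifelse(coef[zero] == 0, 1, 0)
        out[[pat]] <- data.frame(
            site_id = rownames(m)[rows], b0 = coef[1L, ],
            t(coef[-1L, , drop = FALSE]),
            t(pval[-1L, , drop = FALSE]),
            n = n, row.names = NULL, stringsAsFactors = FALSE,
            check.names = FALSE)
        names(out[[pat]]) <- c("site_id", "b0",
                               paste0("b_", covariates),
                               paste0("p_", covariates), "n")
    }
    if (skipped)
        message("fitFactorModel: skipped ", skipped,
                " site(s) (too few observations or rank-deficient)")
    if (!length(out))
        stop("no site could be fitted")
    fits <- do.call(rbind, out)
    fits <- fits[match(intersect(rownames(m), fits$site_id),
                       fits$site_id), , drop = FALSE]
    rownames(fits) <- NULL
    for (cv in covariates)
        fits[[paste0("q_", cv)]] <- fdrAdjust(fits[[paste0("p_", cv)]])
    fits
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjustment with monotonicity enforcement, as implemented
#' by \code{stats::p.adjust(method = "BH")}; applied separately per
#' coefficient by \code{\link{fitFactorModel}}.
#'
#' @param p p-values in [0, 1].
#' @return q-values (elementwise >= p), order-invariant and idempotent.
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
fdrAdjust <- function(p) {
    stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
    p.adjust(p, method = "BH")
}

#' Call factor-affected sites from the linear model
#'
#' A site is affected by a factor when the factor's q-value is at or
#' below \code{qThreshold} (and, if \code{slopeThreshold} > 0, the
#' slope magnitude reaches it); direction follows the slope sign. The
#' default is FDR-only calling (\code{slopeThreshold = 0}); a 5-point
#' slope floor can be requested to mirror the pairwise magnitude rule.
#'
#' @param fits output of \code{\link{fitFactorModel}}.
#' @param qThreshold FDR threshold (default 0.05).
#' @param slopeThreshold optional minimum |slope| in points.
#' @return named list per covariate of list(hyper, hypo) site-id sets.
#' @export
callFactorChanges <- function(fits, qThreshold = 0.05,
                              slopeThreshold = 0) {
    covs <- sub("^b_", "", grep("^b_", names(fits), value = TRUE))
    out <- lapply(covs, function(cv) {
        b <- fits[[paste0("b_", cv)]]
        q <- fits[[paste0("q_", cv)]]
        hit <- q <= qThreshold & abs(b) >= slopeThreshold
        list(hyper = fits$site_id[hit & b > 0],
             hypo = fits$site_id[hit & b < 0])
    })
    names(out) <- covs
    out
}
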