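#' Pairwise per-site differential methylation (volcano test)
#'
#' For every site with at least two unmasked values in each group,
#' computes the difference in mean methylation (exposed minus
#' reference, percentage points) and a two-sided p-value from the
#' equal-variance (Student) two-sample t statistic. Sites with fewer
#' than two values in either group are skipped and excluded from the
#' comparison's denominator. Degenerate sites are resolved by
#' convention: zero pooled variance with equal means gives p = 1 (no
#' evidence), zero pooled variance with unequal means gives p = 0;
#' both cases are counted in a message.
#'
#' @param x a \code{\linkS4class{DreamSet}} (typically already passed
#'   through \code{\link{filterSites}} restricted to the two groups).
#' @param referenceSamples,exposedSamples column names or indices of
#'   the two groups.
#' @return data.frame(site_id, delta, t, p, n_ref, n_exp); plotting a
#'   volcano is \code{delta} against \code{-log10(p)}.
#' @examples
#' m <- cbind(r1 = c(10, 50), r2 = c(12, 52), e1 = c(30, 50),
#'            e2 = c(32, 54))
#' rownames(m) <- c("chr1:0", "chr1:10")
#' d <- DreamSet(m, matrix(200L, 2, 4, dimnames = dimnames(m)),
#'               rownames(m))
#' diffTest(d, c("r1", "r2"), c("e1", "e2"))
#' @export
diffTest <- function(x, referenceSamples, exposedSamples) {
    m <- methPercent(x)
    mr <- m[, referenceSamples, drop = FALSE]
    me <- m[, exposedSamples, drop = FALSE]
    if (ncol(mr) == 0L || ncol(me) == 0L) stop("empty group")
    nr <- rowSums(!is.na(mr))
    ne <- rowSums(!is.na(me))
    ok <- nr >= 2L & ne >= 2L
    if (any(!ok))
        message("diffTest: skipping ", sum(!ok),
                " site(s) with < 2 values in a group")
    mr <- mr[ok, , drop = FALSE]; me <- me[ok, , drop = FALSE]
    nr <- nr[ok]; ne <- ne[ok]
    mur <- rowMeans(mr, na.rm = TRUE)
    mue <- rowMeans(me, na.rm = TRUE)
    ssr <- rowSums((mr - mur)^2, na.rm = TRUE)
    sse <- rowSums((me - mue)^2, na.rm = TRUE)
    df <- nr + ne - 2L
    sp2 <- (ssr + sse) / df
    delta <- mue - mur
    se <- sqrt(sp2 * (1 / nr + 1 / ne))
    t <- delta / se
    p <- 2 * pt(-abs(t), df)
    degen <- sp2 == 0
    if (any(degen)) {
        t[degen] <- ifelse(delta[degen] == 0, 0, sign(delta[degen]) * Inf)
        p[degen] <- ifelse(delta[degen] == 0, 1, 0)
        message("diffTest: ", sum(degen),
                " zero-variance site(s) resolved by convention")
    }
    data.frame(site_id = rownames(m)[ok], delta = delta, t = t, p = p,
               n_ref = nr, n_exp = ne, row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Flag changed sites by the joint magnitude/significance rule
#'
#' A site is \emph{changed} when p <= \code{alpha} and the absolute
#' methylation difference is at least \code{deltaThreshold} percentage
#' points; direction is \code{hyper} for positive and \code{hypo} for
#' negative differences. No multiple-testing correction is applied in
#' these pairwise volcano calls (only the multivariate factor model is
#' FDR-corrected; see \code{\link{fitFactorModel}}).
#'
#' @param diffcalls output of \code{\link{diffTest}}.
#' @param deltaThreshold minimum absolute change (default 5 points).
#' @param alpha significance level (default 0.05, inclusive).
#' @return the input with \code{changed} and \code{direction}
#'   (\code{hyper}/\code{hypo}/\code{none}) columns added.
#' @seealso \code{\link{changedSets}}
#' @export
callChanged <- function(diffcalls, deltaThreshold = 5, alpha = 0.05) {
    stopifnot(deltaThreshold > 0, alpha > 0)
    changed <- diffcalls$p <= alpha &
        abs(diffcalls$delta) >= deltaThreshold
    diffcalls$changed <- changed
    diffcalls$direction <- ifelse(!changed, "none",
                                  ifelse(diffcalls$delta > 0,
                                         "hyper", "hypo"))
    diffcalls
}

#' Extract hyper-/hypomethylated site-id sets
#'
#' @param calls output of \code{\link{callChanged}} (or of
#'   \code{\link{callFactorChanges}} for one factor).
#' @return list(hyper = character ids, hypo = character ids).
#' @export
changedSets <- function(calls) {
    list(hyper = calls$site_id[calls$direction == "hyper"],
         hypo = calls$site_id[calls$direction == "hypo"])
}

#' Summarise changed sites by CGI class and baseline compartment
#'
#' Tabulates changed sites by (CGI class x direction) and by (baseline
#' compartment x direction). Two denominators are produced, matching
#' the two bar-chart conventions: proportions over \emph{all} analysed
#' sites, and an island-only breakdown whose denominator is the number
#' of analysed island sites.
#'
#' @param calls output of \code{\link{callChanged}}.
#' @param annotation data.frame with \code{site_id}, \code{cgi_class}
#'   and optionally \code{compartment} (low/mid/high); every scored
#'   site must be annotated.
#' @return list(byClass, byCompartment, islandOnly, nAnalysed,
#'   nIsland); each table has columns (category, direction, n,
#'   proportion).
#' @export
compartmentSummary <- function(calls, annotation) {
    i <- match(calls$site_id, annotation$site_id)
    if (anyNA(i))
        stop("no annotation for site(s): ",
             paste(head(calls$site_id[is.na(i)], 3L), collapse = ", "))
    ann <- annotation[i, , drop = FALSE]
    nAll <- nrow(calls)
    tab <- function(category, denom) {
        keep <- calls$changed & !is.na(category)
        if (!any(keep))
            return(data.frame(category = character(0),
                              direction = character(0),
                              n = integer(0), proportion = numeric(0)))
        t <- as.data.frame(table(category = category[keep],
                                 direction = calls$direction[keep]))
        t <- t[t$direction %in% c("hyper", "hypo"), , drop = FALSE]
        names(t)[3L] <- "n"
        t$proportion <- t$n / denom
        t$category <- as.character(t$category)
        t$direction <- as.character(t$direction)
        rownames(t) <- NULL
        t
    }
    byClass <- tab(ann$cgi_class, nAll)
    byComp <- if ("compartment" %in% names(ann))
        tab(ann$compartment, nAll) else NULL
    isIsle <- ann$cgi_class == "island"
    nIsland <- sum(isIsle)
    islandCalls <- calls[isIsle, , drop = FALSE]
    islandOnly <- if (nIsland > 0L && any(islandCalls$changed)) {
        dirs <- factor(islandCalls$direction[islandCalls$changed],
                       levels = c("hyper", "hypo"))
        t <- as.data.frame(table(direction = dirs))
        names(t)[2L] <- "n"
        t$proportion <- t$n / nIsland
        t$direction <- as.character(t$direction)
        t
    } else data.frame(direction = character(0), n = integer(0),
                      proportion = numeric(0))
    list(byClass = byClass, byCompartment = byComp,
         islandOnly = islandOnly, nAnalysed = nAll, nIsland = nIsland)
}

#' Two-sample t-test power for a methylation difference
#'
#' Power of the two-sided equal-variance t-test to detect an absolute
#' difference \code{delta} (percentage points) between two groups of
#' \code{nPerGroup} samples with common standard deviation \code{sd},
#' via the noncentral t distribution with noncentrality
#' |delta| / (sd sqrt(2/n)) and 2n - 2 degrees of freedom. With
#' \code{sd = 0} the power is defined as 1 for a non-zero difference
#' and \code{alpha} otherwise.
#'
#' @param delta effect size(s), percentage points.
#' @param sd pooled standard deviation(s), > 0 (or 0, see above).
#' @param nPerGroup samples per group (>= 2).
#' @param alpha two-sided significance level.
#' @return power in [0, 1], vectorised over \code{delta}/\code{sd}.
#' @examples
#' sitePower(10, 4, 3)
#' @export
sitePower <- function(delta, sd, nPerGroup, alpha = 0.05) {
    stopifnot(nPerGroup >= 2, all(sd >= 0))
    df <- 2 * nPerGroup - 2
    tcrit <- qt(1 - alpha / 2, df)
    ncp <- abs(delta) / (sd * sqrt(2 / nPerGroup))
    pow <- 1 - pt(tcrit, df, ncp) + pt(-tcrit, df, ncp)
    pow[sd == 0] <- ifelse(delta[sd == 0] != 0, 1, alpha)
    pow
}

#' Average detection power across large-effect sites
#'
#' Computes, for each site whose observed group difference exceeds
#' \code{minDelta} points, the t-test power at the site's pooled
#' standard deviation and the design's group sizes, and averages them —
#' the design-adequacy summary used for the ageing comparison (3 vs 3
#' mice).
#'
#' @param x a filtered \code{\linkS4class{DreamSet}}.
#' @param referenceSamples,exposedSamples the two groups.
#' @param minDelta only sites with |delta| strictly greater than this
#'   qualify (default 5).
#' @param alpha significance level.
#' @return list(perSite = data.frame(site_id, delta, sd, power),
#'   averagePower, nSites).
#' @export
powerReport <- function(x, referenceSamples, exposedSamples,
                        minDelta = 5, alpha = 0.05) {
    d <- diffTest(x, referenceSamples, exposedSamples)
    mr <- methPercent(x)[d$site_id, referenceSamples, drop = FALSE]
    me <- methPercent(x)[d$site_id, exposedSamples, drop = FALSE]
    ssr <- rowSums((mr - rowMeans(mr, na.rm = TRUE))^2, na.rm = TRUE)
    sse <- rowSums((me - rowMeans(me, na.rm = TRUE))^2, na.rm = TRUE)
    sd <- sqrt((ssr + sse) / (d$n_ref + d$n_exp - 2L))
    qual <- abs(d$delta) > minDelta
    n <- floor((d$n_ref + d$n_exp) / 2)
    pow <- sitePower(d$delta, sd, nPerGroup = min(n), alpha = alpha)
    perSite <- data.frame(site_id = d$site_id, delta = d$delta,
                          sd = sd, power = pow)[qual, , drop = FALSE]
    rownames(perSite) <- NULL
    list(perSite = perSite,
         averagePower = mean(perSite$power),
         nSites = nrow(perSite))
}
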