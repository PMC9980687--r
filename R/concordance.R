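#' Exact intersection-pattern (UpSet) counts
#'
#' For named sets drawn from a common universe, counts, for every
#' non-empty combination of the sets, the elements belonging to exactly
#' that combination and no other (UpSet semantics), plus the pairwise
#' shared fractions |A intersect B| / |A|.
#'
#' @param sets named list of character vectors (site or gene ids).
#' @param universe optional universe; defaults to the union. An element
#'   outside the universe is an error naming it.
#' @return list(patterns = data.frame(pattern, count) over all 2^k - 1
#'   combinations, sharedFraction = k x k matrix with entry [i, j] =
#'   |i intersect j| / |i|).
#' @examples
#' overlapSets(list(A = c("s1", "s2"), B = c("s2", "s3")))
#' @export
overlapSets <- function(sets, universe = NULL) {
    stopifnot(is.list(sets), !is.null(names(sets)))
    if (is.null(universe)) universe <- unique(unlist(sets))
    bad <- setdiff(unlist(sets), universe)
    if (length(bad))
        stop("element outside universe: ", bad[1L])
    k <- length(sets)
    elems <- unique(unlist(sets))
    memb <- vapply(sets, function(s) elems %in% s,
                   logical(length(elems)))
    if (length(elems) == 1L) memb <- matrix(memb, nrow = 1L,
                                            dimnames = list(NULL,
                                                            names(sets)))
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))
    combos <- combos[rowSums(combos) > 0L, , drop = FALSE]
    names(combos) <- names(sets)
    patKey <- apply(memb + 0L, 1L, paste0, collapse = "")
    counts <- table(patKey)
    pattern <- apply(combos, 1L, function(z)
        paste(names(sets)[as.logical(z)], collapse = "&"))
    key <- apply(combos, 1L, function(z)
        paste0(as.integer(z), collapse = ""))
    patterns <- data.frame(pattern = pattern,
                           count = as.integer(counts[key]),
                           stringsAsFactors = FALSE)
    patterns$count[is.na(patterns$count)] <- 0L
    rownames(patterns) <- NULL
    shared <- matrix(NA_real_, k, k,
                     dimnames = list(names(sets), names(sets)))
    for (i in seq_len(k)) for (j in seq_len(k))
        shared[i, j] <- if (length(sets[[i]]))
            length(intersect(sets[[i]], sets[[j]])) / length(sets[[i]])
        else NA_real_
    list(patterns = patterns, sharedFraction = shared)
}

#' Age-drift concordance of an exposure
#'
#' Restricts to sites significantly changed with age (|delta| at or
#' above \code{minAgeChange} points and p <= \code{alpha}), pairs each
#' site's age change with its change under an exposure, and reports the
#' Pearson correlation, its two-sided p-value and the OLS slope of
#' exposure change on age change.
#'
#' @param ageCalls \code{\link{diffTest}} output for old vs young.
#' @param exposureDeltas data.frame(site_id, delta) for the exposure
#'   (pairwise delta or linear-model slope).
#' @param minAgeChange magnitude threshold on the age delta (default
#'   5).
#' @param alpha significance threshold on the age p-value; set to 1 to
#'   use the magnitude rule alone.
#' @return list(r, p, slope, n); with fewer than 3 paired sites the
#'   statistics are NA and only n is reported.
#' @export
driftScatter <- function(ageCalls, exposureDeltas, minAgeChange = 5,
                         alpha = 0.05) {
    keep <- abs(ageCalls$delta) >= minAgeChange & ageCalls$p <= alpha
    age <- ageCalls[keep, c("site_id", "delta")]
    i <- match(age$site_id, exposureDeltas$site_id)
    ok <- !is.na(i)
    xa <- age$delta[ok]
    xe <- exposureDeltas$delta[i[ok]]
    n <- length(xa)
    if (n < 3L)
        return(list(r = NA_real_, p = NA_real_, slope = NA_real_,
                    n = n))
    ct <- cor.test(xa, xe, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value,
         slope = cov(xe, xa) / var(xa), n = n)
}

#' Enrichment odds ratio for factor/cancer concordance
#'
#' Builds the 2x2 table of the universe by membership in a
#' factor-changed set and a cancer-changed set and reports the odds
#' ratio (ad/bc, no continuity correction) with a Woolf (log-scale)
#' 95\% confidence interval. A zero overlap cell gives OR 0 with CI
#' [0, 0]. The p-value is a two-sided Fisher exact test, intended for
#' BH adjustment across a family of tests (see
#' \code{\link{enrichmentTable}}).
#'
#' @param factorSet,cancerSet character id sets, both within
#'   \code{universe}.
#' @param universe character vector of all eligible ids (for
#'   gene-level tests: the genes measured on both sides).
#' @return list(a, b, c, d, or, ciLow, ciHigh, p).
#' @examples
#' u <- paste0("g", 1:1000)
#' enrichmentOR(u[1:100], u[c(1:20, 101:260)], u)  # OR = 1
#' @export
enrichmentOR <- function(factorSet, cancerSet, universe) {
    if (!length(universe)) stop("empty universe")
    if (length(setdiff(factorSet, universe)) ||
        length(setdiff(cancerSet, universe)))
        stop("set element outside universe")
    inF <- universe %in% factorSet
    inC <- universe %in% cancerSet
    a <- sum(inF & inC)
    b <- sum(inF & !inC)
    c <- sum(!inF & inC)
    d <- sum(!inF & !inC)
    p <- fisher.test(matrix(c(a, b, c, d), 2L, byrow = TRUE))$p.value
    if (a == 0L)
        return(list(a = a, b = b, c = c, d = d, or = 0,
                    ciLow = 0, ciHigh = 0, p = p))
    or <- (a * d) / (b * c)
    selog <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    list(a = a, b = b, c = c, d = d, or = or,
         ciLow = exp(log(or) - 1.96 * selog),
         ciHigh = exp(log(or) + 1.96 * selog), p = p)
}

#' Family of enrichment tests with BH-adjusted q-values
#'
#' Runs \code{\link{enrichmentOR}} for every (factor, direction) set
#' against the matching cancer direction set and adjusts the Fisher
#' p-values by Benjamini-Hochberg across the whole family.
#'
#' @param factorSets named list of lists: per factor, list(hyper, hypo)
#'   id sets (as from \code{\link{callFactorChanges}} or
#'   \code{\link{changedSets}}, mapped to genes).
#' @param cancerSets list(hyper, hypo) gene sets changed in cancer.
#' @param universe common gene universe.
#' @return data.frame(factor, direction, a, b, c, d, or, ciLow,
#'   ciHigh, p, q).
#' @export
enrichmentTable <- function(factorSets, cancerSets, universe) {
    rows <- list()
    for (f in names(factorSets)) for (dir in c("hyper", "hypo")) {
        e <- enrichmentOR(factorSets[[f]][[dir]], cancerSets[[dir]],
                          universe)
        rows[[paste(f, dir)]] <- data.frame(
            factor = f, direction = dir, as.data.frame(e),
            stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out$q <- fdrAdjust(out$p)
    out
}

#' Gene-level mouse/cancer methylation concordance
#'
#' Matches each gene's promoter representative CCCGGG site (the member
#' closest to the TSS, from \code{\link{mapPromoters}} in \code{tcga}
#' mode) with a tumour-minus-normal beta-value difference, converted
#' from the [-1, 1] beta scale to percentage points (x 100). Genes
#' missing on either side are dropped and counted; duplicate gene rows
#' in the cancer table keep the first occurrence with a warning.
#'
#' @param promoterMap output of \code{\link{mapPromoters}}.
#' @param siteDeltas data.frame(site_id, delta): per-site change from
#'   the mouse analysis (pairwise delta or model slope, percentage
#'   points).
#' @param cancerTable data.frame(gene, beta_diff) with beta_diff in
#'   [-1, 1].
#' @return data.frame(gene, site_id, mouse_delta, cancer_delta); the
#'   attribute \code{dropped} records how many genes fell out on each
#'   side.
#' @export
geneConcordance <- function(promoterMap, siteDeltas, cancerTable) {
    if (any(abs(cancerTable$beta_diff) > 1, na.rm = TRUE))
        stop("beta_diff must be on the [-1, 1] beta scale")
    if (anyDuplicated(cancerTable$gene)) {
        warning("duplicate gene rows in cancer table; keeping first")
        cancerTable <- cancerTable[!duplicated(cancerTable$gene), ,
                                   drop = FALSE]
    }
    rep <- promoterMap[promoterMap$representative, , drop = FALSE]
    i <- match(rep$site_id, siteDeltas$site_id)
    genes <- data.frame(gene = rep$gene, site_id = rep$site_id,
                        mouse_delta = siteDeltas$delta[i],
                        stringsAsFactors = FALSE)
    noMouse <- sum(is.na(genes$mouse_delta))
    genes <- genes[!is.na(genes$mouse_delta), , drop = FALSE]
    j <- match(genes$gene, cancerTable$gene)
    noCancer <- sum(is.na(j))
    genes$cancer_delta <- 100 * cancerTable$beta_diff[j]
    genes <- genes[!is.na(genes$cancer_delta), , drop = FALSE]
    rownames(genes) <- NULL
    attr(genes, "dropped") <- c(no_mouse_delta = noMouse,
                                no_cancer_value = noCancer)
    genes
}

#' Threshold a matched gene table into direction sets
#'
#' @param genes output of \code{\link{geneConcordance}}.
#' @param threshold minimum |change| in points on each side (default
#'   5).
#' @return list(factorSets = list(hyper, hypo) by mouse change,
#'   cancerSets = list(hyper, hypo) by cancer change, universe).
#' @export
concordanceSets <- function(genes, threshold = 5) {
    list(factorSets = list(
             hyper = genes$gene[genes$mouse_delta >= threshold],
             hypo = genes$gene[genes$mouse_delta <= -threshold]),
         cancerSets = list(
             hyper = genes$gene[genes$cancer_delta >= threshold],
             hypo = genes$gene[genes$cancer_delta <= -threshold]),
         universe = genes$gene)
}
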