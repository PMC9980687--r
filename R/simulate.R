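#' Default animal-group design for the synthetic study
#'
#' Seven exposure groups of six mice crossing microbiota (germ-free vs
#' SPF), Il10 genotype and azoxymethane (AOM) treatment, plus small
#' young/old groups (n = 3) for the ageing comparison, which is analysed
#' separately from the exposure model.
#'
#' @return data.frame(group, n, microbiota, il10ko, aom, age_class).
#' @examples
#' defaultDreamDesign()
#' @export
defaultDreamDesign <- function() {
    data.frame(
        group = c("GF_WT", "SPF_WT", "GF_IL10KO", "SPF_IL10KO",
                  "SPF_WT_AOM", "GF_IL10KO_AOM", "SPF_IL10KO_AOM",
                  "Young", "Old"),
        n = c(rep(6L, 7L), 3L, 3L),
        microbiota = c(0L, 1L, 0L, 1L, 1L, 0L, 1L, 0L, 0L),
        il10ko     = c(0L, 0L, 1L, 1L, 0L, 1L, 1L, 0L, 0L),
        aom        = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 0L, 0L),
        age_class  = c(rep("adult", 7L), "young", "old"),
        stringsAsFactors = FALSE)
}

#' Default additive effect table
#'
#' One row per (factor, CGI class) pair: when a sample carries the
#' factor, a random \code{fraction} of that class's sites is shifted by
#' \code{shift} percentage points. Magnitudes of +/-10 points sit well
#' above the 5-point call threshold; the fractions echo the relative
#' scale and direction seen in colonic methylome exposure studies
#' (microbiota and Il10 loss each touching a few percent of open-sea
#' sites, AOM mostly hypomethylating, ageing both losing methylation
#' globally and gaining it at CpG islands).
#'
#' @return data.frame(factor, cgi_class, shift, fraction).
#' @examples
#' defaultEffectTable()
#' @export
defaultEffectTable <- function() {
    data.frame(
        factor = c("microbiota", "microbiota", "microbiota",
                   "il10ko", "il10ko", "il10ko",
                   "aom", "aom",
                   "age", "age", "age", "age"),
        cgi_class = c("other", "other", "island",
                      "other", "other", "island",
                      "other", "other",
                      "other", "other", "island", "shore"),
        shift = c(-10, 10, 8,
                  -10, 10, 8,
                  -10, 10,
                  -10, 10, 10, 10),
        fraction = c(0.030, 0.012, 0.004,
                     0.020, 0.012, 0.005,
                     0.049, 0.010,
                     0.066, 0.050, 0.040, 0.020),
        stringsAsFactors = FALSE)
}

#' Build a simulation configuration
#'
#' See \linkS4class{DreamSimConfig} for the meaning of every field.
#' Invalid settings (proportions not summing to 1, fewer than nine
#' spike-in levels, non-positive efficiencies, groups of fewer than two
#' animals) raise a configuration error via the class validity check.
#'
#' @param nSites number of CCCGGG sites.
#' @param compartmentFractions named island/shore/other proportions.
#' @param baselineShapes per-class Beta shape pairs for baseline
#'   methylation fractions.
#' @param effectTable see \code{\link{defaultEffectTable}}.
#' @param design see \code{\link{defaultDreamDesign}}.
#' @param depthMean,depthDispersion negative-binomial depth law.
#' @param cTrue explicit per-sample digestion efficiencies (empty =
#'   draw from \code{cRange}).
#' @param cRange log-uniform range for drawn efficiencies.
#' @param mouseSd per-mouse biological jitter (percentage points).
#' @param labileFraction,labileBias shared-susceptibility pools: a
#'   \code{labileFraction} share of sites is loss-prone and another
#'   gain-prone, and each factor spends \code{labileBias} of its effect
#'   budget inside its direction's pool, so exposures and ageing
#'   converge on partly shared sites as they do in colonic mucosa.
#' @param spikeLevels nine spike-in methylation percentages.
#' @param spikeDepth spike-in depth.
#' @param sexFraction fraction of sites on chrX.
#' @param seed integer seed.
#' @return A \code{DreamSimConfig}.
#' @examples
#' DreamSimConfig(nSites = 100, seed = 7)
#' @export
DreamSimConfig <- function(nSites = 22000,
                           compartmentFractions = c(island = 0.25,
                                                    shore = 0.15,
                                                    other = 0.60),
                           baselineShapes = list(island = c(0.8, 15),
                                                 shore = c(2, 5),
                                                 other = c(5, 2)),
                           effectTable = defaultEffectTable(),
                           design = defaultDreamDesign(),
                           depthMean = 300, depthDispersion = 5,
                           cTrue = numeric(0), cRange = c(0.7, 1.4),
                           mouseSd = 2, labileFraction = 0.02,
                           labileBias = 0.8,
                           spikeLevels = seq(0, 100, 12.5),
                           spikeDepth = 10000, sexFraction = 0.03,
                           seed = 1L) {
    new("DreamSimConfig",
        nSites = as.integer(nSites),
        compartmentFractions = compartmentFractions,
        baselineShapes = baselineShapes,
        effectTable = effectTable,
        design = design,
        depthMean = depthMean, depthDispersion = depthDispersion,
        cTrue = cTrue, cRange = cRange, mouseSd = mouseSd,
        labileFraction = labileFraction, labileBias = labileBias,
        spikeLevels = spikeLevels, spikeDepth = spikeDepth,
        sexFraction = sexFraction, seed = as.integer(seed))
}

#' Simulate the CCCGGG site census with ground truth
#'
#' Places \code{nSites} hexamer sites on synthetic chromosomes (chr1-19
#' plus a \code{sexFraction} share on chrX so the autosome filter has
#' something to remove), assigns each a CGI class and a baseline
#' methylation level drawn from its class's Beta law, then plants the
#' factor effects of \code{effectTable}: per factor, a random fraction
#' of each class's sites gets the stated additive shift. Per-group true
#' methylation is baseline plus the shifts of the factors the group
#' carries (ageing shifts apply to the old group only), clipped to
#' [0, 100].
#'
#' @param config a \code{\linkS4class{DreamSimConfig}}.
#' @return list with \code{sites} (a \code{GRanges} with mcols
#'   \code{site_id}, \code{cgi_class}) and \code{truth} (data.frame with
#'   site_id, chrom, start0, cgi_class, per-factor \code{shift_*}
#'   columns, and one \code{true_<group>} column per design group).
#' @examples
#' s <- simulateSites(DreamSimConfig(nSites = 50, seed = 1))
#' table(s$truth$cgi_class)
#' @export
simulateSites <- function(config) {
    validObject(config)
    set.seed(substream_seed(config@seed, 1L))
    n <- config@nSites
    cls <- sample(names(config@compartmentFractions), n, replace = TRUE,
                  prob = config@compartmentFractions)
    nX <- rbinom(1L, n, config@sexFraction)
    chrom <- c(rep("chrX", nX),
               sample(paste0("chr", 1:19), n - nX, replace = TRUE))
    chrom <- sample(chrom)
    start0 <- sample.int(190000000L, n)   # unique across the genome
    o <- order(chrom, start0)
    chrom <- chrom[o]; start0 <- start0[o]; cls <- cls[o]
    site_id <- paste0(chrom, ":", start0)

    base <- numeric(n)
    for (k in names(config@baselineShapes)) {
        i <- cls == k
        sh <- config@baselineShapes[[k]]
        base[i] <- 100 * rbeta(sum(i), sh[1L], sh[2L])
    }

    # loss-/gain-prone pools: factors of the same direction converge on
    # partly shared sites, as exposures and ageing do in colonic mucosa
    lf <- config@labileFraction
    pool <- sample(c("loss", "gain", "none"), n, replace = TRUE,
                   prob = c(lf, lf, 1 - 2 * lf))
    factors <- unique(config@effectTable$factor)
    shifts <- matrix(0, n, length(factors),
                     dimnames = list(NULL, factors))
    for (f in factors) {
        rows <- config@effectTable[config@effectTable$factor == f, ]
        for (r in seq_len(nrow(rows))) {
            elig <- which(cls == rows$cgi_class[r] & shifts[, f] == 0)
            if (!length(elig)) next
            want <- if (rows$shift[r] < 0) "loss" else "gain"
            inPool <- pool[elig] == want
            pf <- mean(inPool)
            f0 <- rows$fraction[r]
            pIn <- if (pf > 0) min(1, f0 * config@labileBias / pf) else 0
            pOut <- max(0, f0 - pIn * pf) / max(1 - pf, 1e-9)
            prob <- ifelse(inPool, pIn, min(1, pOut))
            hit <- elig[runif(length(elig)) < prob]
            shifts[hit, f] <- rows$shift[r]
        }
    }

    truth <- data.frame(site_id = site_id, chrom = chrom,
                        start0 = start0, cgi_class = cls,
                        baseline = base, stringsAsFactors = FALSE)
    for (f in factors) truth[[paste0("shift_", f)]] <- shifts[, f]

    for (g in seq_len(nrow(config@design))) {
        d <- config@design[g, ]
        m <- base
        for (f in c("microbiota", "il10ko", "aom"))
            if (f %in% factors && d[[f]] == 1L) m <- m + shifts[, f]
        if ("age" %in% factors && d$age_class == "old")
            m <- m + shifts[, "age"]
        truth[[paste0("true_", d$group)]] <- pmin(100, pmax(0, m))
    }

    sites <- GRanges(chrom, IRanges(start0 + 1L, width = 6L))
    mcols(sites)$site_id <- site_id
    mcols(sites)$cgi_class <- cls
    list(sites = sites, truth = truth)
}

# inverse-calibration read-level success probability: a read from a site
# with true methylation fraction m under digestion efficiency c carries
# the methylated signature with probability m / (m + c (1 - m)), so that
# applying the correction formula with c recovers m without bias
signature_prob <- function(m, c_eff) {
    p <- m / (m + c_eff * (1 - m))
    p[m <= 0] <- 0
    p[m >= 1] <- 1
    p
}

#' Simulate signature counts, spike-ins and the design table
#'
#' Draws, for every site and mouse, a read depth from the
#' negative-binomial law and a methylated-signature count from a
#' binomial whose success probability is the inverse of the correction
#' formula at the sample's true digestion efficiency — so quantifying
#' the counts with the true \code{c} is unbiased for the planted truth.
#' Mouse-level variation adds Gaussian jitter (sd \code{mouseSd} points,
#' truncated to [0, 100]) to the group truth before drawing. Spike-in
#' standards are generated the same way at the nine known levels with
#' fixed depth \code{spikeDepth}.
#'
#' @param truth the truth table from \code{\link{simulateSites}}.
#' @param config the same \code{\linkS4class{DreamSimConfig}}.
#' @return list with \code{counts} (site_id, sample_id, n_meth,
#'   n_unmeth), \code{spikes} (standard_id, expected_meth, n_meth,
#'   n_unmeth, sample_id), \code{design} (sample_id, group, microbiota,
#'   il10ko, aom, age_class) and \code{cTrue} (named per-sample vector).
#' @examples
#' cfg <- DreamSimConfig(nSites = 20, seed = 3)
#' sim <- simulateCounts(simulateSites(cfg)$truth, cfg)
#' head(sim$counts)
#' @export
simulateCounts <- function(truth, config) {
    validObject(config)
    set.seed(substream_seed(config@seed, 2L))
    des <- config@design
    design <- do.call(rbind, lapply(seq_len(nrow(des)), function(g) {
        data.frame(sample_id = paste(des$group[g], seq_len(des$n[g]),
                                     sep = "_"),
                   group = des$group[g],
                   microbiota = des$microbiota[g],
                   il10ko = des$il10ko[g], aom = des$aom[g],
                   age_class = des$age_class[g],
                   stringsAsFactors = FALSE)
    }))
    ns <- nrow(design)
    cTrue <- config@cTrue
    if (length(cTrue) == 0L)
        cTrue <- exp(runif(ns, log(config@cRange[1L]),
                           log(config@cRange[2L])))
    else if (length(cTrue) == 1L)
        cTrue <- rep(cTrue, ns)
    else if (length(cTrue) != ns)
        stop("cTrue must have length 1 or one entry per sample")
    names(cTrue) <- design$sample_id

    n <- nrow(truth)
    counts <- vector("list", ns)
    spikes <- vector("list", ns)
    for (j in seq_len(ns)) {
        m <- truth[[paste0("true_", design$group[j])]]
        if (config@mouseSd > 0)
            m <- pmin(100, pmax(0, m + rnorm(n, 0, config@mouseSd)))
        p <- signature_prob(m / 100, cTrue[j])
        D <- rnbinom(n, size = config@depthDispersion,
                     mu = config@depthMean)
        X <- rbinom(n, D, p)
        counts[[j]] <- data.frame(site_id = truth$site_id,
                                  sample_id = design$sample_id[j],
                                  n_meth = X, n_unmeth = D - X,
                                  stringsAsFactors = FALSE)
        ps <- signature_prob(config@spikeLevels / 100, cTrue[j])
        Xs <- rbinom(9L, config@spikeDepth, ps)
        spikes[[j]] <- data.frame(
            standard_id = sprintf("std%02d", seq_len(9L)),
            expected_meth = config@spikeLevels,
            n_meth = Xs, n_unmeth = config@spikeDepth - Xs,
            sample_id = design$sample_id[j],
            stringsAsFactors = FALSE)
    }
    list(counts = do.call(rbind, counts),
         spikes = do.call(rbind, spikes),
         design = design, cTrue = cTrue)
}

#' Simulate a complete synthetic DREAM study
#'
#' Convenience wrapper running \code{\link{simulateSites}} then
#' \code{\link{simulateCounts}}; fully reproducible from
#' \code{config@seed}.
#'
#' @param config a \code{\linkS4class{DreamSimConfig}}.
#' @return list(sites, truth, counts, spikes, design, cTrue).
#' @examples
#' sim <- simulateDreamData(DreamSimConfig(nSites = 10, seed = 2))
#' names(sim)
#' @export
simulateDreamData <- function(config) {
    s <- simulateSites(config)
    cts <- simulateCounts(s$truth, config)
    c(s, cts)
}
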