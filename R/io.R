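#' Read and write signature-count tables
#'
#' Tab-separated with header \code{site_id, sample_id, n_meth,
#' n_unmeth}; comment lines starting \code{#} (parameter provenance
#' written by the writers) are tolerated. Duplicate (site, sample)
#' keys, missing columns and non-integer counts are format errors that
#' name the offender.
#'
#' @param path file path.
#' @return data.frame(site_id, sample_id, n_meth, n_unmeth).
#' @export
readCountTable <- function(path) {
    d <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
    need <- c("site_id", "sample_id", "n_meth", "n_unmeth")
    miss <- setdiff(need, names(d))
    if (length(miss))
        stop("count table ", path, " lacks column(s): ",
             paste(miss, collapse = ", "))
    for (col in c("n_meth", "n_unmeth")) {
        v <- d[[col]]
        if (!is.numeric(v) || any(is.na(v)) || any(v != floor(v)) ||
            any(v < 0)) {
            bad <- which(!is.finite(suppressWarnings(as.numeric(v))) |
                         as.numeric(v) != floor(as.numeric(v)))[1L]
            stop("non-integer count in column ", col, " near line ",
                 (bad %||% 1L) + 1L)
        }
        d[[col]] <- as.integer(v)
    }
    key <- paste(d$site_id, d$sample_id)
    if (anyDuplicated(key))
        stop("duplicate (site_id, sample_id): ",
             key[duplicated(key)][1L])
    d[need]
}

#' @rdname readCountTable
#' @param counts data.frame to write.
#' @param provenance optional named character vector written as
#'   \code{# key=value} header comments.
#' @export
writeCountTable <- function(counts, path, provenance = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(provenance))
        writeLines(paste0("# ", names(provenance), "=", provenance),
                   con)
    utils::write.table(counts, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a spike-in observation table
#'
#' Tab-separated with header \code{standard_id, expected_meth, n_meth,
#' n_unmeth, sample_id}; expects nine standards per sample with
#' expected levels fixed per standard across samples.
#'
#' @param path file path.
#' @return data.frame in the spike-in layout.
#' @export
readSpikeTable <- function(path) {
    d <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
    need <- c("standard_id", "expected_meth", "n_meth", "n_unmeth",
              "sample_id")
    miss <- setdiff(need, names(d))
    if (length(miss))
        stop("spike table lacks column(s): ",
             paste(miss, collapse = ", "))
    d[need]
}

#' Read a sample design table
#'
#' Tab-separated with header \code{sample_id, microbiota, il10ko, aom,
#' age_class} (and optionally \code{group}).
#'
#' @param path file path.
#' @return data.frame of the design.
#' @export
readDesignTable <- function(path) {
    d <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
    need <- c("sample_id", "microbiota", "il10ko", "aom", "age_class")
    miss <- setdiff(need, names(d))
    if (length(miss))
        stop("design table lacks column(s): ",
             paste(miss, collapse = ", "))
    d
}

#' Read a TSS annotation table
#'
#' Tab-separated with header \code{gene, chrom, strand, tss}; the TSS
#' coordinate is 1-based.
#'
#' @param path file path.
#' @return data.frame(gene, chrom, strand, tss).
#' @export
readTssTable <- function(path) {
    d <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
    need <- c("gene", "chrom", "strand", "tss")
    miss <- setdiff(need, names(d))
    if (length(miss))
        stop("TSS table lacks column(s): ",
             paste(miss, collapse = ", "))
    d
}

#' Read BED intervals (e.g. a CpG-island track) as GRanges
#'
#' Minimal 3+ column BED: 0-based half-open intervals, converted to the
#' 1-based closed convention used internally.
#'
#' @param path BED file path.
#' @return \code{GRanges}.
#' @export
readBedIntervals <- function(path) {
    d <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
    if (ncol(d) < 3L) stop("BED needs at least 3 columns")
    if (any(d[[3L]] <= d[[2L]]))
        stop("BED interval with end <= start at line ",
             which(d[[3L]] <= d[[2L]])[1L])
    GRanges(d[[1L]], IRanges(d[[2L]] + 1L, d[[3L]]))
}

#' Write CCCGGG sites as BED
#'
#' Six-base intervals in BED convention (0-based half-open), name
#' column = site_id.
#'
#' @param sites \code{GRanges} of sites.
#' @param path output path.
#' @export
writeSitesBed <- function(sites, path) {
    utils::write.table(
        data.frame(chrom = as.character(seqnames(sites)),
                   start = start(sites) - 1L, end = end(sites),
                   name = granges_site_id(sites)),
        path, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
    invisible(path)
}

#' Run the synthetic end-to-end analysis
#'
#' Orchestrates the full flow on simulated inputs: simulate the study,
#' calibrate each sample from its spike-ins, build and filter the
#' methylation matrix, run the pairwise comparisons against the
#' germ-free wild-type reference (and old vs young), fit the
#' three-factor linear model on the adult animals, and compute the
#' drift concordances. Outputs are written as tab-separated tables
#' under \code{outDir} together with a JSON manifest (parameters, seed,
#' package version); identical configurations reproduce identical
#' files.
#'
#' @param config a \code{\linkS4class{DreamSimConfig}}.
#' @param outDir output directory (created if needed); \code{NULL}
#'   skips writing.
#' @param comparisons named list of c(reference, exposed) group pairs
#'   for the pairwise stage.
#' @return invisible list with the intermediate objects (sim, dset,
#'   filtered per comparison, calls, fits, drift).
#' @export
runPipeline <- function(config, outDir = NULL,
                        comparisons = list(
                            microbiota = c("GF_WT", "SPF_WT"),
                            il10ko = c("GF_WT", "GF_IL10KO"),
                            inflammation = c("GF_WT", "SPF_IL10KO"),
                            aom = c("SPF_WT", "SPF_WT_AOM"),
                            age = c("Young", "Old"))) {
    sim <- simulateDreamData(config)
    cal <- estimateCorrectionFactor(sim$spikes)
    dset <- buildDreamSet(sim$counts, cal, sim$design)
    ann <- data.frame(site_id = mcols(sim$sites)$site_id,
                      cgi_class = mcols(sim$sites)$cgi_class,
                      stringsAsFactors = FALSE)

    cd <- colData(dset)
    calls <- list(); deltas <- list(); filtered <- list()
    for (nm in names(comparisons)) {
        pair <- comparisons[[nm]]
        if (!all(pair %in% cd$group)) next
        sub <- dset[, cd$group %in% pair]
        sub <- filterSites(sub)
        ref <- colnames(sub)[colData(sub)$group == pair[1L]]
        exp <- colnames(sub)[colData(sub)$group == pair[2L]]
        d <- callChanged(diffTest(sub, ref, exp))
        filtered[[nm]] <- sub
        calls[[nm]] <- d
        deltas[[nm]] <- d[, c("site_id", "delta")]
    }

    adult <- dset[, cd$age_class == "adult"]
    adult <- filterSites(adult)
    fits <- fitFactorModel(adult)

    drift <- NULL
    if ("age" %in% names(calls)) {
        drift <- lapply(deltas[setdiff(names(deltas), "age")],
                        function(d) driftScatter(calls$age, d))
    }

    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeSitesBed(sim$sites, file.path(outDir, "sites.bed"))
        prov <- c(seed = config@seed, nSites = config@nSites)
        writeCountTable(sim$counts, file.path(outDir, "counts.tsv"),
                        provenance = prov)
        utils::write.table(sim$design,
                           file.path(outDir, "design.tsv"),
                           sep = "\t", quote = FALSE,
                           row.names = FALSE)
        utils::write.table(cal, file.path(outDir, "calibration.tsv"),
                           sep = "\t", quote = FALSE,
                           row.names = FALSE)
        for (nm in names(calls))
            utils::write.table(calls[[nm]],
                               file.path(outDir,
                                         paste0("diff_", nm, ".tsv")),
                               sep = "\t", quote = FALSE,
                               row.names = FALSE)
        utils::write.table(fits, file.path(outDir, "factor_fits.tsv"),
                           sep = "\t", quote = FALSE,
                           row.names = FALSE)
        manifest <- list(
            seed = config@seed, nSites = config@nSites,
            samples = nrow(sim$design),
            comparisons = comparisons,
            stages = c("simulate", "calibrate", "quantify", "filter",
                       "diff", "model", "drift"),
            version = as.character(utils::packageVersion("dreamdrift")))
        jsonlite::write_json(manifest,
                             file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE)
    }
    invisible(list(sim = sim, calibration = cal, dset = dset,
                   annotation = ann, filtered = filtered,
                   calls = calls, fits = fits, drift = drift))
}
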