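test_that("CCCGGG discovery matches hand cases and a naive scan", {
    s <- findCCCGGGSites(c(chr1 = "AACCCGGGTT"))
    expect_equal(length(s), 1L)
    expect_equal(GenomicRanges::start(s), 3L)        # 0-based start 2
    expect_equal(S4Vectors::mcols(s)$site_id, "chr1:2")

    s2 <- findCCCGGGSites(c(chr1 = "CCCGGGCCCGGG"))
    expect_equal(S4Vectors::mcols(s2)$site_id, c("chr1:0", "chr1:6"))

    # case-insensitive; N never matches
    s3 <- findCCCGGGSites(c(chr1 = "aacccgggtt", chr2 = "CCCGGN"))
    expect_equal(S4Vectors::mcols(s3)$site_id, "chr1:2")

    # naive regex scan as independent oracle on a random sequence
    set.seed(31)
    seqs <- vapply(1:3, function(i)
        paste(sample(c("A", "C", "G", "T", "N"), 100000, TRUE,
                     prob = c(.24, .26, .26, .23, .01)),
              collapse = ""), "")
    names(seqs) <- paste0("chr", 1:3)
    found <- findCCCGGGSites(seqs)
    naive <- do.call(rbind, lapply(names(seqs), function(ch) {
        hits <- gregexpr("CCCGGG", seqs[[ch]], fixed = TRUE)[[1]]
        if (hits[1] == -1) return(NULL)
        data.frame(chrom = ch, start0 = as.integer(hits) - 1L)
    }))
    expect_equal(S4Vectors::mcols(found)$site_id,
                 paste0(naive$chrom, ":", naive$start0))
})

test_that("CGI classification honours the 2,000 bp shore boundary", {
    # island covers 0-based [1000, 1200); last covered base 1199
    cgi <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(1001, 1200))
    sites <- siteIdToGRanges(c(
        "chr1:1100",            # inside -> island
        "chr1:3199",            # 1199 + 2000 -> shore (inclusive)
        "chr1:3200",            # 2001 away -> other
        "chr1:1200",            # first base past the edge -> shore
        "chr2:500"))            # no island on chr2 -> other
    cls <- classifyCGI(sites, cgi)
    expect_equal(cls, c("island", "shore", "other", "shore", "other"))

    # exhaustive, exclusive partition on random data
    set.seed(8)
    rs <- siteIdToGRanges(paste0("chr1:", sample.int(100000, 300)))
    rc <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(5000, 40000),
                                                  c(6000, 42000)))
    p <- classifyCGI(rs, rc)
    expect_true(all(p %in% c("island", "shore", "other")))

    bad <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5, 5))
    GenomicRanges::width(bad) <- 0L
    expect_error(classifyCGI(rs, bad), "end <= start")
})

test_that("promoter windows are stranded and pick the closest site", {
    tss <- data.frame(gene = c("gp", "gm"), chrom = "chr1",
                      strand = c("+", "-"), tss = 10000L)
    sites <- siteIdToGRanges(c(
        "chr1:8600",    # pos 8601, within +/-1500 of plus-strand TSS
        "chr1:8400",    # pos 8401, outside symmetric window
        "chr1:9199",    # pos 9200, d = 800
        "chr1:9799",    # pos 9800, d = 200 -> representative
        "chr1:11399",   # pos 11400
        "chr1:11501"))  # pos 11502, outside both windows

    pm <- mapPromoters(sites, tss, "symmetric_1500")
    gp <- pm[pm$gene == "gp", ]
    expect_setequal(gp$site_id,
                    c("chr1:8600", "chr1:9199", "chr1:9799",
                      "chr1:11399"))
    expect_equal(gp$site_id[gp$representative], "chr1:9799")

    # tcga mode on the minus strand covers [9500, 11500] in genome
    # coordinates: upstream is to the right of the TSS
    pt <- mapPromoters(sites, tss, "tcga")
    gm <- pt[pt$gene == "gm", ]
    expect_setequal(gm$site_id,
                    c("chr1:9799", "chr1:11399"))
    gpt <- pt[pt$gene == "gp", ]   # plus strand: [8500, 10500]
    expect_setequal(gpt$site_id,
                    c("chr1:8600", "chr1:9199", "chr1:9799"))

    # tie at equal distance breaks toward the lower coordinate
    tie <- siteIdToGRanges(c("chr1:9799", "chr1:10199"))  # d = 200 both
    tp <- mapPromoters(tie, tss[1, ], "symmetric_1500")
    expect_equal(tp$site_id[tp$representative], "chr1:9799")

    # membership invariant to site ordering
    pm2 <- mapPromoters(rev(sites), tss, "symmetric_1500")
    expect_setequal(paste(pm2$gene, pm2$site_id),
                    paste(pm$gene, pm$site_id))

    expect_warning(mapPromoters(sites, tss[c(1, 1), ],
                                "symmetric_1500"),
                   "duplicate")
})

test_that("baseline compartments split at 20/80 with boundaries in mid", {
    m <- matrix(c(10, 50, 95, 80, 20, NA,
                  10, 50, 95, 80, 20, NA), 6, 2,
                dimnames = list(paste0("chr1:", 1:6 * 10),
                                c("ref1", "ref2")))
    d <- toyDreamSet(m)
    comp <- baselineCompartment(d, c("ref1", "ref2"))
    expect_equal(unname(comp),
                 c("low", "mid", "high", "mid", "mid", NA))

    # stratum counts equal a brute-force recount on random data
    set.seed(12)
    mm <- matrix(runif(600, 0.5, 99.5), 100, 6)
    dd <- toyDreamSet(mm)
    cc <- baselineCompartment(dd, 1:3)
    mu <- rowMeans(mm[, 1:3])
    expect_equal(unname(table(cc)["high"]), sum(mu > 80))
    expect_equal(unname(table(cc)["low"]), sum(mu < 20))
    expect_equal(unname(table(cc)["mid"]), sum(mu >= 20 & mu <= 80))
})
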