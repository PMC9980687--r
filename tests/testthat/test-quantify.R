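test_that("signature counting follows the SmaI/XmaI read-start rules", {
    r <- data.frame(site_id = "chr1:10", sample_id = "s1",
                    seq = c("CCGGGAT", "GGGTTAA", "CCGGGCC"))
    out <- countSignatures(r)
    expect_equal(out$n_meth, 2L)
    expect_equal(out$n_unmeth, 1L)
    expect_equal(attr(out, "discarded"), 0L)

    # neither signature -> discarded; lower case accepted
    r2 <- data.frame(site_id = "chr1:10", sample_id = "s1",
                     seq = c("ACGGG", "ccgggt", "gggaa", "TTTTT"))
    out2 <- countSignatures(r2)
    expect_equal(out2$n_meth, 1L)
    expect_equal(out2$n_unmeth, 1L)
    expect_equal(attr(out2, "discarded"), 2L)

    empty <- countSignatures(r[0, ])
    expect_equal(nrow(empty), 0L)
})

test_that("signature counting conserves reads and skips malformed records", {
    set.seed(1)
    n <- 500L
    r <- data.frame(
        site_id = sample(paste0("chr1:", 1:20 * 7), n, replace = TRUE),
        sample_id = sample(c("a", "b"), n, replace = TRUE),
        seq = sample(c("CCGGGT", "GGGAT", "ACCCA", ""), n,
                     replace = TRUE))
    expect_warning(out <- countSignatures(r), "malformed")
    total <- sum(out$n_meth) + sum(out$n_unmeth) +
        attr(out, "discarded") + attr(out, "malformed")
    expect_equal(total, n)
    # a (site, sample) with no signature reads is absent
    expect_true(all(out$n_meth + out$n_unmeth > 0L))
})

test_that("methylation formula reproduces worked values and identities", {
    expect_equal(methylationValue(0, 0, 1), 50)
    expect_equal(methylationValue(99, 99, 1), 50)
    expect_equal(methylationValue(10, 10, 2), 100 * 21 / 31.5,
                 tolerance = 1e-12)
    expect_equal(methylationValue(199, 0, 1), 99.75, tolerance = 1e-12)
    for (a in c(0, 1, 7, 1000))
        expect_equal(methylationValue(a, a, 1), 50)
    # reflection: swapping counts and inverting c mirrors about 50
    set.seed(2)
    x <- rpois(50, 40); y <- rpois(50, 40)
    cc <- runif(50, 0.3, 3)
    expect_equal(methylationValue(x, y, cc),
                 100 - methylationValue(y, x, 1 / cc),
                 tolerance = 1e-9)
    # monotone in each count
    expect_true(all(diff(methylationValue(0:50, 10, 1)) > 0))
    expect_true(all(diff(methylationValue(10, 0:50, 1)) < 0))
    expect_error(methylationValue(1, 1, 0), "c must be")
    expect_error(methylationValue(-1, 1, 1), "non-negative")
})

test_that("correction-factor estimation recovers known efficiencies", {
    cal1 <- estimateCorrectionFactor(exactSpikes(1.0))
    expect_equal(cal1$c, 1.0, tolerance = 0.01)
    expect_true(cal1$accepted)

    # independent grid-search oracle at c_true = 0.7
    sp <- exactSpikes(0.7)
    grid <- exp(seq(log(0.05), log(20), length.out = 20001))
    ss <- vapply(grid, function(g)
        sum((methylationValue(sp$n_meth, sp$n_unmeth, g) -
             sp$expected_meth)^2), 0)
    cal <- estimateCorrectionFactor(sp)
    expect_equal(cal$c, 0.7, tolerance = 0.02)
    expect_equal(cal$c, grid[which.min(ss)], tolerance = 1e-3)
    expect_true(cal$accepted)

    # efficiency far out of range is estimated but flagged rejected
    cal3 <- estimateCorrectionFactor(randomSpikes(3.0))
    expect_equal(cal3$c, 3.0, tolerance = 0.15)
    expect_false(cal3$accepted)

    one <- exactSpikes(1)[c(1, 1, 1), ]
    expect_error(estimateCorrectionFactor(one), "distinct expected")
})

test_that("matrix assembly applies per-sample calibration and drops rejects", {
    cts <- data.frame(site_id = "chr1:5",
                      sample_id = c("s1", "s2"),
                      n_meth = 10L, n_unmeth = 10L)
    cal <- data.frame(sample_id = c("s1", "s2"), c = c(1, 2),
                      accepted = TRUE)
    d <- buildDreamSet(cts, cal)
    expect_equal(unname(methPercent(d)[1, "s1"]), 50)
    expect_equal(unname(methPercent(d)[1, "s2"]), 100 * 21 / 31.5)
    expect_equal(unname(readDepth(d)[1, ]), c(20L, 20L))

    cal$accepted[2] <- FALSE
    expect_message(d2 <- buildDreamSet(cts, cal), "rejected")
    expect_equal(ncol(d2), 1L)
    expect_error(buildDreamSet(cts, cal[1, ]), "s2")
})

test_that("site filter enforces depth, autosome and group-fraction rules", {
    set.seed(7)
    n <- 100L
    ids <- c(paste0("chr", sample(1:19, 90, TRUE), ":", 1:90 * 11),
             paste0("chrX:", 91:100 * 11))
    cov <- matrix(sample(c(40L, 100L, 400L), n * 8, TRUE,
                         prob = c(0.25, 0.25, 0.5)), n, 8)
    dimnames(cov) <- list(ids, paste0("s", 1:8))
    m <- matrix(50, n, 8, dimnames = dimnames(cov))
    groups <- rep(c("g1", "g2"), each = 4L)
    d <- DreamSet(m, cov, ids)

    expect_message(f <- filterSites(d, groups = groups), "keeping")
    # brute-force recount oracle
    keep <- logical(n)
    for (i in seq_len(n)) {
        auto <- !startsWith(ids[i], "chrX")
        ok <- TRUE
        for (g in c("g1", "g2")) {
            jj <- groups == g
            ok <- ok && sum(cov[i, jj] >= 100) >= ceiling(0.75 * sum(jj))
        }
        keep[i] <- auto && ok
    }
    expect_equal(nrow(f), sum(keep))
    expect_setequal(rownames(methPercent(f)), ids[keep])
    # sub-threshold cells masked, surviving cells untouched
    expect_true(all(is.na(methPercent(f)[readDepth(f) < 100])))
    expect_true(all(!is.na(methPercent(f)[readDepth(f) >= 100])))

    # inclusive boundary: depth exactly 100 everywhere keeps everything
    d2 <- toyDreamSet(matrix(50, 4, 4), coverage = 100L)
    expect_message(f2 <- filterSites(d2), "keeping 4/4")
    expect_equal(nrow(f2), 4L)

    # high-coverage chrX site still removed
    dX <- DreamSet(matrix(50, 1, 4,
                          dimnames = list("chrX:5", paste0("s", 1:4))),
                   matrix(10000L, 1, 4,
                          dimnames = list("chrX:5", paste0("s", 1:4))),
                   "chrX:5")
    expect_message(fX <- filterSites(dX), "keeping 0/1")
    expect_equal(nrow(fX), 0L)

    # idempotence
    ff <- suppressMessages(filterSites(f, groups = groups))
    expect_equal(methPercent(ff), methPercent(f))
    expect_equal(rownames(readDepth(ff)), rownames(readDepth(f)))
})
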