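test_that("UpSet pattern counts are exact", {
    o <- overlapSets(list(A = "a", B = "b"))
    expect_equal(o$patterns$count[o$patterns$pattern == "A"], 1L)
    expect_equal(o$patterns$count[o$patterns$pattern == "B"], 1L)
    expect_equal(o$patterns$count[o$patterns$pattern == "A&B"], 0L)

    # A subset of B: the A-only pattern is empty
    o2 <- overlapSets(list(A = c("x", "y"), B = c("x", "y", "z")))
    expect_equal(o2$patterns$count[o2$patterns$pattern == "A"], 0L)
    expect_equal(o2$patterns$count[o2$patterns$pattern == "A&B"], 2L)
    expect_equal(o2$sharedFraction["A", "B"], 1)
    expect_equal(o2$sharedFraction["B", "A"], 2 / 3)

    expect_error(overlapSets(list(A = "q"), universe = c("a", "b")),
                 "outside universe")
})

test_that("UpSet counts equal brute-force enumeration on random sets", {
    set.seed(19)
    u <- paste0("s", 1:400)
    sets <- list(M = sample(u, 120), I = sample(u, 90),
                 A = sample(u, 60))
    o <- overlapSets(sets, universe = u)
    # brute force: walk every element of the union
    union_ <- unique(unlist(sets))
    brute <- table(vapply(union_, function(e) {
        inn <- names(sets)[vapply(sets, function(s) e %in% s, TRUE)]
        paste(inn, collapse = "&")
    }, ""))
    for (i in seq_len(nrow(o$patterns))) {
        pat <- o$patterns$pattern[i]
        expected <- if (pat %in% names(brute)) unname(brute[pat]) else 0L
        expect_equal(o$patterns$count[i], as.integer(expected))
    }
    expect_equal(sum(o$patterns$count), length(union_))
})

test_that("drift concordance recovers identity, negation and known rho", {
    age <- data.frame(site_id = paste0("s", 1:50),
                      delta = seq(-20, 20, length.out = 50),
                      p = 0.001)
    keep <- abs(age$delta) >= 5
    idn <- driftScatter(age, age[, c("site_id", "delta")])
    expect_equal(idn$r, 1)
    expect_equal(idn$slope, 1)
    expect_equal(idn$n, sum(keep))
    neg <- driftScatter(age, data.frame(site_id = age$site_id,
                                        delta = -age$delta))
    expect_equal(neg$r, -1)

    # three-point closed form
    a3 <- data.frame(site_id = c("a", "b", "c"),
                     delta = c(6, 10, 20), p = 0.001)
    e3 <- data.frame(site_id = c("a", "b", "c"), delta = c(1, 5, 4))
    d3 <- driftScatter(a3, e3)
    x <- a3$delta; y <- e3$delta
    rHand <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(d3$r, rHand, tolerance = 1e-12)
    expect_equal(d3$slope,
                 sum((x - mean(x)) * (y - mean(y))) /
                     sum((x - mean(x))^2), tolerance = 1e-12)

    # too few paired sites -> undefined
    tiny <- driftScatter(a3[1:2, ], e3)
    expect_true(is.na(tiny$r))
    expect_equal(tiny$n, 2L)

    # bivariate-normal simulation recovers the planted correlation
    set.seed(6)
    n <- 2000L
    za <- rnorm(n); zb <- 0.4 * za + sqrt(1 - 0.16) * rnorm(n)
    sim <- driftScatter(
        data.frame(site_id = paste0("s", 1:n), delta = 10 + 4 * za,
                   p = 0.001),
        data.frame(site_id = paste0("s", 1:n), delta = 3 * zb),
        minAgeChange = 0)
    expect_lt(abs(sim$r - 0.4), 0.05)
})

test_that("enrichment odds ratios follow the Woolf construction", {
    u <- paste0("g", 1:1000)
    # independence-proportional table (20, 80, 180, 720)
    fac <- u[1:100]
    can <- u[c(1:20, 101:280)]
    e <- enrichmentOR(fac, can, u)
    expect_equal(c(e$a, e$b, e$c, e$d), c(20, 80, 180, 720))
    expect_equal(e$or, 1)

    # zero overlap cell: OR 0 with CI [0, 0]
    z <- enrichmentOR(u[1:50], u[51:100], u)
    expect_equal(z$or, 0)
    expect_equal(c(z$ciLow, z$ciHigh), c(0, 0))

    # hand-computed Woolf CI on (30, 70, 100, 1800)
    u2 <- paste0("h", 1:2000)
    f2 <- u2[1:100]
    c2 <- u2[c(1:30, 101:200)]
    e2 <- enrichmentOR(f2, c2, u2)
    expect_equal(c(e2$a, e2$b, e2$c, e2$d), c(30, 70, 100, 1800))
    orHand <- (30 * 1800) / (70 * 100)
    seHand <- sqrt(1 / 30 + 1 / 70 + 1 / 100 + 1 / 1800)
    expect_equal(e2$or, orHand, tolerance = 1e-12)
    expect_equal(e2$ciLow, exp(log(orHand) - 1.96 * seHand),
                 tolerance = 1e-12)
    expect_equal(e2$ciHigh, exp(log(orHand) + 1.96 * seHand),
                 tolerance = 1e-12)

    # OR unchanged when the two set roles are swapped
    sw <- enrichmentOR(c2, f2, u2)
    expect_equal(sw$or, e2$or)

    expect_error(enrichmentOR("x", "y", character(0)), "empty universe")

    tab <- enrichmentTable(list(age = list(hyper = f2,
                                           hypo = u2[301:320])),
                           list(hyper = c2, hypo = u2[311:340]), u2)
    expect_equal(nrow(tab), 2L)
    expect_equal(tab$q, p.adjust(tab$p, "BH"))
})

test_that("gene-level matching converts beta scale and drops unmatched", {
    pm <- data.frame(gene = c("g1", "g2", "g3"),
                     chrom = "chr1", strand = "+", tss = 1000L,
                     site_id = c("chr1:900", "chr1:950", "chr1:980"),
                     position = c(901L, 951L, 981L),
                     distance = c(99L, 49L, 19L),
                     representative = TRUE)
    deltas <- data.frame(site_id = c("chr1:900", "chr1:950"),
                         delta = c(7, -2))
    cancer <- data.frame(gene = c("g1", "g4"), beta_diff = 0.08)
    expect_silent(g <- geneConcordance(pm, deltas, cancer))
    expect_equal(g$gene, "g1")                   # g2 lacks cancer data,
    expect_equal(g$cancer_delta, 8.0)            # g3 lacks mouse delta
    expect_equal(g$mouse_delta, 7)
    expect_equal(unname(attr(g, "dropped")), c(1, 1))

    sets <- concordanceSets(g)
    expect_equal(sets$factorSets$hyper, "g1")
    expect_equal(sets$cancerSets$hyper, "g1")

    cancer2 <- rbind(cancer, data.frame(gene = "g1", beta_diff = -0.5))
    expect_warning(geneConcordance(pm, deltas, cancer2), "duplicate")
    expect_error(geneConcordance(pm, deltas,
                                 data.frame(gene = "g1",
                                            beta_diff = 8)),
                 "beta scale")

    # matched count equals the set intersection size on random tables
    set.seed(44)
    genes <- paste0("G", 1:300)
    pmr <- data.frame(gene = genes, chrom = "chr1", strand = "+",
                      tss = 1L, site_id = paste0("chr1:", 1:300),
                      position = 1:300, distance = 0L,
                      representative = TRUE)
    dl <- data.frame(site_id = paste0("chr1:", sample(300, 200)),
                     delta = rnorm(200))
    ct <- data.frame(gene = sample(genes, 150),
                     beta_diff = runif(150, -0.5, 0.5))
    gm <- geneConcordance(pmr, dl, ct)
    manual <- intersect(pmr$gene[pmr$site_id %in% dl$site_id], ct$gene)
    expect_setequal(gm$gene, manual)
})
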