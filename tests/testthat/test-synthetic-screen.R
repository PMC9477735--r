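test_that("genome layout obeys the configured geometry", {
    # forced layout: one gene, no intergenic space -> [0, 1000) on disk,
    # i.e. 1..1000 in R coordinates
    g1 <- simulateGenome(ScreenSimConfig(nGenes = 1, geneLength = 1000L,
                                         intergenicFraction = 0, seed = 3))
    expect_length(g1, 1L)
    expect_equal(BiocGenerics::start(g1), 1L)
    expect_equal(BiocGenerics::end(g1), 1000L)

    # determinism
    cfg <- ScreenSimConfig(nGenes = 100, seed = 7)
    expect_identical(simulateGenome(cfg), simulateGenome(cfg))

    # intergenic fraction 0.5 doubles the per-gene span; genes disjoint
    # (checked by brute-force pairwise interval comparison)
    cfg2 <- ScreenSimConfig(nGenes = 100, geneLength = 1000L,
                            intergenicFraction = 0.5, seed = 5)
    g <- simulateGenome(cfg2)
    starts <- BiocGenerics::start(g)
    ends <- BiocGenerics::end(g)
    expect_equal(diff(starts), rep(2000L, 99L))
    for (i in seq_len(length(g) - 1L))
        expect_true(all(starts[(i + 1):length(g)] > ends[i] |
                        ends[(i + 1):length(g)] < starts[i]))

    # multi-chromosome layout puts every gene on a declared chromosome
    cfg3 <- ScreenSimConfig(nGenes = 10, nChromosomes = 3, seed = 2)
    g3 <- simulateGenome(cfg3)
    expect_setequal(unique(as.character(GenomeInfoDb::seqnames(g3))),
                    c("chr1", "chr2", "chr3"))

    expect_error(ScreenSimConfig(nGenes = 0), "positive")
    expect_error(ScreenSimConfig(geneLength = 0L), "positive")
})

test_that("variable gene lengths are drawn from the configured range", {
    cfg <- ScreenSimConfig(nGenes = 200, geneLength = c(500L, 1500L),
                           intergenicFraction = 0, seed = 9)
    g <- simulateGenome(cfg)
    w <- BiocGenerics::width(g)
    expect_true(all(w >= 500 & w <= 1500))
    expect_gt(length(unique(w)), 10L)
})

test_that("screen simulation is reproducible and conserves cells", {
    cfg <- smallConfig(hitGenes = c(g0007 = "positive_regulator"),
                       penetrance = 0.5)
    s1 <- simulateScreen(cfg)
    s2 <- simulateScreen(cfg)
    expect_identical(insertions(s1, "high"), insertions(s2, "high"))
    expect_identical(insertions(s1, "low"), insertions(s2, "low"))
    expect_identical(annotation(s1), annotation(s2))
    expect_identical(screenTruth(s1), hitGenes(cfg))

    # sorting and recovery only remove cells
    expect_lte(length(insertions(s1, "high")) +
               length(insertions(s1, "low")), nCells(cfg))
    # each population is at most the sorted tail
    nSort <- floor(nCells(cfg) * sortFraction(cfg))
    expect_lte(length(insertions(s1, "high")), nSort)
    expect_lte(length(insertions(s1, "low")), nSort)

    expect_error(simulateScreen(smallConfig(nCells = 10L)),
                 "degenerate sort")
})

test_that("sorting everything with full recovery gives identical populations", {
    cfg <- smallConfig(nCells = 5000L, sortFraction = 1, recoveryRate = 1)
    s <- simulateScreen(cfg)
    high <- BiocGenerics::sort(insertions(s, "high"), ignore.strand = TRUE)
    low <- BiocGenerics::sort(insertions(s, "low"), ignore.strand = TRUE)
    expect_equal(length(high), nCells(cfg))
    expect_identical(GenomicRanges::granges(high),
                     GenomicRanges::granges(low))

    # and the per-gene mutation ratio over all genes is ~1
    tab <- contingenciesFromScreen(s)
    ratio <- mutationRatio(tab$a, tab$b, tab$c, tab$d)
    expect_true(all(abs(ratio - 1) < 1e-12))
})

test_that("a fully penetrant strong hit dominates the screen", {
    cfg <- ScreenSimConfig(nGenes = 100, geneLength = 5000L,
                           intergenicFraction = 0.5, nCells = 1e5L,
                           hitGenes = c(g0010 = "positive_regulator"),
                           penetrance = 1, effectLogShift = 6, seed = 21)
    res <- analyzeScreen(contingenciesFromScreen(simulateScreen(cfg)))
    expect_equal(res$gene_id[1L], "g0010")
    expect_lt(res$ratio[1L], 1)
    expect_equal(res$direction[1L], "positive_regulator")
    expect_lt(res$p_adj[1L], 1e-6)
})

test_that("a negative regulator enriches in the low-reporter tail's complement", {
    cfg <- ScreenSimConfig(nGenes = 100, geneLength = 5000L,
                           intergenicFraction = 0.5, nCells = 1e5L,
                           hitGenes = c(g0042 = "negative_regulator"),
                           penetrance = 1, effectLogShift = 6, seed = 22)
    res <- analyzeScreen(contingenciesFromScreen(simulateScreen(cfg)))
    expect_equal(res$gene_id[1L], "g0042")
    expect_gt(res$ratio[1L], 1)
    expect_equal(res$direction[1L], "negative_regulator")
})

test_that("hit significance does not weaken as penetrance grows", {
    pOfHit <- function(pen, seed) {
        cfg <- ScreenSimConfig(nGenes = 50, geneLength = 5000L,
                               intergenicFraction = 0.2, nCells = 3e4L,
                               hitGenes = c(g0005 = "positive_regulator"),
                               penetrance = pen, effectLogShift = 3,
                               seed = seed)
        res <- analyzeScreen(contingenciesFromScreen(simulateScreen(cfg)))
        res$p[res$gene_id == "g0005"]
    }
    seeds <- c(101, 202, 303)
    med <- vapply(c(0, 0.5, 1), function(pen)
        stats::median(vapply(seeds, function(s) pOfHit(pen, s),
                             numeric(1))), numeric(1))
    expect_true(med[2] <= med[1])
    expect_true(med[3] <= med[2])
})

test_that("deep null screens produce calibrated Fisher statistics", {
    # At ~200 unique sense insertions per gene the discreteness of the
    # exact test is negligible and the null P values are near-uniform.
    cfg <- ScreenSimConfig(nGenes = 200, geneLength = 10000L,
                           intergenicFraction = 0, nCells = 1e6L,
                           hitGenes = character(), penetrance = 0,
                           recoveryRate = 1, seed = 77)
    res <- analyzeScreen(contingenciesFromScreen(simulateScreen(cfg)))
    ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
    expect_gt(ks$p.value, 0.01)
    # no gene reaches screen-wide significance under the global null
    expect_equal(sum(res$p_adj < 0.05), 0L)
})

test_that("fixtures round-trip through the readers", {
    cfg <- smallConfig(nCells = 3000L,
                       hitGenes = c(g0002 = "negative_regulator"))
    s <- simulateScreen(cfg)
    dir <- withr::local_tempdir()
    paths <- writeFixture(s, dir)
    expect_true(all(file.exists(paths)))

    # compare record content (the readers do not know the simulated
    # chromosome lengths, so seqinfo legitimately differs)
    asRecords <- function(gr)
        data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   pos = BiocGenerics::start(gr),
                   end = BiocGenerics::end(gr),
                   strand = as.character(BiocGenerics::strand(gr)))
    high <- readInsertions(paths[["high"]], "high")
    expect_equal(asRecords(high), asRecords(insertions(s, "high")))
    low <- readInsertions(paths[["low"]], "low")
    expect_equal(asRecords(low), asRecords(insertions(s, "low")))

    ann <- readAnnotation(paths[["annotation"]])
    expect_equal(asRecords(ann), asRecords(annotation(s)))
    expect_identical(names(ann), names(annotation(s)))

    truth <- utils::read.table(paths[["truth"]], header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
    expect_equal(stats::setNames(truth$direction, truth$gene_id),
                 screenTruth(s))

    # n insertions written -> n data lines
    expect_equal(length(readLines(paths[["high"]])),
                 length(insertions(s, "high")))
})

test_that("an empty population writes a valid empty file", {
    cfg <- smallConfig(nCells = 3000L, recoveryRate = 1e-12)
    # recovery this low leaves (almost surely) empty populations
    s <- simulateScreen(cfg)
    expect_equal(length(insertions(s, "high")), 0L)
    dir <- withr::local_tempdir()
    paths <- writeFixture(s, dir)
    expect_true(file.exists(paths[["high"]]))
    expect_length(readInsertions(paths[["high"]], "high"), 0L)
})
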