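# Reading, writing and preprocessing of abundance tables.

test_that("QIIME-classic TSV reading handles counts, taxonomy and errors", {
    tf <- writeQiimeFixture(c(
        "# Constructed from biom file",
        "#OTU ID\ts1\ts2\ts3\ts4",
        "otu1\t1\t0\t3\t2",
        "otu2\t0\t5\t0\t1",
        "otu3\t2\t2\t2\t2"))
    x <- readAbundanceTable(tf)
    expect_s4_class(x, "AbundanceTable")
    expect_identical(dim(x), c(3L, 4L))
    expect_false(isRelative(x))
    expect_identical(organismLabels(x), c("otu1", "otu2", "otu3"))
    expect_identical(abundances(x)["otu2", "s2"], 5)

    # taxonomy column becomes the organism labels and is excluded from values
    tf2 <- writeQiimeFixture(c(
        "#OTU ID\ts1\ts2\ttaxonomy",
        "1\t1\t2\tk__Bacteria; g__Rothia",
        "2\t3\t4\tk__Bacteria; g__Neisseria"))
    x2 <- readAbundanceTable(tf2)
    expect_identical(organismLabels(x2),
                     c("k__Bacteria; g__Rothia", "k__Bacteria; g__Neisseria"))
    expect_identical(unname(abundances(x2)[, "s2"]), c(2, 4))

    expect_error(readAbundanceTable(writeQiimeFixture(c(
        "#OTU ID\ts1\ts2", "otu1\t1\t-2"))), "negative")
    expect_error(readAbundanceTable(writeQiimeFixture(c(
        "#OTU ID\ts1\ts2", "otu1\t1"))), "line 2")
    expect_error(readAbundanceTable(tempfile()), "not found")
})

test_that("TSV write/read round-trips the matrix bit-exactly", {
    set.seed(42)
    vals <- matrix(runif(12), 3, 4,
                   dimnames = list(paste0("o", 1:3), paste0("s", 1:4)))
    vals[1, 2] <- 0
    x <- AbundanceTable(vals)
    tf <- tempfile(fileext = ".tsv")
    writeAbundanceTable(x, tf)
    y <- readAbundanceTable(tf)
    expect_identical(abundances(y), abundances(x))

    # lineages survive through the taxonomy column
    xt <- AbundanceTable(vals, lineage = paste0("k__B; g__G", 1:3))
    writeAbundanceTable(xt, tf)
    yt <- readAbundanceTable(tf)
    expect_identical(organismLabels(yt), paste0("k__B; g__G", 1:3))
    expect_identical(unname(abundances(yt)), unname(abundances(xt)))
})

test_that("read-depth filter drops extreme samples with strict bounds", {
    x <- AbundanceTable(matrix(c(1500, 2500, 60000), 1,
                               dimnames = list("o1", c("low", "mid", "high"))))
    kept <- filterSamplesByDepth(x, 2000, 50000)
    expect_identical(sampleIds(kept), "mid")

    # totals exactly at the bounds are retained
    x2 <- AbundanceTable(matrix(c(2000, 50000, 30000), 1,
                                dimnames = list("o1", c("a", "b", "c"))))
    expect_identical(ncol(filterSamplesByDepth(x2, 2000, 50000)), 3L)
    expect_identical(ncol(filterSamplesByDepth(x2, 0, Inf)), 3L)

    rel <- normalizeRelative(x)
    expect_error(filterSamplesByDepth(rel, 2000, 50000), "relative")
})

test_that("relative-abundance normalization is columnwise and idempotent", {
    x <- AbundanceTable(matrix(c(2, 2, 0, 1, 3, 4), 3,
                               dimnames = list(paste0("o", 1:3), c("s1", "s2"))))
    r <- normalizeRelative(x)
    expect_true(isRelative(r))
    expect_equal(unname(abundances(r)[, "s1"]), c(0.5, 0.5, 0))
    r2 <- normalizeRelative(r)
    expect_equal(abundances(r2), abundances(r), tolerance = 1e-12)

    bad <- AbundanceTable(matrix(c(1, 0, 0, 0), 2,
                                 dimnames = list(c("o1", "o2"), c("ok", "empty"))))
    expect_error(normalizeRelative(bad), "empty")
})

test_that("taxonomy merge sums lineage groups and labels the lowest rank", {
    lin <- c("k__B; p__P1; c__C; o__O; f__F1; g__Rothia",
             "k__B; p__P1; c__C; o__O; f__F1; g__Rothia",
             "k__B; p__P1; c__C; o__O; f__F1; g__Kocuria",
             "k__B; p__P2; c__C2; o__O2; f__Lachnospiraceae; g__")
    vals <- matrix(c(0.1, 0.2,
                     0.3, 0.0,
                     0.2, 0.1,
                     0.4, 0.7), 4, 2, byrow = TRUE,
                   dimnames = list(paste0("otu", 1:4), c("s1", "s2")))
    x <- AbundanceTable(vals, lineage = lin)
    g <- mergeToLevel(x, "genus")
    expect_identical(nrow(g), 3L)
    expect_equal(unname(abundances(g)["[G] Rothia", ]), c(0.4, 0.2))
    # OTU resolved only to family keeps the bracketed family label
    expect_true("[F] Lachnospiraceae" %in% organismLabels(g))
    # column totals are conserved
    expect_equal(colSums(abundances(g)), colSums(abundances(x)))

    # lineages distinct at the target level merge nothing
    expect_identical(nrow(mergeToLevel(x[1:3, ], "genus")), 2L)
    expect_identical(nrow(mergeToLevel(x[c(1, 3), ], "genus")), 2L)

    expect_error(mergeToLevel(AbundanceTable(
        matrix(1, 1, 1, dimnames = list("", "s1")))), "lineage")
})

test_that("prevalence filter removes organisms below the strict cutoff", {
    n <- 100
    vals <- rbind(rare = c(rep(1, 4), rep(0, n - 4)),
                  edge = c(rep(1, 5), rep(0, n - 5)),
                  common = rep(1, n))
    colnames(vals) <- paste0("s", seq_len(n))
    x <- AbundanceTable(vals)
    f <- filterPrevalence(x, 0.05)
    expect_identical(organismLabels(f), c("edge", "common"))  # 5% retained
    expect_identical(organismLabels(filterPrevalence(x, 0)),
                     organismLabels(x))
    # surviving row order preserved
    expect_identical(organismLabels(filterPrevalence(x, 0.04)),
                     c("rare", "edge", "common"))
})

test_that("AbundanceTable validity enforces the container invariants", {
    expect_error(AbundanceTable(matrix(-1, 1, 1)), "non-negative")
    expect_error(AbundanceTable(matrix(1, 2, 1,
        dimnames = list(c("a", "a"), "s1"))), "unique")
    expect_error(AbundanceTable(matrix(c(0.5, 0.4), 2, 1,
        dimnames = list(c("a", "b"), "s1")), isRelative = TRUE), "sum to 1")
})
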