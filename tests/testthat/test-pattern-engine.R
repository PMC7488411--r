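# Partition counting, the pattern catalog, constrained scoring, and
# threshold maximization.

test_that("candidate thresholds are the sorted unique observed values", {
    expect_identical(candidateThresholds(c(0, 0, 0.2, 0.5, 0.2)),
                     c(0, 0.2, 0.5))
    expect_identical(candidateThresholds(c(0.1, 0.1)), 0.1)
    expect_identical(candidateThresholds(0.3), 0.3)
})

test_that("partition counting assigns samples to presence/absence cells", {
    pc <- partitionCounts(rbind(c(0, 0, 1, 1), c(0, 0, 1, 1)), c(0, 0))
    expect_equal(cellFractions(pc),
                 c("00" = 0.5, "01" = 0, "10" = 0, "11" = 0.5))
    pc2 <- partitionCounts(rbind(c(0, 2, 0, 2), c(3, 0, 3, 0)), c(0, 0))
    expect_equal(cellFractions(pc2),
                 c("00" = 0, "01" = 0.5, "10" = 0.5, "11" = 0))
    # thresholds at the maxima leave every observation absent
    x <- rbind(runif(10), runif(10), runif(10))
    pc3 <- partitionCounts(x, apply(x, 1, max))
    expect_equal(unname(cellFractions(pc3)[["000"]]), 1)
    expect_error(partitionCounts(list(1:3, 1:4), c(0, 0)), "same length")
    expect_error(partitionCounts(rbind(1:4, 1:4), 0), "one threshold per organism")
})

test_that("the pattern catalog matches the interpretable cell sets", {
    cat2 <- patternCatalog(2)
    expect_length(cat2, 4L)
    expect_setequal(includedCells(cat2[["co-presence"]]), c("00", "11"))
    expect_setequal(constrainedCells(cat2[["co-presence"]]), c("00", "11"))
    expect_setequal(includedCells(cat2[["co-exclusion"]]), c("00", "10", "01"))
    expect_setequal(constrainedCells(cat2[["co-exclusion"]]), c("10", "01"))
    expect_setequal(includedCells(cat2[["one-way(2|1)"]]), c("00", "10", "11"))
    expect_setequal(constrainedCells(cat2[["one-way(2|1)"]]), c("10", "11"))

    cat3 <- patternCatalog(3)
    cellsets <- unique(lapply(cat3, function(s) sort(includedCells(s))))
    expect_length(cellsets, 5L)  # pattern A and 3D one-way share one set
    expect_setequal(includedCells(cat3[["pattern A / 3D one-way"]]),
                    c("000", "111", "010", "001"))
    expect_setequal(includedCells(cat3[["3D co-exclusion type 2"]]),
                    c("000", "110", "101", "011"))
    expect_setequal(includedCells(cat3[["all-together-or-alone"]]),
                    c("000", "111", "001", "010", "100"))

    cat4 <- patternCatalog(4)
    expect_setequal(includedCells(cat4[["4D one-way"]]),
                    c("0000", "1111", "0001", "0010", "0100"))
    # every pattern scores the all-absent cell: co-absence never contradicts
    for (spec in c(cat2, cat3, cat4)) {
        k <- specDimension(spec)
        expect_true(strrep("0", k) %in% includedCells(spec))
        expect_true(all(constrainedCells(spec) %in% includedCells(spec)))
    }
    expect_error(patternCatalog(5), "unsupported")
})

test_that("constrained scores sum included cells and gate on m", {
    cat3 <- patternCatalog(3)
    octants <- c("000" = 0.48, "001" = 0.12, "010" = 0.18, "011" = 0.05,
                 "100" = 0, "101" = 0, "110" = 0.02, "111" = 0.16)
    expect_equal(scoreFromCounts(octants, cat3[["pattern A / 3D one-way"]],
                                 m = 0.1), 0.94)
    # degenerate all-absent guard: perfect p00 alone is not co-presence
    cat2 <- patternCatalog(2)
    expect_true(is.na(scoreFromCounts(c("00" = 1, "01" = 0, "10" = 0, "11" = 0),
                                      cat2[["co-presence"]], m = 0.05)))
    expect_equal(scoreFromCounts(c("00" = 0.4, "01" = 0.3, "10" = 0.3,
                                   "11" = 0),
                                 cat2[["co-exclusion"]], m = 0.1), 1.0)
    # the constraint is strict: a fraction equal to m fails, tol loosens it
    expect_true(is.na(scoreFromCounts(c("00" = 0.9, "01" = 0, "10" = 0,
                                        "11" = 0.1),
                                      cat2[["co-presence"]], m = 0.1)))
    expect_equal(scoreFromCounts(c("00" = 0.9, "01" = 0, "10" = 0, "11" = 0.1),
                                 cat2[["co-presence"]], m = 0.1, tol = 0.005),
                 1.0)
    expect_error(scoreFromCounts(octants, cat2[["co-presence"]], 0.1),
                 "dimension mismatch")
})

test_that("threshold maximization finds the exact optimum", {
    cat2 <- patternCatalog(2)
    x1 <- c(0, 0, 0, 0, 5, 6, 7, 8)
    x2 <- c(0, 0, 0, 0, 3, 4, 5, 6)
    h <- bestScore(rbind(x1, x2), cat2[["co-presence"]], m = 0.25)
    expect_equal(patternScore(h), 1.0)
    expect_equal(thresholds(h), c(0, 0))

    # 5 samples (0,0), 4 (1,1), 1 discordant (1,0): maximum is 0.9
    X1 <- c(0, 0, 0, 0, 0, 1, 2, 3, 4, 5)
    X2 <- c(0, 0, 0, 0, 0, 1, 2, 3, 4, 0)
    h2 <- bestScore(rbind(X1, X2), cat2[["co-presence"]], m = 0.2)
    expect_equal(patternScore(h2), 0.9)
    o <- oracleBestScore(rbind(X1, X2), c("00", "11"), c("00", "11"), 0.2)
    expect_equal(patternScore(h2), o$score)
    expect_equal(thresholds(h2), o$epsilons)

    # constant profiles admit no valid binarization
    expect_null(bestScore(rbind(rep(0.1, 10), rep(0.1, 10)),
                          cat2[["co-presence"]], m = 0.05))
    # hit score equals the sum of its included cell fractions
    expect_equal(patternScore(h2),
                 sum(cellFractions(h2@counts)[includedCells(cat2[["co-presence"]])]))
})

test_that("best scores are invariant under organism swap and monotone maps", {
    set.seed(101)
    cat2 <- patternCatalog(2)
    for (rep in 1:5) {
        p <- randomProfiles(2, 16)
        for (nm in c("co-presence", "co-exclusion")) {
            h12 <- bestScore(p, cat2[[nm]], 0.1)
            h21 <- bestScore(p[2:1, ], cat2[[nm]], 0.1)
            expect_equal(is.null(h12), is.null(h21))
            if (!is.null(h12)) expect_equal(patternScore(h12),
                                            patternScore(h21))
        }
        # one-way(2|1) on (X1, X2) equals one-way(1|2) on (X2, X1)
        a <- bestScore(p, cat2[["one-way(2|1)"]], 0.1)
        b <- bestScore(p[2:1, ], cat2[["one-way(1|2)"]], 0.1)
        expect_equal(is.null(a), is.null(b))
        if (!is.null(a)) expect_equal(patternScore(a), patternScore(b))
        # strictly increasing transforms leave every binarization unchanged
        q <- p; q[1, ] <- exp(q[1, ]); q[2, ] <- q[2, ]^3
        for (nm in names(cat2)) {
            h <- bestScore(p, cat2[[nm]], 0.1)
            ht <- bestScore(q, cat2[[nm]], 0.1)
            expect_equal(is.null(h), is.null(ht))
            if (!is.null(h)) expect_equal(patternScore(h), patternScore(ht))
        }
    }
})

test_that("best score is non-increasing in the population threshold m", {
    set.seed(202)
    specs <- c(patternCatalog(2), patternCatalog(3))
    for (rep in 1:5) {
        for (spec in specs) {
            p <- randomProfiles(specDimension(spec), 20)
            ms <- c(0, 0.05, 0.1, 0.2, 0.3)
            sc <- vapply(ms, function(m) {
                h <- bestScore(p, spec, m)
                if (is.null(h)) -Inf else patternScore(h)
            }, numeric(1))
            # NaN diffs arise only from consecutive invalid (-Inf) scores
            expect_true(all(diff(sc) <= 1e-12 | is.nan(diff(sc))))
        }
    }
})

test_that("scanning recovers planted patterns and respects the score gate", {
    x <- AbundanceTable(rbind(org1 = c(0, 2, 0, 2, 0, 2),
                              org2 = c(3, 0, 3, 0, 3, 0)))
    hits <- scanPatterns(x, 2, m = 0.1, sMin = 0.9)
    expect_length(hits, 1L)
    expect_identical(hits[[1]]@specName, "co-exclusion")
    expect_equal(patternScore(hits[[1]]), 1.0)
    expect_length(scanPatterns(x, 2, m = 0.1, sMin = 1.0), 1L)
    # an unreachable gate returns nothing
    x2 <- AbundanceTable(rbind(org1 = c(0, 2, 0, 2, 2, 2),
                               org2 = c(3, 0, 3, 0, 3, 3)))
    expect_length(scanPatterns(x2, 2,
                               specs = patternCatalog(2)["co-exclusion"],
                               m = 0.1, sMin = 0.99), 0L)

    # three organisms occupying cells 000/111/010/001: pattern A, with the
    # conditioning organism first, and no 3D co-presence at the same gate
    x3 <- tableFromCells(c("000" = 3, "111" = 3, "010" = 3, "001" = 3))
    hits3 <- scanPatterns(x3, 3, m = 0.1, sMin = 0.9)
    expect_length(hits3, 1L)
    expect_identical(hits3[[1]]@specName, "pattern A / 3D one-way")
    expect_identical(hitOrganisms(hits3[[1]]), c("org1", "org2", "org3"))
    expect_equal(patternScore(hits3[[1]]), 1.0)
})

test_that("a 3D type-1 co-exclusion induces all three 2D co-exclusions", {
    x <- tableFromCells(c("000" = 3, "100" = 3, "010" = 3, "001" = 3))
    hits3 <- scanPatterns(x, 3, m = 0.1, sMin = 1.0)
    expect_true("3D co-exclusion type 1" %in%
                    vapply(hits3, function(h) h@specName, character(1)))
    hits2 <- scanPatterns(x, 2, specs = patternCatalog(2)["co-exclusion"],
                          m = 0.1, sMin = 1.0)
    expect_length(hits2, 3L)  # every pair co-excludes
})

test_that("hit tables carry organisms, thresholds, cell fractions, score", {
    x <- tableFromCells(c("00" = 3, "11" = 3))
    hits <- scanPatterns(x, 2, m = 0.1, sMin = 0.9)
    tab <- hitsTable(hits)
    expect_true(all(c("organism1", "organism2", "pattern", "epsilon1",
                      "epsilon2", "p00", "p01", "p10", "p11", "score",
                      "m", "s_min") %in% colnames(tab)))
    expect_equal(tab$p00 + tab$p01 + tab$p10 + tab$p11,
                 rep(1, nrow(tab)))
    tf <- tempfile(fileext = ".tsv")
    writeHits(hits, tf)
    back <- read.delim(tf, check.names = FALSE)
    expect_identical(nrow(back), nrow(tab))
})
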