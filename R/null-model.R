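# Shuffle-based zero-type-1-error gating. Pattern reporting on real data is
# restricted to (population threshold m, minimal score S_min) combinations at
# which shuffled data contain zero patterns, so any reported pattern has, by
# construction, no counterpart in the null.

#' Shuffle abundance profiles
#'
#' The default null model permutes each organism's profile independently
#' across samples, preserving every organism's abundance-value distribution
#' (some organisms are always rare, others dominant) while destroying
#' between-organism structure; relative tables are then renormalized per
#' sample so columns again sum to 1. The alternative \code{"dataset"} model
#' shuffles all values jointly across the whole matrix.
#'
#' @param x an \linkS4class{AbundanceTable}.
#' @param seed integer seed; the same seed reproduces the same shuffle.
#' @param mode \code{"profile"} (default) or \code{"dataset"}.
#' @return a shuffled \linkS4class{AbundanceTable}.
#' @export
shuffleProfiles <- function(x, seed = NULL, mode = c("profile", "dataset")) {
    stopifnot(is(x, "AbundanceTable"))
    mode <- match.arg(mode)
    a <- abundances(x)
    out <- .withSeed(seed, {
        if (mode == "profile") {
            t(apply(a, 1L, function(r) r[sample.int(length(r))]))
        } else {
            matrix(a[sample.int(length(a))], nrow(a), ncol(a))
        }
    })
    if (ncol(a) == 1L) out <- matrix(out, nrow = nrow(a))
    rel <- isRelative(x)
    if (rel) {
        cs <- colSums(out)
        if (any(cs == 0)) {
            # a renormalizable relative table cannot contain empty samples;
            # fall back to an unnormalized shuffle in this degenerate case
            rel <- FALSE
        } else {
            out <- sweep(out, 2L, cs, "/")
        }
    }
    AbundanceTable(out, organismLabels = organismLabels(x),
                   sampleIds = sampleIds(x), isRelative = rel,
                   lineage = rowData(x)$lineage)
}

#' Feasibility grid over (m, S_min) from shuffled data
#'
#' Scans shuffled copies of the table for every population threshold m in
#' \code{mGrid} and counts, for each minimal score in \code{sGrid}, how many
#' patterns survive. Grid cells where the count is zero in every shuffle are
#' feasible: scanning real data only at feasible cells guarantees that the
#' identical scan of the shuffled data returns nothing.
#'
#' @param x an \linkS4class{AbundanceTable}.
#' @param dimension tuple size k.
#' @param specs pattern specs; defaults to the catalog for \code{dimension}.
#' @param mGrid population thresholds; default 0.05 to 0.35 in steps of
#'   0.025 (13 values).
#' @param sGrid minimal scores; default 0.90 to 0.99 in steps of 0.01
#'   plus 1 (11 values).
#' @param nShuffles number of independent shuffles (counts are summed; more
#'   shuffles can only shrink the feasible region).
#' @param seed integer seed for the shuffles.
#' @return a \linkS4class{FeasibilityGrid}.
#' @export
feasibilityGrid <- function(x, dimension = 2,
                            specs = patternCatalog(dimension),
                            mGrid = defaultMGrid(),
                            sGrid = defaultSMinGrid(),
                            nShuffles = 1, seed = NULL) {
    stopifnot(is(x, "AbundanceTable"), length(mGrid) >= 1L,
              length(sGrid) >= 1L, nShuffles >= 1L)
    mGrid <- sort(mGrid)
    sGrid <- sort(sGrid)
    k <- as.integer(dimension)
    counts <- matrix(0L, length(mGrid), length(sGrid),
                     dimnames = list(m = format(mGrid), s_min = format(sGrid)))
    for (b in seq_len(nShuffles)) {
        shufSeed <- if (is.null(seed)) NULL else seed + b - 1L
        shuf <- shuffleProfiles(x, seed = shufSeed)
        counts <- counts + .gridCounts(shuf, k, specs, mGrid, sGrid)
    }
    new("FeasibilityGrid", mValues = mGrid, sMinValues = sGrid,
        shuffledCounts = counts, feasible = counts == 0L,
        nShuffles = as.integer(nShuffles), dimension = k)
}

# Pattern counts for every (m, S_min) cell on one table: each tuple/spec/
# orientation contributes its best valid score per m in a single
# enumeration pass, then scores are thresholded against the S_min axis.
.gridCounts <- function(x, k, specs, mGrid, sGrid) {
    specs <- .dedupeSpecs(specs)
    orients <- lapply(specs, .orientationPerms)
    a <- abundances(x)
    counts <- matrix(0L, length(mGrid), length(sGrid))
    if (nrow(a) < k) return(counts)
    combos <- utils::combn(nrow(a), k)
    for (ci in seq_len(ncol(combos))) {
        tuple <- combos[, ci]
        for (si in seq_along(specs)) {
            for (p in orients[[si]]) {
                sByM <- bestScoreByM(a[tuple[p], , drop = FALSE],
                                     specs[[si]], mGrid)
                hit <- outer(sByM, sGrid, function(s, thr) !is.na(s) & s >= thr)
                counts <- counts + hit
            }
        }
    }
    counts
}

#' Default population-threshold grid (0.05 to 0.35, step 0.025)
#' @return numeric vector of 13 values.
#' @export
defaultMGrid <- function() seq(0.05, 0.35, by = 0.025)

#' Default minimal-score grid (0.90 to 0.99 step 0.01, plus 1)
#' @return numeric vector of 11 values.
#' @export
defaultSMinGrid <- function() c(seq(0.90, 0.99, by = 0.01), 1)

#' Scan real data restricted to the feasible grid cells
#'
#' Runs the pattern scan only at (m, S_min) combinations that are feasible
#' in \code{grid} (zero shuffled patterns). Each (organism tuple, pattern,
#' role assignment) is reported once, annotated with the least stringent
#' feasible cell at which it passes: smallest m first, then smallest S_min.
#'
#' @param x the real (unshuffled) \linkS4class{AbundanceTable}; \code{grid}
#'   should have been computed on a shuffle of the same table.
#' @param grid a \linkS4class{FeasibilityGrid}.
#' @param specs pattern specs matching those used for the grid.
#' @return list of \linkS4class{PatternHit} objects with \code{m} and
#'   \code{sMin} set to the annotating cell. Empty, with a warning, when no
#'   grid cell is feasible.
#' @export
significantPatterns <- function(x, grid,
                                specs = patternCatalog(grid@dimension)) {
    stopifnot(is(x, "AbundanceTable"), is(grid, "FeasibilityGrid"))
    feas <- grid@feasible
    if (!any(feas)) {
        warning("no (m, S_min) combination is free of shuffled patterns; ",
                "nothing can be reported at zero type-1 error")
        return(list())
    }
    out <- list()
    seen <- character(0)
    for (mi in seq_along(grid@mValues)) {
        sIdx <- which(feas[mi, ])
        if (!length(sIdx)) next
        mVal <- grid@mValues[mi]
        sFeas <- grid@sMinValues[sIdx]
        hits <- scanPatterns(x, dimension = grid@dimension, specs = specs,
                             m = mVal, sMin = min(sFeas))
        for (h in hits) {
            key <- paste(c(h@organisms, h@specName), collapse = "\r")
            if (key %in% seen) next
            pass <- sFeas[sFeas <= h@score]
            if (!length(pass)) next
            seen <- c(seen, key)
            h@m <- mVal
            h@sMin <- min(pass)
            out[[length(out) + 1L]] <- h
        }
    }
    out
}

#' Write a feasibility grid as TSV
#'
#' Rows are population thresholds m, columns minimal scores S_min, cells
#' \code{"real/shuffled"} pattern counts when real-data counts are supplied
#' (otherwise just the shuffled counts).
#'
#' @param grid a \linkS4class{FeasibilityGrid}.
#' @param path output file.
#' @param realCounts optional matrix of real-data counts with the grid's
#'   shape.
#' @return \code{path}, invisibly.
#' @export
writeGrid <- function(grid, path, realCounts = NULL) {
    sc <- grid@shuffledCounts
    cells <- if (is.null(realCounts)) {
        matrix(as.character(sc), nrow(sc))
    } else {
        stopifnot(identical(dim(realCounts), dim(sc)))
        matrix(paste0(realCounts, "/", sc), nrow(sc))
    }
    df <- data.frame(m = grid@mValues, cells, check.names = FALSE)
    colnames(df) <- c("m", format(grid@sMinValues))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
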