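# Core pattern-specific scoring machinery: candidate presence thresholds,
# presence/absence partition counting, the interpretable pattern catalog,
# constrained score evaluation, and exhaustive maximization over thresholds.

#' Candidate presence/absence thresholds for one abundance profile
#'
#' Presence is strict (\code{abundance > epsilon}), so any threshold between
#' two consecutive observed values yields the same binarization as the lower
#' value; the sorted unique observed values are therefore the complete,
#' finite search space for the threshold maximization.
#'
#' @param profile numeric abundance vector.
#' @return sorted unique values of \code{profile}.
#' @examples
#' candidateThresholds(c(0, 0, 0.2, 0.5, 0.2))
#' @export
candidateThresholds <- function(profile) {
    stopifnot(is.numeric(profile), length(profile) >= 1L)
    sort(unique(profile))
}

#' Tabulate presence/absence partition fractions
#'
#' Each sample is assigned to the cell \code{(1[X1 > eps1], ..., 1[Xk > epsk])};
#' fractions are cell counts divided by the number of samples.
#'
#' @param profiles k abundance vectors over the same samples: a numeric
#'   matrix with k rows, or a list of k equal-length vectors.
#' @param epsilons numeric vector of k presence thresholds.
#' @return a \linkS4class{PartitionCounts}.
#' @examples
#' partitionCounts(rbind(c(0, 2, 0, 2), c(3, 0, 3, 0)), c(0, 0))
#' @export
partitionCounts <- function(profiles, epsilons) {
    profiles <- .asProfileMatrix(profiles)
    k <- nrow(profiles)
    if (length(epsilons) != k)
        stop("need one threshold per organism: got ", length(epsilons),
             " thresholds for ", k, " profiles")
    n <- ncol(profiles)
    w <- 2^(k - seq_len(k))
    idx <- 1L + as.integer(colSums((profiles > epsilons) * w))
    f <- tabulate(idx, nbins = 2L^k) / n
    names(f) <- cellNames(k)
    new("PartitionCounts", fractions = f, nSamples = as.integer(n))
}

#' The interpretable Boolean pattern catalog
#'
#' Returns the named patterns for a tuple dimension. Cell bit order matches
#' organism order (bit 1 = organism 1); for one-way relations organism 1 is
#' the provider. The 3D "pattern A" (two organisms co-present when a third
#' is present and co-excluded when it is absent) shares its cell set with
#' the 3D one-way relation (organism 1 requires two others), so the catalog
#' carries it once with a dual interpretation.
#'
#' @param dimension 2, 3 or 4.
#' @return named list of \linkS4class{PatternSpec} objects.
#' @examples
#' names(patternCatalog(3))
#' @export
patternCatalog <- function(dimension) {
    dimension <- as.integer(dimension)
    specs <- switch(as.character(dimension),
        "2" = list(
            PatternSpec("co-presence", 2L, c("00", "11"), c("00", "11"),
                "both organisms present or absent together"),
            PatternSpec("co-exclusion", 2L, c("00", "10", "01"),
                c("10", "01"),
                "the organisms are never present together"),
            PatternSpec("one-way(2|1)", 2L, c("00", "10", "11"),
                c("10", "11"),
                "organism 2 (dependent) present only when organism 1 (provider) is present"),
            PatternSpec("one-way(1|2)", 2L, c("00", "01", "11"),
                c("01", "11"),
                "organism 1 (dependent) present only when organism 2 (provider) is present")
        ),
        "3" = list(
            PatternSpec("3D co-exclusion type 1", 3L,
                c("000", "100", "010", "001"), c("100", "010", "001"),
                "at most one of the three organisms present at a time"),
            PatternSpec("3D co-exclusion type 2", 3L,
                c("000", "110", "101", "011"), c("110", "101", "011"),
                "each pair co-present only when the third organism is absent"),
            PatternSpec("3D co-presence", 3L, c("000", "111"),
                c("000", "111"),
                "all three organisms present or absent together"),
            PatternSpec("pattern A / 3D one-way", 3L,
                c("000", "111", "010", "001"), c("111", "010", "001"),
                paste("organisms 2 and 3 co-present when organism 1 is present,",
                      "co-excluded when it is absent; equivalently organism 1",
                      "requires organisms 2 and 3 to be present")),
            PatternSpec("all-together-or-alone", 3L,
                c("000", "111", "001", "010", "100"),
                c("111", "100", "010", "001"),
                "the three organisms present only all together or individually")
        ),
        "4" = list(
            PatternSpec("4D co-presence", 4L, c("0000", "1111"),
                c("0000", "1111"),
                "all four organisms present or absent together"),
            PatternSpec("4D one-way", 4L,
                c("0000", "1111", "0001", "0010", "0100"),
                c("1111", "0001", "0010", "0100"),
                "organism 1 requires the three other organisms to be present")
        ),
        stop("unsupported pattern dimension: ", dimension,
             " (the catalog covers k = 2, 3, 4)")
    )
    names(specs) <- vapply(specs, specName, character(1))
    specs
}

#' Constrained pattern score from partition fractions
#'
#' The score is the sum of the fractions in the pattern's included cells,
#' valid only when every constrained cell fraction exceeds the population
#' threshold m (the guard against degenerate optima in which raising the
#' presence threshold empties the data into the all-absent cell). Invalid
#' configurations return \code{NA}.
#'
#' @param counts a \linkS4class{PartitionCounts}, or a numeric vector of
#'   cell fractions named by \code{\link{cellNames}} for externally
#'   tabulated proportions (which, at finite printed precision, need not
#'   divide an integer count).
#' @param spec a \linkS4class{PatternSpec} of the same dimension.
#' @param m population threshold in [0, 1).
#' @param tol constraint slack for finite-precision fractions: the
#'   requirement becomes \code{p > m - tol}. Defaults to 0 (strict). Set it
#'   to half the last reported digit when scoring rounded published
#'   proportions.
#' @return the score in [0, 1], or \code{NA} when a constraint fails.
#' @examples
#' ct <- partitionCounts(rbind(c(0, 2, 0, 2), c(3, 0, 3, 0)), c(0, 0))
#' scoreFromCounts(ct, patternCatalog(2)[["co-exclusion"]], m = 0.1)
#' @export
setGeneric("scoreFromCounts", function(counts, spec, m, tol = 0)
    standardGeneric("scoreFromCounts"))

#' @rdname scoreFromCounts
#' @export
setMethod("scoreFromCounts", "PartitionCounts", function(counts, spec, m,
                                                         tol = 0) {
    scoreFromCounts(counts@fractions, spec, m, tol)
})

#' @rdname scoreFromCounts
#' @export
setMethod("scoreFromCounts", "numeric", function(counts, spec, m, tol = 0) {
    stopifnot(is(spec, "PatternSpec"), m >= 0, m < 1)
    cells <- cellNames(spec@dimension)
    if (length(counts) != length(cells))
        stop("dimension mismatch: expected ", length(cells), " cells, got ",
             length(counts))
    if (is.null(names(counts)) || !all(cells %in% names(counts)))
        stop("cell fractions must be named by cellNames(", spec@dimension, ")")
    if (any(counts[spec@constrainedCells] <= m - tol))
        return(NA_real_)
    unname(sum(counts[spec@includedCells]))
})

# Automorphisms of a spec: role permutations leaving both cell sets fixed.
.specAutomorphisms <- function(spec) {
    k <- spec@dimension
    perms <- .permutations(k)
    keep <- apply(perms, 1L, function(g) {
        setequal(.permuteCells(spec@includedCells, g), spec@includedCells) &&
            setequal(.permuteCells(spec@constrainedCells, g),
                     spec@constrainedCells)
    })
    perms[keep, , drop = FALSE]
}

# Distinct role assignments (organism orderings) for a spec on an unordered
# k-tuple: one representative per coset of the automorphism group, so a
# fully symmetric pattern is evaluated once and pattern A three times (each
# organism as the conditioning one). Representatives are returned in
# lexicographic order with the identity first.
.orientationPerms <- function(spec) {
    k <- spec@dimension
    perms <- .permutations(k)
    aut <- .specAutomorphisms(spec)
    seen <- character(0)
    reps <- list()
    for (i in seq_len(nrow(perms))) {
        p <- perms[i, ]
        keys <- apply(aut, 1L, function(g) paste(p[g], collapse = ","))
        if (any(keys %in% seen)) next
        seen <- c(seen, keys)
        reps[[length(reps) + 1L]] <- p
    }
    reps
}

# Drop specs whose cell sets are a role-permutation image of an earlier
# spec (e.g. the mirrored one-way orientation): orientation enumeration in
# the scan recovers the dropped direction.
.dedupeSpecs <- function(specs) {
    canon <- vapply(specs, function(s) {
        perms <- .permutations(s@dimension)
        keys <- apply(perms, 1L, function(g) {
            paste(paste(sort(.permuteCells(s@includedCells, g)), collapse = "|"),
                  paste(sort(.permuteCells(s@constrainedCells, g)), collapse = "|"),
                  sep = "//")
        })
        min(keys)
    }, character(1))
    specs[!duplicated(canon)]
}

# Exhaustive maximization engine. Iterates threshold assignments in
# lexicographic order over per-organism candidate lists, carrying prefix
# cell-weight sums so each assignment costs one tabulate() over samples.
# mode "best": track the maximizing assignment for a single m (first
#   maximum wins, i.e. the lexicographically smallest epsilon vector).
# mode "allm": return the best valid score for every value of an m grid in
#   the same single pass (no epsilon bookkeeping).
.enumerateThresholds <- function(profiles, spec, m, mode = "best") {
    profiles <- .asProfileMatrix(profiles)
    k <- nrow(profiles)
    if (k != spec@dimension)
        stop("spec dimension ", spec@dimension, " does not match ",
             k, " profiles")
    n <- ncol(profiles)
    cells <- cellNames(k)
    inc <- match(spec@includedCells, cells)
    con <- match(spec@constrainedCells, cells)
    cands <- lapply(seq_len(k), function(i) candidateThresholds(profiles[i, ]))
    w <- 2^(k - seq_len(k))
    # presence[[i]] is a U_i x n logical matrix, row j = (X_i > cands[[i]][j])
    presence <- lapply(seq_len(k), function(i)
        outer(cands[[i]], profiles[i, ], function(e, x) x > e))
    nbins <- 2L^k
    if (mode == "allm") {
        best <- rep(NA_real_, length(m))
    } else {
        best <- NA_real_
        bestEps <- NULL
        bestFrac <- NULL
    }
    idx_stack <- integer(k)  # current candidate index per organism
    recurse <- function(depth, acc) {
        Ui <- length(cands[[depth]])
        for (j in seq_len(Ui)) {
            idx_stack[depth] <<- j
            acc2 <- acc + w[depth] * presence[[depth]][j, ]
            if (depth < k) {
                recurse(depth + 1L, acc2)
            } else {
                f <- tabulate(acc2 + 1L, nbins = nbins) / n
                cmin <- min(f[con])
                s <- sum(f[inc])
                if (mode == "allm") {
                    ok <- cmin > m
                    if (any(ok)) {
                        cur <- best[ok]
                        upd <- is.na(cur) | s > cur
                        if (any(upd)) {
                            cur[upd] <- s
                            best[ok] <<- cur
                        }
                    }
                } else if (cmin > m && (is.na(best) || s > best + 1e-12)) {
                    # strict improvement beyond float noise: true score gaps
                    # are multiples of 1/n, so ties keep the first (lexico-
                    # graphically smallest) threshold assignment
                    best <<- s
                    bestEps <<- vapply(seq_len(k), function(i)
                        cands[[i]][idx_stack[i]], numeric(1))
                    bestFrac <<- f
                }
            }
        }
    }
    recurse(1L, numeric(n))
    if (mode == "allm") return(best)
    if (is.na(best)) return(NULL)
    names(bestFrac) <- cells
    list(score = best, epsilons = bestEps,
         counts = new("PartitionCounts", fractions = bestFrac,
                      nSamples = as.integer(n)))
}

#' Maximize a pattern score over presence thresholds
#'
#' Exhaustively evaluates \code{\link{scoreFromCounts}} over the Cartesian
#' product of \code{\link{candidateThresholds}} for each profile and returns
#' the maximizing hit. Ties are broken by the lexicographically smallest
#' threshold vector (the most inclusive presence calls).
#'
#' @param profiles k abundance vectors (matrix rows or list), organism i in
#'   role i of \code{spec}.
#' @param spec a \linkS4class{PatternSpec}.
#' @param m population threshold in [0, 1).
#' @param organisms optional organism labels recorded in the hit.
#' @return a \linkS4class{PatternHit}, or \code{NULL} when every threshold
#'   assignment violates the m-constraints.
#' @examples
#' x1 <- c(0, 0, 0, 0, 5, 6, 7, 8); x2 <- c(0, 0, 0, 0, 3, 4, 5, 6)
#' bestScore(rbind(x1, x2), patternCatalog(2)[["co-presence"]], m = 0.25)
#' @export
bestScore <- function(profiles, spec, m, organisms = NULL) {
    profiles <- .asProfileMatrix(profiles)
    res <- .enumerateThresholds(profiles, spec, m, mode = "best")
    if (is.null(res)) return(NULL)
    if (is.null(organisms)) {
        organisms <- rownames(profiles)
        if (is.null(organisms))
            organisms <- paste0("organism_", seq_len(nrow(profiles)))
    }
    new("PatternHit", organisms = organisms, specName = spec@name,
        epsilons = res$epsilons, counts = res$counts, score = res$score,
        m = m, sMin = NA_real_)
}

# Best valid score for each m of a grid, in one enumeration pass.
bestScoreByM <- function(profiles, spec, mGrid) {
    .enumerateThresholds(profiles, spec, mGrid, mode = "allm")
}

#' Scan a table for Boolean patterns
#'
#' Evaluates every k-combination of organisms against every pattern spec and
#' returns the hits whose maximized score reaches \code{sMin}. Unordered
#' combinations are enumerated once; patterns that distinguish organism
#' roles (one-way relations, pattern A) are evaluated in every
#' non-equivalent role assignment, and mirrored duplicate specs (the second
#' one-way orientation) are folded into the orientation enumeration so each
#' (organism set, pattern, role assignment) is reported at most once.
#'
#' @param x an \linkS4class{AbundanceTable}.
#' @param dimension tuple size k (2, 3 or 4).
#' @param specs list of \linkS4class{PatternSpec}; defaults to the full
#'   catalog for \code{dimension}.
#' @param m population threshold.
#' @param sMin minimal reported score in [0, 1].
#' @return list of \linkS4class{PatternHit} objects.
#' @seealso \code{\link{hitsTable}}, \code{\link{significantPatterns}}
#' @export
scanPatterns <- function(x, dimension = 2, specs = patternCatalog(dimension),
                         m = 0.1, sMin = 0.9) {
    stopifnot(is(x, "AbundanceTable"), sMin >= 0, sMin <= 1)
    k <- as.integer(dimension)
    if (nrow(x) < k)
        stop("table has fewer organisms than the scan dimension")
    specs <- .dedupeSpecs(specs)
    orients <- lapply(specs, .orientationPerms)
    a <- abundances(x)
    labels <- organismLabels(x)
    combos <- utils::combn(nrow(a), k)
    hits <- list()
    for (ci in seq_len(ncol(combos))) {
        tuple <- combos[, ci]
        for (si in seq_along(specs)) {
            spec <- specs[[si]]
            for (p in orients[[si]]) {
                ord <- tuple[p]
                hit <- bestScore(a[ord, , drop = FALSE], spec, m,
                                 organisms = labels[ord])
                if (!is.null(hit) && hit@score >= sMin)
                    hits[[length(hits) + 1L]] <- hit
            }
        }
    }
    hits
}

#' Tabulate pattern hits
#'
#' Flattens a list of same-dimension \linkS4class{PatternHit} objects into a
#' data frame with one row per hit: organism labels in role order, pattern
#' name, optimal thresholds, every cell fraction in lexicographic cell
#' order, score, and the scan thresholds.
#'
#' @param hits list of \linkS4class{PatternHit} objects of one dimension.
#' @return a \code{data.frame} (zero rows for an empty hit list).
#' @export
hitsTable <- function(hits) {
    if (length(hits) == 0L)
        return(data.frame(pattern = character(0), score = numeric(0)))
    k <- unique(vapply(hits, function(h) length(h@organisms), integer(1)))
    if (length(k) != 1L)
        stop("hits must share one dimension to tabulate")
    cells <- cellNames(k)
    rows <- lapply(hits, function(h) {
        out <- c(as.list(stats::setNames(h@organisms,
                                         paste0("organism", seq_len(k)))),
                 list(pattern = h@specName),
                 as.list(stats::setNames(h@epsilons,
                                         paste0("epsilon", seq_len(k)))),
                 as.list(stats::setNames(h@counts@fractions,
                                         paste0("p", cells))),
                 list(score = h@score, m = h@m, s_min = h@sMin))
        as.data.frame(out, check.names = FALSE)
    })
    do.call(rbind, rows)
}

#' Write pattern hits as TSV
#'
#' @param hits list of \linkS4class{PatternHit} objects.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeHits <- function(hits, path) {
    utils::write.table(hitsTable(hits), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
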