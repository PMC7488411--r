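# Planted-pattern synthetic abundance tables. Samples are assigned to the
# cells of each planted pattern (balanced), organism abundances are drawn so
# that the generating thresholds reproduce the assignment exactly, and a
# chosen fraction of samples is made discordant, so the recoverable pattern
# score is exactly 1 - discordantFraction.

#' Generate an abundance table with planted Boolean patterns
#'
#' For each planted spec, \code{nSamples} samples are spread round-robin over
#' the pattern's included cells (balanced occupancy), then
#' \code{round(discordantFraction * nSamples)} samples - taken evenly from
#' the included cells - are moved to non-included cells. "Present" abundances
#' are drawn uniformly above the organism's generating threshold, "absent"
#' abundances are exact zeros (or sub-threshold positives with
#' \code{absentNoise}, which forces the scan to find a nonzero threshold).
#' Discordant samples take extreme values (absent 0, present above every
#' concordant abundance) so no threshold re-assignment can reclassify them
#' without emptying a constrained cell. Independent sparse noise organisms
#' are appended.
#'
#' @param nSamples number of samples; at least twice the largest planted
#'   cell count, and divisible enough that
#'   \code{discordantFraction * nSamples} is what you mean.
#' @param specs list of \linkS4class{PatternSpec} to plant (each gets its
#'   own fresh organisms); defaults to one 2D co-presence.
#' @param noiseOrganisms number of independent noise organisms.
#' @param discordantFraction fraction of samples moved off-pattern, in
#'   [0, 0.5).
#' @param absentNoise draw concordant "absent" values as small positives
#'   below the generating threshold instead of exact zeros.
#' @param seed integer seed; generation is deterministic per seed.
#' @return list with \code{table} (a raw-count-free abundance
#'   \linkS4class{AbundanceTable}) and \code{truth}, a data frame of the
#'   planted tuples: organisms, pattern, generating thresholds and the
#'   target score \code{1 - round(d * n) / n}.
#' @examples
#' sim <- generatePatternTable(40, patternCatalog(2)["co-exclusion"],
#'                             noiseOrganisms = 2, seed = 1)
#' sim$truth
#' @export
generatePatternTable <- function(nSamples,
                                 specs = patternCatalog(2)["co-presence"],
                                 noiseOrganisms = 5,
                                 discordantFraction = 0,
                                 absentNoise = FALSE,
                                 seed = NULL) {
    stopifnot(nSamples >= 2, discordantFraction >= 0, discordantFraction < 0.5)
    if (is(specs, "PatternSpec")) specs <- list(specs)
    for (s in specs) {
        if (nSamples < 2L * length(s@includedCells))
            stop("infeasible occupancy: pattern '", s@name, "' occupies ",
                 length(s@includedCells), " cells, needing at least ",
                 2L * length(s@includedCells), " samples")
    }
    .withSeed(seed, {
        rows <- list()
        labels <- character(0)
        truth <- list()
        for (si in seq_along(specs)) {
            spec <- specs[[si]]
            k <- spec@dimension
            inc <- spec@includedCells
            excl <- setdiff(cellNames(k), inc)
            nd <- round(discordantFraction * nSamples)
            if (nd > nSamples - length(inc))
                stop("discordant fraction leaves an included cell empty")
            cellOf <- rep(inc, length.out = nSamples)[sample.int(nSamples)]
            disc <- logical(nSamples)
            if (nd > 0) {
                # remove evenly: pop one sample per included cell, cycling
                pool <- split(seq_len(nSamples), factor(cellOf, levels = inc))
                take <- integer(0)
                ci <- 1L
                while (length(take) < nd) {
                    cell <- inc[ci]
                    if (length(pool[[cell]]) > 1L) {
                        take <- c(take, pool[[cell]][1L])
                        pool[[cell]] <- pool[[cell]][-1L]
                    }
                    ci <- ci %% length(inc) + 1L
                }
                cellOf[take] <- rep(excl, length.out = nd)
                disc[take] <- TRUE
            }
            eps <- if (absentNoise) stats::runif(k, 0.04, 0.08) else rep(0, k)
            bits <- vapply(cellOf, function(cell) .cellBits(cell),
                           integer(k))
            if (k == 1L) bits <- matrix(bits, nrow = 1L)
            orgLabels <- sprintf("planted%d_%s_org%d", si,
                                 gsub("[^A-Za-z0-9]+", "_", spec@name),
                                 seq_len(k))
            for (i in seq_len(k)) {
                v <- numeric(nSamples)
                pres <- bits[i, ] == 1L
                conc_pres <- pres & !disc
                disc_pres <- pres & disc
                v[conc_pres] <- stats::runif(sum(conc_pres), eps[i] + 0.05,
                                             eps[i] + 0.55)
                v[disc_pres] <- stats::runif(sum(disc_pres), eps[i] + 0.7, 1)
                if (absentNoise) {
                    conc_abs <- !pres & !disc
                    v[conc_abs] <- stats::runif(sum(conc_abs), eps[i] / 2,
                                                eps[i])
                }
                rows[[length(rows) + 1L]] <- v
            }
            labels <- c(labels, orgLabels)
            truth[[si]] <- data.frame(
                pattern = spec@name,
                organisms = paste(orgLabels, collapse = ","),
                dimension = k,
                epsilons = paste(signif(eps, 6), collapse = ","),
                target_score = 1 - nd / nSamples)
        }
        for (j in seq_len(noiseOrganisms)) {
            prev <- stats::runif(1, 0.3, 0.7)
            mask <- stats::runif(nSamples) < prev
            v <- numeric(nSamples)
            v[mask] <- stats::runif(sum(mask), 0.05, 1)
            rows[[length(rows) + 1L]] <- v
            labels <- c(labels, sprintf("noise_org%d", j))
        }
        values <- do.call(rbind, rows)
        tab <- AbundanceTable(values, organismLabels = labels,
                              sampleIds = sprintf("sample_%03d",
                                                  seq_len(nSamples)),
                              isRelative = FALSE)
        list(table = tab, truth = do.call(rbind, truth))
    })
}
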