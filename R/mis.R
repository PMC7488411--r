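# Mutual-information-score baseline on binarized profiles. MIS is the
# maximum over presence-threshold pairs of H1 + H2 - H12 (natural-log
# entropies), the score whose pattern-type-dependent ceiling (ln 2 for
# balanced co-presence/co-exclusion, far lower for one-way relations)
# motivates pattern-specific scoring.

# Shannon entropy in nats of a vector of probabilities; 0 * log 0 = 0.
.entropy <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
}

#' Mutual information score for a pair of abundance profiles
#'
#' Binarizes both profiles at every candidate-threshold pair (the same
#' finite search space as the pattern engine, so MIS and pattern scores are
#' compared on identical binarizations) and maximizes the binary mutual
#' information \code{H1 + H2 - H12}, with natural-log entropies. Ties are
#' broken by the lexicographically smallest threshold pair.
#'
#' @param profile1,profile2 numeric abundance vectors of equal length.
#' @return a \linkS4class{MisResult}.
#' @examples
#' # ideal balanced co-presence: MIS = ln 2
#' x <- rep(c(0, 1), each = 10)
#' misValue(misScore(x, x))
#' @export
misScore <- function(profile1, profile2) {
    stopifnot(is.numeric(profile1), is.numeric(profile2))
    if (length(profile1) != length(profile2))
        stop("profiles must have the same number of samples")
    n <- length(profile1)
    stopifnot(n >= 1L)
    c1 <- candidateThresholds(profile1)
    c2 <- candidateThresholds(profile2)
    best <- -Inf
    bestEps <- c(NA_real_, NA_real_)
    bestH <- c(H1 = 0, H2 = 0, H12 = 0)
    for (e1 in c1) {
        b1 <- profile1 > e1
        p1 <- mean(b1)
        H1 <- .entropy(c(p1, 1 - p1))
        for (e2 in c2) {
            b2 <- profile2 > e2
            p2 <- mean(b2)
            H2 <- .entropy(c(p2, 1 - p2))
            joint <- c(mean(!b1 & !b2), mean(!b1 & b2),
                       mean(b1 & !b2), mean(b1 & b2))
            H12 <- .entropy(joint)
            mi <- H1 + H2 - H12
            if (mi > best + 1e-15) {
                best <- mi
                bestEps <- c(e1, e2)
                bestH <- c(H1 = H1, H2 = H2, H12 = H12)
            }
        }
    }
    # clamp tiny negative rounding residue so validity's [0, min(H1,H2)] holds
    score <- max(unname(bestH["H1"] + bestH["H2"] - bestH["H12"]), 0)
    if (score == 0) bestH <- c(H1 = bestH[["H1"]], H2 = bestH[["H2"]],
                               H12 = bestH[["H1"]] + bestH[["H2"]])
    new("MisResult", score = score, epsilons = bestEps, entropies = bestH)
}

#' Pairwise MIS over all organism pairs of a table
#'
#' @param x an \linkS4class{AbundanceTable}.
#' @return a \code{data.frame} with one row per unordered organism pair:
#'   labels, optimal thresholds, entropies and the MIS in nats.
#' @export
misPairs <- function(x) {
    stopifnot(is(x, "AbundanceTable"))
    a <- abundances(x)
    labels <- organismLabels(x)
    combos <- utils::combn(nrow(a), 2L)
    rows <- lapply(seq_len(ncol(combos)), function(ci) {
        i <- combos[1L, ci]; j <- combos[2L, ci]
        r <- misScore(a[i, ], a[j, ])
        data.frame(organism1 = labels[i], organism2 = labels[j],
                   epsilon1 = r@epsilons[1L], epsilon2 = r@epsilons[2L],
                   H1 = r@entropies[["H1"]], H2 = r@entropies[["H2"]],
                   H12 = r@entropies[["H12"]], mis = r@score)
    })
    do.call(rbind, rows)
}
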