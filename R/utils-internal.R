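# Internal helpers: binary cell bookkeeping, permutations, seeded evaluation.

#' Names of the 2^k presence/absence cells for a k-tuple of organisms
#'
#' Cells are bit strings \code{b1 b2 ... bk} where bit i is 1 when organism i
#' is present. The order is lexicographic with organism 1 as the most
#' significant bit: \code{"00", "01", "10", "11"} for k = 2.
#'
#' @param k tuple dimension (number of organisms), an integer >= 1.
#' @return character vector of length \code{2^k}.
#' @examples
#' cellNames(2)
#' @export
cellNames <- function(k) {
    k <- as.integer(k)
    stopifnot(length(k) == 1L, k >= 1L)
    idx <- 0:(2L^k - 1L)
    vapply(idx, function(i) {
        bits <- rev((i %/% 2L^(0:(k - 1L))) %% 2L)
        paste(bits, collapse = "")
    }, character(1))
}

# Split a cell name into its integer bits (b1 first).
.cellBits <- function(cell) {
    as.integer(strsplit(cell, "")[[1]])
}

# Permute the bit positions of cell names: new bit i is the old bit perm[i]
# (organism in role i was previously in role perm[i]).
.permuteCells <- function(cells, perm) {
    vapply(cells, function(cell) {
        bits <- .cellBits(cell)
        paste(bits[perm], collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

# All permutations of 1:k (k <= ~6), rows = permutations, in lexicographic
# order so the identity comes first.
.permutations <- function(k) {
    if (k == 1L) return(matrix(1L, 1L, 1L))
    sub <- .permutations(k - 1L)
    out <- vector("list", k)
    for (first in seq_len(k)) {
        rest <- setdiff(seq_len(k), first)
        out[[first]] <- cbind(first, matrix(rest[sub], nrow(sub)))
    }
    res <- do.call(rbind, out)
    dimnames(res) <- NULL
    res
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL evaluates `code` as-is.
.withSeed <- function(seed, code) {
    if (is.null(seed)) return(code)
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
    code
}

# Coerce a k x n matrix or a list of k equal-length vectors to a k x n matrix.
.asProfileMatrix <- function(profiles) {
    if (is.list(profiles)) {
        n <- unique(lengths(profiles))
        if (length(n) != 1L)
            stop("abundance profiles must all have the same length")
        profiles <- do.call(rbind, profiles)
    }
    if (!is.matrix(profiles) || !is.numeric(profiles))
        stop("profiles must be a numeric matrix (rows = organisms) or a list of vectors")
    if (ncol(profiles) < 1L) stop("profiles must cover at least one sample")
    profiles
}
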