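# Independent brute-force oracles and small fixture builders. The oracle
# deliberately shares no code with the package's enumeration engine: it
# assigns every sample to its cell by string construction for every
# combination of observed threshold values.

# Brute-force maximization of a constrained cell-sum score.
# profiles: k x n matrix; inc/con: character cell names; m: scalar.
# Returns list(score, epsilons) or NULL; ties keep the lexicographically
# smallest threshold vector.
oracleBestScore <- function(profiles, inc, con, m) {
    k <- nrow(profiles)
    n <- ncol(profiles)
    cands <- lapply(seq_len(k), function(i) sort(unique(profiles[i, ])))
    grid <- expand.grid(rev(cands), KEEP.OUT.ATTRS = FALSE)
    grid <- grid[, rev(seq_len(k)), drop = FALSE]  # column i = epsilon_i
    best <- NULL
    for (r in seq_len(nrow(grid))) {
        eps <- as.numeric(grid[r, ])
        cellstr <- do.call(paste0, lapply(seq_len(k), function(i)
            as.integer(profiles[i, ] > eps[i])))
        freq <- table(factor(cellstr, levels = BoolPatterns::cellNames(k))) / n
        if (any(freq[con] <= m)) next
        s <- sum(freq[inc])
        if (is.null(best) || s > best$score + 1e-12)
            best <- list(score = s, epsilons = eps)
    }
    best
}

# Binary mutual information (nats) maximized over thresholds, computed from
# first principles for the oracle side of MIS checks.
oracleMis <- function(x1, x2) {
    H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
    best <- 0
    for (e1 in sort(unique(x1))) for (e2 in sort(unique(x2))) {
        b1 <- x1 > e1; b2 <- x2 > e2
        joint <- c(mean(!b1 & !b2), mean(!b1 & b2),
                   mean(b1 & !b2), mean(b1 & b2))
        mi <- H(c(mean(b1), 1 - mean(b1))) + H(c(mean(b2), 1 - mean(b2))) -
            H(joint)
        if (mi > best) best <- mi
    }
    best
}

# A sparse random k x n profile matrix with a small support so threshold
# grids stay modest; values mimic zero-inflated relative abundances.
randomProfiles <- function(k, n, support = c(0, 0, 0, 0.02, 0.05, 0.1,
                                             0.2, 0.4)) {
    m <- matrix(sample(support, k * n, replace = TRUE), nrow = k)
    rownames(m) <- paste0("org", seq_len(k))
    m
}

# Abundance table from explicit cell occupancies: `cells` maps cell name to
# sample count; organisms take value `hi` when present, 0 when absent.
tableFromCells <- function(cells, hi = 1) {
    k <- nchar(names(cells)[1])
    values <- do.call(cbind, lapply(names(cells), function(cell) {
        bits <- as.integer(strsplit(cell, "")[[1]])
        matrix(rep(bits * hi, cells[[cell]]), nrow = k)
    }))
    AbundanceTable(values,
                   organismLabels = paste0("org", seq_len(k)),
                   sampleIds = paste0("s", seq_len(ncol(values))))
}

# QIIME-classic TSV fixture on disk; returns the path.
writeQiimeFixture <- function(lines) {
    tf <- tempfile(fileext = ".tsv")
    writeLines(lines, tf)
    tf
}
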