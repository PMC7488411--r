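#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors metadata metadata<- DataFrame SimpleList
NULL

#' AbundanceTable: organisms x samples microbial abundance matrix
#'
#' An \code{AbundanceTable} holds one assay named \code{"abundance"} with
#' organisms as rows and samples as columns, either raw sequencing-read
#' counts or relative abundances (columns summing to 1). It extends
#' \linkS4class{SummarizedExperiment}, so all the usual subsetting and
#' annotation machinery applies; \code{rowData(x)$lineage} optionally stores
#' the semicolon-delimited taxonomy string of each organism.
#'
#' @slot int_metadata the \code{is_relative} flag lives in
#'   \code{metadata(x)$is_relative}.
#' @seealso \code{\link{AbundanceTable}} (constructor),
#'   \code{\link{normalizeRelative}}, \code{\link{scanPatterns}}
#' @export
setClass("AbundanceTable", contains = "SummarizedExperiment")

setValidity("AbundanceTable", function(object) {
    msg <- character(0)
    if (!"abundance" %in% assayNames(object))
        return("assay 'abundance' is required")
    a <- assay(object, "abundance")
    if (!is.numeric(a))
        msg <- c(msg, "abundance values must be numeric")
    else if (any(a < 0, na.rm = TRUE) || anyNA(a))
        msg <- c(msg, "abundance values must be non-negative and non-missing")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "organism labels must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be present and unique")
    rel <- metadata(object)$is_relative
    if (is.null(rel) || !is.logical(rel) || length(rel) != 1L || is.na(rel))
        msg <- c(msg, "metadata(x)$is_relative must be TRUE or FALSE")
    else if (isTRUE(rel) && ncol(object) > 0) {
        cs <- colSums(a)
        if (any(abs(cs - 1) > 1e-9))
            msg <- c(msg, "relative tables require every column to sum to 1 (within 1e-9)")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an AbundanceTable
#'
#' @param values numeric matrix of non-negative abundances, rows = organisms,
#'   columns = samples.
#' @param organismLabels character vector of unique organism labels
#'   (taxonomy strings or OTU ids); defaults to \code{rownames(values)}.
#' @param sampleIds character vector of unique sample identifiers; defaults
#'   to \code{colnames(values)}.
#' @param isRelative logical flag: do columns sum to 1 (relative abundances)?
#' @param lineage optional character vector of semicolon-delimited taxonomy
#'   strings, stored in \code{rowData()$lineage}.
#' @return an \linkS4class{AbundanceTable}.
#' @examples
#' m <- matrix(c(1, 0, 3, 2, 0, 4), nrow = 2, dimnames =
#'   list(c("orgA", "orgB"), c("s1", "s2", "s3")))
#' AbundanceTable(m)
#' @export
AbundanceTable <- function(values, organismLabels = rownames(values),
                           sampleIds = colnames(values), isRelative = FALSE,
                           lineage = NULL) {
    values <- as.matrix(values)
    if (is.null(organismLabels))
        organismLabels <- paste0("organism_", seq_len(nrow(values)))
    if (is.null(sampleIds))
        sampleIds <- paste0("sample_", seq_len(ncol(values)))
    dimnames(values) <- list(organismLabels, sampleIds)
    rd <- if (is.null(lineage)) NULL else DataFrame(lineage = lineage)
    se <- SummarizedExperiment(assays = SimpleList(abundance = values),
                               rowData = rd)
    metadata(se)$is_relative <- isTRUE(isRelative)
    new("AbundanceTable", se)
}

#' PatternSpec: a named Boolean relationship pattern
#'
#' A pattern is defined by the set of presence/absence cells whose sample
#' fractions contribute to its score (\code{includedCells}) and the subset of
#' those cells whose fraction must exceed the population threshold m
#' (\code{constrainedCells}). Cell names follow \code{\link{cellNames}}.
#'
#' @slot name human-readable pattern name, e.g. \code{"co-exclusion"}.
#' @slot dimension tuple size k (2, 3 or 4 for the built-in catalog).
#' @slot includedCells cells summed into the score.
#' @slot constrainedCells cells required to exceed m; a subset of
#'   \code{includedCells}.
#' @slot interpretation free-text reading of the pattern.
#' @seealso \code{\link{patternCatalog}}
#' @export
setClass("PatternSpec", representation(
    name = "character",
    dimension = "integer",
    includedCells = "character",
    constrainedCells = "character",
    interpretation = "character"
))

setValidity("PatternSpec", function(object) {
    k <- object@dimension
    cells <- cellNames(k)
    msg <- character(0)
    if (!all(object@includedCells %in% cells))
        msg <- c(msg, "includedCells must be valid k-bit cell names")
    if (!all(object@constrainedCells %in% object@includedCells))
        msg <- c(msg, "constrainedCells must be a subset of includedCells")
    if (!strrep("0", k) %in% object@includedCells)
        msg <- c(msg, "the all-absent cell must be included (co-absence does not contradict any pattern)")
    if (anyDuplicated(object@includedCells))
        msg <- c(msg, "includedCells must be unique")
    if (length(msg)) msg else TRUE
})

PatternSpec <- function(name, dimension, includedCells, constrainedCells,
                        interpretation = name) {
    new("PatternSpec", name = name, dimension = as.integer(dimension),
        includedCells = includedCells, constrainedCells = constrainedCells,
        interpretation = interpretation)
}

#' PartitionCounts: sample fractions of the 2^k presence/absence cells
#'
#' For k organisms binarized at a threshold assignment, the fraction of
#' samples falling in each of the \code{2^k} cells. Fractions are exact
#' counts divided by the number of samples and sum to 1.
#'
#' @slot fractions named numeric vector over \code{cellNames(k)}.
#' @slot nSamples number of samples tabulated.
#' @export
setClass("PartitionCounts", representation(
    fractions = "numeric",
    nSamples = "integer"
))

setValidity("PartitionCounts", function(object) {
    f <- object@fractions
    k <- round(log2(length(f)))
    msg <- character(0)
    if (2^k != length(f) || is.null(names(f)) ||
        !identical(names(f), cellNames(max(k, 1))))
        msg <- c(msg, "fractions must be named by cellNames(k) in order")
    if (abs(sum(f) - 1) > 1e-9)
        msg <- c(msg, "cell fractions must sum to 1")
    n <- object@nSamples
    if (length(n) != 1L || n < 1L)
        msg <- c(msg, "nSamples must be a positive integer")
    else if (any(abs(f * n - round(f * n)) > 1e-6))
        msg <- c(msg, "each fraction must be an integer count divided by nSamples")
    if (length(msg)) msg else TRUE
})

#' PatternHit: a detected pattern instance
#'
#' @slot organisms organism labels in role order (label i plays bit i of the
#'   pattern's cell names; for one-way patterns organism 1 is the provider).
#' @slot specName name of the matched \linkS4class{PatternSpec}.
#' @slot epsilons optimal presence/absence thresholds, one per organism.
#' @slot counts the \linkS4class{PartitionCounts} at the optimum.
#' @slot score pattern strength: sum of included-cell fractions in (0, 1].
#' @slot m population threshold the hit was scanned at.
#' @slot sMin minimal-score gate the hit was reported at (NA outside
#'   \code{\link{significantPatterns}}).
#' @export
setClass("PatternHit", representation(
    organisms = "character",
    specName = "character",
    epsilons = "numeric",
    counts = "PartitionCounts",
    score = "numeric",
    m = "numeric",
    sMin = "numeric"
))

setValidity("PatternHit", function(object) {
    msg <- character(0)
    if (length(object@organisms) != length(object@epsilons))
        msg <- c(msg, "one threshold per organism is required")
    if (object@score < 0 || object@score > 1 + 1e-12)
        msg <- c(msg, "score must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' MisResult: maximized binary mutual information for an organism pair
#'
#' @slot score mutual information in nats at the optimal thresholds,
#'   \code{H1 + H2 - H12}.
#' @slot epsilons the maximizing presence/absence thresholds.
#' @slot entropies named vector \code{c(H1=, H2=, H12=)} at the optimum.
#' @export
setClass("MisResult", representation(
    score = "numeric",
    epsilons = "numeric",
    entropies = "numeric"
))

setValidity("MisResult", function(object) {
    e <- object@entropies
    msg <- character(0)
    if (!identical(names(e), c("H1", "H2", "H12")))
        msg <- c(msg, "entropies must be named H1, H2, H12")
    else {
        if (abs(object@score - (e["H1"] + e["H2"] - e["H12"])) > 1e-12)
            msg <- c(msg, "score must equal H1 + H2 - H12")
        if (object@score < -1e-12 ||
            object@score > min(e["H1"], e["H2"]) + 1e-12)
            msg <- c(msg, "mutual information must lie in [0, min(H1, H2)]")
    }
    if (length(msg)) msg else TRUE
})

#' FeasibilityGrid: shuffle-based (m, S_min) gate
#'
#' For every combination of population threshold m and minimal score S_min,
#' the number of patterns detected in shuffled (null) data. A cell is
#' feasible when that count is zero in every shuffle; real-data reporting
#' restricted to feasible cells has zero type-1 error by construction.
#'
#' @slot mValues sorted population thresholds (rows).
#' @slot sMinValues sorted minimal scores (columns).
#' @slot shuffledCounts integer matrix of pattern counts summed over
#'   shuffles.
#' @slot feasible logical matrix, \code{shuffledCounts == 0}.
#' @slot nShuffles number of independent shuffles aggregated.
#' @slot dimension tuple dimension scanned.
#' @export
setClass("FeasibilityGrid", representation(
    mValues = "numeric",
    sMinValues = "numeric",
    shuffledCounts = "matrix",
    feasible = "matrix",
    nShuffles = "integer",
    dimension = "integer"
))

setValidity("FeasibilityGrid", function(object) {
    msg <- character(0)
    if (!identical(dim(object@shuffledCounts),
                   c(length(object@mValues), length(object@sMinValues))))
        msg <- c(msg, "shuffledCounts must be length(mValues) x length(sMinValues)")
    if (!identical(dim(object@feasible), dim(object@shuffledCounts)))
        msg <- c(msg, "feasible must match shuffledCounts in shape")
    else if (!identical(as.vector(object@feasible),
                        as.vector(object@shuffledCounts == 0)))
        msg <- c(msg, "feasible must be exactly shuffledCounts == 0")
    if (is.unsorted(object@mValues) || is.unsorted(object@sMinValues))
        msg <- c(msg, "grid axes must be sorted increasing")
    if (length(msg)) msg else TRUE
})

#' PatternNetwork: typed (multi-layer) graph of detected patterns
#'
#' Wraps an \pkg{igraph} graph in which 2D hits are organism-organism edges
#' (directed provider -> dependent for one-way relations) and each >= 3D hit
#' is a pattern node linked to its member organisms by membership edges, the
#' multi-layer representation used for higher-dimensional patterns.
#'
#' @slot graph the underlying \pkg{igraph} object.
#' @seealso \code{\link{buildNetwork}}, \code{\link{exportNetwork}}
#' @export
setClass("PatternNetwork", representation(graph = "ANY"))

setValidity("PatternNetwork", function(object) {
    if (!igraph::is_igraph(object@graph))
        return("graph slot must hold an igraph object")
    TRUE
})
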