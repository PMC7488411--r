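# Accessors and show methods for the core classes.

#' @describeIn AbundanceTable the abundance matrix (organisms x samples).
#' @param x an AbundanceTable.
#' @export
abundances <- function(x) {
    stopifnot(is(x, "AbundanceTable"))
    assay(x, "abundance")
}

#' @describeIn AbundanceTable organism labels (row names).
#' @export
organismLabels <- function(x) rownames(x)

#' @describeIn AbundanceTable sample identifiers (column names).
#' @export
sampleIds <- function(x) colnames(x)

#' @describeIn AbundanceTable TRUE when columns are relative abundances
#'   summing to 1.
#' @export
isRelative <- function(x) {
    stopifnot(is(x, "AbundanceTable"))
    isTRUE(metadata(x)$is_relative)
}

setMethod("show", "AbundanceTable", function(object) {
    cat(sprintf("AbundanceTable: %d organisms x %d samples (%s)\n",
                nrow(object), ncol(object),
                if (isRelative(object)) "relative abundances" else "raw counts"))
    callNextMethod()
})

#' @describeIn PatternSpec pattern name.
#' @param object,x a PatternSpec.
#' @export
specName <- function(x) x@name

#' @describeIn PatternSpec tuple dimension k.
#' @export
specDimension <- function(x) x@dimension

#' @describeIn PatternSpec cells contributing to the score.
#' @export
includedCells <- function(x) x@includedCells

#' @describeIn PatternSpec cells whose fraction must exceed m.
#' @export
constrainedCells <- function(x) x@constrainedCells

setMethod("show", "PatternSpec", function(object) {
    cat(sprintf("PatternSpec '%s' (k = %d)\n", object@name, object@dimension))
    cat("  score cells: ", paste(object@includedCells, collapse = " + "), "\n")
    cat("  constrained: ", paste(paste0("p", object@constrainedCells, " > m"),
                                 collapse = "; "), "\n")
    cat("  ", object@interpretation, "\n", sep = "")
})

#' @describeIn PartitionCounts named cell fractions.
#' @param x a PartitionCounts.
#' @export
cellFractions <- function(x) x@fractions

#' @describeIn PartitionCounts number of samples tabulated.
#' @export
nSamples <- function(x) x@nSamples

setMethod("show", "PartitionCounts", function(object) {
    cat(sprintf("PartitionCounts over %d samples:\n", object@nSamples))
    print(round(object@fractions, 4))
})

#' @describeIn PatternHit pattern strength score.
#' @param x a PatternHit.
#' @export
patternScore <- function(x) x@score

#' @describeIn PatternHit optimal presence thresholds (one per organism).
#' @export
thresholds <- function(x) x@epsilons

#' @describeIn PatternHit organism labels in role order.
#' @export
hitOrganisms <- function(x) x@organisms

setMethod("show", "PatternHit", function(object) {
    cat(sprintf("PatternHit '%s': S = %.4g (m = %g)\n",
                object@specName, object@score, object@m))
    cat("  organisms:", paste(object@organisms, collapse = ", "), "\n")
    cat("  epsilon:  ", paste(signif(object@epsilons, 4), collapse = ", "), "\n")
})

#' @describeIn MisResult mutual information score in nats.
#' @param x a MisResult.
#' @export
misValue <- function(x) x@score

setMethod("show", "MisResult", function(object) {
    cat(sprintf("MIS = %.4f nats at epsilon = (%s)\n", object@score,
                paste(signif(object@epsilons, 4), collapse = ", ")))
    cat(sprintf("  H1 = %.4f, H2 = %.4f, H12 = %.4f\n",
                object@entropies["H1"], object@entropies["H2"],
                object@entropies["H12"]))
})

#' @describeIn FeasibilityGrid logical feasibility matrix (m rows,
#'   S_min columns).
#' @param x a FeasibilityGrid.
#' @export
feasibleCells <- function(x) x@feasible

#' @describeIn FeasibilityGrid shuffled pattern counts per grid cell.
#' @export
shuffledCounts <- function(x) x@shuffledCounts

setMethod("show", "FeasibilityGrid", function(object) {
    cat(sprintf("FeasibilityGrid: %d m-values x %d S_min values, %d shuffle(s), k = %d\n",
                length(object@mValues), length(object@sMinValues),
                object@nShuffles, object@dimension))
    cat(sprintf("  feasible cells (zero shuffled patterns): %d of %d\n",
                sum(object@feasible), length(object@feasible)))
})

#' @describeIn PatternNetwork the underlying igraph object.
#' @param x a PatternNetwork.
#' @export
patternGraph <- function(x) x@graph

setMethod("show", "PatternNetwork", function(object) {
    g <- object@graph
    kinds <- igraph::V(g)$node_kind
    cat(sprintf("PatternNetwork: %d OTU node(s), %d pattern node(s), %d edge(s)\n",
                sum(kinds == "otu"), sum(kinds == "pattern"),
                igraph::ecount(g)))
})
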