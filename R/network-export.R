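# Typed pattern networks. Pairwise hits become organism-organism edges
# (directed provider -> dependent for one-way relations); each >= 3D hit
# becomes a pattern node linked to its member organisms, giving the
# multi-layer graph used to represent higher-dimensional patterns alongside
# pairwise ones.

# Extract the phylum from a semicolon-delimited lineage string.
.parsePhylum <- function(lineage) {
    if (is.null(lineage) || is.na(lineage)) return(NA_character_)
    parts <- .parseLineage(lineage)
    raw <- trimws(strsplit(lineage, ";", fixed = TRUE)[[1]])
    tagged <- grep("^p__", raw, ignore.case = TRUE)
    if (length(tagged)) {
        val <- sub("^p__", "", raw[tagged[1]], ignore.case = TRUE)
        return(if (nzchar(val)) val else NA_character_)
    }
    if (length(parts) >= 2L && nzchar(parts[2L])) return(parts[2L])
    NA_character_
}

#' Build a typed pattern network from hits
#'
#' Creates OTU nodes only for organisms participating in at least one hit,
#' annotated with their phylum (parsed from \code{rowData(x)$lineage} when
#' available) and mean relative abundance across samples (the conventional
#' node-size attribute). 2D hits contribute one relation edge each; every
#' >= 3D hit contributes one pattern node with a membership link to each of
#' its k organisms.
#'
#' @param hits list of \linkS4class{PatternHit} objects (dimensions may be
#'   mixed).
#' @param x the \linkS4class{AbundanceTable} the hits came from.
#' @return a \linkS4class{PatternNetwork}.
#' @export
buildNetwork <- function(hits, x) {
    stopifnot(is(x, "AbundanceTable"))
    labels <- organismLabels(x)
    for (h in hits)
        if (!all(h@organisms %in% labels))
            stop("hit references organism(s) absent from the table: ",
                 paste(setdiff(h@organisms, labels), collapse = ", "))
    g <- igraph::make_empty_graph(directed = TRUE)
    if (length(hits)) {
        orgs <- unique(unlist(lapply(hits, function(h) h@organisms)))
        meanAb <- rowMeans(abundances(x))[orgs]
        lin <- rowData(x)$lineage
        phyla <- if (is.null(lin)) rep(NA_character_, length(orgs)) else
            vapply(lin[match(orgs, labels)], .parsePhylum, character(1),
                   USE.NAMES = FALSE)
        g <- igraph::add_vertices(g, length(orgs), name = orgs,
                                  node_kind = "otu", phylum = phyla,
                                  mean_abundance = unname(meanAb),
                                  pattern_type = NA_character_,
                                  score = NA_real_)
        pat_i <- 0L
        for (h in hits) {
            k <- length(h@organisms)
            if (k == 2L) {
                oneway <- startsWith(h@specName, "one-way")
                g <- igraph::add_edges(
                    g, h@organisms,
                    edge_kind = "relation", pattern_type = h@specName,
                    score = h@score,
                    direction = if (oneway) "provider->dependent" else "none")
            } else {
                pat_i <- pat_i + 1L
                pname <- sprintf("pattern_%02d: %s", pat_i, h@specName)
                g <- igraph::add_vertices(g, 1L, name = pname,
                                          node_kind = "pattern",
                                          phylum = NA_character_,
                                          mean_abundance = NA_real_,
                                          pattern_type = h@specName,
                                          score = h@score)
                for (org in h@organisms)
                    g <- igraph::add_edges(g, c(pname, org),
                                           edge_kind = "membership",
                                           pattern_type = h@specName,
                                           score = h@score,
                                           direction = "none")
            }
        }
    }
    new("PatternNetwork", graph = g)
}

#' Export a pattern network
#'
#' \code{"graphml"} writes GraphML with all node attributes (label, kind,
#' phylum, mean abundance, pattern type, score) and edge attributes (kind,
#' pattern type, score, direction); \code{"edge_tsv"} writes one row per
#' edge. Relationship types are stored as attributes, not colors; rendering
#' is a viewer concern.
#'
#' @param network a \linkS4class{PatternNetwork}.
#' @param path output file.
#' @param format \code{"graphml"} or \code{"edge_tsv"}.
#' @return \code{path}, invisibly.
#' @export
exportNetwork <- function(network, path, format = c("graphml", "edge_tsv")) {
    stopifnot(is(network, "PatternNetwork"))
    format <- match.arg(format)
    g <- network@graph
    if (format == "graphml") {
        igraph::write_graph(g, path, format = "graphml")
    } else {
        e <- igraph::as_data_frame(g, what = "edges")
        if (nrow(e) == 0L)
            e <- data.frame(from = character(0), to = character(0),
                            edge_kind = character(0),
                            pattern_type = character(0),
                            score = numeric(0), direction = character(0))
        utils::write.table(e, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}

#' Read a GraphML pattern network back
#'
#' @param path a GraphML file written by \code{\link{exportNetwork}}.
#' @return a \linkS4class{PatternNetwork}.
#' @export
readNetwork <- function(path) {
    new("PatternNetwork", graph = igraph::read_graph(path, format = "graphml"))
}
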