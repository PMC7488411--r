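# Reading, writing and preprocessing of organisms x samples abundance tables
# (QIIME-classic TSV dialect, optional BIOM), mirroring the standard HMP-style
# acquisition pipeline: read-depth filter, relative-abundance normalization,
# taxonomy-level merge, prevalence filter.

#' Read an abundance table
#'
#' Reads a QIIME-classic OTU table: tab-separated, \code{#}-prefixed comment
#' lines skipped (a \code{#OTU ID} line is recognized as the header), first
#' column organism/OTU ids, optional trailing \code{taxonomy} column whose
#' strings become the organism labels. A BIOM path is supported via the
#' \pkg{biomformat} package.
#'
#' @param path file to read.
#' @param format \code{"tsv"} (default) or \code{"biom"}.
#' @return an \linkS4class{AbundanceTable} with raw values
#'   (\code{isRelative(x)} is \code{FALSE}).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("#OTU ID\ts1\ts2", "otu1\t3\t0", "otu2\t1\t2"), tf)
#' readAbundanceTable(tf)
#' @export
readAbundanceTable <- function(path, format = c("tsv", "biom")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "biom") return(.readBiom(path))
    lines <- readLines(path)
    is_comment <- startsWith(lines, "#")
    header_line <- which(is_comment & grepl("^#\\s*OTU[ _]?ID", lines,
                                            ignore.case = TRUE))
    if (length(header_line)) {
        header_idx <- header_line[length(header_line)]
    } else {
        header_idx <- which(!is_comment)[1]
        if (is.na(header_idx)) stop("no header line found in ", path)
    }
    header <- strsplit(sub("^#", "", lines[header_idx]), "\t", fixed = TRUE)[[1]]
    if (length(header) < 2L)
        stop("malformed header at line ", header_idx,
             ": expected tab-separated organism id and sample columns")
    data_idx <- setdiff(which(!is_comment), seq_len(header_idx))
    fields <- strsplit(lines[data_idx], "\t", fixed = TRUE)
    bad <- which(lengths(fields) != length(header))
    if (length(bad))
        stop("malformed row at line ", data_idx[bad[1]], ": expected ",
             length(header), " fields, found ", lengths(fields)[bad[1]])
    has_tax <- tolower(header[length(header)]) == "taxonomy"
    value_cols <- seq(2L, length(header) - if (has_tax) 1L else 0L)
    otu_ids <- vapply(fields, `[[`, character(1), 1L)
    values <- matrix(NA_real_, length(fields), length(value_cols))
    for (i in seq_along(fields))
        values[i, ] <- suppressWarnings(as.numeric(fields[[i]][value_cols]))
    if (anyNA(values)) {
        bad <- which(apply(values, 1L, anyNA))[1]
        stop("non-numeric abundance value at line ", data_idx[bad])
    }
    if (any(values < 0)) {
        bad <- which(apply(values, 1L, function(r) any(r < 0)))[1]
        stop("negative abundance value at line ", data_idx[bad])
    }
    lineage <- NULL
    if (has_tax) {
        labels <- vapply(fields, function(f) f[[length(header)]], character(1))
        if (anyDuplicated(labels)) {
            warning("duplicate taxonomy labels made unique")
            labels <- make.unique(labels)
        }
        lineage <- labels
    } else {
        labels <- otu_ids
    }
    if (anyDuplicated(labels)) stop("duplicate organism ids in ", path)
    AbundanceTable(values, organismLabels = labels,
                   sampleIds = header[value_cols], isRelative = FALSE,
                   lineage = lineage)
}

.readBiom <- function(path) {
    if (!requireNamespace("biomformat", quietly = TRUE))
        stop("reading BIOM files requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    values <- as(biomformat::biom_data(b), "matrix")
    AbundanceTable(values, isRelative = FALSE)
}

#' Write an abundance table as QIIME-classic TSV
#'
#' Values are written with 17 significant digits so a read-back reproduces
#' the matrix bit-exactly. When lineages are stored in
#' \code{rowData(x)$lineage}, a trailing \code{taxonomy} column is emitted.
#'
#' @param x an \linkS4class{AbundanceTable}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeAbundanceTable <- function(x, path) {
    stopifnot(is(x, "AbundanceTable"))
    a <- abundances(x)
    fmt <- function(v) {
        out <- formatC(v, digits = 17, format = "g")
        out[v == round(v) & abs(v) < 2^53] <- format(v[v == round(v) & abs(v) < 2^53],
                                                     scientific = FALSE, trim = TRUE)
        out
    }
    lineage <- rowData(x)$lineage
    has_tax <- !is.null(lineage)
    ids <- if (has_tax) paste0("OTU_", seq_len(nrow(a))) else rownames(a)
    header <- paste(c("#OTU ID", colnames(a), if (has_tax) "taxonomy"),
                    collapse = "\t")
    rows <- vapply(seq_len(nrow(a)), function(i) {
        paste(c(ids[i], fmt(a[i, ]), if (has_tax) lineage[i]), collapse = "\t")
    }, character(1))
    writeLines(c(header, rows), path)
    invisible(path)
}

#' Filter samples by sequencing read depth
#'
#' Excludes samples with significantly low or high total read counts; the
#' defaults drop samples with fewer than 2000 or more than 50000 reads
#' (bounds are strict: totals equal to a bound are retained). Surviving
#' sample order is preserved.
#'
#' @param x an \linkS4class{AbundanceTable} of raw counts.
#' @param minReads,maxReads read-depth bounds.
#' @return the filtered \linkS4class{AbundanceTable}.
#' @export
filterSamplesByDepth <- function(x, minReads = 2000, maxReads = 50000) {
    stopifnot(is(x, "AbundanceTable"), minReads < maxReads)
    if (isRelative(x))
        stop("read-depth filtering applies to raw counts, not relative abundances")
    depth <- colSums(abundances(x))
    x[, depth >= minReads & depth <= maxReads]
}

#' Normalize each sample to relative abundances
#'
#' Divides every column by its total so columns sum to 1; idempotent.
#'
#' @param x an \linkS4class{AbundanceTable}; every column sum must be > 0.
#' @return the normalized table with \code{isRelative(x)} \code{TRUE}.
#' @export
normalizeRelative <- function(x) {
    stopifnot(is(x, "AbundanceTable"))
    a <- abundances(x)
    cs <- colSums(a)
    if (any(cs == 0))
        stop("cannot normalize zero-total sample(s): ",
             paste(colnames(a)[cs == 0], collapse = ", "))
    out <- sweep(a, 2L, cs, "/")
    assay(x, "abundance") <- out
    metadata(x)$is_relative <- TRUE
    validObject(x)
    x
}

.TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus",
                "species")
.RANK_LETTER <- c(kingdom = "K", phylum = "P", class = "C", order = "O",
                  family = "F", genus = "G", species = "S")

# Split a semicolon-delimited lineage into per-rank names; greengenes-style
# "g__Name" prefixes are stripped, empty assignments become "".
.parseLineage <- function(label) {
    parts <- trimws(strsplit(label, ";", fixed = TRUE)[[1]])
    parts <- sub("^[kpcofgs]__", "", parts, ignore.case = TRUE)
    parts
}

#' Merge organisms to a taxonomy level
#'
#' Rows whose semicolon-delimited lineages agree up to \code{level} are
#' summed. The merged label names the lowest rank actually assigned, using
#' the bracketed-rank convention \code{"[G] Rothia"} (\code{[F]} when the
#' organism is resolved only to family, and so on).
#'
#' @param x an \linkS4class{AbundanceTable} whose organism labels (or
#'   \code{rowData(x)$lineage}) are lineage strings such as
#'   \code{"k__Bacteria; ...; g__Rothia"}.
#' @param level target rank, one of kingdom, phylum, class, order, family,
#'   genus, species.
#' @return the merged table; each column total is conserved.
#' @export
mergeToLevel <- function(x, level = "genus") {
    stopifnot(is(x, "AbundanceTable"))
    level <- match.arg(level, .TAX_RANKS)
    depth <- match(level, .TAX_RANKS)
    labels <- rowData(x)$lineage
    if (is.null(labels)) labels <- organismLabels(x)
    parsed <- lapply(labels, .parseLineage)
    bad <- labels[lengths(parsed) == 0 | !nzchar(vapply(parsed, `[`, "", 1L))]
    if (length(bad))
        stop("unparseable lineage label(s): ", paste(bad, collapse = "; "))
    prefix <- vapply(parsed, function(p) {
        p <- c(p, rep("", max(0, depth - length(p))))[seq_len(depth)]
        paste(p, collapse = ";")
    }, character(1))
    groups <- split(seq_along(prefix), factor(prefix, levels = unique(prefix)))
    a <- abundances(x)
    merged <- t(vapply(groups, function(i) colSums(a[i, , drop = FALSE]),
                       numeric(ncol(a))))
    if (ncol(a) == 1L) merged <- matrix(merged, ncol = 1L)
    keys <- names(groups)
    mklabel <- function(key) {
        p <- strsplit(key, ";", fixed = TRUE)[[1]]
        assigned <- which(nzchar(p))
        low <- assigned[length(assigned)]
        sprintf("[%s] %s", .RANK_LETTER[[.TAX_RANKS[low]]], p[low])
    }
    lab <- vapply(keys, mklabel, character(1), USE.NAMES = FALSE)
    if (anyDuplicated(lab)) lab <- make.unique(lab)
    AbundanceTable(merged, organismLabels = lab, sampleIds = sampleIds(x),
                   isRelative = isRelative(x), lineage = keys)
}

#' Filter organisms by prevalence
#'
#' Removes organisms with nonzero abundance in fewer than
#' \code{minFraction} of samples (\code{"fewer than"} is strict: an organism
#' present in exactly that fraction is retained). Row order is preserved.
#'
#' @param x an \linkS4class{AbundanceTable}.
#' @param minFraction minimum prevalence, e.g. \code{0.05} for 5\%.
#' @return the filtered table (possibly with zero rows).
#' @export
filterPrevalence <- function(x, minFraction = 0.05) {
    stopifnot(is(x, "AbundanceTable"), minFraction >= 0, minFraction <= 1)
    prev <- rowSums(abundances(x) > 0) / ncol(x)
    x[prev >= minFraction, ]
}
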