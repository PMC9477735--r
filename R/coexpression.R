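#' @include AllClasses.R AllGenerics.R
NULL

#' Load a gene-by-sample expression matrix
#'
#' Reads a delimited expression atlas (first column gene identifiers,
#' remaining columns numeric expression values per tissue/sample; tab- or
#' comma-separated, detected from the extension and the header line).
#' Rows with any missing value are dropped with a message. Duplicate gene
#' identifiers are collapsed to a single row by the mean (or the maximum)
#' of their values, with a message.
#'
#' @param path path to the atlas file.
#' @param collapse how to collapse duplicated gene ids, `"mean"`
#'   (default) or `"max"`.
#' @return Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns.
#' @export
loadExpressionMatrix <- function(path, collapse = c("mean", "max")) {
    collapse <- match.arg(collapse)
    if (!file.exists(path))
        stop("file not found: ", path)
    firstLine <- readLines(path, n = 1L)
    if (!length(firstLine) || !nzchar(firstLine))
        stop("format error: empty expression file ", path)
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE) ||
               (!grepl("\t", firstLine) && grepl(",", firstLine))) ","
           else "\t"
    tbl <- utils::read.table(path, sep = sep, header = TRUE,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             quote = "\"", comment.char = "")
    if (ncol(tbl) < 2L)
        stop("format error: expected identifier column plus samples")
    ids <- as.character(tbl[[1L]])
    vals <- tbl[, -1L, drop = FALSE]
    for (j in seq_along(vals)) {
        v <- suppressWarnings(as.numeric(vals[[j]]))
        bad <- which(is.na(v) & !is.na(vals[[j]]) &
                     !vals[[j]] %in% c("NA", ""))
        if (length(bad))
            stop("format error: non-numeric value at row ", bad[1L],
                 ", column ", j + 1L)
        vals[[j]] <- v
    }
    mat <- as.matrix(vals)
    incomplete <- rowSums(is.na(mat)) > 0L
    if (any(incomplete)) {
        message("dropping ", sum(incomplete), " row(s) with missing values")
        mat <- mat[!incomplete, , drop = FALSE]
        ids <- ids[!incomplete]
    }
    if (anyDuplicated(ids)) {
        message("collapsing ", sum(duplicated(ids)),
                " duplicated gene id(s) by ", collapse)
        fun <- if (collapse == "mean") mean else max
        mat <- do.call(rbind, lapply(split(seq_along(ids), ids), function(i)
            apply(mat[i, , drop = FALSE], 2L, fun)))
        # split() orders groups; restore first-appearance order
        mat <- mat[unique(ids), , drop = FALSE]
    } else {
        rownames(mat) <- ids
    }
    mat
}

#' Filter out low-variance genes
#'
#' Retains rows whose sample variance (n - 1 denominator) is at least
#' `threshold`, preserving row order. The default threshold of 1 (in
#' squared expression units) removes genes whose expression barely varies
#' across tissues and would contribute spurious correlations.
#'
#' @param mat numeric matrix, genes in rows.
#' @param threshold minimum row variance to keep (default 1).
#' @return The filtered matrix.
#' @examples
#' m <- rbind(flat = rep(5, 4), varying = c(0, 2, 4, 6))
#' filterLowVariance(m)
#' @export
filterLowVariance <- function(mat, threshold = 1) {
    stopifnot(is.matrix(mat), is.numeric(mat))
    if (threshold < 0)
        stop("threshold must be >= 0")
    if (ncol(mat) < 2L)
        stop("need at least 2 samples to compute variances")
    v <- apply(mat, 1L, stats::var)
    mat[v >= threshold, , drop = FALSE]
}

#' Correlate all genes to a query gene
#'
#' Pearson correlation of every row of the expression matrix with the
#' query gene's row, across samples. Genes with zero variance (which
#' cannot occur after [filterLowVariance()] with a positive threshold)
#' have an undefined correlation and are excluded with a warning.
#'
#' @param mat numeric matrix, genes in rows (>= 3 samples).
#' @param queryGene row name of the query gene.
#' @param varianceThreshold optional, recorded in the result for
#'   provenance.
#' @return A [CoexpressionResult-class].
#' @export
correlateToGene <- function(mat, queryGene, varianceThreshold = NA_real_) {
    stopifnot(is.matrix(mat), is.numeric(mat))
    if (!queryGene %in% rownames(mat))
        stop("query gene not found in matrix: ", queryGene)
    if (ncol(mat) < 3L)
        stop("need at least 3 samples for correlation")
    r <- suppressWarnings(
        drop(stats::cor(t(mat), mat[queryGene, ], method = "pearson")))
    names(r) <- rownames(mat)
    if (anyNA(r)) {
        warning(sum(is.na(r)), " gene(s) with undefined correlation ",
                "(zero variance) excluded")
        r <- r[!is.na(r)]
    }
    new("CoexpressionResult",
        queryGene = queryGene,
        correlations = r,
        varianceThreshold = as.numeric(varianceThreshold))
}

#' Select co-expressed partner genes above a correlation cut-off
#'
#' Genes whose Pearson correlation to the query is at least `cutoff`,
#' excluding the query itself, sorted by descending correlation with
#' lexicographic tie-breaking.
#'
#' @param result a [CoexpressionResult-class].
#' @param cutoff correlation cut-off in \[-1, 1\] (default 0.7).
#' @return Character vector of selected gene ids.
#' @export
selectCoexpressed <- function(result, cutoff = 0.7) {
    stopifnot(is(result, "CoexpressionResult"))
    if (cutoff < -1 || cutoff > 1)
        stop("cutoff must lie in [-1, 1]")
    r <- result@correlations
    r <- r[names(r) != result@queryGene]
    r <- r[r >= cutoff]
    names(r)[order(-r, names(r))]
}
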