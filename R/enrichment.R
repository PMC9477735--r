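#' @include AllClasses.R
NULL

# Relative tolerance for point-probability ties in the two-sided rule.
.FISHER_REL_TOL <- 1e-7

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided P value for a 2x2 contingency table with fixed margins,
#' under the minimum-likelihood rule: the sum of hypergeometric point
#' probabilities over all tables (with the observed margins) whose point
#' probability does not exceed that of the observed table, with a 1e-7
#' relative tolerance for ties. This is the convention of mainstream
#' statistical software. Point probabilities are evaluated in log space,
#' so the computation is stable at screen scale (margins of order 1e6).
#'
#' All four arguments are vectorized; `(a, b)` is one population's
#' (in-gene, all-other) split and `(c, d)` the other's.
#'
#' @param a,b,c,d non-negative integer counts; both row sums `a + b` and
#'   `c + d` must be positive.
#' @return P values in (0, 1].
#' @examples
#' fisherTwoSided(5, 95, 5, 95)   # identical proportions: 1
#' fisherTwoSided(20, 980, 80, 920)
#' @export
fisherTwoSided <- function(a, b, c, d) {
    n <- length(a)
    stopifnot(length(b) == n, length(c) == n, length(d) == n)
    .checkCounts(c(a, b, c, d), "contingency counts")
    if (any(a + b <= 0) || any(c + d <= 0))
        stop("degenerate table: a row sum is zero")
    p <- vapply(seq_len(n), function(i)
        .fisher1(a[i], b[i], c[i], d[i]), numeric(1))
    pmin(p, 1)
}

.fisher1 <- function(a, b, c, d) {
    m <- a + b                       # high-population margin
    nn <- c + d                      # low-population margin
    k <- a + c                       # in-gene column margin
    lo <- max(0, k - nn)
    hi <- min(k, m)
    lp <- stats::dhyper(lo:hi, m, nn, k, log = TRUE)
    lobs <- stats::dhyper(a, m, nn, k, log = TRUE)
    sum(exp(lp[lp <= lobs + log1p(.FISHER_REL_TOL)]))
}

#' Benjamini-Hochberg adjusted P values
#'
#' Step-up false-discovery-rate adjustment across one family of tests:
#' for P values sorted ascending, `adj[j] = min(k >= j) min(1, m * p[k] / k)`,
#' returned in the input order. A thin validating interface over
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p numeric vector of raw P values, all in (0, 1].
#' @return Adjusted P values in the input order.
#' @examples
#' benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04))
#' @export
benjaminiHochberg <- function(p) {
    if (!length(p))
        stop("empty P value vector")
    if (any(is.na(p)) || any(p <= 0) || any(p > 1))
        stop("P values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Mutation ratio between sorted populations
#'
#' The fraction of unique sense insertions mapping to a gene in the
#' high-reporter population divided by the corresponding fraction in the
#' low-reporter population: `(a / (a + b)) / (c / (c + d))`. This is the
#' y-axis of the fishtail plot; values below 1 mark candidate positive
#' regulators (insertions depleted from the high population). When
#' `c = 0` and `a > 0` the ratio is `Inf`; when `a = c = 0` it is `NaN`
#' (undefined, such genes carry no insertions and are excluded upstream).
#'
#' @inheritParams fisherTwoSided
#' @return Numeric ratios (possibly `Inf` or `NaN`), vectorized.
#' @examples
#' mutationRatio(20, 80, 5, 95)   # 4
#' @export
mutationRatio <- function(a, b, c, d) {
    if (any(a + b <= 0) || any(c + d <= 0))
        stop("degenerate table: a row sum is zero")
    (a / (a + b)) / (c / (c + d))
}

#' Analyse a haploid gene-trap screen
#'
#' The screen statistic end to end: per-gene two-sided Fisher's exact
#' test on the 2x2 insertion-count tables, Benjamini-Hochberg adjustment
#' across all tested genes as one family, mutation ratio and combined
#' unique-mutation count (the fishtail coordinates), and hit calling.
#' A regulator direction is assigned only to genes with
#' `p_adj < alpha`: `positive_regulator` when the mutation ratio is below
#' 1, `negative_regulator` when above 1.
#'
#' Genes with no insertions in either population (`a = c = 0`) are
#' untestable and dropped before testing. No minimum-insertion prefilter
#' is applied by default (`minCombined = 0`).
#'
#' @param tables `data.frame` with columns `gene_id`, `a`, `b`, `c`, `d`
#'   (see [buildContingencies()]).
#' @param alpha FDR threshold for hit calling (default 0.05).
#' @param minCombined optional minimum `a + c` for a gene to be tested.
#' @return A [S4Vectors::DataFrame] with one row per tested gene, sorted
#'   by `p_adj` then `gene_id`, with columns `gene_id`, `a`, `b`, `c`,
#'   `d`, `p`, `p_adj`, `ratio`, `combined`, `direction`.
#' @examples
#' tab <- data.frame(gene_id = c("nul", "hit"),
#'                   a = c(10, 0), b = c(990, 1000),
#'                   c = c(12, 40), d = c(988, 960))
#' analyzeScreen(tab)
#' @export
analyzeScreen <- function(tables, alpha = 0.05, minCombined = 0) {
    tables <- as.data.frame(tables)
    need <- c("gene_id", "a", "b", "c", "d")
    if (!all(need %in% names(tables)))
        stop("tables must have columns: ", paste(need, collapse = ", "))
    if (!nrow(tables))
        stop("empty input: no contingency tables")
    combined <- tables$a + tables$c
    keep <- combined > 0 & combined >= minCombined
    tables <- tables[keep, , drop = FALSE]
    if (!nrow(tables))
        stop("no testable genes after filtering")

    p <- fisherTwoSided(tables$a, tables$b, tables$c, tables$d)
    padj <- benjaminiHochberg(p)
    ratio <- mutationRatio(tables$a, tables$b, tables$c, tables$d)
    direction <- rep("none", nrow(tables))
    sig <- padj < alpha
    direction[sig & ratio < 1] <- "positive_regulator"
    direction[sig & ratio > 1] <- "negative_regulator"

    res <- S4Vectors::DataFrame(
        gene_id = tables$gene_id,
        a = tables$a, b = tables$b, c = tables$c, d = tables$d,
        p = p, p_adj = padj,
        ratio = ratio,
        combined = tables$a + tables$c,
        direction = direction)
    res <- res[order(res$p_adj, res$gene_id), ]
    rownames(res) <- NULL
    S4Vectors::metadata(res) <- list(alpha = alpha,
                                     minCombined = minCombined)
    res
}

#' Read a processed per-gene screen count table
#'
#' Reads the published tabular screen results schema: gene symbol, the
#' gene's unique mutation count in the low-reporter population, all other
#' low-population mutations, the gene's count in the high-reporter
#' population, all other high-population mutations, then the reported P
#' value and FDR-corrected P value (low counts precede high counts).
#' The reported P columns are retained so recomputed statistics can be
#' validated against them with [validateReportedStatistics()].
#'
#' @param path TSV or CSV file with the seven documented columns.
#' @return `data.frame` with columns `gene_id`, `a`, `b`, `c`, `d`
#'   (a/b = high population, c/d = low population), `p_reported`,
#'   `p_adj_reported`.
#' @export
readSupplementaryTable <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tbl <- utils::read.table(path, sep = sep, header = TRUE,
                             stringsAsFactors = FALSE, quote = "\"",
                             check.names = FALSE, comment.char = "")
    if (ncol(tbl) < 7L)
        stop("format error: expected 7 columns ",
             "(gene, low-in-gene, low-other, high-in-gene, high-other, ",
             "P, adjusted P), found ", ncol(tbl))
    cnt <- tbl[, 2:5]
    for (j in seq_along(cnt)) {
        v <- suppressWarnings(as.numeric(cnt[[j]]))
        if (any(is.na(v)) || any(v != round(v)) || any(v < 0))
            stop("format error: non-integer count in column ", j + 1L)
        cnt[[j]] <- as.integer(v)
    }
    data.frame(gene_id = as.character(tbl[[1L]]),
               a = cnt[[3L]], b = cnt[[4L]],
               c = cnt[[1L]], d = cnt[[2L]],
               p_reported = as.numeric(tbl[[6L]]),
               p_adj_reported = as.numeric(tbl[[7L]]),
               stringsAsFactors = FALSE)
}

#' Validate reported screen statistics by recomputation
#'
#' Recomputes the two-sided Fisher P values and Benjamini-Hochberg
#' adjusted P values from the per-gene counts of a published screen table
#' and compares them with the table's reported columns.
#'
#' @param tbl `data.frame` from [readSupplementaryTable()].
#' @param alpha FDR threshold used for the hit-set concordance summary.
#' @return A list with the recomputed `results` DataFrame, the maximum
#'   absolute and relative deviations of recomputed from reported values
#'   (`maxAbsDiffP`, `maxRelDiffP`, `maxAbsDiffPAdj`, `maxRelDiffPAdj`)
#'   and the hit-set concordance at `alpha` (`nReportedHits`,
#'   `nRecomputedHits`, `nConcordantHits`).
#' @export
validateReportedStatistics <- function(tbl, alpha = 0.05) {
    res <- analyzeScreen(tbl, alpha = alpha)
    m <- match(res$gene_id, tbl$gene_id)
    pRep <- tbl$p_reported[m]
    qRep <- tbl$p_adj_reported[m]
    relDiff <- function(x, y) {
        ok <- !is.na(y) & y > 0
        if (!any(ok)) return(NA_real_)
        max(abs(x[ok] - y[ok]) / y[ok])
    }
    repHits <- tbl$gene_id[!is.na(tbl$p_adj_reported) &
                           tbl$p_adj_reported < alpha]
    newHits <- res$gene_id[res$p_adj < alpha]
    list(results = res,
         maxAbsDiffP = max(abs(res$p - pRep), na.rm = TRUE),
         maxRelDiffP = relDiff(res$p, pRep),
         maxAbsDiffPAdj = max(abs(res$p_adj - qRep), na.rm = TRUE),
         maxRelDiffPAdj = relDiff(res$p_adj, qRep),
         nReportedHits = length(repHits),
         nRecomputedHits = length(newHits),
         nConcordantHits = length(intersect(repHits, newHits)))
}

#' Write screen enrichment results to TSV
#'
#' Serializes the [analyzeScreen()] output with an infinite mutation
#' ratio written as the literal `inf`. The fishtail plot coordinates are
#' the `combined` (x) and `ratio` (y, log scale) columns.
#'
#' @param results DataFrame or data.frame from [analyzeScreen()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeResults <- function(results, path) {
    results <- as.data.frame(results)
    if (!nrow(results))
        stop("empty results")
    out <- results
    out$ratio <- ifelse(is.infinite(out$ratio), "inf",
                        format(out$ratio, digits = 15, trim = TRUE,
                               scientific = FALSE))
    status <- try(utils::write.table(out, path, sep = "\t", quote = FALSE,
                                     row.names = FALSE), silent = TRUE)
    if (inherits(status, "try-error"))
        stop("failed writing ", path, ": ", attr(status, "condition")$message)
    invisible(path)
}
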