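#' @include AllClasses.R
NULL

.STRANDS <- c("+", "-")
.POPULATIONS <- c("high", "low")

#' Read gene-trap insertion sites from a BED-like file
#'
#' Parses a BED file of single-bp integration sites (chrom, start, end,
#' name, score, strand; 0-based half-open on disk) into a `GRanges` of
#' width-1 sites labelled with the sorted population they came from.
#' Every data line is validated; malformed lines are rejected with an
#' error naming the line number. Lines starting with `#`, `track` or
#' `browser` are skipped.
#'
#' @param path path to the BED file.
#' @param population population label, `"high"` or `"low"`.
#' @return `GRanges` of insertion sites with `strand` set and a
#'   `population` metadata column (1-based positions in R).
#' @seealso [writeFixture()], [deduplicateInsertions()]
#' @export
readInsertions <- function(path, population = c("high", "low")) {
    population <- match.arg(population)
    if (!file.exists(path))
        stop("file not found: ", path)
    lines <- readLines(path)
    keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
    lineNo <- which(keep)
    lines <- lines[keep]
    if (!length(lines)) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr)$population <- character()
        return(gr)
    }

    fields <- strsplit(lines, "\t", fixed = TRUE)
    n <- lengths(fields)
    if (any(n < 6L))
        stop("format error at line ", lineNo[which(n < 6L)[1L]],
             ": expected >= 6 BED columns incl. strand")
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    strand <- vapply(fields, `[[`, "", 6L)
    bad <- is.na(start) | is.na(end) | start < 0
    if (any(bad))
        stop("format error at line ", lineNo[which(bad)[1L]],
             ": non-numeric or negative coordinates")
    if (any(start > end))
        stop("format error at line ", lineNo[which(start > end)[1L]],
             ": start > end")
    if (any(!strand %in% .STRANDS))
        stop("format error at line ",
             lineNo[which(!strand %in% .STRANDS)[1L]],
             ": strand must be + or -")
    gr <- GenomicRanges::GRanges(
        seqnames = chrom,
        ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                                  width = 1L),
        strand = strand)
    S4Vectors::mcols(gr)$population <- rep(population, length(gr))
    gr
}

#' Read a gene annotation from BED6 or GFF/GTF
#'
#' BED6 files are read with the gene id taken from the name column
#' (0-based half-open coordinates converted on ingestion). GFF/GTF files
#' (detected by extension) are imported with [rtracklayer::import()],
#' restricted to `gene` features, with the id taken from `gene_id`, `ID`
#' or `Name` attributes; their 1-based coordinates are used as is.
#'
#' @param path path to a BED6 or GFF/GTF annotation.
#' @return A named `GRanges` of gene bodies.
#' @export
readAnnotation <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    if (grepl("\\.(gff3?|gtf)$", path, ignore.case = TRUE)) {
        gr <- rtracklayer::import(path)
        if ("type" %in% names(S4Vectors::mcols(gr)))
            gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
        mc <- S4Vectors::mcols(gr)
        id <- if ("gene_id" %in% names(mc)) mc$gene_id
              else if ("ID" %in% names(mc)) mc$ID
              else mc$Name
        if (is.null(id))
            stop("annotation has no gene_id/ID/Name attribute")
        names(gr) <- as.character(id)
        S4Vectors::mcols(gr) <- NULL
    } else {
        lines <- readLines(path)
        keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
        lineNo <- which(keep)
        fields <- strsplit(lines[keep], "\t", fixed = TRUE)
        if (!length(fields))
            stop("empty annotation: ", path)
        if (any(lengths(fields) < 6L))
            stop("format error at line ",
                 lineNo[which(lengths(fields) < 6L)[1L]],
                 ": expected BED6")
        start <- as.numeric(vapply(fields, `[[`, "", 2L))
        end <- as.numeric(vapply(fields, `[[`, "", 3L))
        if (any(is.na(start)) || any(is.na(end)) || any(start >= end))
            stop("invalid annotation: start must be < end")
        gr <- GenomicRanges::GRanges(
            seqnames = vapply(fields, `[[`, "", 1L),
            ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                                      end = as.integer(end)),
            strand = vapply(fields, `[[`, "", 6L))
        names(gr) <- vapply(fields, `[[`, "", 4L)
    }
    gr
}

#' Deduplicate insertion sites to unique integration events
#'
#' A unique insertion is identified by (chromosome, position, strand);
#' duplicate records arising from sequencing the same integration more
#' than once are collapsed. The output is sorted by chromosome, position
#' and strand, and the operation is idempotent.
#'
#' @param sites `GRanges` of insertion sites from a single population.
#' @return Sorted `GRanges` with at most one record per
#'   (chromosome, position, strand).
#' @export
deduplicateInsertions <- function(sites) {
    stopifnot(is(sites, "GRanges"))
    pop <- S4Vectors::mcols(sites)$population
    if (!is.null(pop) && length(unique(pop)) > 1L)
        stop("mixed population labels: deduplicate one population at a time")
    if (!length(sites))
        return(sites)
    o <- order(as.character(GenomeInfoDb::seqnames(sites)),
               BiocGenerics::start(sites),
               as.character(BiocGenerics::strand(sites)))
    sites <- sites[o]
    key <- paste(GenomeInfoDb::seqnames(sites),
                 BiocGenerics::start(sites),
                 BiocGenerics::strand(sites))
    sites[!duplicated(key)]
}

#' Count unique sense insertions per gene
#'
#' A site is counted for a gene when it falls within the gene body
#' (half-open file coordinates; closed 1-based intervals in R) on the
#' gene's strand, i.e. in the sense orientation of the gene-trap cassette.
#' Antisense and intergenic sites contribute to no gene and are excluded
#' from `totalMapped`. With overlapping gene annotations a sense site is
#' counted once for each gene it falls in, but contributes only once to
#' `totalMapped`.
#'
#' @param sites deduplicated `GRanges` of insertion sites.
#' @param annotation named `GRanges` of gene bodies.
#' @return A list with `counts` (named integer, one entry per annotated
#'   gene) and `totalMapped` (number of distinct sites assigned to at
#'   least one gene).
#' @export
mapToGenes <- function(sites, annotation) {
    stopifnot(is(sites, "GRanges"), is(annotation, "GRanges"))
    if (any(BiocGenerics::width(annotation) < 1L))
        stop("invalid annotation: empty gene body (start >= end)")
    if (is.null(names(annotation)) || any(!nzchar(names(annotation))))
        stop("invalid annotation: genes must be named")
    counts <- GenomicRanges::countOverlaps(annotation, sites)
    names(counts) <- names(annotation)
    totalMapped <- sum(GenomicRanges::countOverlaps(sites, annotation) > 0L)
    list(counts = as.integer(counts) |> stats::setNames(names(annotation)),
         totalMapped = as.integer(totalMapped))
}

#' Build per-gene 2x2 contingency tables
#'
#' For each gene, `a` is its unique sense insertion count in the
#' high-reporter population, `b` all other unique sense gene-mapped
#' insertions in that population, and `c`/`d` the same for the
#' low-reporter population. Genes absent from one population get a zero
#' count there.
#'
#' @param highCounts,lowCounts named integer vectors of per-gene counts
#'   (from [mapToGenes()]).
#' @param totalHigh,totalLow total unique sense gene-mapped insertions
#'   per population.
#' @return `data.frame` with columns `gene_id`, `a`, `b`, `c`, `d`.
#' @export
buildContingencies <- function(highCounts, lowCounts, totalHigh, totalLow) {
    genes <- union(names(highCounts), names(lowCounts))
    if (!length(genes))
        stop("no genes in input counts")
    a <- ifelse(genes %in% names(highCounts), highCounts[genes], 0L)
    c_ <- ifelse(genes %in% names(lowCounts), lowCounts[genes], 0L)
    a[is.na(a)] <- 0L
    c_[is.na(c_)] <- 0L
    if (any(a > totalHigh))
        stop("inconsistent counts: gene count exceeds totalHigh")
    if (any(c_ > totalLow))
        stop("inconsistent counts: gene count exceeds totalLow")
    data.frame(gene_id = genes,
               a = as.integer(a),
               b = as.integer(totalHigh - a),
               c = as.integer(c_),
               d = as.integer(totalLow - c_),
               stringsAsFactors = FALSE)
}

#' Per-gene contingency tables from a simulated screen
#'
#' In-memory equivalent of [contingenciesFromFiles()] for a
#' [SimulatedScreen-class]: deduplicates each population's recovered
#' insertions, counts unique sense insertions per gene and builds the
#' per-gene 2x2 tables.
#'
#' @param screen a [SimulatedScreen-class].
#' @return `data.frame` as returned by [buildContingencies()].
#' @export
contingenciesFromScreen <- function(screen) {
    stopifnot(is(screen, "SimulatedScreen"))
    ann <- screen@annotation
    high <- deduplicateInsertions(screen@insertionsHigh)
    low <- deduplicateInsertions(screen@insertionsLow)
    mh <- mapToGenes(high, ann)
    ml <- mapToGenes(low, ann)
    buildContingencies(mh$counts, ml$counts, mh$totalMapped, ml$totalMapped)
}

#' Per-gene contingency tables straight from files
#'
#' Convenience wrapper running the whole mapping stage: read both
#' insertion files, deduplicate, assign sense insertions to gene bodies
#' and build the per-gene 2x2 tables.
#'
#' @param highPath,lowPath BED-like insertion files per population.
#' @param annotationPath BED6 or GFF gene annotation.
#' @return `data.frame` as returned by [buildContingencies()].
#' @export
contingenciesFromFiles <- function(highPath, lowPath, annotationPath) {
    ann <- readAnnotation(annotationPath)
    high <- deduplicateInsertions(readInsertions(highPath, "high"))
    low <- deduplicateInsertions(readInsertions(lowPath, "low"))
    mh <- mapToGenes(high, ann)
    ml <- mapToGenes(low, ann)
    buildContingencies(mh$counts, ml$counts, mh$totalMapped, ml$totalMapped)
}
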