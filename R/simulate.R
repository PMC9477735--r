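#' @include AllClasses.R AllGenerics.R
NULL

# Deterministic gene layout given the current RNG state. Genes are placed
# head-to-tail, each followed by an intergenic gap of len * f / (1 - f) bp
# so that a fraction f of the genome is intergenic; strands are uniform
# random. Genes never overlap by construction.
.layoutGenome <- function(config) {
    n <- config@nGenes
    len <- config@geneLength
    lens <- if (length(len) == 1L) rep.int(len, n) else
        sample(seq.int(len[1L], len[2L]), n, replace = TRUE)
    f <- config@intergenicFraction
    gaps <- as.integer(round(lens * f / (1 - f)))
    strands <- sample(c("+", "-"), n, replace = TRUE)

    # contiguous blocks of genes per pseudo-chromosome
    chromOf <- sort(rep_len(seq_len(config@nChromosomes), n))
    starts <- integer(n)
    chromLen <- integer(config@nChromosomes)
    for (k in seq_len(config@nChromosomes)) {
        i <- which(chromOf == k)
        starts[i] <- cumsum(c(1L, (lens + gaps)[i[-length(i)]]))
        chromLen[k] <- sum(lens[i] + gaps[i])
    }
    chroms <- paste0("chr", chromOf)
    seqinfo <- GenomeInfoDb::Seqinfo(
        seqnames = paste0("chr", seq_len(config@nChromosomes)),
        seqlengths = pmax(chromLen, 1L))
    gr <- GenomicRanges::GRanges(
        seqnames = chroms,
        ranges = IRanges::IRanges(start = starts, width = lens),
        strand = strands,
        seqinfo = seqinfo)
    names(gr) <- .geneIds(n)
    gr
}

#' Simulate a toy genome annotation
#'
#' Lays out `nGenes` non-overlapping gene bodies with random strands on one
#' or more pseudo-chromosomes, with the configured intergenic spacing.
#' Deterministic for a given `seed`.
#'
#' @param config a [ScreenSimConfig-class].
#' @return A named [GenomicRanges::GRanges] of gene bodies (1-based,
#'   closed intervals in R; exported fixtures use BED 0-based half-open
#'   coordinates).
#' @examples
#' simulateGenome(ScreenSimConfig(nGenes = 3, geneLength = 1000L, seed = 7))
#' @export
simulateGenome <- function(config) {
    stopifnot(is(config, "ScreenSimConfig"))
    validObject(config)
    .withSeed(config@seed, .layoutGenome(config))
}

#' Simulate a phenotype-sorted gene-trap screen
#'
#' Runs the full generative model of the screen: one gene-trap integration
#' per cell at a uniform genomic position with uniform strand; disruption
#' of a gene only by sense-orientation insertions within the gene body;
#' a log-normal reporter shifted down (positive regulators) or up (negative
#' regulators) with probability `penetrance` when a hit gene is disrupted;
#' quantile sorting of the bottom and top `sortFraction` of cells by
#' reporter intensity; and Bernoulli recovery of each sorted cell's
#' insertion with probability `recoveryRate`. Ties in the reporter ranking
#' are broken by cell index, so the output is bit-reproducible for a given
#' seed.
#'
#' @param config a [ScreenSimConfig-class].
#' @return A [SimulatedScreen-class].
#' @examples
#' cfg <- ScreenSimConfig(nGenes = 50, nCells = 20000,
#'                        hitGenes = c(g0001 = "positive_regulator"),
#'                        penetrance = 1, seed = 42)
#' sim <- simulateScreen(cfg)
#' sim
#' @export
simulateScreen <- function(config) {
    stopifnot(is(config, "ScreenSimConfig"))
    validObject(config)
    nSort <- as.integer(floor(config@nCells * config@sortFraction))
    if (nSort < 1L)
        stop("degenerate sort: nCells * sortFraction < 1")

    .withSeed(config@seed, {
        ann <- .layoutGenome(config)
        n <- config@nCells
        seqlens <- GenomeInfoDb::seqlengths(ann)
        total <- sum(as.numeric(seqlens))
        # uniform position over the concatenated genome
        u <- ceiling(stats::runif(n) * total)
        breaks <- cumsum(as.numeric(seqlens))
        chromIdx <- findInterval(u - 1, c(0, breaks), rightmost.closed = TRUE)
        pos <- as.integer(u - c(0, breaks)[chromIdx])
        strand <- sample(c("+", "-"), n, replace = TRUE)
        cells <- GenomicRanges::GRanges(
            seqnames = names(seqlens)[chromIdx],
            ranges = IRanges::IRanges(start = pos, width = 1L),
            strand = strand,
            seqinfo = GenomeInfoDb::seqinfo(ann))

        logI <- stats::rnorm(n, config@reporterLogMean, config@reporterLogSd)
        penetrant <- stats::runif(n) < config@penetrance
        if (length(config@hitGenes)) {
            hitAnn <- ann[names(config@hitGenes)]
            ov <- GenomicRanges::findOverlaps(cells, hitAnn)
            # sense-only disruption: findOverlaps with stranded subject
            # already requires matching strands
            i <- S4Vectors::queryHits(ov)
            dir <- unname(config@hitGenes[S4Vectors::subjectHits(ov)])
            shift <- ifelse(dir == "positive_regulator",
                            -config@effectLogShift, config@effectLogShift)
            affected <- i[penetrant[i]]
            logI[affected] <- logI[affected] + shift[penetrant[i]]
        }

        ord <- order(logI)                  # stable: ties broken by index
        lowIdx <- ord[seq_len(nSort)]
        highIdx <- ord[seq.int(n - nSort + 1L, n)]
        keepLow <- stats::runif(nSort) < config@recoveryRate
        keepHigh <- stats::runif(nSort) < config@recoveryRate

        low <- cells[lowIdx[keepLow]]
        high <- cells[highIdx[keepHigh]]
        S4Vectors::mcols(low)$population <- rep("low", length(low))
        S4Vectors::mcols(high)$population <- rep("high", length(high))

        new("SimulatedScreen",
            annotation = ann,
            insertionsHigh = high,
            insertionsLow = low,
            truth = config@hitGenes,
            config = config)
    })
}

#' Write a simulated screen to plain-text fixture files
#'
#' Emits one BED6 file of insertion sites per sorted population
#' (name = population label, score = 0, 0-based half-open single-bp
#' intervals), the gene annotation as BED6 (name = gene id), the truth
#' table as TSV and the configuration as a flat key-value text file. The
#' files round-trip through [readInsertions()] and [readAnnotation()].
#'
#' @param screen a [SimulatedScreen-class].
#' @param directory output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
writeFixture <- function(screen, directory) {
    stopifnot(is(screen, "SimulatedScreen"))
    if (!dir.exists(directory) &&
        !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create directory: ", directory)

    paths <- c(
        high = file.path(directory, "insertions_high.bed"),
        low = file.path(directory, "insertions_low.bed"),
        annotation = file.path(directory, "annotation.bed"),
        truth = file.path(directory, "truth.tsv"),
        config = file.path(directory, "config.txt"))

    .exportBed <- function(gr, name, path) {
        S4Vectors::mcols(gr) <- NULL
        if (length(gr)) {
            S4Vectors::mcols(gr)$name <- name
            S4Vectors::mcols(gr)$score <- 0L
        }
        tryCatch(rtracklayer::export(gr, path, format = "BED"),
                 error = function(e)
                     stop("failed writing ", path, ": ",
                          conditionMessage(e), call. = FALSE))
    }
    .exportBed(screen@insertionsHigh, rep("high", length(screen@insertionsHigh)),
               paths[["high"]])
    .exportBed(screen@insertionsLow, rep("low", length(screen@insertionsLow)),
               paths[["low"]])
    .exportBed(screen@annotation, names(screen@annotation),
               paths[["annotation"]])

    truth <- data.frame(gene_id = names(screen@truth),
                        direction = unname(screen@truth))
    utils::write.table(truth, paths[["truth"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)

    cfg <- screen@config
    kv <- c(nGenes = cfg@nGenes,
            geneLength = paste(cfg@geneLength, collapse = "-"),
            intergenicFraction = cfg@intergenicFraction,
            nChromosomes = cfg@nChromosomes,
            nCells = cfg@nCells,
            hitGenes = paste(sprintf("%s:%s", names(cfg@hitGenes),
                                     cfg@hitGenes), collapse = ","),
            penetrance = cfg@penetrance,
            reporterLogMean = cfg@reporterLogMean,
            reporterLogSd = cfg@reporterLogSd,
            effectLogShift = cfg@effectLogShift,
            sortFraction = cfg@sortFraction,
            recoveryRate = cfg@recoveryRate,
            seed = cfg@seed)
    writeLines(paste(names(kv), unname(kv), sep = "\t"), paths[["config"]])

    invisible(paths)
}
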