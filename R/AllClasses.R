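#' Configuration for a simulated haploid gene-trap screen
#'
#' An S4 container for every generative parameter of the screen simulator:
#' the toy genome layout, the number of mutagenized cells, the identity and
#' direction of planted regulator ("hit") genes, the reporter model, and the
#' FACS sorting/recovery model. A single integer seed makes the whole
#' simulation reproducible.
#'
#' The simulated screen mirrors a phenotype-sorted haploid mutagenesis
#' experiment: each near-haploid cell carries exactly one gene-trap
#' integration at a uniform genomic position with uniform random strand.
#' An integration disrupts a gene only when it falls within the gene body
#' in the sense orientation (classic gene-trap behaviour). Reporter
#' intensity is log-normal; disrupting a planted positive regulator shifts
#' the log-intensity down by `effectLogShift` (negative regulators shift it
#' up) with probability `penetrance`. Cells are ranked by reporter intensity
#' and the bottom and top `sortFraction` quantiles are sorted into the
#' "low" and "high" populations; each sorted cell's insertion is recovered
#' by sequencing with probability `recoveryRate`.
#'
#' @slot nGenes integer, number of annotated genes in the toy genome.
#' @slot geneLength integer of length 1 (fixed length, bp) or 2 (range to
#'   sample uniformly per gene).
#' @slot intergenicFraction numeric in \[0, 1): fraction of the genome that
#'   is intergenic; each gene of length L is followed by a gap of
#'   L * f / (1 - f) bp.
#' @slot nChromosomes integer, number of pseudo-chromosomes (default 1).
#' @slot nCells integer, number of independently mutagenized cells.
#' @slot hitGenes named character: names are gene ids, values are
#'   `"positive_regulator"` or `"negative_regulator"`.
#' @slot penetrance numeric in \[0, 1\], probability that a sense insertion
#'   in a hit gene actually shifts the reporter.
#' @slot reporterLogMean,reporterLogSd numeric, log-scale location and
#'   spread of the reporter intensity distribution (sd > 0).
#' @slot effectLogShift numeric, magnitude of the log-scale reporter shift
#'   in affected cells.
#' @slot sortFraction numeric in (0, 1\]; the default 0.04 sorts the bottom
#'   4 percent and top 4 percent of cells, as in typical reporter screens.
#' @slot recoveryRate numeric in (0, 1\], probability a sorted cell's
#'   insertion is recovered by sequencing.
#' @slot seed integer seed for all random draws.
#'
#' @seealso [simulateScreen()], [simulateGenome()]
#' @export
setClass("ScreenSimConfig",
    representation(
        nGenes = "integer",
        geneLength = "integer",
        intergenicFraction = "numeric",
        nChromosomes = "integer",
        nCells = "integer",
        hitGenes = "character",
        penetrance = "numeric",
        reporterLogMean = "numeric",
        reporterLogSd = "numeric",
        effectLogShift = "numeric",
        sortFraction = "numeric",
        recoveryRate = "numeric",
        seed = "integer"
    )
)

.validScreenSimConfig <- function(object) {
    msg <- character()
    if (length(object@nGenes) != 1L || is.na(object@nGenes) ||
        object@nGenes < 1L)
        msg <- c(msg, "nGenes must be a single integer >= 1")
    if (!length(object@geneLength) %in% 1:2 ||
        any(is.na(object@geneLength)) || any(object@geneLength < 1L))
        msg <- c(msg, "geneLength must be one positive length or a range")
    if (length(object@geneLength) == 2L &&
        object@geneLength[1L] > object@geneLength[2L])
        msg <- c(msg, "geneLength range must be increasing")
    if (object@intergenicFraction < 0 || object@intergenicFraction >= 1)
        msg <- c(msg, "intergenicFraction must be in [0, 1)")
    if (object@nChromosomes < 1L || object@nChromosomes > object@nGenes)
        msg <- c(msg, "nChromosomes must be in [1, nGenes]")
    if (object@nCells < 1L)
        msg <- c(msg, "nCells must be >= 1")
    if (length(object@hitGenes)) {
        if (is.null(names(object@hitGenes)) ||
            any(!nzchar(names(object@hitGenes))))
            msg <- c(msg, "hitGenes must be named by gene id")
        bad <- setdiff(object@hitGenes,
                       c("positive_regulator", "negative_regulator"))
        if (length(bad))
            msg <- c(msg, paste0("unknown hit direction: ",
                                 paste(bad, collapse = ", ")))
        missing <- setdiff(names(object@hitGenes), .geneIds(object@nGenes))
        if (length(missing))
            msg <- c(msg, paste0("hitGenes not in the simulated genome: ",
                                 paste(missing, collapse = ", ")))
    }
    for (p in c("penetrance", "recoveryRate", "sortFraction")) {
        v <- slot(object, p)
        if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
            msg <- c(msg, paste0(p, " must be a single value in [0, 1]"))
    }
    if (object@sortFraction <= 0)
        msg <- c(msg, "sortFraction must be > 0")
    if (object@recoveryRate <= 0)
        msg <- c(msg, "recoveryRate must be > 0")
    if (object@reporterLogSd <= 0)
        msg <- c(msg, "reporterLogSd must be > 0")
    if (length(msg)) msg else TRUE
}

setValidity("ScreenSimConfig", .validScreenSimConfig)

.geneIds <- function(n) sprintf("g%04d", seq_len(n))

#' Create a screen simulation configuration
#'
#' Constructor for [ScreenSimConfig-class]. Defaults describe a 500-gene
#' toy genome (10 kb genes, half of the genome intergenic) screened at
#' 1e5 cells with 4 percent tail sorting, a unit-log-sd reporter, a
#' 3-sd knockout effect with 90 percent penetrance, and 80 percent
#' sequencing recovery of sorted insertions.
#'
#' @param nGenes,geneLength,intergenicFraction,nChromosomes genome layout,
#'   see [ScreenSimConfig-class].
#' @param nCells number of mutagenized cells.
#' @param hitGenes named character vector mapping gene id (e.g. `"g0001"`)
#'   to `"positive_regulator"` or `"negative_regulator"`.
#' @param penetrance,reporterLogMean,reporterLogSd,effectLogShift reporter
#'   model parameters.
#' @param sortFraction,recoveryRate sorting and sequencing model.
#' @param seed integer seed.
#' @return A validated `ScreenSimConfig` object.
#' @examples
#' cfg <- ScreenSimConfig(nGenes = 20, nCells = 1000,
#'                        hitGenes = c(g0005 = "positive_regulator"),
#'                        seed = 1)
#' cfg
#' @export
ScreenSimConfig <- function(nGenes = 500L, geneLength = 10000L,
                            intergenicFraction = 0.5, nChromosomes = 1L,
                            nCells = 100000L, hitGenes = character(),
                            penetrance = 0.9, reporterLogMean = 0,
                            reporterLogSd = 1, effectLogShift = 3,
                            sortFraction = 0.04, recoveryRate = 0.8,
                            seed = 1L) {
    if (any(geneLength < 1) || nGenes < 1 || nCells < 1)
        stop("invalid config: lengths and counts must be positive")
    new("ScreenSimConfig",
        nGenes = as.integer(nGenes),
        geneLength = as.integer(geneLength),
        intergenicFraction = as.numeric(intergenicFraction),
        nChromosomes = as.integer(nChromosomes),
        nCells = as.integer(nCells),
        hitGenes = hitGenes,
        penetrance = as.numeric(penetrance),
        reporterLogMean = as.numeric(reporterLogMean),
        reporterLogSd = as.numeric(reporterLogSd),
        effectLogShift = as.numeric(effectLogShift),
        sortFraction = as.numeric(sortFraction),
        recoveryRate = as.numeric(recoveryRate),
        seed = as.integer(seed))
}

#' A simulated haploid gene-trap screen with known ground truth
#'
#' Holds the simulated gene annotation, the unique-ready insertion sites
#' recovered from the high- and low-reporter sorted populations (as
#' [GenomicRanges::GRanges] of width-1 integration sites with strand), the
#' truth mapping of planted hit genes, and the generating configuration.
#'
#' @slot annotation `GRanges` of gene bodies, named by gene id.
#' @slot insertionsHigh,insertionsLow `GRanges` of recovered insertion
#'   sites per sorted population, with a `population` metadata column.
#' @slot truth named character, gene id to regulator direction.
#' @slot config the generating [ScreenSimConfig-class].
#' @seealso [simulateScreen()], [writeFixture()]
#' @export
setClass("SimulatedScreen",
    representation(
        annotation = "GRanges",
        insertionsHigh = "GRanges",
        insertionsLow = "GRanges",
        truth = "character",
        config = "ScreenSimConfig"
    )
)

.validSimulatedScreen <- function(object) {
    msg <- character()
    chroms <- GenomeInfoDb::seqlevels(object@annotation)
    for (s in c("insertionsHigh", "insertionsLow")) {
        ins <- slot(object, s)
        if (length(ins) &&
            !all(as.character(GenomeInfoDb::seqnames(ins)) %in% chroms))
            msg <- c(msg, paste0(s, " lie outside the simulated genome"))
    }
    if (!identical(object@truth, object@config@hitGenes))
        msg <- c(msg, "truth does not match config hitGenes")
    if (length(msg)) msg else TRUE
}

setValidity("SimulatedScreen", .validSimulatedScreen)

#' Correlations of an expression atlas to one query gene
#'
#' Result container for [correlateToGene()]: the Pearson correlation of
#' every retained atlas gene to the query gene, together with the variance
#' threshold that was applied upstream.
#'
#' @slot queryGene character, the query gene id.
#' @slot correlations named numeric in \[-1, 1\], one value per gene
#'   (including the query itself, r = 1).
#' @slot varianceThreshold numeric, the row-variance filter applied before
#'   correlation (NA if unknown).
#' @seealso [selectCoexpressed()]
#' @export
setClass("CoexpressionResult",
    representation(
        queryGene = "character",
        correlations = "numeric",
        varianceThreshold = "numeric"
    )
)

setValidity("CoexpressionResult", function(object) {
    msg <- character()
    if (length(object@queryGene) != 1L)
        msg <- c(msg, "queryGene must be a single id")
    if (is.null(names(object@correlations)))
        msg <- c(msg, "correlations must be named by gene id")
    r <- object@correlations[!is.na(object@correlations)]
    if (length(r) && (min(r) < -1 - 1e-12 || max(r) > 1 + 1e-12))
        msg <- c(msg, "correlations must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
})

#' A fitted four-parameter logistic dose-response curve
#'
#' Parameters of the 4PL model
#' `y = bottom + (top - bottom) / (1 + (ec50 / x)^hill)` fitted by
#' [fit4PL()]. By construction the fitted response at `x = ec50` equals
#' `(top + bottom) / 2`, the half-maximal response.
#'
#' @slot bottom,top numeric plateaus, in response units.
#' @slot ec50 numeric > 0, half-maximal effective concentration, in dose
#'   units.
#' @slot hill numeric, dimensionless slope; negative for curves that
#'   decrease with dose.
#' @slot residualSse numeric >= 0, residual sum of squares of the fit.
#' @slot extrapolated logical, TRUE when the fitted EC50 lies outside the
#'   observed dose range.
#' @export
setClass("DoseResponseFit",
    representation(
        bottom = "numeric",
        top = "numeric",
        ec50 = "numeric",
        hill = "numeric",
        residualSse = "numeric",
        extrapolated = "logical"
    )
)

setValidity("DoseResponseFit", function(object) {
    msg <- character()
    if (object@ec50 <= 0) msg <- c(msg, "ec50 must be > 0")
    if (object@residualSse < 0) msg <- c(msg, "residualSse must be >= 0")
    if (identical(object@top, object@bottom))
        msg <- c(msg, "top must differ from bottom for a valid fit")
    if (length(msg)) msg else TRUE
})
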