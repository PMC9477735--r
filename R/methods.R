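#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn ScreenSimConfig-class number of simulated genes
#' @param x a `ScreenSimConfig` or `SimulatedScreen` object.
#' @export
setMethod("nGenes", "ScreenSimConfig", function(x) x@nGenes)

#' @describeIn ScreenSimConfig-class number of mutagenized cells
#' @export
setMethod("nCells", "ScreenSimConfig", function(x) x@nCells)

#' @describeIn ScreenSimConfig-class named direction vector of planted hits
#' @export
setMethod("hitGenes", "ScreenSimConfig", function(x) x@hitGenes)

#' @describeIn ScreenSimConfig-class sorted tail fraction per population
#' @export
setMethod("sortFraction", "ScreenSimConfig", function(x) x@sortFraction)

setMethod("show", "ScreenSimConfig", function(object) {
    cat("ScreenSimConfig\n")
    cat("  genome: ", object@nGenes, " genes (",
        paste(object@geneLength, collapse = "-"), " bp) on ",
        object@nChromosomes, " chromosome(s), intergenic fraction ",
        object@intergenicFraction, "\n", sep = "")
    cat("  cells:  ", object@nCells, ", sort fraction ",
        object@sortFraction, ", recovery ", object@recoveryRate,
        "\n", sep = "")
    cat("  hits:   ", length(object@hitGenes), " gene(s), penetrance ",
        object@penetrance, ", effect ", object@effectLogShift,
        " log-units\n", sep = "")
    cat("  reporter: logN(", object@reporterLogMean, ", ",
        object@reporterLogSd, "), seed ", object@seed, "\n", sep = "")
})

#' @describeIn SimulatedScreen-class the simulated gene annotation
#' @param object a `SimulatedScreen`.
#' @export
setMethod("annotation", "SimulatedScreen", function(object, ...)
    object@annotation)

#' @describeIn SimulatedScreen-class recovered insertions of one population
#' @param x a `SimulatedScreen`.
#' @param population `"high"` or `"low"`.
#' @export
setMethod("insertions", "SimulatedScreen",
    function(x, population = c("high", "low")) {
        population <- match.arg(population)
        if (population == "high") x@insertionsHigh else x@insertionsLow
    })

#' @describeIn SimulatedScreen-class ground-truth hit directions
#' @export
setMethod("screenTruth", "SimulatedScreen", function(x) x@truth)

setMethod("show", "SimulatedScreen", function(object) {
    cat("SimulatedScreen\n")
    cat("  annotation:", length(object@annotation), "genes on",
        length(GenomeInfoDb::seqlevels(object@annotation)),
        "chromosome(s)\n")
    cat("  insertions: high =", length(object@insertionsHigh),
        ", low =", length(object@insertionsLow), "\n")
    if (length(object@truth))
        cat("  truth:", paste(names(object@truth), object@truth,
                              sep = "=", collapse = ", "), "\n")
    else cat("  truth: no planted hits\n")
})

#' @describeIn CoexpressionResult-class named correlation vector
#' @param x a `CoexpressionResult`.
#' @export
setMethod("correlations", "CoexpressionResult", function(x) x@correlations)

setMethod("show", "CoexpressionResult", function(object) {
    r <- sort(object@correlations, decreasing = TRUE)
    r <- r[names(r) != object@queryGene]
    cat("CoexpressionResult for", object@queryGene, "over",
        length(object@correlations), "genes\n")
    if (!is.na(object@varianceThreshold))
        cat("  variance filter: sigma^2 >=", object@varianceThreshold, "\n")
    top <- utils::head(r, 5L)
    cat("  top partners:",
        paste(sprintf("%s (r=%.3f)", names(top), top), collapse = ", "),
        "\n")
})

#' @describeIn DoseResponseFit-class half-maximal effective concentration
#' @param x a `DoseResponseFit`.
#' @export
setMethod("ec50", "DoseResponseFit", function(x) x@ec50)

#' @describeIn DoseResponseFit-class all four parameters as a named vector
#' @param object a `DoseResponseFit`.
#' @param ... ignored.
#' @export
setMethod("coef", "DoseResponseFit", function(object, ...)
    c(bottom = object@bottom, top = object@top,
      ec50 = object@ec50, hill = object@hill))

setMethod("show", "DoseResponseFit", function(object) {
    cat("DoseResponseFit (4PL)\n")
    cat(sprintf("  bottom = %.4g, top = %.4g, hill = %.4g\n",
                object@bottom, object@top, object@hill))
    cat(sprintf("  EC50 = %.4g%s, residual SSE = %.4g\n", object@ec50,
                if (object@extrapolated) " (extrapolated)" else "",
                object@residualSse))
})
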