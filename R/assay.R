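#' @include AllClasses.R AllGenerics.R
NULL

#' Relative response ratio for split-luciferase complementation
#'
#' Normalizes a luminescence reading between a negative control (empty
#' vector) and a positive complementation control, in percent:
#' `RRR = (value - negative) / (positive - negative) * 100`. The result
#' is invariant under a common positive rescaling and offset of all three
#' readings, so it is comparable across plates and instrument gains.
#'
#' @param value mean luminescence of the condition of interest
#'   (arbitrary units); vectorized.
#' @param positive,negative mean luminescence of the positive and
#'   negative controls (same units).
#' @return RRR in percent.
#' @examples
#' relativeResponseRatio(c(200, 650, 1100), positive = 1100, negative = 200)
#' @export
relativeResponseRatio <- function(value, positive, negative) {
    if (any(positive == negative))
        stop("positive and negative controls are equal: division by zero")
    (value - negative) / (positive - negative) * 100
}

# 4PL response at dose x. Used both for prediction and inside the fit.
.fourPL <- function(x, bottom, top, ec50, hill)
    bottom + (top - bottom) / (1 + (ec50 / x)^hill)

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of the 4PL model
#' `y = bottom + (top - bottom) / (1 + (ec50 / x)^hill)`
#' by Levenberg-Marquardt ([minpack.lm::nlsLM]), parameterized internally
#' on log(EC50) over log-dose for conditioning. Initial values: `bottom`
#' and `top` from the response extremes, the sign of `hill` from the
#' Spearman rank correlation of dose and response, and EC50 from the dose
#' whose response is nearest the half-range crossing — a robust recipe
#' for the 7-8-point titrations typical of reporter assays. The fit is
#' deterministic for fixed inputs. `bottom` is free by default (reporter
#' assays often have a nonzero baseline); set `constrainBottomZero = TRUE`
#' to pin it at 0.
#'
#' The 4PL parameterization is aliased: `(bottom, top, hill)` and
#' `(top, bottom, -hill)` describe the same curve. Initialization from
#' the data resolves the alias so that `bottom`/`top` track the response
#' extremes and the sign of `hill` encodes the direction of the
#' dose-response (negative for decreasing curves). The EC50 and the
#' fitted curve are alias-invariant.
#'
#' @param doses positive numeric vector of doses (>= 4 distinct values).
#' @param responses numeric responses, same length.
#' @param weights optional non-negative fit weights.
#' @param constrainBottomZero logical, fix `bottom = 0`.
#' @param maxIter maximum Levenberg-Marquardt iterations.
#' @return A [DoseResponseFit-class]; the fitted EC50 is flagged
#'   `extrapolated` when it lies outside the observed dose range.
#' @examples
#' d <- 10^seq(-2, 2, length.out = 8)
#' y <- 0.1 + 0.8 / (1 + (3 / d)^1.2)
#' fit <- fit4PL(d, y)
#' ec50(fit)
#' @export
fit4PL <- function(doses, responses, weights = NULL,
                   constrainBottomZero = FALSE, maxIter = 200L) {
    stopifnot(length(doses) == length(responses))
    if (any(doses <= 0))
        stop("doses must be positive")
    if (length(unique(doses)) < 4L)
        stop("need at least 4 distinct doses")
    if (is.null(weights))
        weights <- rep(1, length(doses))
    rng <- range(responses)
    if (diff(rng) <= 1e-12 * max(1, abs(mean(responses))))
        stop("flat-curve: responses do not vary, 4PL is unidentifiable")

    rs <- suppressWarnings(
        stats::cor(doses, responses, method = "spearman"))
    hill0 <- if (is.na(rs) || rs >= 0) 1 else -1
    half <- mean(rng)
    le0 <- log(doses[which.min(abs(responses - half))])
    dat <- data.frame(x = doses, y = responses)

    fit <- tryCatch({
        if (constrainBottomZero)
            minpack.lm::nlsLM(
                y ~ top / (1 + exp(hill * (le - log(x)))),
                data = dat, weights = weights,
                start = list(top = rng[2], le = le0, hill = hill0),
                control = minpack.lm::nls.lm.control(maxiter = maxIter))
        else
            minpack.lm::nlsLM(
                y ~ bottom + (top - bottom) / (1 + exp(hill * (le - log(x)))),
                data = dat, weights = weights,
                start = list(bottom = rng[1], top = rng[2],
                             le = le0, hill = hill0),
                control = minpack.lm::nls.lm.control(maxiter = maxIter))
    }, error = function(e)
        stop("4PL fit failed: ", conditionMessage(e), call. = FALSE))

    cf <- stats::coef(fit)
    bottom <- if (constrainBottomZero) 0 else unname(cf[["bottom"]])
    top <- unname(cf[["top"]])
    ec <- exp(unname(cf[["le"]]))
    new("DoseResponseFit",
        bottom = bottom,
        top = top,
        ec50 = ec,
        hill = unname(cf[["hill"]]),
        residualSse = sum(stats::resid(fit)^2),
        extrapolated = ec < min(doses) || ec > max(doses))
}

#' Predicted 4PL response at given doses
#'
#' @param object a [DoseResponseFit-class].
#' @param doses positive numeric doses.
#' @param ... ignored.
#' @return Predicted responses.
#' @export
setMethod("predict", "DoseResponseFit", function(object, doses, ...)
    .fourPL(doses, object@bottom, object@top, object@ec50, object@hill))
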