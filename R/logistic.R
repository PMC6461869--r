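#' Logistic dose-response curve
#'
#' Evaluates the single-logistic inhibition model
#' \deqn{Y = c / (1 + e^{b (x - a)})}
#' where `x` is the stressor level (for salt assays, log10 of the suspension
#' EC in dS/m), `a` is the logIC50 (the level at which growth is inhibited to
#' half of `c`), `b` is the slope of inhibition and `c` is the uninhibited
#' growth rate. For `b > 0` the curve decreases strictly in `x`, and
#' `logistic(a, a, b, c)` equals `c/2` exactly — the definition of the IC50.
#'
#' @param x numeric vector of stressor levels.
#' @param a logIC50 (midpoint) parameter.
#' @param b slope parameter; positive values give inhibition with
#'   increasing `x`.
#' @param c_max uninhibited (control) growth rate.
#' @return numeric vector of growth rates, same length as `x`.
#' @seealso [double_logistic()], [fit_tolerance()]
#' @examples
#' logistic(0.5, a = 0, b = 2, c_max = 100)  # 100 / (1 + e)
#' @export
logistic <- function(x, a, b, c_max) {
  stopifnot(is.finite(a), is.finite(b), is.finite(c_max))
  c_max / (1 + exp(b * (x - a)))
}

#' Double-logistic dose-response curve
#'
#' Evaluates the double-logistic model
#' \deqn{Y = c_{opt}/(1 + e^{b_{low}(x - a_{low})}) +
#'       c_{opt}/(1 + e^{b_{high}(x - a_{high})}) - c_{opt}}
#' describing growth inhibited both below and above an internal optimum:
#' `b_low < 0` gives inhibition toward low stressor values with midpoint
#' `a_low`, `b_high > 0` inhibition toward high values with midpoint
#' `a_high`, and `c_opt` is the growth rate at the optimum. When the two
#' transitions are well separated the curve plateaus at `c_opt` between
#' `a_low` and `a_high`; as `a_low` tends to minus infinity it reduces to
#' the single logistic in (`a_high`, `b_high`, `c_opt`).
#'
#' @param x numeric vector of stressor levels (log10 suspension EC, or
#'   suspension pH on a linear axis).
#' @param a_low,b_low midpoint and (negative) slope of the low-side
#'   inhibition.
#' @param a_high,b_high midpoint and (positive) slope of the high-side
#'   inhibition.
#' @param c_opt growth rate at the optimum.
#' @return numeric vector of growth rates.
#' @seealso [logistic()], [find_optimum()]
#' @export
double_logistic <- function(x, a_low, b_low, a_high, b_high, c_opt) {
  stopifnot(is.finite(a_low), is.finite(b_low), is.finite(a_high),
            is.finite(b_high), is.finite(c_opt))
  c_opt / (1 + exp(b_low * (x - a_low))) +
    c_opt / (1 + exp(b_high * (x - a_high))) - c_opt
}

#' Normalise assay growth rates to the within-sample maximum
#'
#' Divides the growth rates of a dose-response assay by the maximum observed
#' growth in that sample, so the best level has normalised growth 1. This is
#' the scale on which tolerance models are fitted, and makes curves
#' comparable across samples whose absolute leucine-incorporation rates
#' differ.
#'
#' @param assay a `dose_response_assay` (see [dose_response_assay()]) or a
#'   plain numeric vector of growth rates.
#' @return an object of the same kind with growth scaled to max 1.
#' @examples
#' normalize_growth(c(2, 4, 1))
#' @export
normalize_growth <- function(assay) {
  if (is.numeric(assay)) {
    g <- assay
  } else {
    stopifnot(inherits(assay, "dose_response_assay"))
    g <- assay$growth
  }
  if (any(g < 0)) stop("growth rates must be non-negative")
  m <- max(g)
  if (m <= 0) stop("all growth rates are zero: dead assay, nothing to normalise")
  if (is.numeric(assay)) return(g / m)
  assay$growth <- g / m
  assay
}

#' Construct a dose-response assay
#'
#' Bundles the stressor levels and growth rates of one community tolerance
#' assay for a single sample. Levels are sorted increasing; salt levels are
#' suspension EC in dS/m (strictly positive, log-transformed at fit time),
#' pH levels are suspension pH on a linear axis.
#'
#' @param sample_id sample identifier.
#' @param stressor `"salt"` or `"ph"`.
#' @param levels numeric vector of assay levels.
#' @param growth numeric vector of growth rates (leucine incorporation,
#'   arbitrary units), same length as `levels`.
#' @return an object of class `dose_response_assay`: a list with elements
#'   `sample_id`, `stressor`, `levels`, `growth`.
#' @export
dose_response_assay <- function(sample_id, stressor = c("salt", "ph"),
                                levels, growth) {
  stressor <- match.arg(stressor)
  levels <- as.numeric(levels)
  growth <- as.numeric(growth)
  if (length(levels) != length(growth))
    stop("'levels' and 'growth' must have the same length")
  if (anyNA(levels) || anyNA(growth))
    stop("assay levels and growth must not contain NA")
  if (stressor == "salt" && any(levels <= 0))
    stop("salt assay levels (suspension EC) must be strictly positive")
  if (any(growth < 0)) stop("growth rates must be non-negative")
  ord <- order(levels)
  levels <- levels[ord]; growth <- growth[ord]
  if (any(diff(levels) == 0))
    stop("assay levels must be distinct")
  structure(list(sample_id = as.character(sample_id), stressor = stressor,
                 levels = levels, growth = growth),
            class = "dose_response_assay")
}

#' @export
print.dose_response_assay <- function(x, ...) {
  cat(sprintf("<dose_response_assay> sample %s, stressor %s, %d levels\n",
              x$sample_id, x$stressor, length(x$levels)))
  print(data.frame(level = x$levels, growth = signif(x$growth, 4)))
  invisible(x)
}
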