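#' Control parameters for tolerance model fitting
#'
#' @param ptol,ftol convergence tolerances on parameters and objective
#'   passed to the Levenberg-Marquardt optimiser.
#' @param maxfev maximum number of residual evaluations.
#' @param aic_delta how much smaller (in AIC units) the double-logistic fit
#'   must be than the single-logistic fit before it is preferred for salt
#'   assays.
#' @param b_init initial absolute slope for the inhibition sides.
#' @param b_max upper bound on absolute slopes.
#' @param a_margin how far (in x units) the midpoints may lie outside the
#'   observed level range.
#' @return a list of control settings.
#' @export
tol_control <- function(ptol = 1e-8, ftol = 1e-10, maxfev = 10000,
                        aic_delta = 2, b_init = 4, b_max = 100,
                        a_margin = 2) {
  list(ptol = ptol, ftol = ftol, maxfev = maxfev, aic_delta = aic_delta,
       b_init = b_init, b_max = b_max, a_margin = a_margin)
}

## AIC from a least-squares fit; RSS floored so that noise-free (RSS ~ 0)
## fits compare by parameter count alone rather than by -Inf log-likelihoods.
ls_aic <- function(rss, n, k) {
  rss <- max(rss, n * 1e-24)
  n * log(rss / n) + 2 * (k + 1)
}

## index of the level whose growth is nearest half of the maximum,
## restricted to indices 'side' (a subset of seq_along(y))
nearest_half_max <- function(x, y, side) {
  if (length(side) == 0L) return(NA_real_)
  x[side][which.min(abs(y[side] - max(y) / 2))]
}

fit_single_logistic <- function(x, y, control) {
  a0 <- nearest_half_max(x, y, seq_along(x))
  start <- list(a = a0, b = control$b_init, cmax = max(y))
  lo <- c(a = min(x) - control$a_margin, b = 1e-6, cmax = 1e-6)
  hi <- c(a = max(x) + control$a_margin, b = control$b_max, cmax = Inf)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ cmax / (1 + exp(b * (x - a))),
                      start = start, lower = lo, upper = hi,
                      control = minpack.lm::nls.lm.control(
                        ptol = control$ptol, ftol = control$ftol,
                        maxfev = control$maxfev, maxiter = 1000)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- coef(fit)
  rss <- sum((y - logistic(x, p[["a"]], p[["b"]], p[["cmax"]]))^2)
  list(par = c(a = p[["a"]], b = p[["b"]], c = p[["cmax"]]),
       rss = rss, aic = ls_aic(rss, length(y), 3L))
}

fit_double_logistic <- function(x, y, control) {
  i_opt <- which.max(y)
  ah0 <- nearest_half_max(x, y, which(x >= x[i_opt]))
  al0 <- nearest_half_max(x, y, which(x <= x[i_opt]))
  if (!is.finite(ah0)) ah0 <- max(x)
  if (!is.finite(al0) || al0 >= ah0) al0 <- min(x) - 0.5
  start <- list(al = al0, bl = -control$b_init,
                ah = ah0, bh = control$b_init, copt = max(y))
  lo <- c(al = min(x) - control$a_margin, bl = -control$b_max,
          ah = min(x) - control$a_margin, bh = 1e-6, copt = 1e-6)
  hi <- c(al = max(x) + control$a_margin, bl = -1e-6,
          ah = max(x) + control$a_margin, bh = control$b_max, copt = Inf)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ copt / (1 + exp(bl * (x - al))) +
          copt / (1 + exp(bh * (x - ah))) - copt,
      start = start, lower = lo, upper = hi,
      control = minpack.lm::nls.lm.control(
        ptol = control$ptol, ftol = control$ftol,
        maxfev = control$maxfev, maxiter = 1000)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- coef(fit)
  pred <- double_logistic(x, p[["al"]], p[["bl"]], p[["ah"]], p[["bh"]],
                          p[["copt"]])
  rss <- sum((y - pred)^2)
  list(par = c(a_low = p[["al"]], b_low = p[["bl"]],
               a_high = p[["ah"]], b_high = p[["bh"]], c_opt = p[["copt"]]),
       rss = rss, aic = ls_aic(rss, length(y), 5L))
}

#' Fit a community tolerance dose-response model
#'
#' Fits logistic dose-response models to one community growth assay and
#' extracts the sample's community-level trait indicator. Growth is first
#' normalised to the within-sample maximum ([normalize_growth()]). For salt
#' assays the predictor is `x = log10(suspension EC)` and both the
#' single-logistic (growth inhibited only by increasing salinity) and the
#' double-logistic model (growth also inhibited at low salinity) are fitted
#' by least squares; the double model is selected only when it converges,
#' improves AIC by more than `aic_delta`, places its low-side midpoint
#' within one x-unit of the observed range, and keeps `a_low < a_high` —
#' a reproducible surrogate for deciding by eye whether growth falls off on
#' both sides. The salt trait indicator is the logIC50 toward higher
#' suspension EC (`a` for the single model, `a_high` for the double model).
#' For pH assays the predictor is suspension pH (linear axis), only the
#' double-logistic model is fitted, and the trait indicator is `pH_opt`,
#' the pH maximising the fitted curve (located by [find_optimum()]).
#'
#' @param assay a [dose_response_assay()] with at least 5 (salt) or
#'   6 (pH) levels.
#' @param control fitting control settings from [tol_control()].
#' @return an object of class `tolerance_fit` with components
#'   `sample_id`, `stressor`, `model` (`"single"` or `"double"`),
#'   `coefficients`, `trait` (`"log_ic50"` or `"ph_opt"`), `trait_value`,
#'   `r2`, `converged`, `aic` (per candidate model), and the fitted data
#'   (`x`, `y`). Methods: [print()], [summary()], [coef()], [predict()],
#'   [fitted()], [residuals()], [plot()], [simulate()].
#' @examples
#' x <- seq(-1.5, 2, length.out = 8)
#' a <- dose_response_assay("s1", "salt", 10^x, logistic(x, 0.8, 3, 1))
#' f <- fit_tolerance(a)
#' coef(f); f$trait_value
#' @export
fit_tolerance <- function(assay, control = tol_control()) {
  stopifnot(inherits(assay, "dose_response_assay"))
  if (assay$stressor == "salt") fit_salt_tolerance(assay, control)
  else fit_ph_tolerance(assay, control)
}

#' @rdname fit_tolerance
#' @export
fit_salt_tolerance <- function(assay, control = tol_control()) {
  stopifnot(inherits(assay, "dose_response_assay"),
            assay$stressor == "salt")
  if (length(assay$levels) < 5)
    stop("salt assays need at least 5 levels to fit a tolerance model")
  assay <- normalize_growth(assay)
  x <- log10(assay$levels)
  y <- assay$growth
  fs <- fit_single_logistic(x, y, control)
  fd <- fit_double_logistic(x, y, control)
  use_double <- !is.null(fd) && !is.null(fs) &&
    fd$par[["a_low"]] < fd$par[["a_high"]] &&
    fd$par[["a_low"]] > min(x) - 1 &&
    fd$aic < fs$aic - control$aic_delta
  if (is.null(fs) && is.null(fd)) {
    return(new_tolerance_fit(assay, x, y, model = "single",
                             par = NULL, trait = "log_ic50",
                             trait_value = NA_real_, rss = NA_real_,
                             aic = c(single = NA_real_, double = NA_real_),
                             converged = FALSE, control = control))
  }
  sel <- if (use_double) fd else if (!is.null(fs)) fs else fd
  model <- if (use_double || is.null(fs)) "double" else "single"
  trait_value <- if (model == "single") sel$par[["a"]] else sel$par[["a_high"]]
  new_tolerance_fit(assay, x, y, model = model, par = sel$par,
                    trait = "log_ic50", trait_value = trait_value,
                    rss = sel$rss,
                    aic = c(single = if (is.null(fs)) NA_real_ else fs$aic,
                            double = if (is.null(fd)) NA_real_ else fd$aic),
                    converged = TRUE, control = control)
}

#' @rdname fit_tolerance
#' @export
fit_ph_tolerance <- function(assay, control = tol_control()) {
  stopifnot(inherits(assay, "dose_response_assay"),
            assay$stressor == "ph")
  if (length(assay$levels) < 6)
    stop("pH assays need at least 6 levels to fit a tolerance model")
  assay <- normalize_growth(assay)
  x <- assay$levels
  y <- assay$growth
  fd <- fit_double_logistic(x, y, control)
  if (is.null(fd)) {
    return(new_tolerance_fit(assay, x, y, model = "double", par = NULL,
                             trait = "ph_opt", trait_value = NA_real_,
                             rss = NA_real_,
                             aic = c(single = NA_real_, double = NA_real_),
                             converged = FALSE, control = control))
  }
  fit <- new_tolerance_fit(assay, x, y, model = "double", par = fd$par,
                           trait = "ph_opt", trait_value = NA_real_,
                           rss = fd$rss,
                           aic = c(single = NA_real_, double = fd$aic),
                           converged = TRUE, control = control)
  opt <- find_optimum(fit, search_interval = range(x))
  fit$trait_value <- as.numeric(opt)
  fit$x_opt <- as.numeric(opt)
  fit$optimum_degenerate <- attr(opt, "degenerate")
  fit
}

new_tolerance_fit <- function(assay, x, y, model, par, trait, trait_value,
                              rss, aic, converged, control) {
  sst <- sum((y - mean(y))^2)
  r2 <- if (!converged || !is.finite(rss)) {
    NA_real_
  } else if (sst <= 0) {
    1
  } else {
    max(0, 1 - rss / sst)
  }
  structure(list(sample_id = assay$sample_id, stressor = assay$stressor,
                 model = model, coefficients = par, trait = trait,
                 trait_value = trait_value, r2 = r2, rss = rss, aic = aic,
                 converged = converged, x = x, y = y,
                 levels = assay$levels, n = length(x),
                 x_opt = if (model == "double" && trait == "ph_opt")
                   trait_value else NA_real_,
                 optimum_degenerate = FALSE,
                 control = control),
            class = "tolerance_fit")
}

#' Locate the optimum of a fitted double-logistic curve
#'
#' Finds the stressor value maximising a double-logistic curve over a search
#' interval by coarse grid evaluation (step 0.01) followed by local
#' refinement. Ties are broken toward the lower stressor value. If the curve
#' is flat or monotone over the interval (e.g. a single-logistic-like fit
#' with the low side pushed out of range), the maximiser sits on the
#' interval boundary and the result is flagged degenerate.
#'
#' @param fit a converged `tolerance_fit` with a double-logistic model, or a
#'   named numeric vector with elements `a_low`, `b_low`, `a_high`,
#'   `b_high`, `c_opt`.
#' @param search_interval numeric length-2 interval to search; defaults to
#'   the fitted data range (or `c(a_low, a_high)` for a bare parameter
#'   vector).
#' @return the maximising stressor value, with attributes `value` (curve
#'   height there) and `degenerate` (TRUE for flat curves or boundary
#'   maxima).
#' @export
find_optimum <- function(fit, search_interval = NULL) {
  if (inherits(fit, "tolerance_fit")) {
    if (!fit$converged) stop("cannot locate the optimum of an unconverged fit")
    if (fit$model != "double")
      stop("find_optimum() applies to double-logistic fits")
    par <- fit$coefficients
    if (is.null(search_interval)) search_interval <- range(fit$x)
  } else {
    par <- fit
    if (is.null(search_interval))
      search_interval <- c(par[["a_low"]], par[["a_high"]])
  }
  stopifnot(length(search_interval) == 2, diff(search_interval) >= 0)
  f <- function(x) double_logistic(x, par[["a_low"]], par[["b_low"]],
                                   par[["a_high"]], par[["b_high"]],
                                   par[["c_opt"]])
  lo <- search_interval[1]; hi <- search_interval[2]
  grid <- seq(lo, hi, by = 0.01)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  vals <- f(grid)
  if (diff(range(vals)) < 1e-12) {   # flat curve
    out <- lo
    attr(out, "value") <- vals[1]
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  i <- which.max(vals)               # first (lowest-x) maximum on ties
  xl <- max(lo, grid[i] - 0.01); xr <- min(hi, grid[i] + 0.01)
  ref <- optimize(f, interval = c(xl, xr), maximum = TRUE, tol = 1e-10)
  if (ref$objective > vals[i]) {
    x_opt <- ref$maximum; v <- ref$objective
  } else {
    x_opt <- grid[i]; v <- vals[i]
  }
  degenerate <- (x_opt - lo) < 0.011 || (hi - x_opt) < 0.011
  out <- x_opt
  attr(out, "value") <- v
  attr(out, "degenerate") <- degenerate
  out
}
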