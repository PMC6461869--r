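#' @export
coef.tolerance_fit <- function(object, ...) object$coefficients

#' Predict from a fitted tolerance model
#'
#' Evaluates the selected dose-response model at new stressor values, on the
#' normalised-growth scale (maximum observed growth = 1).
#'
#' @param object a `tolerance_fit`.
#' @param newdata numeric vector of predictor values: log10 suspension EC
#'   for salt fits, suspension pH for pH fits. Defaults to the fitted `x`.
#' @param ... unused.
#' @return numeric vector of predicted normalised growth.
#' @export
predict.tolerance_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("cannot predict from an unconverged fit")
  x <- if (is.null(newdata)) object$x else as.numeric(newdata)
  p <- object$coefficients
  if (object$model == "single") {
    logistic(x, p[["a"]], p[["b"]], p[["c"]])
  } else {
    double_logistic(x, p[["a_low"]], p[["b_low"]], p[["a_high"]],
                    p[["b_high"]], p[["c_opt"]])
  }
}

#' @export
fitted.tolerance_fit <- function(object, ...) predict(object)

#' @export
residuals.tolerance_fit <- function(object, ...) object$y - fitted(object)

#' @export
print.tolerance_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Community tolerance fit — sample %s, %s assay\n",
              x$sample_id, if (x$stressor == "salt") "salt" else "pH"))
  if (!x$converged) {
    cat("  model did not converge; no trait indicator available\n")
    return(invisible(x))
  }
  cat(sprintf("  model: %s-logistic on %d levels, R² = %.3f\n",
              x$model, x$n, x$r2))
  cat("  coefficients:\n")
  print(signif(x$coefficients, digits))
  lab <- if (x$trait == "log_ic50") "logIC50 [log10 dS/m]" else "pH_opt"
  cat(sprintf("  trait indicator %s = %s\n", lab,
              format(signif(x$trait_value, digits))))
  invisible(x)
}

#' @export
summary.tolerance_fit <- function(object, ...) {
  out <- list(sample_id = object$sample_id, stressor = object$stressor,
              model = object$model, converged = object$converged,
              coefficients = object$coefficients,
              trait = object$trait, trait_value = object$trait_value,
              r2 = object$r2, rss = object$rss, aic = object$aic,
              n = object$n,
              residual_range = if (object$converged)
                range(residuals(object)) else c(NA_real_, NA_real_))
  class(out) <- "summary.tolerance_fit"
  out
}

#' @export
print.summary.tolerance_fit <- function(x, ...) {
  cat(sprintf("Tolerance fit summary — sample %s (%s)\n", x$sample_id,
              x$stressor))
  cat(sprintf("  selected model: %s (AIC single %.2f, double %.2f)\n",
              x$model, x$aic[["single"]], x$aic[["double"]]))
  cat(sprintf("  converged: %s, R² = %.4f, RSS = %.3g, n = %d\n",
              x$converged, x$r2, x$rss, x$n))
  cat(sprintf("  %s = %.4f\n", x$trait, x$trait_value))
  invisible(x)
}

#' Plot a fitted tolerance curve
#'
#' Draws the normalised growth observations against the stressor axis with
#' the fitted dose-response curve and the trait indicator (logIC50 or
#' pH_opt) marked.
#'
#' @param x a `tolerance_fit`.
#' @param n_curve number of points at which to draw the fitted curve.
#' @param ... passed to [plot()].
#' @return invisibly, `x`.
#' @export
plot.tolerance_fit <- function(x, n_curve = 200, ...) {
  xlab <- if (x$stressor == "salt")
    expression(log[10] ~ "suspension EC (dS/m)") else "suspension pH"
  plot(x$x, x$y, xlab = xlab, ylab = "normalised growth",
       main = sprintf("sample %s (%s-logistic)", x$sample_id, x$model), ...)
  if (x$converged) {
    xs <- seq(min(x$x), max(x$x), length.out = n_curve)
    lines(xs, predict(x, xs))
    abline(v = x$trait_value, lty = 2)
  }
  invisible(x)
}

#' Simulate assays from a fitted tolerance model
#'
#' Draws new dose-response assays from the fitted curve at the observed
#' levels, with multiplicative log-normal noise of a given coefficient of
#' variation — the same error model the study simulator uses.
#'
#' @param object a converged `tolerance_fit`.
#' @param nsim number of assays to simulate.
#' @param seed optional integer seed.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param ... unused.
#' @return a list of [dose_response_assay()] objects.
#' @export
simulate.tolerance_fit <- function(object, nsim = 1, seed = NULL,
                                   noise_cv = 0.05, ...) {
  if (!object$converged) stop("cannot simulate from an unconverged fit")
  if (!is.null(seed)) set.seed(seed)
  mu <- pmax(predict(object), 0)
  lapply(seq_len(nsim), function(i) {
    g <- apply_lognormal_noise(mu, noise_cv)
    dose_response_assay(paste0(object$sample_id, "_sim", i),
                        object$stressor, object$levels, g)
  })
}
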