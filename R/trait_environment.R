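#' Build per-sample trait profiles
#'
#' Joins the fitted community trait indicators (logIC50 from salt fits,
#' pH_opt from pH fits) to the site metadata, keeping one row per sample
#' with at least one converged fit. This table is the hinge between the
#' physiological and the compositional halves of the analysis.
#'
#' @param fits list of `tolerance_fit` objects (salt and/or pH per sample).
#' @param metadata site metadata with a `sample_id` column.
#' @return a data.frame with `sample_id`, `log_ic50`, `ph_opt` and the
#'   metadata columns.
#' @export
trait_profiles <- function(fits, metadata) {
  stopifnot(all(vapply(fits, inherits, logical(1), "tolerance_fit")))
  rows <- lapply(fits, function(f)
    data.frame(sample_id = f$sample_id, trait = f$trait,
               value = if (f$converged) f$trait_value else NA_real_,
               stringsAsFactors = FALSE))
  long <- do.call(rbind, rows)
  ids <- unique(long$sample_id)
  prof <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (tr in c("log_ic50", "ph_opt")) {
    v <- long$value[match(paste(ids, tr), paste(long$sample_id, long$trait))]
    prof[[tr]] <- v
  }
  merge(prof, metadata, by = "sample_id", sort = FALSE)
}

new_regression_result <- function(fit, n, excluded_ids = character(0)) {
  s <- summary(fit)
  co <- coef(s)
  structure(list(slope = co[2, 1], intercept = co[1, 1],
                 r2 = s$r.squared, p_value = co[2, 4], n = n,
                 excluded_ids = excluded_ids, lm = fit),
            class = "trait_regression")
}

#' @export
print.trait_regression <- function(x, ...) {
  cat(sprintf(
    "trait regression: slope %.4f, intercept %.4f, R² = %.3f, p = %.3g, n = %d\n",
    x$slope, x$intercept, x$r2, x$p_value, x$n))
  if (length(x$excluded_ids))
    cat("  excluded:", paste(x$excluded_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Regress community salt tolerance on soil salinity
#'
#' Ordinary least squares of the community logIC50 on log10 soil EC, the
#' trait-environment relationship that demonstrates environmental filtering
#' by salinity. The slope test is two-sided.
#'
#' @param profiles trait profiles from [trait_profiles()] (needs
#'   `log_ic50` and `soil_ec`).
#' @return a `trait_regression` with `slope`, `intercept`, `r2`,
#'   `p_value`, `n`, `excluded_ids`.
#' @export
regress_salt_trait <- function(profiles) {
  d <- profiles[is.finite(profiles$log_ic50) & is.finite(profiles$soil_ec), ]
  if (nrow(d) < 3) stop("need at least 3 samples with salt traits")
  x <- log10(d$soil_ec)
  if (var(x) == 0) stop("soil EC has zero variance; cannot regress")
  new_regression_result(lm(d$log_ic50 ~ x), n = nrow(d))
}

#' Regress community pH optimum on soil pH
#'
#' Ordinary least squares of pH_opt on soil pH, after excluding samples
#' with soil pH below `exclusion_threshold` (default 5.5; the relationship
#' between soil pH and the community pH optimum is linear only above that
#' value — below it, pH_opt plateaus above the soil pH). The boundary
#' sample at exactly the threshold is retained.
#'
#' @param profiles trait profiles (needs `ph_opt` and `soil_ph`).
#' @param exclusion_threshold soil-pH cutoff below which samples are
#'   excluded from the regression (they are recorded in `excluded_ids`).
#' @return a `trait_regression`.
#' @export
regress_ph_trait <- function(profiles, exclusion_threshold = 5.5) {
  d <- profiles[is.finite(profiles$ph_opt) & is.finite(profiles$soil_ph), ]
  excluded <- d$sample_id[d$soil_ph < exclusion_threshold]
  d <- d[d$soil_ph >= exclusion_threshold, ]
  if (nrow(d) < 3)
    stop("fewer than 3 samples remain above the soil-pH threshold")
  if (var(d$soil_ph) == 0) stop("soil pH has zero variance; cannot regress")
  new_regression_result(lm(ph_opt ~ soil_ph, data = d), n = nrow(d),
                        excluded_ids = excluded)
}

#' Diversity multiple regression with type II sums of squares
#'
#' Fits, within one gradient, the multiple linear regression of Shannon
#' diversity on log10 soil EC and soil pH, and partitions it by analysis
#' of variance with type II sums of squares: each term's SS is the
#' residual-SS increase when that term alone is dropped from the full
#' model, so the test of each predictor is adjusted for the other — the
#' appropriate decomposition when the two environmental drivers are
#' correlated along a gradient.
#'
#' @param shannon named numeric vector of per-sample Shannon diversities
#'   (names are sample ids).
#' @param profiles trait profiles / metadata with `sample_id`, `soil_ec`,
#'   `soil_ph` and optionally `gradient`.
#' @param gradient if given, restrict to samples of this gradient.
#' @return a data.frame (one row per term plus residuals) with `sum_sq`,
#'   `df`, `f_value`, `p_value`; attributes `overall_f`, `overall_p`,
#'   `r2`, `n`, `lm`.
#' @export
shannon_regression <- function(shannon, profiles, gradient = NULL) {
  d <- profiles
  if (!is.null(gradient)) d <- d[d$gradient == gradient, ]
  d <- d[d$sample_id %in% names(shannon), ]
  if (nrow(d) < 5) stop("need at least 5 samples in the gradient subset")
  d$H <- shannon[d$sample_id]
  d$log_ec <- log10(d$soil_ec)
  if (abs(cor(d$log_ec, d$soil_ph)) >= 1 - 1e-12)
    stop("log EC and pH are perfectly collinear; type II SS undefined")
  fit <- lm(H ~ log_ec + soil_ph, data = d)
  a2 <- tryCatch(car::Anova(fit, type = 2), error = function(e) NULL)
  if (!is.null(a2)) {
    out <- data.frame(term = rownames(a2), sum_sq = a2[["Sum Sq"]],
                      df = a2[["Df"]], f_value = a2[["F value"]],
                      p_value = a2[["Pr(>F)"]], stringsAsFactors = FALSE)
  } else {
    # saturated (zero-residual) fit: the SS decomposition is still defined
    # by nested-model residual differences, but F tests are not
    rss_full <- sum(resid(fit)^2)
    ss <- c(log_ec = sum(resid(lm(H ~ soil_ph, data = d))^2) - rss_full,
            soil_ph = sum(resid(lm(H ~ log_ec, data = d))^2) - rss_full)
    out <- data.frame(term = c("log_ec", "soil_ph", "Residuals"),
                      sum_sq = c(ss, rss_full),
                      df = c(1, 1, fit$df.residual),
                      f_value = NA_real_, p_value = NA_real_,
                      stringsAsFactors = FALSE)
  }
  s <- summary(fit)
  attr(out, "overall_f") <- unname(s$fstatistic[1])
  attr(out, "overall_p") <- unname(pf(s$fstatistic[1], s$fstatistic[2],
                                      s$fstatistic[3], lower.tail = FALSE))
  attr(out, "r2") <- s$r.squared
  attr(out, "n") <- nrow(d)
  attr(out, "lm") <- fit
  out
}
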