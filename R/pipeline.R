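#' Pipeline run configuration
#'
#' Collects every threshold, permutation count and seed of the end-to-end
#' analysis in one list. All stage seeds are derived from the single
#' `seed`, so a run is fully determined by its configuration.
#'
#' @param seed master seed.
#' @param n_taxa,read_depth,noise_cv simulator settings
#'   (see [simulate_study()]).
#' @param halophiles enable obligate-halophile taxa in the simulator.
#' @param min_depth minimum reads for a sample to be kept (inclusive).
#' @param rarefy_depth even rarefaction depth.
#' @param min_otu_total minimum rarefied total reads for an OTU
#'   (inclusive).
#' @param abundance_threshold,rho_threshold bioindicator screen settings
#'   (see [screen_otus()]).
#' @param ph_exclusion soil-pH cutoff for the pH trait regression.
#' @param n_perm_dbrda,n_perm_mantel permutation counts.
#' @return a `tolgrad_config` list.
#' @export
tolgrad_config <- function(seed = 1, n_taxa = 500, read_depth = 12000,
                           noise_cv = 0.05, halophiles = FALSE,
                           min_depth = 10000, rarefy_depth = 10000,
                           min_otu_total = 10,
                           abundance_threshold = 0.01, rho_threshold = 0.5,
                           ph_exclusion = 5.5,
                           n_perm_dbrda = 10000, n_perm_mantel = 9999) {
  stopifnot(rarefy_depth >= 1, min_depth >= 0, min_otu_total >= 0,
            abundance_threshold > 0, abundance_threshold <= 1,
            rho_threshold > 0, rho_threshold <= 1,
            n_perm_dbrda >= 1, n_perm_mantel >= 1, noise_cv >= 0)
  structure(list(seed = seed, n_taxa = n_taxa, read_depth = read_depth,
                 noise_cv = noise_cv, halophiles = halophiles,
                 min_depth = min_depth, rarefy_depth = rarefy_depth,
                 min_otu_total = min_otu_total,
                 abundance_threshold = abundance_threshold,
                 rho_threshold = rho_threshold,
                 ph_exclusion = ph_exclusion,
                 n_perm_dbrda = n_perm_dbrda,
                 n_perm_mantel = n_perm_mantel),
            class = "tolgrad_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys present in the file override the defaults of [tolgrad_config()].
#'
#' @param path YAML file path.
#' @return a `tolgrad_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(tolgrad_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(tolgrad_config, vals)
}

#' Fit tolerance models for every assay of a study
#'
#' @param assays list of [dose_response_assay()] objects.
#' @param control fitting control ([tol_control()]).
#' @return a named list of `tolerance_fit` objects.
#' @export
fit_all_assays <- function(assays, control = tol_control()) {
  lapply(assays, fit_tolerance, control = control)
}

#' Tabulate a list of tolerance fits
#'
#' One row per fit with the double-logistic parameter slots (single-model
#' fits report their parameters in the high-side columns, since the single
#' logistic is the high-side term alone).
#'
#' @param fits list of `tolerance_fit` objects.
#' @return a data.frame with columns `sample_id`, `stressor`, `model`,
#'   `a_low`, `b_low`, `a_high`, `b_high`, `c_opt`, `trait_value`, `r2`,
#'   `converged`.
#' @export
fits_table <- function(fits) {
  do.call(rbind, lapply(unname(fits), function(f) {
    p <- f$coefficients
    if (is.null(p)) p <- c()
    g <- function(k) if (k %in% names(p)) unname(p[k]) else NA_real_
    if (f$model == "single") {
      row <- data.frame(a_low = NA_real_, b_low = NA_real_,
                        a_high = g("a"), b_high = g("b"), c_opt = g("c"))
    } else {
      row <- data.frame(a_low = g("a_low"), b_low = g("b_low"),
                        a_high = g("a_high"), b_high = g("b_high"),
                        c_opt = g("c_opt"))
    }
    cbind(data.frame(sample_id = f$sample_id, stressor = f$stressor,
                     model = f$model, stringsAsFactors = FALSE),
          row,
          data.frame(trait_value = f$trait_value, r2 = f$r2,
                     converged = f$converged))
  }))
}

#' Write / read assays as long-format TSV
#'
#' Columns `sample_id`, `stressor`, `level`, `growth`; one row per assay
#' level.
#'
#' @param assays list of [dose_response_assay()] (or a `tolgrad_study`).
#' @param path file path.
#' @return `write_assays()` the path, invisibly; `read_assays()` a named
#'   list of assays (`<sample_id>.<stressor>`).
#' @export
write_assays <- function(assays, path) {
  if (inherits(assays, "tolgrad_study")) {
    long <- assay_table(assays)
  } else {
    long <- do.call(rbind, lapply(assays, function(a)
      data.frame(sample_id = a$sample_id, stressor = a$stressor,
                 level = a$levels, growth = a$growth,
                 stringsAsFactors = FALSE)))
  }
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assays
#' @export
read_assays <- function(path) {
  long <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "stressor", "level", "growth") %in%
                  names(long)))
  key <- paste(long$sample_id, long$stressor, sep = ".")
  lapply(split(long, factor(key, levels = unique(key))), function(d)
    dose_response_assay(d$sample_id[1], d$stressor[1], d$level, d$growth))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full tolerance-gradient pipeline
#'
#' Orchestrates, under a single master seed: simulation of the study
#' ([simulate_study()]); OTU-table preparation ([prepare_otu_table()]);
#' tolerance-model fitting for every salt and pH assay and assembly of the
#' trait profiles; the trait-environment regressions and the per-gradient
#' Shannon-diversity type-II ANOVA; the composition-trait linkage
#' (Bray-Curtis after Hellinger, PCoA, trait-constrained dbRDA, Mantel
#' tests overall and per gradient, distance-decay slopes and the
#' trait-equivalence ratio); and the bioindicator screen per gradient with
#' its cross-gradient and cross-trait summaries. If `outdir` is given,
#' every stage's tables are written as TSV/JSON together with a manifest
#' recording seeds, thresholds and per-stage record counts; rerunning with
#' the same configuration reproduces the outputs exactly.
#'
#' @param config a [tolgrad_config()].
#' @param outdir optional output directory (created if missing).
#' @param quiet suppress stage messages.
#' @return an object of class `tolgrad_run`: a list with the study, the
#'   prepared table, fits, profiles, regression, linkage and bioindicator
#'   results, and the manifest.
#' @export
run_pipeline <- function(config = tolgrad_config(), outdir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "tolgrad_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed

  say("stage simulate: master seed %d", seed)
  study <- simulate_study(seed = derive_seed(seed, 1001L),
                          n_taxa = config$n_taxa,
                          read_depth = config$read_depth,
                          noise_cv = config$noise_cv,
                          niche = niche_config(halophiles = config$halophiles))

  say("stage prep: depth >= %d, rarefy to %d, OTU total >= %d",
      config$min_depth, config$rarefy_depth, config$min_otu_total)
  prepared <- prepare_otu_table(study$otu, min_depth = config$min_depth,
                                rarefy_depth = config$rarefy_depth,
                                min_otu_total = config$min_otu_total,
                                seed = derive_seed(seed, 1002L),
                                quiet = quiet)
  prep_log <- attr(prepared, "prep_log")

  say("stage fit: %d assays", length(study$assays))
  fits <- fit_all_assays(study$assays)
  profiles <- trait_profiles(fits, study$metadata)
  kept <- sample_ids(prepared)
  profiles <- profiles[profiles$sample_id %in% kept, ]

  say("stage traits: regressions and diversity ANOVA")
  salt_reg <- regress_salt_trait(profiles)
  ph_reg <- regress_ph_trait(profiles, config$ph_exclusion)
  H <- shannon(prepared)
  shannon_anova <- lapply(
    setNames(nm = unique(profiles$gradient)),
    function(g) shannon_regression(H, profiles, gradient = g))

  say("stage link: ordination and Mantel tests")
  complete <- profiles[is.finite(profiles$log_ic50) &
                         is.finite(profiles$ph_opt), ]
  sub <- otu_table(prepared$counts[complete$sample_id, , drop = FALSE],
                   prepared$taxonomy)
  sub <- filter_rare_otus(sub, 1)        # drop OTUs absent from the subset
  d_comm <- bray_curtis(hellinger(sub))
  pcoa_res <- pcoa_ord(d_comm)
  constraints <- data.frame(log_ic50 = complete$log_ic50,
                            ph_opt = complete$ph_opt,
                            gradient = as.integer(complete$gradient ==
                                                    complete$gradient[1]),
                            row.names = complete$sample_id)
  dbrda_res <- dbrda_traits(d_comm, constraints,
                            n_perm = config$n_perm_dbrda,
                            seed = derive_seed(seed, 1003L))
  d_salt <- trait_distance(complete, "log_ic50")
  d_ph <- trait_distance(complete, "ph_opt")
  mantel_all <- list(
    salt = mantel_traits(d_comm, d_salt, config$n_perm_mantel,
                         seed = derive_seed(seed, 1004L)),
    ph = mantel_traits(d_comm, d_ph, config$n_perm_mantel,
                       seed = derive_seed(seed, 1005L)))
  mantel_by_gradient <- lapply(
    setNames(nm = unique(complete$gradient)), function(g) {
      idx <- complete$gradient == g
      sg <- filter_rare_otus(otu_table(
        sub$counts[complete$sample_id[idx], , drop = FALSE],
        sub$taxonomy), 1)
      dg <- bray_curtis(hellinger(sg))
      pg <- complete[idx, ]
      list(salt = mantel_traits(dg, trait_distance(pg, "log_ic50"),
                                config$n_perm_mantel,
                                seed = derive_seed(seed, 1006L)),
           ph = mantel_traits(dg, trait_distance(pg, "ph_opt"),
                              config$n_perm_mantel,
                              seed = derive_seed(seed, 1007L)))
    })
  decay_salt <- distance_decay_slope(d_comm, d_salt)
  decay_ph <- distance_decay_slope(d_comm, d_ph)
  equivalence <- equivalence_ratio(decay_ph$slope, decay_salt$slope)

  say("stage screen: bioindicator OTUs")
  screens <- lapply(setNames(nm = unique(complete$gradient)), function(g) {
    idx <- complete$sample_id[complete$gradient == g]
    tg <- otu_table(prepared$counts[idx, , drop = FALSE],
                    prepared$taxonomy)
    screen_otus(tg, complete, config$abundance_threshold,
                config$rho_threshold)
  })
  overlap_salt_pos <- if (length(screens) >= 2)
    cross_gradient_overlap(screens[[1]], screens[[2]], "salt", "positive")
  else character(0)
  cross_trait <- lapply(screens, cross_trait_table)

  manifest <- list(
    package = "tolgrad",
    version = as.character(packageVersion("tolgrad")),
    config = unclass(config),
    stage_seeds = list(simulate = derive_seed(seed, 1001L),
                       prep = derive_seed(seed, 1002L),
                       dbrda = derive_seed(seed, 1003L),
                       mantel = derive_seed(seed, 1004L)),
    counts = prep_log,
    n_fits = length(fits),
    n_profiles = nrow(profiles))

  run <- structure(list(
    config = config, study = study, prepared = prepared, fits = fits,
    profiles = profiles, salt_regression = salt_reg,
    ph_regression = ph_reg, shannon_anova = shannon_anova,
    pcoa = pcoa_res, dbrda = dbrda_res, mantel = mantel_all,
    mantel_by_gradient = mantel_by_gradient,
    decay = list(salt = decay_salt, ph = decay_ph),
    equivalence_ratio = equivalence,
    screens = screens, overlap_salt_positive = overlap_salt_pos,
    cross_trait = cross_trait, manifest = manifest),
    class = "tolgrad_run")

  if (!is.null(outdir)) write_run(run, outdir)
  run
}

#' @export
print.tolgrad_run <- function(x, ...) {
  cat("<tolgrad_run>\n")
  cat(sprintf("  samples: %d profiled / %d simulated; OTUs kept: %d\n",
              nrow(x$profiles), nrow(x$study$metadata),
              ncol(x$prepared$counts)))
  cat(sprintf("  logIC50 ~ log10 soil EC: slope %.3f, R² = %.3f\n",
              x$salt_regression$slope, x$salt_regression$r2))
  cat(sprintf("  pH_opt ~ soil pH:        slope %.3f, R² = %.3f\n",
              x$ph_regression$slope, x$ph_regression$r2))
  cat(sprintf("  Mantel rho: salt %.3f (p %.3g), pH %.3f (p %.3g)\n",
              x$mantel$salt$rho, x$mantel$salt$p_value,
              x$mantel$ph$rho, x$mantel$ph$p_value))
  cat(sprintf("  dbRDA constrained fraction: %.3f\n",
              x$dbrda$constrained_fraction))
  cat(sprintf("  trait equivalence: 1 pH unit ~ %.3f logIC50 units\n",
              x$equivalence_ratio))
  invisible(x)
}

#' Write every table of a pipeline run to a directory
#'
#' @param run a `tolgrad_run`.
#' @param outdir directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_tsv(run$study$metadata, p("metadata.tsv"))
  write_tsv(run$study$taxa, p("taxa.tsv"))
  write_otu_table(run$study$otu, p("otu_raw.tsv"))
  write_otu_table(run$prepared, p("otu_prepared.tsv"))
  write_assays(run$study, p("assays.tsv"))
  write_tsv(run$study$truth, p("ground_truth.tsv"))
  write_tsv(fits_table(run$fits), p("fits.tsv"))
  write_tsv(run$profiles, p("trait_profiles.tsv"))
  regs <- rbind(
    data.frame(response = "log_ic50", predictor = "log10_soil_ec",
               slope = run$salt_regression$slope,
               intercept = run$salt_regression$intercept,
               r2 = run$salt_regression$r2,
               p_value = run$salt_regression$p_value,
               n = run$salt_regression$n),
    data.frame(response = "ph_opt", predictor = "soil_ph",
               slope = run$ph_regression$slope,
               intercept = run$ph_regression$intercept,
               r2 = run$ph_regression$r2,
               p_value = run$ph_regression$p_value,
               n = run$ph_regression$n))
  write_tsv(regs, p("trait_regressions.tsv"))
  for (g in names(run$shannon_anova))
    write_tsv(run$shannon_anova[[g]],
              p(sprintf("shannon_anova_%s.tsv", g)))
  sc <- data.frame(sample_id = rownames(run$pcoa$scores),
                   run$pcoa$scores[, seq_len(min(4, ncol(run$pcoa$scores))),
                                   drop = FALSE])
  write_tsv(sc, p("pcoa_scores.tsv"))
  link <- list(
    mantel = lapply(run$mantel, unclass),
    mantel_by_gradient = lapply(run$mantel_by_gradient,
                                function(g) lapply(g, unclass)),
    dbrda = list(constrained_fraction = run$dbrda$constrained_fraction,
                 permutation_p = as.list(run$dbrda$permutation_p),
                 n_permutations = run$dbrda$n_permutations),
    decay = run$decay,
    equivalence_ratio = run$equivalence_ratio)
  jsonlite::write_json(link, p("linkage.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (g in names(run$screens))
    write_tsv(run$screens[[g]], p(sprintf("bioindicators_%s.tsv", g)))
  writeLines(run$overlap_salt_positive, p("overlap_salt_positive.txt"))
  jsonlite::write_json(run$manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(outdir)
}
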