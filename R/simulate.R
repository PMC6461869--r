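#' Default sampling design for the synthetic gradients
#'
#' Describes two salinity gradients, each sampled in three transects of
#' eight points (24 samples per gradient): an agricultural gradient (AG)
#' with soil EC 0.1-3 dS/m and near-neutral pH, and a natural-vegetation
#' gradient (NV) with soil EC 0.2-9 dS/m, a wider pH span and a built-in
#' negative correlation between soil EC and soil pH (saline lakeshore soils
#' are also the most alkaline-to-acid extreme of that gradient). Soil EC is
#' measured in a 1:5 soil:water extract, in dS/m.
#'
#' @param n_transects transects per gradient.
#' @param n_points sampling points per transect.
#' @param ec_noise_sd log10-scale noise on soil EC between transects.
#' @param ph_noise_sd noise on soil pH (pH units).
#' @return a design configuration list.
#' @export
gradient_design <- function(n_transects = 3, n_points = 8,
                            ec_noise_sd = 0.05, ph_noise_sd = 0.15) {
  list(
    gradients = list(
      AG = list(ec_range = c(0.1, 3), ph_range = c(5.5, 7.0),
                ec_ph_cor = 0, om_range = c(2.8, 4.8)),
      NV = list(ec_range = c(0.2, 9), ph_range = c(4.5, 8.5),
                ec_ph_cor = -1, om_range = c(7.6, 10.0))
    ),
    n_transects = n_transects, n_points = n_points,
    ec_noise_sd = ec_noise_sd, ph_noise_sd = ph_noise_sd
  )
}

#' Default taxon niche configuration
#'
#' Controls the trait distributions of the simulated taxa pool. Salt
#' tolerance (per-taxon logIC50, log10 dS/m on the suspension-EC axis) is a
#' two-component mixture of salt-sensitive and halotolerant taxa; pH niches
#' are Gaussian with an optimum and a breadth; base abundances are
#' log-normal. `filter_slope` sets how sharply soil EC filters taxa in and
#' out of communities (per log10 dS/m); `assay_slope` is the slope of the
#' per-taxon logistic growth response in the tolerance assay. With
#' `halophiles = TRUE` the halotolerant taxa become obligate: their growth
#' and abundance also drop at low salinity, which gives communities from
#' saline soils a low-EC inhibition side and triggers double-logistic fits.
#'
#' @param frac_tolerant fraction of taxa in the halotolerant component.
#' @param mean_sensitive,mean_tolerant component means of the per-taxon
#'   salt logIC50 (log10 dS/m).
#' @param salt_sd within-component standard deviation of salt logIC50.
#' @param ph_opt_range range of per-taxon pH optima.
#' @param breadth_meanlog,breadth_sdlog log-normal parameters of the pH
#'   niche breadth (pH units).
#' @param abundance_sdlog log-normal spread of base abundances.
#' @param filter_slope abundance-filter steepness along soil EC.
#' @param assay_slope per-taxon logistic slope in the salt assay.
#' @param halophiles logical; make halotolerant taxa obligate halophiles.
#' @return a niche configuration list.
#' @export
niche_config <- function(frac_tolerant = 0.3, mean_sensitive = 0.0,
                         mean_tolerant = 1.1, salt_sd = 0.35,
                         ph_opt_range = c(4, 9),
                         breadth_meanlog = log(1.2), breadth_sdlog = 0.3,
                         abundance_sdlog = 1, filter_slope = 3,
                         assay_slope = 4, halophiles = FALSE) {
  stopifnot(frac_tolerant >= 0, frac_tolerant <= 1, salt_sd >= 0)
  list(frac_tolerant = frac_tolerant, mean_sensitive = mean_sensitive,
       mean_tolerant = mean_tolerant, salt_sd = salt_sd,
       ph_opt_range = ph_opt_range, breadth_meanlog = breadth_meanlog,
       breadth_sdlog = breadth_sdlog, abundance_sdlog = abundance_sdlog,
       filter_slope = filter_slope, assay_slope = assay_slope,
       halophiles = halophiles)
}

#' Generate site metadata along the synthetic gradients
#'
#' Lays out soil EC log-uniformly from the low to the high end of each
#' gradient along the sampling points of every transect (plus small
#' between-transect noise), assigns soil pH either independently within the
#' gradient's range or, for gradients with `ec_ph_cor < 0`, decreasing with
#' log soil EC plus noise, and draws organic-matter content uniformly
#' within the gradient's range.
#'
#' @param design a design configuration from [gradient_design()].
#' @param seed integer seed; output is deterministic given the seed.
#' @return a data.frame with columns `sample_id`, `gradient`, `transect`,
#'   `point`, `soil_ec`, `soil_ph`, `om_pct`.
#' @examples
#' md <- generate_gradient_metadata(gradient_design(), seed = 1)
#' table(md$gradient)
#' @export
generate_gradient_metadata <- function(design = gradient_design(), seed) {
  set.seed(derive_seed(seed, 11L))
  out <- list()
  for (g in names(design$gradients)) {
    cfg <- design$gradients[[g]]
    if (any(cfg$ec_range <= 0))
      stop("soil EC range bounds must be strictly positive")
    lec_lo <- log10(cfg$ec_range[1]); lec_hi <- log10(cfg$ec_range[2])
    for (tr in LETTERS[seq_len(design$n_transects)]) {
      pts <- seq_len(design$n_points)
      frac <- if (design$n_points == 1) 0.5 else (pts - 1) / (design$n_points - 1)
      lec <- lec_lo + frac * (lec_hi - lec_lo) +
        rnorm(design$n_points, 0, design$ec_noise_sd)
      if (!is.null(cfg$ec_ph_cor) && cfg$ec_ph_cor < 0) {
        t01 <- (lec - lec_lo) / max(lec_hi - lec_lo, 1e-12)
        ph <- cfg$ph_range[2] - t01 * diff(cfg$ph_range) +
          rnorm(design$n_points, 0, design$ph_noise_sd)
      } else {
        ph <- runif(design$n_points, cfg$ph_range[1], cfg$ph_range[2])
      }
      ph <- pmin(pmax(ph, 3), 10)
      out[[paste(g, tr)]] <- data.frame(
        sample_id = sprintf("%s_%s%d", g, tr, pts),
        gradient = g, transect = tr, point = pts,
        soil_ec = 10^lec, soil_ph = ph,
        om_pct = runif(design$n_points, cfg$om_range[1], cfg$om_range[2]),
        stringsAsFactors = FALSE)
    }
  }
  md <- do.call(rbind, out)
  rownames(md) <- NULL
  stopifnot(!anyDuplicated(md$sample_id))
  md
}

## small pool of plausible 16S lineages for synthetic taxonomy strings
taxonomy_pool <- function() {
  c("k__Bacteria;p__Proteobacteria;c__Alphaproteobacteria;o__Sphingomonadales;f__Sphingomonadaceae;g__Sphingomonas;s__",
    "k__Bacteria;p__Proteobacteria;c__Gammaproteobacteria;o__Xanthomonadales;f__Xanthomonadaceae;g__Lysobacter;s__",
    "k__Bacteria;p__Bacteroidetes;c__Saprospirae;o__Saprospirales;f__Chitinophagaceae;g__;s__",
    "k__Bacteria;p__Actinobacteria;c__Actinobacteria;o__Actinomycetales;f__Micrococcaceae;g__Arthrobacter;s__",
    "k__Bacteria;p__Gemmatimonadetes;c__Gemmatimonadetes;o__Gemmatimonadales;f__Gemmatimonadaceae;g__;s__",
    "k__Bacteria;p__Planctomycetes;c__Planctomycetia;o__Pirellulales;f__Pirellulaceae;g__;s__",
    "k__Bacteria;p__Firmicutes;c__Bacilli;o__Bacillales;f__Bacillaceae;g__Bacillus;s__",
    "k__Bacteria;p__Acidobacteria;c__Acidobacteriia;o__Acidobacteriales;f__Acidobacteriaceae;g__;s__",
    "k__Archaea;p__Euryarchaeota;c__Halobacteria;o__Halobacteriales;f__Halobacteriaceae;g__;s__",
    "k__Archaea;p__Thaumarchaeota;c__;o__Nitrososphaerales;f__Nitrososphaeraceae;g__;s__")
}

#' Generate a taxa pool with salt and pH niches
#'
#' Draws `n_taxa` taxa whose salt tolerance (per-taxon logIC50 on the
#' log10 suspension-EC axis) comes from a salt-sensitive / halotolerant
#' mixture, whose pH niches are Gaussian (optimum and breadth), and whose
#' base abundances are log-normal. These niches are the ground truth that
#' both the OTU table and the aggregate growth assays are generated from.
#'
#' @param n_taxa number of taxa (at least 2).
#' @param niche a niche configuration from [niche_config()].
#' @param seed integer seed.
#' @return a data.frame with columns `otu_id`, `taxonomy`, `salt_logic50`,
#'   `ph_optimum`, `ph_breadth`, `base_abundance`, `halophile`.
#' @export
generate_taxa <- function(n_taxa, niche = niche_config(), seed) {
  if (n_taxa < 2) stop("need at least 2 taxa")
  set.seed(derive_seed(seed, 23L))
  tolerant <- runif(n_taxa) < niche$frac_tolerant
  mu <- ifelse(tolerant, niche$mean_tolerant, niche$mean_sensitive)
  data.frame(
    otu_id = sprintf("OTU_%04d", seq_len(n_taxa)),
    taxonomy = sample(taxonomy_pool(), n_taxa, replace = TRUE),
    salt_logic50 = rnorm(n_taxa, mu, niche$salt_sd),
    ph_optimum = runif(n_taxa, niche$ph_opt_range[1], niche$ph_opt_range[2]),
    ph_breadth = rlnorm(n_taxa, niche$breadth_meanlog, niche$breadth_sdlog),
    base_abundance = rlnorm(n_taxa, 0, niche$abundance_sdlog),
    halophile = tolerant & isTRUE(niche$halophiles),
    stringsAsFactors = FALSE)
}

## Environmental filter of taxon abundance along soil EC: a decreasing
## logistic in log10(soil EC) centred on the taxon's salt tolerance, times
## (for obligate halophiles) an increasing logistic two log-units below it.
salt_niche_weight <- function(log_ec, taxa, slope) {
  w <- 1 / (1 + exp(slope * (log_ec - taxa$salt_logic50)))
  if (any(taxa$halophile)) {
    low <- 1 / (1 + exp(-slope * (log_ec - (taxa$salt_logic50 - 2))))
    w <- ifelse(taxa$halophile, w * low, w)
  }
  w
}

ph_niche_weight <- function(ph, taxa) {
  exp(-(ph - taxa$ph_optimum)^2 / (2 * taxa$ph_breadth^2))
}

#' Expected community composition under the niche filters
#'
#' For each site, the expected relative abundance of each taxon is
#' proportional to its base abundance times a decreasing logistic filter of
#' log10 soil EC centred on its salt tolerance, times a Gaussian filter of
#' soil pH centred on its pH optimum. Rows are normalised to sum to 1;
#' these are the multinomial probabilities behind [generate_otu_table()]
#' and the weights behind the community-aggregate assays.
#'
#' @param sites site metadata ([generate_gradient_metadata()]).
#' @param taxa taxa pool ([generate_taxa()]).
#' @param filter_slope steepness of the salt abundance filter.
#' @return a samples x taxa matrix of expected relative abundances.
#' @export
expected_composition <- function(sites, taxa, filter_slope = 3) {
  if (nrow(taxa) == 0) stop("taxa pool is empty")
  p <- matrix(NA_real_, nrow(sites), nrow(taxa),
              dimnames = list(sites$sample_id, taxa$otu_id))
  for (i in seq_len(nrow(sites))) {
    w <- taxa$base_abundance *
      salt_niche_weight(log10(sites$soil_ec[i]), taxa, filter_slope) *
      ph_niche_weight(sites$soil_ph[i], taxa)
    if (sum(w) <= 0) stop("no taxon can live at site ", sites$sample_id[i])
    p[i, ] <- w / sum(w)
  }
  p
}

#' Generate an OTU count table by multinomial sampling
#'
#' Draws `read_depth` reads per sample from the expected composition of
#' [expected_composition()], emulating a finished amplicon OTU table
#' (sequencing itself — PCR, clustering, taxonomy assignment — is not
#' simulated).
#'
#' @inheritParams expected_composition
#' @param read_depth reads per sample (>= 1).
#' @param seed integer seed.
#' @return an [otu_table()] of samples x taxa counts with taxonomy.
#' @export
generate_otu_table <- function(sites, taxa, read_depth = 12000, seed,
                               filter_slope = 3) {
  if (read_depth < 1) stop("read_depth must be at least 1")
  if (nrow(taxa) == 0) stop("taxa pool is empty")
  p <- expected_composition(sites, taxa, filter_slope)
  set.seed(derive_seed(seed, 37L))
  counts <- matrix(0, nrow(p), ncol(p), dimnames = dimnames(p))
  for (i in seq_len(nrow(p)))
    counts[i, ] <- rmultinom(1, read_depth, p[i, ])[, 1]
  otu_table(counts, taxonomy = setNames(taxa$taxonomy, taxa$otu_id))
}

## default salt assay levels: control at the sample's baseline suspension
## EC (soil EC / 10, the 1:5 extract diluted further into the assay
## suspension) plus seven NaCl additions spanning 0.007-5.5 mol/l,
## converted to EC at ~85 dS/m per mol/l NaCl.
salt_assay_levels <- function(soil_ec, n_added = 7) {
  base <- soil_ec / 10
  mols <- exp(seq(log(0.007), log(5.5), length.out = n_added))
  c(base, base + 85 * mols)
}

## default pH assay levels: buffered series pH 3-8 in 0.5 steps plus the
## unbuffered suspension at the sample's own soil pH (12 levels)
ph_assay_levels <- function(soil_ph) {
  lv <- seq(3, 8, by = 0.5)
  own <- soil_ph
  while (any(abs(lv - own) < 1e-6)) own <- own + 0.01
  c(lv, own)
}

## per-taxon growth response matrices (levels x taxa), unit maximal rate
taxon_salt_response <- function(log_ec, taxa, assay_slope) {
  r <- sapply(seq_len(nrow(taxa)), function(t)
    1 / (1 + exp(assay_slope * (log_ec - taxa$salt_logic50[t]))))
  r <- matrix(r, nrow = length(log_ec))
  if (any(taxa$halophile)) {
    for (t in which(taxa$halophile)) {
      r[, t] <- r[, t] /
        (1 + exp(-assay_slope * (log_ec - (taxa$salt_logic50[t] - 2))))
    }
  }
  r
}

taxon_ph_response <- function(ph, taxa) {
  r <- sapply(seq_len(nrow(taxa)), function(t)
    exp(-(ph - taxa$ph_optimum[t])^2 / (2 * taxa$ph_breadth[t]^2)))
  matrix(r, nrow = length(ph))
}

#' Generate a community-aggregate dose-response assay
#'
#' Community growth at each assay level is the abundance-weighted sum of
#' per-taxon responses: a decreasing logistic in log10 suspension EC for
#' salt (centred on each taxon's salt tolerance), a Gaussian in suspension
#' pH for pH. Multiplicative log-normal noise with coefficient of variation
#' `noise_cv` (mean 1) is applied on top. The no-salt control level sits at
#' the sample's baseline suspension EC, taken as `soil_ec / 10`.
#'
#' @param site one row of site metadata.
#' @param taxa taxa pool.
#' @param abundances relative abundances of the taxa at this site
#'   (sums to 1).
#' @param stressor `"salt"` or `"ph"`.
#' @param levels assay levels; defaults to the standard 8-level salt /
#'   12-level pH design.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @param assay_slope per-taxon logistic slope for the salt response.
#' @return a [dose_response_assay()].
#' @export
generate_assay <- function(site, taxa, abundances,
                           stressor = c("salt", "ph"), levels = NULL,
                           noise_cv = 0.05, seed = 1, assay_slope = 4) {
  stressor <- match.arg(stressor)
  if (noise_cv < 0) stop("noise coefficient of variation must be non-negative")
  stopifnot(length(abundances) == nrow(taxa))
  if (abs(sum(abundances) - 1) > 1e-6)
    stop("abundances must sum to 1")
  if (stressor == "salt") {
    if (is.null(levels)) levels <- salt_assay_levels(site$soil_ec)
    if (any(levels <= 0)) stop("salt levels (suspension EC) must be positive")
    mu <- as.vector(taxon_salt_response(log10(levels), taxa, assay_slope) %*%
                      abundances)
  } else {
    if (is.null(levels)) levels <- ph_assay_levels(site$soil_ph)
    mu <- as.vector(taxon_ph_response(levels, taxa) %*% abundances)
  }
  set.seed(derive_seed(seed, 101L))
  g <- apply_lognormal_noise(mu, noise_cv)
  dose_response_assay(site$sample_id, stressor, levels, g)
}

#' True community-aggregate salt tolerance of a noise-free curve
#'
#' Computes the ground-truth logIC50 of the noise-free aggregate salt
#' response by dense grid search: the log10 suspension EC at which the
#' aggregate curve falls to half its maximum over the grid, refined by
#' root finding.
#'
#' @inheritParams generate_assay
#' @param interval log10 suspension-EC interval to search.
#' @return the true aggregate logIC50 (log10 dS/m).
#' @export
true_salt_ic50 <- function(taxa, abundances, assay_slope = 4,
                           interval = c(-4, 4)) {
  f <- function(x) as.vector(taxon_salt_response(x, taxa, assay_slope) %*%
                               abundances)
  grid <- seq(interval[1], interval[2], by = 0.001)
  v <- f(grid)
  gmax <- max(v)
  i_max <- which.max(v)
  below <- which(v[i_max:length(v)] < gmax / 2)
  if (length(below) == 0)
    stop("aggregate curve never falls below half-maximum inside the interval")
  j <- i_max + below[1] - 1
  stats::uniroot(function(x) f(x) - gmax / 2,
                 lower = grid[j - 1], upper = grid[j], tol = 1e-10)$root
}

#' True community-aggregate pH optimum of a noise-free curve
#'
#' @inheritParams true_salt_ic50
#' @param interval suspension-pH interval to search.
#' @return the pH maximising the noise-free aggregate pH response.
#' @export
true_ph_optimum <- function(taxa, abundances, interval = c(2.5, 10)) {
  f <- function(x) as.vector(taxon_ph_response(x, taxa) %*% abundances)
  grid <- seq(interval[1], interval[2], by = 0.001)
  grid[which.max(f(grid))]
}

#' Simulate a complete tolerance-gradient study
#'
#' Generates, from one master seed, the full synthetic data set the
#' pipeline consumes: site metadata for the two gradients, a niche-
#' structured taxa pool, a multinomially sampled OTU count table, salt and
#' pH dose-response assays for every sample (aggregated from the same
#' expected composition as the OTU table), and the per-sample ground-truth
#' trait values computed from the noise-free aggregate curves. Per-sample
#' assay seeds are derived from the master seed with a counter scheme, so
#' every component is reproducible and independent.
#'
#' @param seed master integer seed.
#' @param n_taxa taxa pool size.
#' @param read_depth sequencing depth per sample.
#' @param noise_cv assay noise coefficient of variation.
#' @param design design configuration ([gradient_design()]).
#' @param niche niche configuration ([niche_config()]).
#' @return an object of class `tolgrad_study`: a list with `metadata`,
#'   `taxa`, `otu` (an [otu_table()]), `composition` (expected relative
#'   abundances), `assays` (named list of [dose_response_assay()], salt and
#'   pH per sample), and `truth` (per-sample true aggregate `log_ic50` and
#'   `ph_opt`).
#' @examples
#' \donttest{
#' study <- simulate_study(seed = 1, n_taxa = 100, read_depth = 2000)
#' study$truth[1:3, ]
#' }
#' @export
simulate_study <- function(seed, n_taxa = 500, read_depth = 12000,
                           noise_cv = 0.05, design = gradient_design(),
                           niche = niche_config()) {
  metadata <- generate_gradient_metadata(design, seed = derive_seed(seed, 1L))
  taxa <- generate_taxa(n_taxa, niche, seed = derive_seed(seed, 2L))
  comp <- expected_composition(metadata, taxa, niche$filter_slope)
  otu <- generate_otu_table(metadata, taxa, read_depth,
                            seed = derive_seed(seed, 3L),
                            filter_slope = niche$filter_slope)
  assays <- list()
  truth <- data.frame(sample_id = metadata$sample_id,
                      log_ic50 = NA_real_, ph_opt = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(metadata))) {
    site <- metadata[i, ]
    ab <- comp[i, ]
    assays[[paste0(site$sample_id, ".salt")]] <-
      generate_assay(site, taxa, ab, "salt", noise_cv = noise_cv,
                     seed = derive_seed(seed, 1000L + i),
                     assay_slope = niche$assay_slope)
    assays[[paste0(site$sample_id, ".ph")]] <-
      generate_assay(site, taxa, ab, "ph", noise_cv = noise_cv,
                     seed = derive_seed(seed, 2000L + i))
    truth$log_ic50[i] <- true_salt_ic50(taxa, ab, niche$assay_slope)
    truth$ph_opt[i] <- true_ph_optimum(taxa, ab)
  }
  structure(list(metadata = metadata, taxa = taxa, composition = comp,
                 otu = otu, assays = assays, truth = truth,
                 seed = seed, noise_cv = noise_cv),
            class = "tolgrad_study")
}

#' @export
print.tolgrad_study <- function(x, ...) {
  cat(sprintf(paste0("<tolgrad_study> %d samples across %d gradients, ",
                     "%d taxa, %d assays (master seed %d)\n"),
              nrow(x$metadata), length(unique(x$metadata$gradient)),
              nrow(x$taxa), length(x$assays), x$seed))
  invisible(x)
}

#' Long-format table of all assays in a study
#'
#' @param study a `tolgrad_study`.
#' @return a data.frame with columns `sample_id`, `stressor`, `level`,
#'   `growth`.
#' @export
assay_table <- function(study) {
  stopifnot(inherits(study, "tolgrad_study"))
  do.call(rbind, lapply(study$assays, function(a)
    data.frame(sample_id = a$sample_id, stressor = a$stressor,
               level = a$levels, growth = a$growth,
               stringsAsFactors = FALSE, row.names = NULL)))
}
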