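# Shared fixtures, built in code at load time.

# assay sampled from a known single-logistic curve on the log10-EC axis
make_single_assay <- function(a = 0.8, b = 3, cmax = 1,
                              x = seq(-1.5, 2, length.out = 8),
                              noise_cv = 0, seed = NULL,
                              sample_id = "fix") {
  if (!is.null(seed)) set.seed(seed)
  g <- logistic(x, a, b, cmax)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    g <- g * rlnorm(length(g), -sdlog^2 / 2, sdlog)
  }
  dose_response_assay(sample_id, "salt", 10^x, g)
}

# assay sampled from a known double-logistic curve
make_double_assay <- function(a_low, b_low, a_high, b_high, c_opt = 1,
                              x, stressor = "salt", noise_cv = 0,
                              seed = NULL, sample_id = "fix") {
  if (!is.null(seed)) set.seed(seed)
  g <- double_logistic(x, a_low, b_low, a_high, b_high, c_opt)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    g <- g * rlnorm(length(g), -sdlog^2 / 2, sdlog)
  }
  levels <- if (stressor == "salt") 10^x else x
  dose_response_assay(sample_id, stressor, levels, pmax(g, 0))
}

ph_levels_12 <- c(seq(3, 8, by = 0.5), 6.23)

# small labelled count matrix
make_counts <- function(n_samples = 6, n_otus = 10, seed = 99,
                        lambda = 40) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_otus, lambda), n_samples, n_otus,
              dimnames = list(paste0("s", seq_len(n_samples)),
                              paste0("OTU_", seq_len(n_otus))))
  m
}

# a small but complete synthetic study, computed once per test run
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_study(seed = 42, n_taxa = 150, read_depth = 2000)
    cache
  }
})

# Euclidean dist of labelled 2D points
points_dist <- function(n = 8, seed = 5) {
  set.seed(seed)
  xy <- matrix(rnorm(2 * n), n, 2,
               dimnames = list(paste0("s", seq_len(n)), NULL))
  list(xy = xy, d = dist(xy))
}
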