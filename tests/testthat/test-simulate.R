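test_that("gradient metadata follows the two-gradient, 3x8 design", {
  md <- generate_gradient_metadata(gradient_design(), seed = 1)
  expect_equal(nrow(md), 48)
  expect_equal(as.integer(table(md$gradient)), c(24L, 24L))
  expect_false(anyDuplicated(md$sample_id) > 0)
  expect_true(all(md$soil_ec > 0))
  expect_true(all(md$soil_ph >= 3 & md$soil_ph <= 10))
  # EC spans the configured decade along points, increasing on average
  ag <- md[md$gradient == "AG", ]
  expect_gt(cor(ag$point, log10(ag$soil_ec)), 0.9)
  # NV gradient: soil pH decreases with log soil EC by construction
  nv <- md[md$gradient == "NV", ]
  expect_lt(cor(log10(nv$soil_ec), nv$soil_ph), 0)
})

test_that("metadata generation respects custom designs and rejects bad ones", {
  small <- gradient_design(n_transects = 1, n_points = 2)
  expect_equal(nrow(generate_gradient_metadata(small, seed = 1)), 4)
  bad <- gradient_design()
  bad$gradients$AG$ec_range <- c(0, 3)
  expect_error(generate_gradient_metadata(bad, seed = 1),
               "strictly positive")
  # deterministic under a fixed seed
  expect_identical(generate_gradient_metadata(seed = 9),
                   generate_gradient_metadata(seed = 9))
})

test_that("taxa generation produces unique, reproducible, configurable niches", {
  tx <- generate_taxa(500, niche_config(), seed = 7)
  expect_equal(nrow(tx), 500)
  expect_false(anyDuplicated(tx$otu_id) > 0)
  expect_true(all(is.finite(tx$salt_logic50)))
  expect_true(all(tx$ph_breadth > 0))
  expect_identical(tx, generate_taxa(500, niche_config(), seed = 7))
  # degenerate config: point mass at 0.5
  deg <- niche_config(frac_tolerant = 0, mean_sensitive = 0.5, salt_sd = 0)
  expect_true(all(generate_taxa(10, deg, seed = 1)$salt_logic50 == 0.5))
  expect_error(generate_taxa(1, seed = 1), "at least 2")
})

test_that("OTU tables are multinomial draws from the niche-filter expectation", {
  md <- generate_gradient_metadata(gradient_design(), seed = 3)[1:4, ]
  tx <- generate_taxa(30, niche_config(), seed = 3)
  tab <- generate_otu_table(md, tx, read_depth = 500, seed = 3)
  expect_equal(unname(rowSums(tab$counts)), rep(500, 4))
  expect_identical(colnames(tab$counts), tx$otu_id)
  # one-taxon degenerate simplex: all reads in that column
  one <- tx[5, , drop = FALSE]
  t1 <- generate_otu_table(md, rbind(one, one[0, ]), 200, seed = 1)
  expect_true(all(t1$counts[, 1] == 200))
  expect_error(generate_otu_table(md, tx[0, ], 100, seed = 1), "empty")
})

test_that("empirical OTU shares converge to the closed-form expectation", {
  # high-salt site where only one halotolerant taxon thrives
  site <- data.frame(sample_id = "hot", gradient = "NV", transect = "A",
                     point = 1, soil_ec = 30, soil_ph = 7, om_pct = 5)
  tx <- data.frame(otu_id = c("tol", "s1", "s2"),
                   taxonomy = NA_character_,
                   salt_logic50 = c(1.8, -0.5, -0.2),
                   ph_optimum = c(7, 7, 7), ph_breadth = c(2, 2, 2),
                   base_abundance = c(1, 3, 2), halophile = FALSE)
  p_exp <- expected_composition(site, tx)[1, ]
  expect_gt(p_exp[["tol"]], 0.9)
  set.seed(404)
  shares <- replicate(200, {
    draw <- rmultinom(1, 400, p_exp)[, 1] / 400
    draw[["tol"]]
  })
  se <- sqrt(p_exp[["tol"]] * (1 - p_exp[["tol"]]) / 400) / sqrt(200)
  expect_lt(abs(mean(shares) - p_exp[["tol"]]), 4 * se + 1e-3)
  # and the generator itself matches the expectation at large depth
  big <- generate_otu_table(site, tx, read_depth = 50000, seed = 8)
  gof <- suppressWarnings(
    stats::chisq.test(big$counts[1, ], p = p_exp))
  expect_gt(gof$p.value, 0.01)
})

test_that("aggregate assays equal the abundance-weighted sum of taxon responses", {
  site <- data.frame(sample_id = "s", soil_ec = 1, soil_ph = 6.5)
  one <- data.frame(otu_id = "t1", taxonomy = NA, salt_logic50 = 0.7,
                    ph_optimum = 6, ph_breadth = 1.5, base_abundance = 1,
                    halophile = FALSE)
  a <- generate_assay(site, one, 1, "salt", noise_cv = 0, seed = 1,
                      assay_slope = 4)
  # single taxon, no noise: exactly that taxon's logistic curve
  expect_equal(a$growth, logistic(log10(a$levels), 0.7, 4, 1),
               tolerance = 1e-12)
  # control level sits at the baseline suspension EC, soil EC / 10
  expect_equal(min(a$levels), 0.1)
  # vanishing stress recovers the unstressed total
  lo <- generate_assay(site, one, 1, "salt", levels = 1e-8, noise_cv = 0,
                       seed = 1)
  expect_equal(lo$growth, 1, tolerance = 1e-6)
  # two equal-abundance taxa, hand-computed two-term average at x = 0.5
  two <- rbind(one, one)
  two$otu_id <- c("t1", "t2"); two$salt_logic50 <- c(0, 1)
  mid <- generate_assay(site, two, c(0.5, 0.5), "salt",
                        levels = 10^0.5, noise_cv = 0, seed = 1,
                        assay_slope = 4)
  hand <- 0.5 / (1 + exp(4 * 0.5)) + 0.5 / (1 + exp(4 * -0.5))
  expect_equal(mid$growth, hand, tolerance = 1e-12)
  expect_error(generate_assay(site, one, 1, "salt", noise_cv = -0.1),
               "non-negative")
  expect_error(generate_assay(site, two, c(0.9, 0.3), "salt"), "sum to 1")
})

test_that("noise-free aggregate salt curves are non-increasing", {
  tx <- generate_taxa(40, niche_config(), seed = 12)
  site <- data.frame(sample_id = "s", soil_ec = 2, soil_ph = 6.5)
  ab <- expected_composition(site, tx)[1, ]
  a <- generate_assay(site, tx, ab, "salt", noise_cv = 0, seed = 1)
  expect_true(all(diff(a$growth) <= 1e-12))
})

test_that("true aggregate logIC50 never decreases as soil EC increases", {
  tx <- generate_taxa(60, niche_config(), seed = 21)
  ic50 <- vapply(c(0.1, 0.3, 1, 3, 9), function(ec) {
    site <- data.frame(sample_id = "s", soil_ec = ec, soil_ph = 6.5)
    ab <- expected_composition(site, tx)[1, ]
    true_salt_ic50(tx, ab)
  }, numeric(1))
  expect_true(all(diff(ic50) >= -1e-8))
})

test_that("a full study is reproducible byte-for-byte under one master seed", {
  s1 <- simulate_study(seed = 5, n_taxa = 25, read_depth = 300)
  s2 <- simulate_study(seed = 5, n_taxa = 25, read_depth = 300)
  expect_identical(s1, s2)
  s3 <- simulate_study(seed = 6, n_taxa = 25, read_depth = 300)
  expect_false(identical(s1$otu$counts, s3$otu$counts))
  # long-format assay table covers every assay level
  long <- assay_table(s1)
  expect_equal(nrow(long), sum(vapply(s1$assays, function(a)
    length(a$levels), numeric(1))))
})
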