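test_that("Bray-Curtis dissimilarities match hand computations", {
  m <- rbind(s1 = c(1, 1), s2 = c(1, 3), s3 = c(1, 1), s4 = c(0, 5))
  colnames(m) <- c("a", "b")
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["s1", "s3"], 0)
  expect_equal(d["s1", "s2"], 2 / 6, tolerance = 1e-12)
  disj <- rbind(s1 = c(3, 0), s2 = c(0, 7)); colnames(disj) <- c("a", "b")
  expect_equal(as.numeric(bray_curtis(disj)), 1)
  expect_true(all(d >= 0 & d <= 1))
  expect_error(bray_curtis(rbind(s1 = c(0, 0), s2 = c(1, 1))), "zero-sum")
})

test_that("PCoA round-trips Euclidean-embeddable distances", {
  pts <- points_dist(n = 9, seed = 5)
  pc <- pcoa_ord(pts$d)
  # no spurious negative eigenvalues for metric input
  expect_lt(pc$negative_total, 1e-8)
  # pairwise distances among scores reproduce the input distances
  expect_equal(as.matrix(dist(pc$scores)), as.matrix(pts$d),
               tolerance = 1e-8)
  expect_true(all(diff(pc$eigenvalues) <= 1e-10))  # non-increasing
  # three equidistant points: two equal positive eigenvalues
  tri <- matrix(0, 3, 3, dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  tri[upper.tri(tri)] <- 1; tri <- tri + t(tri)
  e <- pcoa_ord(tri)$eigenvalues
  expect_equal(e[1], e[2], tolerance = 1e-12)
  expect_error(pcoa_ord(dist(rnorm(2))), "at least 3")
})

test_that("dbRDA recovers a perfect axis constraint and rejects rank deficiency", {
  pts <- points_dist(n = 10, seed = 8)
  pc <- pcoa_ord(pts$d)
  share <- pc$eigenvalues[1] / sum(pc$eigenvalues[pc$eigenvalues > 0])
  cons <- data.frame(ax1 = pc$scores[, 1], row.names = pc$labels)
  res <- dbrda_traits(pts$d, cons, n_perm = 99, seed = 1)
  expect_equal(res$constrained_fraction, share, tolerance = 1e-6)
  expect_lte(res$permutation_p[["ax1"]], 0.02)  # at the permutation floor
  # duplicated constraint columns are collinear
  cons2 <- data.frame(ax1 = pc$scores[, 1], ax1b = pc$scores[, 1],
                      row.names = pc$labels)
  expect_error(dbrda_traits(pts$d, cons2, n_perm = 9), "rank deficient")
  # mismatched labels are refused
  cons3 <- data.frame(ax1 = pc$scores[, 1],
                      row.names = paste0("x", 1:10))
  expect_error(dbrda_traits(pts$d, cons3, n_perm = 9), "do not match")
})

test_that("adding constraints never lowers the constrained fraction", {
  pts <- points_dist(n = 10, seed = 12)
  set.seed(3)
  cons <- data.frame(c1 = rnorm(10), c2 = rnorm(10),
                     row.names = attr(pts$d, "Labels"))
  f1 <- dbrda_traits(pts$d, cons["c1"], n_perm = 9, seed = 1)$constrained_fraction
  f12 <- dbrda_traits(pts$d, cons, n_perm = 9, seed = 1)$constrained_fraction
  expect_gte(f12, f1 - 1e-12)
  expect_lte(f12, 1)
})

test_that("Mantel statistic behaves as a rank correlation of distances", {
  pts <- points_dist(n = 8, seed = 2)
  r <- mantel_traits(pts$d, pts$d, n_perm = 99, seed = 1)
  expect_equal(r$rho, 1)
  expect_equal(r$n_pairs, 28)
  # invariant under monotone transformation of one matrix
  d2 <- as.matrix(pts$d)^2
  r2 <- mantel_traits(pts$d, d2, n_perm = 99, seed = 1)
  expect_equal(r2$rho, 1)
  # label mismatch refused
  bad <- as.matrix(pts$d); rownames(bad) <- colnames(bad) <- paste0("x", 1:8)
  expect_error(mantel_traits(pts$d, bad, n_perm = 9), "do not match")
})

test_that("sampled Mantel p converges to the exhaustive 5-sample enumeration", {
  set.seed(42)
  xy1 <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("s", 1:5), NULL))
  v2 <- rnorm(5); names(v2) <- rownames(xy1)
  d1 <- dist(xy1); d2 <- dist(v2)
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  rho_obs <- cor(m1[upper.tri(m1)], m2[upper.tri(m2)], method = "spearman")
  # exhaustive null: all 5! joint row/column relabelings of d2
  all_perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  all_perms <- all_perms[apply(all_perms, 1, function(r)
    length(unique(r)) == 5), , drop = FALSE]
  rho_null <- apply(all_perms, 1, function(pm) {
    mp <- m2[pm, pm]
    cor(m1[upper.tri(m1)], mp[upper.tri(mp)], method = "spearman")
  })
  p_exact <- mean(rho_null >= rho_obs - 1e-12)
  r <- mantel_traits(d1, d2, n_perm = 9999, seed = 4)
  expect_equal(r$rho, rho_obs, tolerance = 1e-12)
  expect_lt(abs(r$p_value - p_exact), 0.03)
})

test_that("trait distances are one-dimensional Euclidean metrics", {
  prof <- data.frame(sample_id = c("a", "b", "c"),
                     log_ic50 = c(1, 3, 2.5), ph_opt = c(6, 6, 6))
  d <- as.matrix(trait_distance(prof, "log_ic50"))
  expect_equal(d["a", "b"], 2)
  expect_lte(d["a", "c"], d["a", "b"] + d["b", "c"] + 1e-12)
  expect_true(all(as.matrix(trait_distance(prof, "ph_opt")) == 0))
  prof$log_ic50[2] <- NA
  expect_error(trait_distance(prof, "log_ic50"), "b")
})

test_that("distance-decay regression reads off a planted linear relation", {
  prof <- data.frame(sample_id = paste0("s", 1:7),
                     log_ic50 = seq(0, 3, by = 0.5))
  d_tr <- trait_distance(prof, "log_ic50")
  m <- 0.1 + 0.2 * as.matrix(d_tr); diag(m) <- 0
  res <- distance_decay_slope(stats::as.dist(m), d_tr)
  expect_equal(res$slope, 0.2, tolerance = 1e-10)
  expect_equal(res$intercept, 0.1, tolerance = 1e-10)
  expect_equal(res$n_pairs, 21)
  # relabeling samples leaves the slope unchanged
  perm <- c(3, 1, 2, 7, 5, 6, 4)
  m2 <- m[perm, perm]
  res2 <- distance_decay_slope(stats::as.dist(m2), d_tr)
  expect_equal(res2$slope, res$slope, tolerance = 1e-10)
  # unrelated pairing carries no systematic slope
  set.seed(9)
  slopes <- replicate(50, {
    v <- rnorm(7); names(v) <- prof$sample_id
    distance_decay_slope(stats::as.dist(m), dist(v))$slope
  })
  expect_lt(abs(mean(slopes)), 0.05)
  expect_error(distance_decay_slope(stats::as.dist(m),
                                    trait_distance(data.frame(
                                      sample_id = prof$sample_id,
                                      log_ic50 = rep(1, 7)), "log_ic50")),
               "zero variance")
})

test_that("the trait-equivalence ratio is the slope quotient", {
  expect_equal(equivalence_ratio(0.2, 0.4), 0.5)
  expect_equal(equivalence_ratio(0.3, 0.3), 1)
  expect_equal(equivalence_ratio(0, 0.4), 0)
  expect_error(equivalence_ratio(0.2, 0), "zero")
})
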