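#' Bray-Curtis dissimilarity matrix
#'
#' Pairwise Bray-Curtis dissimilarities between samples,
#' d(i,j) = sum|x_i - x_j| / sum(x_i + x_j) over features. Apply to the
#' [hellinger()]-transformed table to reproduce the standard compositional
#' distance used throughout the linkage analyses.
#'
#' @param mat a non-negative samples x features matrix (e.g. Hellinger-
#'   transformed counts) with no zero-sum rows.
#' @return a `dist` object with sample labels.
#' @export
bray_curtis <- function(mat) {
  mat <- if (inherits(mat, "otu_table")) mat$counts else as.matrix(mat)
  if (any(mat < 0)) stop("Bray-Curtis requires non-negative data")
  rs <- rowSums(mat)
  if (any(rs <= 0))
    stop("zero-sum samples: ", paste(rownames(mat)[rs <= 0], collapse = ", "))
  vegan::vegdist(mat, method = "bray")
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: eigendecomposition of the double-centred
#' squared-distance matrix. Axes with eigenvalue above `tol` are retained
#' and scaled by the square root of their eigenvalue, so Euclidean
#' distances among scores reproduce Euclidean-embeddable input distances.
#' Negative eigenvalues (from non-Euclidean dissimilarities such as
#' Bray-Curtis) are reported, with their total magnitude, but excluded
#' from the scores.
#'
#' @param d a `dist` or labelled symmetric matrix with at least 3 samples.
#' @param tol eigenvalue threshold for retaining an axis.
#' @return an object of class `tol_pcoa`: `eigenvalues` (all, decreasing),
#'   `scores` (samples x retained axes), `variance_explained` (share of the
#'   positive eigenvalue total per retained axis), `negative_total`
#'   (summed magnitude of negative eigenvalues), `labels`.
#' @export
pcoa_ord <- function(d, tol = 1e-8) {
  m <- as.matrix(d)
  n <- nrow(m)
  if (n < 3) stop("PCoA needs at least 3 samples")
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix is not symmetric")
  a <- -0.5 * m^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  b <- ctr %*% a %*% ctr
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  keep <- e$values > tol
  scores <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep))
  rownames(scores) <- rownames(m)
  colnames(scores) <- paste0("PCo", seq_len(ncol(scores)))
  structure(list(
    eigenvalues = e$values,
    scores = scores,
    variance_explained = e$values[keep] / sum(e$values[e$values > 0]),
    negative_total = sum(abs(e$values[e$values < -tol])),
    labels = rownames(m)), class = "tol_pcoa")
}

#' @export
print.tol_pcoa <- function(x, ...) {
  cat(sprintf("<tol_pcoa> %d samples, %d retained axes", length(x$labels),
              ncol(x$scores)))
  cat(sprintf("; axis 1-2 variance %.1f%%, %.1f%%\n",
              100 * x$variance_explained[1],
              100 * ifelse(length(x$variance_explained) > 1,
                           x$variance_explained[2], NA)))
  if (x$negative_total > 0)
    cat(sprintf("  negative eigenvalues excluded (total magnitude %.3g)\n",
                x$negative_total))
  invisible(x)
}

#' Distance-based redundancy analysis constrained by community traits
#'
#' Constrained ordination of a community dissimilarity matrix (capscale-
#' style dbRDA): principal coordinates of the dissimilarities are
#' regressed on the constraining variables — typically the community trait
#' indicators logIC50 and pH_opt plus a gradient indicator. Reports the
#' fraction of total inertia explained by the constraints and a marginal
#' permutation test per constraint (each term tested against the model
#' containing all others).
#'
#' @param d a `dist` of community dissimilarities.
#' @param constraints data.frame of constraining variables; rows matched
#'   to `d` by rownames (or a `sample_id` column). Factors/characters
#'   enter as indicator variables.
#' @param n_perm number of permutations for the marginal tests.
#' @param seed integer seed for the permutations.
#' @return an object of class `tol_dbrda`: `eigenvalues` (constrained then
#'   unconstrained), `site_scores`, `constrained_fraction`,
#'   `permutation_p` (named per constraint), `n_permutations`, and the
#'   underlying vegan model as `model`.
#' @export
dbrda_traits <- function(d, constraints, n_perm = 10000, seed = 1) {
  labels <- attr(d, "Labels")
  if (is.null(labels)) labels <- rownames(as.matrix(d))
  if ("sample_id" %in% names(constraints)) {
    rownames(constraints) <- constraints$sample_id
    constraints$sample_id <- NULL
  }
  if (!setequal(rownames(constraints), labels))
    stop("constraint rows do not match distance labels")
  constraints <- constraints[labels, , drop = FALSE]
  if (anyNA(constraints)) stop("constraints contain missing trait values")
  mm <- stats::model.matrix(~ ., data = constraints)[, -1, drop = FALSE]
  q <- qr(mm)
  if (q$rank < ncol(mm)) {
    dropped <- colnames(mm)[q$pivot[(q$rank + 1):ncol(mm)]]
    stop("constraints are rank deficient; collinear with the rest: ",
         paste(dropped, collapse = ", "))
  }
  mod <- vegan::capscale(d ~ ., data = constraints)
  set.seed(derive_seed(seed, 71L))
  perm <- stats::anova(mod, by = "margin", permutations = n_perm)
  p <- setNames(perm[["Pr(>F)"]], rownames(perm))
  p <- p[!is.na(p)]
  structure(list(
    eigenvalues = c(mod$CCA$eig, mod$CA$eig),
    site_scores = vegan::scores(mod, display = "sites"),
    constrained_fraction = sum(mod$CCA$eig) / mod$tot.chi,
    permutation_p = p,
    n_permutations = n_perm,
    model = mod), class = "tol_dbrda")
}

#' @export
print.tol_dbrda <- function(x, ...) {
  cat(sprintf("<tol_dbrda> constrained fraction %.3f (%d permutations)\n",
              x$constrained_fraction, x$n_permutations))
  cat("  marginal permutation p-values:\n")
  print(signif(x$permutation_p, 3))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Spearman rank correlation between the upper triangles of two distance
#' matrices, with significance from jointly permuting the rows and columns
#' of the second matrix. The test is one-sided for positive association,
#' with p = (exceedances + 1) / (n_perm + 1) — the directional hypothesis
#' that communities more different in tolerance are also more different in
#' composition.
#'
#' @param d1,d2 `dist` objects (or labelled matrices) over the same
#'   samples; `d2` is reordered to match `d1`'s labels.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return an object of class `mantel_result`: `rho`, `p_value`,
#'   `n_permutations`, `n_pairs`.
#' @export
mantel_traits <- function(d1, d2, n_perm = 9999, seed = 1) {
  m1 <- as.matrix(d1)
  n <- nrow(m1)
  if (n < 4) stop("Mantel test needs at least 4 samples")
  labels <- rownames(m1)
  if (is.null(labels)) stop("distance matrices must carry sample labels")
  d2 <- align_dist(d2, labels, "second distance matrix")
  d1 <- stats::as.dist(m1)
  set.seed(derive_seed(seed, 83L))
  mt <- vegan::mantel(d1, d2, method = "spearman", permutations = n_perm)
  structure(list(rho = unname(mt$statistic), p_value = mt$signif,
                 n_permutations = n_perm, n_pairs = n * (n - 1) / 2),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test (Spearman): rho = %.3f, p = %.4g (%d permutations, %d pairs)\n",
              x$rho, x$p_value, x$n_permutations, x$n_pairs))
  invisible(x)
}

#' Euclidean distance matrix of a community trait
#'
#' One-dimensional Euclidean distances |trait_i - trait_j| between the
#' samples' community trait indicators.
#'
#' @param profiles trait profiles ([trait_profiles()]).
#' @param trait `"log_ic50"` or `"ph_opt"`.
#' @return a labelled `dist`.
#' @export
trait_distance <- function(profiles, trait = c("log_ic50", "ph_opt")) {
  trait <- match.arg(trait)
  v <- profiles[[trait]]
  bad <- !is.finite(v)
  if (any(bad))
    stop("missing ", trait, " for samples: ",
         paste(profiles$sample_id[bad], collapse = ", "))
  names(v) <- profiles$sample_id
  dist(v)
}

#' Distance-decay regression of community on trait distances
#'
#' Descriptive OLS of pairwise community dissimilarities on pairwise trait
#' distances over all unordered sample pairs. Because pairs are not
#' independent, no p-value is attached here — inference belongs to the
#' Mantel test; the slope quantifies how much compositional change
#' accompanies a unit change in the trait.
#'
#' @param d_comm community dissimilarity `dist`.
#' @param d_trait trait distance `dist` over the same samples.
#' @return a list with `slope`, `intercept`, `n_pairs`.
#' @export
distance_decay_slope <- function(d_comm, d_trait) {
  m <- as.matrix(d_comm)
  labels <- rownames(m)
  d_trait <- align_dist(d_trait, labels, "trait distance matrix")
  yc <- upper_tri_vec(m)
  xt <- upper_tri_vec(as.matrix(d_trait))
  if (var(xt) == 0) stop("trait distances have zero variance")
  fit <- lm(yc ~ xt)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n_pairs = length(yc))
}

#' Trait-equivalence ratio of compositional turnover
#'
#' Given the distance-decay slopes of community dissimilarity against pH
#' tolerance distance and against salt tolerance (logIC50) distance,
#' returns `slope_ph / slope_salt`: the change in logIC50 (log10 dS/m)
#' associated with the same magnitude of compositional shift as a change
#' of 1 pH unit in the community pH optimum.
#'
#' @param slope_ph distance-decay slope for the pH trait.
#' @param slope_salt distance-decay slope for the salt trait (non-zero).
#' @return the equivalence ratio, in logIC50 units per pH unit.
#' @export
equivalence_ratio <- function(slope_ph, slope_salt) {
  if (slope_salt == 0) stop("salt distance-decay slope is zero")
  slope_ph / slope_salt
}
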