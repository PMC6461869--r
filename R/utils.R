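## Derive a per-unit seed from a master seed and a counter, so that every
## sample / stage consumes an independent, reproducible stream. Plain
## integer arithmetic mod a Mersenne prime keeps results inside the 32-bit
## range R requires of set.seed().
derive_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), is.numeric(counter))
  as.integer((as.numeric(seed) * 48271 + as.numeric(counter) * 69621) %%
               2147483647)
}

## Multiplicative log-normal noise with mean 1 and coefficient of variation
## cv: growth stays positive and its spread scales with its magnitude.
apply_lognormal_noise <- function(mu, cv) {
  if (cv < 0) stop("noise coefficient of variation must be non-negative")
  if (cv == 0) return(mu)
  sdlog <- sqrt(log(1 + cv^2))
  mu * rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

## Upper-triangle vector of a dist or square matrix, in a fixed label order.
upper_tri_vec <- function(d) {
  m <- as.matrix(d)
  m[upper.tri(m)]
}

## Align a dist object to a given label order, erroring on mismatch.
align_dist <- function(d, labels, what = "distance matrix") {
  m <- as.matrix(d)
  if (is.null(rownames(m))) stop(what, " has no sample labels")
  if (!setequal(rownames(m), labels))
    stop("sample labels of ", what, " do not match: missing ",
         paste(setdiff(labels, rownames(m)), collapse = ", "))
  stats::as.dist(m[labels, labels])
}
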