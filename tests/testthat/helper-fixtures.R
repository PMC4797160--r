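# Shared fixtures built in code.

# simulate encounter histories directly from CJS parameters.
# phi, p: vectors (length T-1) or n x (T-1) matrices.
sim_cjs_histories <- function(n, T_, phi, p) {
  if (!is.matrix(phi)) phi <- matrix(phi, n, T_ - 1, byrow = TRUE)
  if (!is.matrix(p)) p <- matrix(p, n, T_ - 1, byrow = TRUE)
  H <- matrix(0L, n, T_)
  H[, 1] <- 1L
  alive <- rep(TRUE, n)
  for (t in seq_len(T_ - 1)) {
    alive <- alive & (stats::runif(n) < phi[, t])
    det <- alive & (stats::runif(n) < p[, t])
    H[det, t + 1] <- 1L
  }
  H
}

# all 2^(T-1) post-release histories for exhaustive checks
all_histories <- function(T_) {
  combos <- expand.grid(rep(list(0:1), T_ - 1))
  H <- cbind(1L, as.matrix(combos))
  dimnames(H) <- NULL
  H
}

# a small complete synthetic dataset, cached across tests in one session
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_per_group = c(sculpin = 60, juvenile_trout = 20,
                                        adult_trout = 60), seed = 42)
      cache <<- simulate_dataset(cfg)
    }
    cache
  }
})

# resident-only pooled cjs_data from a simulated dataset
resident_cjs_data <- function(d, covariates = TRUE) {
  fates <- classify_fates(d$registry, d$tracking)
  H <- build_histories(d$registry, d$tracking, d$config$n_occasions)
  res <- fates == "resident"
  pooled <- pool_occasions(H[res, , drop = FALSE])
  covs <- if (covariates) {
    covariate_table(d$registry, d$tracking, d$reach)[res, , drop = FALSE]
  } else NULL
  cjs_data(pooled, droplevels(d$registry$group[res]), covariates = covs,
           ice = pool_covariate(d$ice_weekly_m * 100, 2))
}
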