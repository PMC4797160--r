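test_that("chi recursion reproduces hand-computed values", {
  expect_equal(chi_tail(0.8, 0.6), c(0.2 + 0.8 * 0.4, 1))
  expect_equal(chi_tail(1, 1), c(0, 1))
  expect_equal(chi_tail(rep(0, 4), rep(0.5, 4)), rep(1, 5))
  # three intervals by hand
  phi <- c(0.9, 0.8, 0.7); p <- c(0.5, 0.6, 0.4)
  chi3 <- 0.3 + 0.7 * 0.6
  chi2 <- 0.2 + 0.8 * 0.4 * chi3
  chi1 <- 0.1 + 0.9 * 0.5 * chi2
  expect_equal(chi_tail(phi, p), c(chi1, chi2, chi3, 1))
})

test_that("single-history likelihood matches closed forms", {
  expect_equal(exp(individual_loglik(c(1, 1), 0.8, 0.6)), 0.48)
  expect_equal(exp(individual_loglik(c(1, 0), 0.8, 0.6)), 0.52)
  # 101: survive, missed, survive, seen
  phi <- c(0.9, 0.8); p <- c(0.5, 0.6)
  expect_equal(exp(individual_loglik(c(1, 0, 1), phi, p)),
               0.9 * 0.5 * 0.8 * 0.6 * 1)
})

test_that("likelihood over all possible histories sums to one (T <= 6)", {
  set.seed(6)
  for (T_ in 3:6) {
    phi <- runif(T_ - 1, 0.3, 0.99)
    p <- runif(T_ - 1, 0.1, 0.9)
    H <- all_histories(T_)
    total <- sum(apply(H, 1, function(h) exp(individual_loglik(h, phi, p))))
    expect_equal(total, 1, tolerance = 1e-12)
  }
})

test_that("design matrices expand to the documented column counts", {
  H <- pool_occasions(matrix(c(rep(1L, 27)), 1, 27, byrow = TRUE))
  H <- H[rep(1, 9), ]
  grp <- factor(rep(c("sculpin", "juvenile_trout", "adult_trout"), 3),
                levels = c("sculpin", "juvenile_trout", "adult_trout"))
  covs <- data.frame(cond = seq(0.8, 1.2, length.out = 9),
                     complex = runif(9, 20, 46),
                     depth = runif(9, 15, 26), distance = runif(9, 5, 270))
  d <- cjs_data(H, grp, covs, ice = seq(0, 45, length.out = 13))
  d1 <- build_design("phi(1)p(1)", d)
  expect_equal(ncol(d1$X_phi) + ncol(d1$X_p), 2)
  d2 <- build_design("phi(t x cond)p(1)", d)
  expect_equal(ncol(d2$X_phi), 26)    # 13 interval intercepts + 13 slopes
  d3 <- build_design("phi(1)p(g x ice)", d)
  expect_equal(ncol(d3$X_p), 6)       # 3 group intercepts + 3 ice slopes
  # the three candidate-model strings of the analysis all parse
  specs <- c("{phi(t x cond)p(g x ice + complex x t)}",
             "{phi(t x cond)p(g x ice + complex x distance x t)}",
             "{phi(t x cond)p(g x ice + depth x distance x t)}")
  for (s in specs) expect_s3_class(parse_model_spec(s), "cjs_spec")
  expect_error(parse_model_spec("phi(banana)p(1)"), "unknown effect 'banana'")
})

test_that("analytic gradient agrees with finite differences", {
  set.seed(12)
  H <- sim_cjs_histories(60, 8, 0.85, 0.5)
  grp <- factor(sample(c("a", "b"), 60, replace = TRUE))
  covs <- data.frame(cond = rnorm(60, 1, 0.1))
  # ice scaled to keep the linear predictor in the interior of the link
  d <- cjs_data(H, grp, covs, ice = seq(0.1, 4, length.out = 7))
  des <- build_design("phi(1 + cond)p(g x ice)", d)
  nll <- winterpit:::cjs_nll_factory(des, d)
  beta <- rnorm(nll$n_par, 0, 0.5)
  ga <- nll$gr(beta)
  gn <- vapply(seq_along(beta), function(j) {
    e <- rep(0, length(beta)); e[j] <- 1e-6
    (nll$fn(beta + e) - nll$fn(beta - e)) / 2e-6
  }, numeric(1))
  expect_lt(max(abs(ga - gn) / (1 + abs(gn))), 1e-5)
})

test_that("individual likelihood equals the m-array likelihood without covariates", {
  set.seed(14)
  H <- sim_cjs_histories(300, 7, 0.8, 0.5)
  grp <- factor(sample(c("a", "b"), 300, replace = TRUE))
  phi <- list(a = runif(6, 0.5, 0.95), b = runif(6, 0.5, 0.95))
  q <- list(a = runif(6, 0.2, 0.8), b = runif(6, 0.2, 0.8))
  ll_ind <- sum(vapply(seq_len(300), function(i) {
    g <- as.character(grp[i])
    individual_loglik(H[i, ], phi[[g]], q[[g]])
  }, numeric(1)))
  arr <- marray(H, grp)
  expect_equal(marray_loglik(arr, phi, q), ll_ind, tolerance = 1e-10)
})

test_that("m-array counts match a hand-tabulated tiny fixture", {
  H <- rbind(c(1, 1, 0, 1),
             c(1, 0, 0, 0),
             c(1, 0, 1, 1),
             c(1, 1, 1, 0))
  arr <- marray(H)
  # releases: occ1 all 4; occ2 fish 1 and 4; occ3 fish 3 and 4
  expect_equal(arr$R, c(4, 2, 2))
  expect_equal(arr$m[1, ], c(2, 1, 0))   # first recaptures from occ 1
  expect_equal(arr$m[2, ], c(0, 1, 1))   # fish 4 at occ 3, fish 1 at occ 4
  expect_equal(arr$m[3, ], c(0, 0, 1))
  expect_equal(arr$never, c(1, 0, 1))
})

test_that("constant-model fit recovers the generating parameters", {
  set.seed(18)
  H <- sim_cjs_histories(800, 8, 0.9, 0.6)
  f <- cjs_fit("phi(1)p(1)", cjs_data(H), cjs_control(n_starts = 3))
  expect_true(f$converged)
  est_phi <- plogis(f$beta[1]); est_p <- plogis(f$beta[2])
  se <- sqrt(diag(f$vcov))
  expect_lt(abs(f$beta[1] - qlogis(0.9)), 3.5 * se[1])
  expect_lt(abs(f$beta[2] - qlogis(0.6)), 3.5 * se[2])
  expect_equal(count_estimable(f), 2, ignore_attr = TRUE)
  # MLE beats the truth by definition
  des <- build_design("phi(1)p(1)", cjs_data(H))
  nll <- winterpit:::cjs_nll_factory(des, cjs_data(H))
  expect_lte(nll$fn(f$beta), nll$fn(c(qlogis(0.9), qlogis(0.6))))
})

test_that("fully time-dependent model has 2T-3 estimable parameters", {
  set.seed(19)
  T_ <- 5
  H <- sim_cjs_histories(900, T_, 0.85, 0.5)
  f <- cjs_fit("phi(t)p(t)", cjs_data(H), cjs_control(n_starts = 3))
  expect_equal(f$n_params, 2 * (T_ - 1))
  expect_equal(as.integer(count_estimable(f)), 2 * T_ - 3)
  expect_true(attr(count_estimable(f), "terminal_confound"))
  # rank equals the count of Hessian eigenvalues above the threshold
  ev <- f$hessian_eigenvalues
  expect_equal(f$n_estimable, sum(ev > 1e-8 * max(abs(ev))))
})

test_that("boundary data drive detection estimates to one", {
  H <- matrix(1L, 150, 6)
  f <- suppressWarnings(cjs_fit("phi(1)p(1)", cjs_data(H),
                                cjs_control(n_starts = 2)))
  reals <- cjs_reals(f, "p", data.frame(t = 2))
  expect_gt(reals$estimate, 0.999)
})

test_that("covariate shift moves the intercept but not fitted real parameters", {
  set.seed(22)
  n <- 400
  cond <- rnorm(n, 1, 0.15)
  phi <- plogis(1.2 + 1.5 * (cond - 1))
  H <- sim_cjs_histories(n, 8, matrix(phi, n, 7), 0.6)
  d1 <- cjs_data(H, covariates = data.frame(cond = cond))
  d2 <- cjs_data(H, covariates = data.frame(cond = cond + 5))
  f1 <- cjs_fit("phi(1 + cond)p(1)", d1,
                cjs_control(n_starts = 3, reltol = 1e-15, maxit = 5000))
  # exact reparameterisation of the optimum under the shift
  b <- as.numeric(f1$beta)
  init2 <- c(b[1] - 5 * b[2], b[2], b[3])
  f2 <- cjs_fit("phi(1 + cond)p(1)", d2,
                cjs_control(n_starts = 1, init = init2, reltol = 1e-15,
                            maxit = 5000))
  r1 <- cjs_reals(f1, "phi", data.frame(t = 1, cond = c(0.9, 1, 1.1)))
  r2 <- cjs_reals(f2, "phi", data.frame(t = 1, cond = c(0.9, 1, 1.1) + 5))
  expect_lt(max(abs(r1$estimate - r2$estimate)), 1e-8)
  expect_lt(abs(f1$loglik - f2$loglik), 1e-8)
})
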