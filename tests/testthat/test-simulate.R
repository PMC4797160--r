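test_that("fixed seeds reproduce the dataset exactly", {
  cfg <- sim_config(n_per_group = c(sculpin = 20, juvenile_trout = 10,
                                    adult_trout = 20), seed = 3)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$registry, d2$registry)
  expect_identical(d1$tracking, d2$tracking)
  expect_identical(d1$winter$air_temp_c, d2$winter$air_temp_c)
  expect_identical(d1$truth$alive, d2$truth$alive)
})

test_that("simulated fish respect group length bounds and imposed condition", {
  cfg <- sim_config(n_per_group = c(sculpin = 10, juvenile_trout = 10,
                                    adult_trout = 10), seed = 1)
  reg <- simulate_fish(cfg)
  expect_equal(nrow(reg), 30)
  expect_true(all(reg$length_mm[reg$group == "sculpin"] > 70))
  jl <- reg$length_mm[reg$group == "juvenile_trout"]
  expect_true(all(jl >= 110 & jl <= 150))
  expect_true(all(reg$length_mm[reg$group == "adult_trout"] > 150))
  expect_true(all(reg$tag_length_mm[reg$group != "adult_trout"] == 12))
  expect_true(all(reg$tag_length_mm[reg$group == "adult_trout"] == 23))
  # zero-variance condition is imposed exactly through the cube law
  cfg0 <- sim_config(n_per_group = c(sculpin = 5, juvenile_trout = 5,
                                     adult_trout = 5),
                     condition_dist = list(
                       mean = c(sculpin = 1, juvenile_trout = 1,
                                adult_trout = 1),
                       sd = c(sculpin = 0, juvenile_trout = 0,
                              adult_trout = 0)),
                     seed = 2)
  reg0 <- simulate_fish(cfg0)
  expect_equal(fulton_condition(reg0$length_mm, reg0$weight_g), rep(1, 15),
               tolerance = 1e-12)
})

test_that("sampled condition matches the configured distribution", {
  n <- 10000
  cfg <- sim_config(n_per_group = c(sculpin = n, juvenile_trout = 1,
                                    adult_trout = 1),
                    condition_dist = list(
                      mean = c(sculpin = 1.1, juvenile_trout = 1,
                               adult_trout = 1),
                      sd = c(sculpin = 0.1, juvenile_trout = 0.1,
                             adult_trout = 0.1)),
                    seed = 5)
  reg <- simulate_fish(cfg)
  k <- fulton_condition(reg$length_mm[reg$group == "sculpin"],
                        reg$weight_g[reg$group == "sculpin"])
  expect_lt(abs(mean(k) - 1.1), 3 * 0.1 / sqrt(n))
})

test_that("a warm flat winter accumulates no freezing degree-days", {
  cfg <- sim_config(seed = 8)
  cfg$winter$temp_ends <- 5
  cfg$winter$temp_min <- 5
  cfg$winter$temp_sd <- 0
  w <- simulate_winter(cfg)
  expect_equal(freezing_degree_days(w$air_temp_c), 0)
  ice <- grow_series(w)
  expect_true(all(ice$h_i_m == 0))
})

test_that("degree-days increase strictly during sub-zero spells", {
  cfg <- sim_config(seed = 8)
  w <- simulate_winter(cfg)
  S <- freezing_degree_days(w$air_temp_c, cumulative = TRUE)
  frost <- w$air_temp_c < 0
  expect_true(all(diff(S)[frost[-1]] > 0))
  expect_equal(S[length(S)], sum(pmax(0, -w$air_temp_c)))
})

test_that("degenerate probabilities give degenerate histories", {
  base <- function(...) {
    sim_config(n_per_group = c(sculpin = 15, juvenile_trout = 5,
                               adult_trout = 15),
               n_occasions = 8, seed = 21, ...)
  }
  # certain survival + certain detection, no transients or tag loss
  cfg <- base(phi_spec = list(intercept = 50, cond_slope = 0, cond_center = 1),
              p_spec = list(intercept = c(sculpin = 50, juvenile_trout = 50,
                                          adult_trout = 50),
                            ice_slope = c(sculpin = 0, juvenile_trout = 0,
                                          adult_trout = 0),
                            complex_slope = 0, complex_center = 33),
              transient_frac = c(sculpin = 0, juvenile_trout = 0,
                                 adult_trout = 0),
              tagloss_rate = c(sculpin = 0, juvenile_trout = 0,
                               adult_trout = 0))
  d <- simulate_dataset(cfg)
  H <- build_histories(d$registry, d$tracking, 8)
  expect_true(all(H == 1L))
  # everyone a transient: zero post-release detections
  cfg2 <- base(transient_frac = c(sculpin = 1, juvenile_trout = 1,
                                  adult_trout = 1))
  d2 <- simulate_dataset(cfg2)
  expect_true(!any(d2$tracking$detected))
})

test_that("detection frequency among latent-alive fish matches the generating p", {
  n <- 6000
  p_true <- 0.6
  cfg <- sim_config(n_per_group = c(sculpin = n, juvenile_trout = 1,
                                    adult_trout = 1),
                    n_occasions = 6,
                    phi_spec = list(intercept = 50, cond_slope = 0,
                                    cond_center = 1),
                    p_spec = list(intercept = c(sculpin = qlogis(p_true),
                                                juvenile_trout = qlogis(p_true),
                                                adult_trout = qlogis(p_true)),
                                  ice_slope = c(sculpin = 0,
                                                juvenile_trout = 0,
                                                adult_trout = 0),
                                  complex_slope = 0, complex_center = 33),
                    transient_frac = c(sculpin = 0, juvenile_trout = 0,
                                       adult_trout = 0),
                    tagloss_rate = c(sculpin = 0, juvenile_trout = 0,
                                     adult_trout = 0),
                    seed = 31)
  d <- simulate_dataset(cfg)
  det <- matrix(d$tracking$detected[order(d$tracking$fish_id,
                                          d$tracking$occasion)],
                ncol = 6, byrow = TRUE)
  present <- d$truth$present[order(d$registry$fish_id), -1]
  frac <- sum(det[present]) / sum(present)
  mc_se <- sqrt(p_true * (1 - p_true) / sum(present))
  expect_lt(abs(frac - p_true), 3 * mc_se)
})

test_that("no fish is detected after latent death or emigration", {
  for (seed in c(2, 13, 77)) {
    d <- simulate_dataset(sim_config(
      n_per_group = c(sculpin = 40, juvenile_trout = 15, adult_trout = 40),
      n_occasions = 12, seed = seed))
    det <- matrix(d$tracking$detected[order(match(d$tracking$fish_id,
                                                  d$registry$fish_id),
                                            d$tracking$occasion)],
                  ncol = 12, byrow = TRUE)
    expect_true(all(!det[!d$truth$present[, -1]]))
  }
})
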