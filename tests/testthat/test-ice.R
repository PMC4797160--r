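test_that("freezing degree-days sum daily frost and match a loop oracle", {
  expect_equal(freezing_degree_days(rep(5, 30)), 0)
  expect_equal(freezing_degree_days(c(-10, -5, 2)), 15)
  set.seed(1)
  temps <- rnorm(120, -4, 6)
  oracle <- 0
  for (x in temps) oracle <- oracle + max(0, -x)
  expect_equal(freezing_degree_days(temps), oracle)
  cum <- freezing_degree_days(temps, cumulative = TRUE)
  expect_true(all(diff(cum) >= 0))
  expect_equal(cum[120], oracle)
  expect_error(freezing_degree_days(numeric(0)), "empty")
})

test_that("effective conductivity interpolates between the layer limits", {
  ph <- ice_physics()
  expect_equal(effective_conductivity(0.3, 0, ph), ph$k_ice)
  expect_equal(effective_conductivity(0, 0.3, ph), ph$k_snow)
  # equal layers: harmonic-type mean of the two conductivities
  expect_equal(effective_conductivity(0.25, 0.25, ph),
               2 * ph$k_ice * ph$k_snow / (ph$k_ice + ph$k_snow),
               tolerance = 1e-12)
  for (hs in c(0.05, 0.2, 1)) {
    k <- effective_conductivity(0.4, hs, ph)
    expect_gt(k, ph$k_snow)
    expect_lt(k, ph$k_ice)
  }
  expect_error(effective_conductivity(0, 0, ph), "positive")
})

test_that("snow-free thickness equals the closed-form Stefan law", {
  ph <- ice_physics()
  for (S in c(0, 1, 10, 100, 1500, 3000)) {
    closed <- sqrt(2 * ph$k_ice * S * 86400 / (ph$rho * ph$latent_heat))
    expect_equal(ice_thickness(S, 0, ph), closed, tolerance = 1e-10)
  }
  expect_equal(ice_thickness(100, 0, ph), 0.3407321, tolerance = 1e-6)
})

test_that("snow cover strictly reduces thickness and preserves monotonicity in S", {
  ph <- ice_physics()
  S_grid <- c(5, 50, 300, 1000, 3000)
  for (hs in c(0.01, 0.1, 0.5, 1)) {
    h_snow <- ice_thickness(S_grid, hs, ph)
    h_bare <- ice_thickness(S_grid, 0, ph)
    expect_true(all(h_snow < h_bare))
    expect_true(all(diff(h_snow) > 0))
  }
  expect_equal(ice_thickness(0, 0.5, ph), 0)
})

test_that("fixed point converges over the physical parameter grid", {
  for (ks in c(0.05, 0.2, 0.5)) {
    ph <- ice_physics(k_snow = ks)
    for (hs in c(0, 0.05, 0.3, 1)) {
      for (S in c(0, 10, 300, 3000)) {
        expect_silent(h <- ice_thickness(S, hs, ph, tol = 1e-12))
        if (S > 0 && hs > 0) {
          k_si <- effective_conductivity(h, hs, ph)
          resid <- h - sqrt(2 * k_si * S * 86400 / (ph$rho * ph$latent_heat))
          expect_lt(abs(resid), 1e-10)
        }
      }
    }
  }
})

test_that("a warm winter grows no ice", {
  dates <- as.Date("2010-11-01") + 0:99
  w <- winter_series(dates, rep(5, 100), rep(0, 100))
  ice <- grow_series(w)
  expect_true(all(ice$h_i_m == 0))
  expect_true(all(ice$degree_days == 0))
})

test_that("constant frost without snow follows the square-root-of-time law", {
  dates <- as.Date("2010-11-01") + 0:139
  w <- winter_series(dates, rep(-10, 140), rep(0, 140))
  ice <- grow_series(w)
  h <- ice$h_i_m
  expect_equal(h[40] / h[10], sqrt(4), tolerance = 1e-10)
  expect_equal(h[90] / h[10], 3, tolerance = 1e-10)
  expect_true(all(diff(h) > 0))
})

test_that("snow shoveling accelerates subsequent ice growth", {
  dates <- as.Date("2010-11-01") + 0:99
  snow <- rep(0.5, 100)
  base <- winter_series(dates, rep(-10, 100), snow)
  shov <- winter_series(dates, rep(-10, 100), snow,
                        shoveling_dates = dates[50])
  h_base <- grow_series(base)$h_i_m
  h_shov <- grow_series(shov)$h_i_m
  expect_equal(h_base[1:49], h_shov[1:49])
  # equal degree-days afterwards, but the shoveled run grows from thinner cover
  expect_true(all(h_shov[50:100] > h_base[50:100]))
  # growth increments immediately after the reset exceed the unshoveled ones
  expect_gt(diff(h_shov)[50], diff(h_base)[50])
})

test_that("weekly means and pooling export the detection covariate", {
  dates <- as.Date("2010-11-01") + 0:27
  w <- winter_series(dates, rep(-5, 28), rep(0, 28))
  ice <- grow_series(w)
  wk <- ice_weekly_means(ice, 4)
  expect_length(wk, 4)
  expect_equal(wk[1], mean(ice$h_i_m[1:7]))
  expect_equal(pool_covariate(wk, 2), c(mean(wk[1:2]), mean(wk[3:4])))
  expect_error(pool_covariate(wk, 3), "multiple")
})
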