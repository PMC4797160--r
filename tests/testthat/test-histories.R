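test_that("moves within tracking accuracy are not discernible", {
  rec <- data.frame(occasion = 1:2, position = c(100.0, 100.4))
  expect_equal(discernible_moves(rec)$direction, "none")
  rec2 <- data.frame(occasion = 1:2, position = c(100.0, 103.0))
  expect_equal(discernible_moves(rec2)$direction, "upstream")
  rec3 <- data.frame(occasion = 1:2, position = c(103.0, 100.0))
  expect_equal(discernible_moves(rec3)$direction, "downstream")
  expect_equal(nrow(discernible_moves(data.frame(occasion = 1,
                                                 position = 5))), 0)
})

test_that("move classification matches a pairwise-difference oracle", {
  set.seed(4)
  pos <- cumsum(rnorm(40, 0, 1.2)) + 200
  rec <- data.frame(occasion = 1:40, position = pos)
  mv <- discernible_moves(rec, accuracy = 0.5)
  d <- diff(pos)
  oracle <- ifelse(abs(d) <= 0.5, "none", ifelse(d > 0, "upstream", "downstream"))
  expect_equal(mv$direction, oracle)
  expect_equal(mv$displacement_m, d)
})

test_that("fate classification follows the transient rules", {
  none <- data.frame(occasion = integer(), position = numeric())
  expect_equal(classify_fate(none), "transient")
  down <- data.frame(occasion = 1:3, position = c(100, 95, 90))
  expect_equal(classify_fate(down, spring_recaptured = FALSE), "transient")
  expect_equal(classify_fate(down, spring_recaptured = TRUE), "resident")
  up <- data.frame(occasion = 1:2, position = c(100, 103))
  expect_equal(classify_fate(up), "resident")
  # lateral activity qualifies as residency even without upstream moves
  lat <- data.frame(occasion = 1:2, position = c(100, 100.2),
                    lateral = c(FALSE, TRUE))
  expect_equal(classify_fate(lat), "resident")
  still <- data.frame(occasion = 1:4, position = rep(50, 4))
  expect_equal(classify_fate(still, spring_recaptured = FALSE), "transient")
})

test_that("fates partition the registry and counts add up", {
  d <- small_dataset()
  fates <- classify_fates(d$registry, d$tracking)
  expect_true(all(fates %in% c("resident", "transient")))
  expect_length(fates, nrow(d$registry))
  tab <- table(fates)
  expect_equal(sum(tab), nrow(d$registry))
})

test_that("mortality truncation zeroes bits after the last upstream move", {
  hist <- rep(1L, 27)
  rec <- data.frame(occasion = c(2, 6, 10, 12, 13, 14),
                    position = c(100, 101, 104, 103.8, 103.9, 103.7))
  out <- truncate_mortality(hist, rec, dead = TRUE)
  # last upstream move ends at occasion 10 (bit 11); later bits zeroed
  expect_equal(out[1:11], rep(1L, 11))
  expect_equal(out[12:27], rep(0L, 16))
  expect_equal(truncate_mortality(hist, rec, dead = FALSE), hist)
  # upstream move at the final occasion: nothing to truncate
  rec2 <- data.frame(occasion = c(25, 26), position = c(100, 105))
  expect_equal(truncate_mortality(hist, rec2, dead = TRUE), hist)
  # dead fish without any upstream move on record
  rec3 <- data.frame(occasion = 1:3, position = c(100, 99, 98))
  expect_warning(out3 <- truncate_mortality(hist, rec3, dead = TRUE),
                 "no upstream")
  expect_equal(out3[-1], rep(0L, 26))
})

test_that("pooling ORs week pairs and keeps the marking occasion", {
  h <- c(1L, rep(0L, 26))
  h[2:3] <- c(1L, 0L)   # weeks 1,2 -> detected in one week
  h[4:5] <- c(0L, 0L)   # weeks 3,4 -> missed in both
  h[6:7] <- c(1L, 1L)
  pooled <- pool_occasions(h)
  expect_equal(ncol(pooled), 14)
  expect_equal(pooled[1, 1:4], c(1L, 1L, 0L, 1L))
  all1 <- matrix(1L, 3, 27)
  expect_equal(pool_occasions(all1), matrix(1L, 3, 14), ignore_attr = TRUE)
})

test_that("pooling is the monotone OR of the source weeks", {
  set.seed(9)
  H <- matrix(rbinom(20 * 27, 1, 0.4), 20, 27)
  H[, 1] <- 1L
  P <- pool_occasions(H)
  for (b in 1:13) {
    expect_equal(P[, b + 1], as.integer(H[, 2 * b] | H[, 2 * b + 1]))
  }
})

test_that("return rate summarises per-occasion detection proportions", {
  H <- matrix(1L, 5, 9)
  rr <- return_rate(H)
  expect_equal(rr$rates, rep(1, 8))
  expect_equal(rr$cv, 0)
  expect_equal(rr$factor, 1)
  H2 <- rbind(c(1, 1, 0), c(1, 0, 1), c(1, 1, 1), c(1, 0, 1), c(1, 0, 0))
  rr2 <- return_rate(H2)
  expect_equal(rr2$rates, c(0.4, 0.6))
  expect_equal(rr2$factor, 1.5)
  expect_equal(rr2$cv, sd(c(0.4, 0.6)) / 0.5)
  H3 <- rbind(c(1, 0, 1), c(1, 0, 0))
  expect_warning(rr3 <- return_rate(H3), "undefined")
  expect_true(is.na(rr3$factor))
})

test_that("Fulton condition converts units correctly", {
  expect_equal(fulton_condition(100, 10), 1.0)
  expect_equal(fulton_condition(150, 33.75), 1.0)
  expect_equal(fulton_condition(150, 40), 100 * 40 / 15^3)
  expect_error(fulton_condition(0, 10), "positive")
})

test_that("fish covariates summarise habitat use and tag burden", {
  reach <- reach_table(rep(50, 11), rep(20, 11), rep(30, 11))
  fish <- data.frame(length_mm = 160, weight_g = 46, tag_weight_g = 0.6,
                     subreach_id = 3)
  rec <- data.frame(position = 275)
  cv <- fish_covariates(fish, rec, reach)
  expect_equal(cv$distance, 275)                 # midpoint of a 550-m reach
  expect_equal(cv$tag_burden, 0.6 / 46)          # ~1.3 %
  expect_equal(cv$cond, fulton_condition(160, 46))
  # a fish using only subreach 2 inherits that subreach's complexity
  ex <- example_reach()
  fish2 <- data.frame(length_mm = 100, weight_g = 10, tag_weight_g = 0.1,
                      subreach_id = 2)
  pos2 <- ex$upstream_end_m[2] - ex$length_m[2] / 2
  cv2 <- fish_covariates(fish2, data.frame(position = pos2), ex)
  expect_equal(cv2$complex, 46.1)
  # no positions: tagging subreach with a warning
  expect_warning(cv3 <- fish_covariates(fish2,
                                        data.frame(position = numeric()), ex),
                 "tagging subreach")
  expect_equal(cv3$complex, 46.1)
})

test_that("positions map to subreaches by cumulative boundaries", {
  reach <- reach_table(c(10, 20, 30), c(1, 2, 3), c(0, 0, 0))
  expect_equal(subreach_of(c(0, 5, 10, 15, 30.5, 60), reach),
               c(1, 1, 1, 2, 3, 3))
  expect_error(subreach_of(61, reach), "outside")
})
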