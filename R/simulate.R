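#' Configuration for the synthetic winter-tracking generator
#'
#' Defines the study conditions emulated by the generator: three groups of
#' fish (benthic sculpin and juvenile trout carrying 12-mm tags, adult
#' trout carrying 23-mm tags), weekly tracking over a boreal winter,
#' detection probabilities that decline with the thickness of the growing
#' ice pack (most steeply for the small tags), survival driven by autumn
#' body condition on the logit scale, a per-group transient fraction that
#' emigrates at release, and occasional tag shedding.
#'
#' Default detection intercepts/slopes are chosen so that weekly detection
#' spans roughly 0.05-0.85 for the 12-mm groups and stays above 0.8 for
#' adult trout across the 0-46 cm ice range of a typical winter; weekly
#' survival at average condition is ~0.998 so that biweekly apparent
#' survival is ~0.995.
#'
#' @param n_per_group Named counts for `sculpin`, `juvenile_trout`,
#'   `adult_trout`.
#' @param n_occasions Weekly tracking occasions (>= 2).
#' @param phi_spec List: `intercept` (weekly logit survival at condition
#'   `cond_center`, recycled over intervals) and `cond_slope`.
#' @param p_spec List: per-group `intercept` (weekly logit detection at
#'   zero ice and centred complexity), per-group `ice_slope` (per cm of
#'   ice), `complex_slope`, and `complex_center`.
#' @param transient_frac Per-group probability of permanent emigration at
#'   release.
#' @param maturity_transient_ratio Among adult trout, the ratio of the
#'   transient probability of spawning vs spent individuals (group mean
#'   preserved, half of adults spawning).
#' @param tagloss_rate Per-group probability of shedding the tag in the
#'   first week (the shed tag is not detected again).
#' @param condition_dist List of per-group `mean` and `sd` of Fulton
#'   condition.
#' @param spring_recapture_prob Recapture probability at the spring survey
#'   for fish alive and present at the end.
#' @param move_sd SD of the between-detection displacement of residents, m.
#' @param move_drift Mean upstream drift of resident displacements, m.
#' @param lateral_prob Probability that a detection carries a discernible
#'   lateral-movement flag.
#' @param winter List of weather-generator settings: `start` date,
#'   `temp_ends` and `temp_min` (degrees C at the season margins and
#'   mid-winter), `temp_sd` daily noise, `snowfall_prob`,
#'   `snowfall_mean_m`, `melt_m_per_deg`, `settle_rate` (daily snowpack
#'   compaction factor), `shovel_days` (day indices of the snow-clearing
#'   occasions).
#' @param seed RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_per_group = c(sculpin = 182, juvenile_trout = 50,
                                       adult_trout = 161),
                       n_occasions = 26L,
                       phi_spec = list(intercept = 6.0, cond_slope = 3.0,
                                       cond_center = 1.0),
                       p_spec = list(intercept = c(sculpin = 1.8,
                                                   juvenile_trout = 1.8,
                                                   adult_trout = 3.4),
                                     ice_slope = c(sculpin = -0.10,
                                                   juvenile_trout = -0.07,
                                                   adult_trout = -0.033),
                                     complex_slope = -0.03,
                                     complex_center = 33),
                       transient_frac = c(sculpin = 0.20,
                                          juvenile_trout = 0.16,
                                          adult_trout = 0.32),
                       maturity_transient_ratio = 2.1,
                       tagloss_rate = c(sculpin = 0, juvenile_trout = 0,
                                        adult_trout = 0.05),
                       condition_dist = list(mean = c(sculpin = 1.0,
                                                      juvenile_trout = 1.0,
                                                      adult_trout = 1.0),
                                             sd = c(sculpin = 0.1,
                                                    juvenile_trout = 0.1,
                                                    adult_trout = 0.1)),
                       spring_recapture_prob = 0.8,
                       move_sd = 2.5, move_drift = 0.2,
                       lateral_prob = 0.1,
                       winter = list(start = as.Date("2010-11-01"),
                                     temp_ends = 1.5, temp_min = -10,
                                     temp_sd = 3, snowfall_prob = 0.5,
                                     snowfall_mean_m = 0.012,
                                     melt_m_per_deg = 0.004,
                                     settle_rate = 0.99,
                                     shovel_days = c(51L, 72L, 133L)),
                       seed = 1L) {
  groups <- c("sculpin", "juvenile_trout", "adult_trout")
  n_per_group <- n_per_group[groups]
  if (anyNA(n_per_group) || any(n_per_group < 1)) {
    stop("n_per_group must give a positive count for each of: ",
         paste(groups, collapse = ", "))
  }
  if (n_occasions < 2) stop("n_occasions must be >= 2")
  probs <- c(transient_frac, tagloss_rate, spring_recapture_prob,
             p_spec_check = NULL)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(list(n_per_group = n_per_group, n_occasions = as.integer(n_occasions),
                 phi_spec = phi_spec, p_spec = p_spec,
                 transient_frac = transient_frac,
                 maturity_transient_ratio = maturity_transient_ratio,
                 tagloss_rate = tagloss_rate,
                 condition_dist = condition_dist,
                 spring_recapture_prob = spring_recapture_prob,
                 move_sd = move_sd, move_drift = move_drift,
                 lateral_prob = lateral_prob,
                 winter = winter, seed = as.integer(seed)),
            class = "sim_config")
}

sim_groups <- c("sculpin", "juvenile_trout", "adult_trout")

# truncated-normal condition draw (positive); sd = 0 gives the mean exactly
draw_condition <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  k <- stats::rnorm(n, mean, sd)
  while (any(bad <- k <= 0)) k[bad] <- stats::rnorm(sum(bad), mean, sd)
  k
}

#' Simulate a fish registry
#'
#' Draws group sizes, lengths within the tagging bounds of each group
#' (sculpin > 70 mm, juvenile trout 110-150 mm, adult trout > 150 mm),
#' Fulton condition from the configured per-group distribution, and weight
#' from the cube law `W = K * L_cm^3 / 100` so that condition is imposed
#' exactly. Tag dimensions follow the group (12 mm / 0.1 g for sculpin and
#' juvenile trout, 23 mm / 0.6 g for adult trout); the tagging subreach is
#' assigned uniformly; adult trout are spawning or spent with equal
#' probability.
#'
#' @param config A [sim_config()].
#' @param reach A [reach_table()] giving the subreaches.
#' @return Registry data frame with one row per fish.
#' @export
simulate_fish <- function(config = sim_config(), reach = example_reach()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_per_group
  group <- factor(rep(sim_groups, n), levels = sim_groups)
  ntot <- sum(n)
  length_mm <- numeric(ntot)
  length_mm[group == "sculpin"] <- stats::runif(n[1], 71, 125)
  length_mm[group == "juvenile_trout"] <- stats::runif(n[2], 110, 150)
  length_mm[group == "adult_trout"] <- stats::runif(n[3], 151, 300)
  cond <- numeric(ntot)
  for (g in sim_groups) {
    idx <- group == g
    cond[idx] <- draw_condition(sum(idx), config$condition_dist$mean[[g]],
                                config$condition_dist$sd[[g]])
  }
  weight_g <- cond * (length_mm / 10)^3 / 100
  tag_length <- ifelse(group == "adult_trout", 23, 12)
  tag_weight <- ifelse(group == "adult_trout", 0.6, 0.1)
  maturity <- rep(NA_character_, ntot)
  adults <- which(group == "adult_trout")
  maturity[adults] <- sample(c("spawning", "spent"), length(adults),
                             replace = TRUE)
  data.frame(fish_id = sprintf("F%04d", seq_len(ntot)),
             group = group,
             length_mm = length_mm, weight_g = weight_g,
             tag_length_mm = tag_length, tag_weight_g = tag_weight,
             subreach_id = sample(reach$subreach_id, ntot, replace = TRUE),
             maturity = maturity,
             spring_recaptured = FALSE,
             stringsAsFactors = FALSE)
}

#' Simulate a daily winter weather series
#'
#' A seasonal air-temperature curve (mild at the season margins, coldest
#' mid-winter) with daily noise, a snowpack that accumulates during frost
#' and melts on warm days, and fixed snow-shoveling dates.
#'
#' @param config A [sim_config()].
#' @return A [winter_series()] covering `7 * n_occasions` days.
#' @export
simulate_winter <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  w <- config$winter
  n_days <- 7L * config$n_occasions
  d <- seq_len(n_days)
  seasonal <- w$temp_ends - (w$temp_ends - w$temp_min) * sin(pi * d / n_days)^2
  temp <- seasonal + stats::rnorm(n_days, 0, w$temp_sd)
  settle <- if (is.null(w$settle_rate)) 0.99 else w$settle_rate
  snow <- numeric(n_days)
  for (i in d) {
    prev <- if (i == 1) 0 else settle * snow[i - 1]
    fall <- if (temp[i] < 0 && stats::runif(1) < w$snowfall_prob) {
      stats::rexp(1, 1 / w$snowfall_mean_m)
    } else 0
    melt <- if (temp[i] > 0) w$melt_m_per_deg * temp[i] else 0
    snow[i] <- max(0, prev + fall - melt)
  }
  dates <- w$start + d - 1L
  shovel <- dates[w$shovel_days[w$shovel_days <= n_days]]
  winter_series(dates, temp, snow, shovel)
}

# per-fish weekly survival and detection probabilities implied by a config
sim_prob_matrices <- function(registry, cond, complex, ice_cm, config) {
  K <- config$n_occasions
  g <- as.character(registry$group)
  ps <- config$p_spec
  eta_p <- outer(ps$intercept[g] +
                   ps$complex_slope * (complex - ps$complex_center),
                 rep(1, K)) +
    outer(ps$ice_slope[g], rep(1, K)) * matrix(ice_cm, nrow(registry), K,
                                               byrow = TRUE)
  fs <- config$phi_spec
  int <- rep_len(fs$intercept, K)
  eta_phi <- matrix(int, nrow(registry), K, byrow = TRUE) +
    fs$cond_slope * (cond - fs$cond_center)
  list(p = stats::plogis(eta_p), phi = stats::plogis(eta_phi))
}

#' Simulate weekly tracking records with known ground truth
#'
#' Latent states evolve by Bernoulli survival on the logit scale driven by
#' individual condition; detections of alive, present fish are Bernoulli
#' with group-specific intercepts and ice slopes plus a structural
#' complexity effect. Transients emigrate immediately at release and are
#' never detected again inside the reach; shed tags likewise produce no
#' further detections. Residents move between detections with an upstream
#' drift and occasional lateral-movement flags; dead fish are not detected
#' after death.
#'
#' @param registry From [simulate_fish()].
#' @param ice_weekly_m Weekly mean ice thickness, m (length `n_occasions`).
#' @param config A [sim_config()].
#' @param reach A [reach_table()].
#' @return List with `tracking` (fish x occasion rows: `fish_id`,
#'   `occasion`, `detected`, `position`, `lateral`), the updated
#'   `registry` (spring recapture flags filled), and `truth` (transient
#'   and tag-loss flags, the latent alive/present matrix, the generating
#'   probability matrices and parameters).
#' @export
simulate_tracking <- function(registry, ice_weekly_m, config = sim_config(),
                              reach = example_reach()) {
  stopifnot(inherits(config, "sim_config"))
  K <- config$n_occasions
  if (length(ice_weekly_m) < K) stop("ice series does not cover all occasions")
  set.seed(config$seed + 2L)
  n <- nrow(registry)
  g <- as.character(registry$group)
  cond <- fulton_condition(registry$length_mm, registry$weight_g)
  sr <- match(registry$subreach_id, reach$subreach_id)
  complex <- reach$complexity[sr]
  home <- reach$upstream_end_m[sr] - reach$length_m[sr] / 2
  total <- attr(reach, "reach_length_m")
  pm <- sim_prob_matrices(registry, cond, complex, ice_weekly_m[seq_len(K)] * 100,
                          config)

  tf <- config$transient_frac[g]
  adults <- g == "adult_trout"
  r <- config$maturity_transient_ratio
  if (!is.null(r) && any(adults)) {
    # split the adult transient rate between maturity states at the
    # configured ratio, preserving the group mean (clamped into [0, 1])
    tf_adult <- config$transient_frac[["adult_trout"]]
    spent_rate <- 2 * tf_adult / (1 + r)
    spawn_rate <- r * spent_rate
    if (spawn_rate > 1) {
      spawn_rate <- 1
      spent_rate <- min(1, max(0, 2 * tf_adult - 1))
    }
    tf[adults] <- ifelse(registry$maturity[adults] == "spawning",
                         spawn_rate, spent_rate)
  }
  transient <- stats::runif(n) < tf
  tagloss <- stats::runif(n) < config$tagloss_rate[g]

  alive <- matrix(TRUE, n, K + 1L)     # col 1 = marking
  for (t in seq_len(K)) {
    alive[, t + 1L] <- alive[, t] & (stats::runif(n) < pm$phi[, t])
  }
  present <- alive
  present[transient, -1L] <- FALSE
  present[tagloss, -1L] <- FALSE

  detected <- matrix(FALSE, n, K)
  for (t in seq_len(K)) {
    avail <- present[, t + 1L]
    detected[avail, t] <- stats::runif(sum(avail)) < pm$p[avail, t]
  }

  position <- matrix(NA_real_, n, K)
  lateral <- matrix(FALSE, n, K)
  for (i in seq_len(n)) {
    occ <- which(detected[i, ])
    if (length(occ) == 0) next
    pos <- home[i]
    for (j in seq_along(occ)) {
      if (j > 1) {
        pos <- pos + stats::rnorm(1, config$move_drift, config$move_sd)
        pos <- min(max(pos, 0), total)
      }
      position[i, occ[j]] <- pos
    }
    lateral[i, occ] <- stats::runif(length(occ)) < config$lateral_prob
  }

  registry$spring_recaptured <- !transient & !tagloss & alive[, K + 1L] &
    stats::runif(n) < config$spring_recapture_prob

  tracking <- data.frame(
    fish_id = rep(registry$fish_id, each = K),
    occasion = rep(seq_len(K), n),
    detected = as.vector(t(detected)),
    position = as.vector(t(position)),
    lateral = as.vector(t(lateral)),
    stringsAsFactors = FALSE)

  list(tracking = tracking, registry = registry,
       truth = list(transient = transient, tagloss = tagloss,
                    alive = alive, present = present,
                    p = pm$p, phi = pm$phi, cond = cond,
                    config = config))
}

#' Simulate a complete winter-tracking dataset
#'
#' Convenience wrapper: weather, ice growth, fish registry, and tracking
#' records, with the generating truth attached.
#'
#' @param config A [sim_config()].
#' @param reach A [reach_table()].
#' @param physics An [ice_physics()].
#' @return List with `registry`, `tracking`, `winter`, `ice` (daily
#'   [grow_series()] output), `ice_weekly_m`, `reach` and `truth`.
#' @export
simulate_dataset <- function(config = sim_config(), reach = example_reach(),
                             physics = ice_physics()) {
  winter <- simulate_winter(config)
  ice <- grow_series(winter, physics)
  ice_weekly <- ice_weekly_means(ice, config$n_occasions)
  registry <- simulate_fish(config, reach)
  sim <- simulate_tracking(registry, ice_weekly, config, reach)
  list(registry = sim$registry, tracking = sim$tracking,
       winter = winter, ice = ice, ice_weekly_m = ice_weekly,
       reach = reach, truth = sim$truth, config = config)
}
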