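#' Physical constants for snow-coupled ice growth
#'
#' Bundles the physical parameters of the degree-day ice growth model:
#' ice density, latent heat of fusion, and the thermal conductivities of
#' the ice and snow layers. Conductivities are not universal constants for
#' river ice; they default to standard literature values and are
#' configurable.
#'
#' @param rho Ice density, kg m^-3.
#' @param latent_heat Latent heat of fusion, J kg^-1 (333.4 J/g).
#' @param k_ice Thermal conductivity of the ice layer, W m^-1 K^-1.
#' @param k_snow Thermal conductivity of the snow layer, W m^-1 K^-1.
#'   Must be smaller than `k_ice`: snow insulates.
#' @return An object of class `ice_physics`.
#' @export
#' @examples
#' ice_physics()
ice_physics <- function(rho = 1000, latent_heat = 333400,
                        k_ice = 2.24, k_snow = 0.2) {
  stopifnot(is.numeric(rho), is.numeric(latent_heat),
            is.numeric(k_ice), is.numeric(k_snow))
  if (any(c(rho, latent_heat, k_ice, k_snow) <= 0)) {
    stop("all ice physics parameters must be strictly positive")
  }
  if (k_snow >= k_ice) {
    stop("k_snow must be smaller than k_ice (snow insulates)")
  }
  structure(list(rho = rho, latent_heat = latent_heat,
                 k_ice = k_ice, k_snow = k_snow),
            class = "ice_physics")
}

#' @export
print.ice_physics <- function(x, ...) {
  cat("Ice growth physics:\n")
  cat(sprintf("  rho     = %g kg/m^3\n", x$rho))
  cat(sprintf("  L       = %g J/kg\n", x$latent_heat))
  cat(sprintf("  k_ice   = %g W/m/K\n", x$k_ice))
  cat(sprintf("  k_snow  = %g W/m/K\n", x$k_snow))
  invisible(x)
}

#' Cumulative freezing degree-days
#'
#' Sums the daily degrees of frost, `max(0, -T_air)`, over a daily air
#' temperature series. This is the thermodynamic driver of the Stefan
#' ice-growth law.
#'
#' @param air_temp Numeric vector of daily mean air temperatures, degrees C.
#' @param through Optional index (last day to include); defaults to the
#'   whole series.
#' @param cumulative If `TRUE` return the running total per day instead of
#'   a single value.
#' @return Freezing degree-days, degrees C day (scalar, or vector when
#'   `cumulative = TRUE`).
#' @export
#' @examples
#' freezing_degree_days(c(-10, -5, 2))  # 15
freezing_degree_days <- function(air_temp, through = length(air_temp),
                                 cumulative = FALSE) {
  if (length(air_temp) == 0) stop("empty air temperature series")
  if (through < 1 || through > length(air_temp)) {
    stop("'through' outside the temperature series")
  }
  frost <- pmax(0, -air_temp[seq_len(through)])
  if (cumulative) cumsum(frost) else sum(frost)
}

#' Effective thermal conductivity of a layered ice-snow pack
#'
#' Series (harmonic-type) combination of the ice and snow layers: the
#' layered pack conducts like a slab of total thickness `h_i + h_s` whose
#' resistance is the sum of the layer resistances.
#'
#' @param h_i Ice thickness, m.
#' @param h_s Snow thickness, m.
#' @param physics An [ice_physics()] object.
#' @return Effective conductivity, W m^-1 K^-1; lies between `k_snow` and
#'   `k_ice`.
#' @export
effective_conductivity <- function(h_i, h_s, physics = ice_physics()) {
  stopifnot(inherits(physics, "ice_physics"))
  if (any(h_i < 0) || any(h_s < 0)) stop("layer thicknesses must be >= 0")
  if (any(h_i + h_s <= 0)) stop("at least one layer must have positive thickness")
  (h_i + h_s) / (h_i / physics$k_ice + h_s / physics$k_snow)
}

#' Ice thickness from freezing degree-days under a snow layer
#'
#' Solves the snow-coupled Stefan relation
#' `h_i = sqrt(2 * k_si(h_i) * S / (rho * L))` for the ice thickness,
#' where the effective conductivity `k_si` itself depends on the current
#' ice thickness through the layer weighting. With no snow the solution is
#' the classical closed-form Stefan square-root law; with snow the pack
#' conducts less and the ice is strictly thinner at equal degree-days.
#' Degree-days (degrees C day) are converted to degrees C s internally.
#'
#' The coupled system is solved self-consistently by fixed-point iteration
#' started from the bare-ice closed form, which is an upper bound.
#'
#' @param S Freezing degree-days, degrees C day (scalar or vector).
#' @param h_s Snow thickness, m (recycled against `S`).
#' @param physics An [ice_physics()] object.
#' @param tol Convergence tolerance on thickness, m.
#' @param max_iter Iteration cap.
#' @return Ice thickness, m, same length as `S`.
#' @export
#' @examples
#' ice_thickness(100, h_s = 0)   # closed-form Stefan value, ~0.341 m
ice_thickness <- function(S, h_s = 0, physics = ice_physics(),
                          tol = 1e-10, max_iter = 100L) {
  stopifnot(inherits(physics, "ice_physics"))
  if (any(S < 0)) stop("degree-days must be >= 0")
  if (any(h_s < 0)) stop("snow depth must be >= 0")
  n <- max(length(S), length(h_s))
  S <- rep_len(S, n)
  h_s <- rep_len(h_s, n)
  S_sec <- S * 86400                      # degree-seconds of freezing
  fac <- 2 * S_sec / (physics$rho * physics$latent_heat)
  h <- sqrt(fac * physics$k_ice)          # bare-ice start (upper bound)
  active <- S > 0 & h_s > 0               # coupling only matters with snow
  iter <- 0L
  while (any(active)) {
    iter <- iter + 1L
    if (iter > max_iter) {
      stop(sprintf(
        "ice thickness fixed point did not converge within %d iterations (last iterate %.6g m)",
        max_iter, max(h[active])))
    }
    k_si <- effective_conductivity(h[active], h_s[active], physics)
    h_new <- sqrt(fac[active] * k_si)
    conv <- abs(h_new - h[active]) < tol
    h[active] <- h_new
    active[active] <- !conv
  }
  h[S == 0] <- 0
  h
}

#' Daily winter weather series
#'
#' Container for the daily forcing of the ice model: air temperature, snow
#' depth on the ice, and the dates on which excess snow was shoveled off
#' the ice to keep the tracking antenna within detection range.
#'
#' @param dates Daily `Date` vector, strictly increasing by one day.
#' @param air_temp_c Daily mean air temperature, degrees C.
#' @param snow_depth_m Daily snow depth on the ice, m.
#' @param shoveling_dates `Date` vector (possibly empty) of snow-clearing
#'   occasions.
#' @return A `winter_series` data frame.
#' @export
winter_series <- function(dates, air_temp_c, snow_depth_m,
                          shoveling_dates = as.Date(character())) {
  dates <- as.Date(dates)
  if (length(dates) < 2 || any(diff(as.integer(dates)) != 1L)) {
    stop("dates must be strictly increasing daily")
  }
  stopifnot(length(air_temp_c) == length(dates),
            length(snow_depth_m) == length(dates))
  if (any(snow_depth_m < 0)) stop("snow depth must be >= 0")
  shoveling_dates <- as.Date(shoveling_dates)
  if (length(shoveling_dates) && !all(shoveling_dates %in% dates)) {
    stop("shoveling dates must fall within the series")
  }
  structure(
    data.frame(date = dates, air_temp_c = air_temp_c,
               snow_depth_m = snow_depth_m),
    shoveling_dates = shoveling_dates,
    class = c("winter_series", "data.frame"))
}

#' @export
print.winter_series <- function(x, ...) {
  cat(sprintf("Winter weather series: %d days (%s to %s), %d shoveling dates\n",
              nrow(x), format(x$date[1]), format(x$date[nrow(x)]),
              length(attr(x, "shoveling_dates"))))
  invisible(x)
}

# Snow depth as used in the conductivity term: after each shoveling
# occasion the layer is reset to `reset_depth` until the next day on which
# the observed series accumulates again.
effective_snow <- function(winter, reset_depth = 0.03) {
  snow <- winter$snow_depth_m
  shovel <- attr(winter, "shoveling_dates")
  if (length(shovel) == 0) return(snow)
  inc <- c(FALSE, diff(snow) > 0)
  out <- snow
  for (d in as.list(shovel)) {
    i <- match(d, winter$date)
    nxt <- which(inc & seq_along(inc) > i)
    j <- if (length(nxt)) min(nxt) - 1L else length(snow)
    out[i:j] <- pmin(out[i:j], reset_depth)
  }
  out
}

#' Grow a daily ice-thickness series over a winter
#'
#' Accumulates freezing degree-days from freeze-up (the first sub-zero
#' day, or from the start of the series) and evaluates the snow-coupled
#' Stefan thickness each day. After each shoveling occasion the snow layer
#' entering the conductivity term is reset to `reset_depth` until snow
#' accumulates again.
#'
#' @param winter A [winter_series()].
#' @param physics An [ice_physics()] object.
#' @param accumulate_from `"freezeup"` (default) starts the degree-day sum
#'   at the first sub-zero day; `"start"` uses the whole series.
#' @param reset_depth Post-shoveling snow depth, m (3 cm).
#' @param ... Passed to [ice_thickness()] (`tol`, `max_iter`).
#' @return An `ice_series` data frame with columns `date`, `degree_days`
#'   and `h_i_m`.
#' @export
grow_series <- function(winter, physics = ice_physics(),
                        accumulate_from = c("freezeup", "start"),
                        reset_depth = 0.03, ...) {
  stopifnot(inherits(winter, "winter_series"))
  accumulate_from <- match.arg(accumulate_from)
  temp <- winter$air_temp_c
  frost <- pmax(0, -temp)
  if (accumulate_from == "freezeup") {
    first_frost <- which(frost > 0)
    if (length(first_frost)) frost[seq_len(first_frost[1] - 1L)] <- 0
  }
  S <- cumsum(frost)
  snow <- effective_snow(winter, reset_depth)
  h <- ice_thickness(S, snow, physics, ...)
  structure(
    data.frame(date = winter$date, degree_days = S, h_i_m = h),
    class = c("ice_series", "data.frame"))
}

#' Weekly (and pooled) means of an ice series
#'
#' Averages the daily thickness over consecutive blocks of `days` days,
#' yielding the per-occasion ice covariate used in detection models.
#'
#' @param ice An `ice_series` from [grow_series()].
#' @param n_weeks Number of weekly blocks to export.
#' @param days Days per block (7).
#' @return Numeric vector of length `n_weeks` of mean thickness, m.
#' @export
ice_weekly_means <- function(ice, n_weeks, days = 7L) {
  stopifnot(inherits(ice, "ice_series"))
  if (n_weeks * days > nrow(ice)) {
    stop("ice series does not cover the requested number of weeks")
  }
  idx <- rep(seq_len(n_weeks), each = days)
  as.numeric(tapply(ice$h_i_m[seq_len(n_weeks * days)], idx, mean))
}

#' Pool per-week covariate values into wider occasions
#'
#' Means of consecutive blocks of `width` weekly values; used to carry the
#' ice covariate onto biweekly pooled tracking occasions.
#'
#' @param weekly Numeric vector of weekly values.
#' @param width Number of weeks per pooled occasion.
#' @return Numeric vector of length `length(weekly) / width`.
#' @export
pool_covariate <- function(weekly, width = 2L) {
  if (length(weekly) %% width != 0) {
    stop("weekly series length must be a multiple of the pooling width")
  }
  as.numeric(tapply(weekly, rep(seq_len(length(weekly) / width), each = width),
                    mean))
}
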