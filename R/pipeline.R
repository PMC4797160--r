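#' Configuration for the full analysis pipeline
#'
#' Inputs may be in-memory objects (registry/tracking data frames,
#' [winter_series()], [reach_table()]) or file paths to the corresponding
#' delimited-text formats.
#'
#' @param registry Registry data frame or CSV path.
#' @param tracking Tracking data frame or CSV path.
#' @param winter [winter_series()] or weather CSV path.
#' @param reach [reach_table()] or CSV path.
#' @param shoveling_dates Used when `winter` is a path.
#' @param physics [ice_physics()] overrides.
#' @param accuracy Movement accuracy, m.
#' @param pool_width Weeks pooled per occasion.
#' @param n_occasions Weekly tracking occasions.
#' @param models Candidate model strings for selection.
#' @param global_model Global model for goodness-of-fit.
#' @param gof List: `levels`, `n_rep` for [median_chat()].
#' @param control [cjs_control()] for candidate-model fits.
#' @param seed Seed governing every stochastic stage.
#' @param out_dir Optional directory; when given, every stage's output is
#'   written there together with a manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(registry, tracking, winter, reach,
                            shoveling_dates = character(),
                            physics = ice_physics(),
                            accuracy = 0.5, pool_width = 2L,
                            n_occasions = 26L,
                            models = c("phi(1)p(g)",
                                       "phi(1 + cond)p(g x ice)",
                                       "phi(1 + cond)p(g x ice + complex)"),
                            global_model = "phi(g x t)p(g x t)",
                            gof = list(levels = c(1, 1.5, 2), n_rep = 10L),
                            control = cjs_control(n_starts = 5L),
                            seed = 1L, out_dir = NULL) {
  if (accuracy <= 0) stop("movement accuracy must be positive")
  structure(list(registry = registry, tracking = tracking, winter = winter,
                 reach = reach, shoveling_dates = shoveling_dates,
                 physics = physics, accuracy = accuracy,
                 pool_width = as.integer(pool_width),
                 n_occasions = as.integer(n_occasions),
                 models = models, global_model = global_model, gof = gof,
                 control = control, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

pipeline_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  message(sprintf("[%s] done in %.2f s", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full winter-tracking analysis pipeline
#'
#' Ice growth, encounter-history construction with fate classification
#' and pooling, CJS fitting of all candidate models, median c-hat
#' goodness of fit on the global model, QAICc ranking, real-parameter
#' estimates from the top model, and the maturity-transience association
#' test. With `out_dir` set, every stage's output is written as
#' CSV/JSON/.inp together with a manifest recording the seed and content
#' hashes.
#'
#' @param config A [pipeline_config()].
#' @return A report list (see details in the package vignette).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)

  registry <- if (is.character(config$registry)) {
    read_registry(config$registry)
  } else config$registry
  tracking <- if (is.character(config$tracking)) {
    read_tracking(config$tracking)
  } else config$tracking
  winter <- if (is.character(config$winter)) {
    read_weather(config$winter, config$shoveling_dates)
  } else config$winter
  reach <- if (is.character(config$reach)) {
    read_reach_table(config$reach)
  } else config$reach

  ice <- pipeline_stage("ice", {
    grow_series(winter, config$physics)
  })
  ice_weekly <- ice_weekly_means(ice, config$n_occasions)
  ice_pooled_cm <- pool_covariate(ice_weekly * 100, config$pool_width)

  histories <- pipeline_stage("histories", {
    build_histories(registry, tracking, config$n_occasions)
  })

  fates <- pipeline_stage("fates", {
    classify_fates(registry, tracking, config$accuracy)
  })
  registry$fate <- fates
  fate_counts <- table(group = registry$group, fate = factor(
    fates, c("resident", "transient")))

  covs <- pipeline_stage("covariates", {
    covariate_table(registry, tracking, reach)
  })

  res_idx <- which(fates == "resident")
  if (length(res_idx) == 0) stop("pipeline stage 'histories' failed: no residents to analyse")
  pooled <- pool_occasions(histories[res_idx, , drop = FALSE],
                           config$pool_width)
  data <- cjs_data(pooled, droplevels(registry$group[res_idx]),
                   covariates = covs[res_idx, , drop = FALSE],
                   ice = ice_pooled_cm)

  return_rates <- lapply(split(seq_along(res_idx),
                               droplevels(registry$group[res_idx])),
                         function(i) {
    suppressWarnings(return_rate(histories[res_idx[i], , drop = FALSE]))
  })

  gof <- pipeline_stage("gof", {
    median_chat(data, config$global_model, levels = config$gof$levels,
                n_rep = config$gof$n_rep, seed = config$seed + 1L,
                control = config$control)
  })
  c_hat <- max(1, gof$c_hat)

  fits <- pipeline_stage("fit", {
    out <- lapply(config$models, function(m) {
      adjust_for_overdispersion(cjs_fit(m, data, config$control), c_hat)
    })
    names(out) <- config$models
    out
  })

  ranking <- pipeline_stage("select", {
    rank_models(fits, c_hat = c_hat)
  })
  top <- fits[[as.character(ranking$model[1])]]
  top_phi <- cjs_reals(top, "phi",
                       newdata = data.frame(t = seq_len(data$T - 1L)))
  top_p <- cjs_reals(top, "p")

  assoc <- NULL
  tab <- maturity_fate_table(registry)
  if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
    assoc <- pipeline_stage("assoc", {
      list(test = mantel_haenszel(tab), risk_ratio = risk_ratio(tab),
           table = tab)
    })
  }

  report <- list(seed = config$seed,
                 ice = ice, ice_weekly_m = ice_weekly,
                 ice_pooled_cm = ice_pooled_cm,
                 registry = registry, fate_counts = fate_counts,
                 return_rates = return_rates,
                 data = data, gof = gof, c_hat = c_hat,
                 fits = fits, ranking = ranking,
                 top_model = as.character(ranking$model[1]),
                 top_phi = top_phi, top_p = top_p,
                 assoc = assoc)

  if (!is.null(config$out_dir)) {
    pipeline_stage("report", write_report(report, data, config))
  }
  report
}

write_report <- function(report, data, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  utils::write.csv(report$ice, out("ice_series.csv"), row.names = FALSE)
  utils::write.csv(report$registry, out("registry_with_fates.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$fate_counts), out("fate_counts.csv"),
                   row.names = FALSE)
  write_inp(data$histories, data$group, data$covariates,
            out("histories.inp"))
  utils::write.csv(as.data.frame(report$ranking), out("model_table.csv"),
                   row.names = FALSE)
  utils::write.csv(report$top_phi, out("survival_estimates.csv"),
                   row.names = FALSE)
  utils::write.csv(report$top_p, out("detection_estimates.csv"),
                   row.names = FALSE)
  top <- report$fits[[report$top_model]]
  jsonlite::write_json(
    list(model = report$top_model,
         log_likelihood = top$loglik,
         n_estimable = top$n_estimable,
         c_hat = report$c_hat,
         beta = as.list(top$beta),
         se = as.list(sqrt(diag(top$vcov)))),
    out("top_fit.json"), auto_unbox = TRUE, digits = NA)
  files <- c("ice_series.csv", "registry_with_fates.csv", "fate_counts.csv",
             "histories.inp", "model_table.csv", "survival_estimates.csv",
             "detection_estimates.csv", "top_fit.json")
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("winterpit")),
    config_hash = rlang::hash(config[setdiff(names(unclass(config)),
                                             "out_dir")]),
    file_hashes = stats::setNames(
      lapply(files, function(f) unname(tools::md5sum(out(f)))), files))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}

#' Plot estimated detection probability against the ice covariate
#'
#' Simple base-graphics display of per-occasion detection estimates per
#' group over the pooled ice series.
#'
#' @param report A [run_pipeline()] report.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot_detection <- function(report, ...) {
  p <- report$top_p
  groups <- unique(p$group)
  occ <- sort(unique(p$t))
  mat <- sapply(groups, function(g) p$estimate[p$group == g][order(p$t[p$group == g])])
  graphics::matplot(occ, mat, type = "b", pch = 1:length(groups),
                    xlab = "pooled occasion", ylab = "detection probability",
                    ylim = c(0, 1), ...)
  graphics::legend("bottomleft", legend = groups, pch = 1:length(groups),
                   col = seq_along(groups), lty = seq_along(groups))
  invisible(report)
}
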