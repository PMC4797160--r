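#' Optimiser settings for CJS fitting
#'
#' Quasi-Newton (BFGS) maximisation with multiple starts from jittered
#' zeros; simulated annealing is engaged as a fallback when no start
#' converges, then polished with BFGS.
#'
#' @param n_starts Number of starts (the first is all-zero on the logit
#'   scale, i.e. all probabilities 0.5).
#' @param jitter_sd SD of the start jitter on the logit scale.
#' @param reltol Relative convergence tolerance.
#' @param maxit Iteration cap per BFGS run.
#' @param init Optional start vector (used as the first start).
#' @param sann_on_failure Engage simulated annealing when BFGS fails.
#' @param sann_maxit Simulated-annealing iterations.
#' @param drop_tol Relative tolerance for dropping linearly dependent
#'   design columns before fitting.
#' @param estimability_tol Hessian eigenvalues below this fraction of the
#'   largest are treated as non-estimable directions.
#' @return A `cjs_control` list.
#' @export
cjs_control <- function(n_starts = 25L, jitter_sd = 0.5, reltol = 1e-8,
                        maxit = 1000L, init = NULL,
                        sann_on_failure = TRUE, sann_maxit = 5000L,
                        drop_tol = 1e-9, estimability_tol = 1e-8) {
  structure(list(n_starts = n_starts, jitter_sd = jitter_sd,
                 reltol = reltol, maxit = maxit, init = init,
                 sann_on_failure = sann_on_failure, sann_maxit = sann_maxit,
                 drop_tol = drop_tol, estimability_tol = estimability_tol),
            class = "cjs_control")
}

# drop linearly dependent columns (pivoted QR within a block)
cjs_drop_dependent <- function(X, tol) {
  if (ncol(X) == 0) return(list(X = X, dropped = character()))
  qd <- qr(X, tol = tol)
  keep <- sort(qd$pivot[seq_len(qd$rank)])
  list(X = X[, keep, drop = FALSE],
       dropped = colnames(X)[setdiff(seq_len(ncol(X)), keep)])
}

#' Fit a Cormack-Jolly-Seber model
#'
#' Maximises the individual-level CJS likelihood (conditional on first
#' release) over the logit-scale coefficients of the supplied model
#' structure. Individual covariates preclude pooling into sufficient
#' statistics, so the likelihood is computed per individual (with
#' frequency weights honoured). Standard errors come from the inverse of
#' the numerically estimated Hessian, restricted to its estimable
#' subspace; the number of estimable parameters is the numerical rank of
#' the Hessian, which also exposes the classical confounding of the
#' terminal survival-detection product in time-dependent models.
#'
#' @param model Model string (see [parse_model_spec()]) or `cjs_spec`.
#' @param data A [cjs_data()].
#' @param control A [cjs_control()].
#' @return A `cjs_fit` with coefficients (`beta`), covariance (`vcov`),
#'   `loglik`, counts of total and estimable parameters, convergence and
#'   terminal-confounding flags.
#' @export
cjs_fit <- function(model, data, control = cjs_control()) {
  spec <- parse_model_spec(model)
  stopifnot(inherits(data, "cjs_data"))
  design <- build_design(spec, data)
  d_phi <- cjs_drop_dependent(design$X_phi, control$drop_tol)
  d_p <- cjs_drop_dependent(design$X_p, control$drop_tol)
  fit_design <- design
  fit_design$X_phi <- d_phi$X
  fit_design$X_p <- d_p$X
  dropped <- c(d_phi$dropped, d_p$dropped)
  nll <- cjs_nll_factory(fit_design, data)
  P <- nll$n_par

  starts <- vector("list", control$n_starts)
  starts[[1]] <- if (!is.null(control$init)) {
    stopifnot(length(control$init) == P)
    control$init
  } else rep(0, P)
  if (control$n_starts > 1) {
    for (s in 2:control$n_starts) {
      starts[[s]] <- starts[[1]] + stats::rnorm(P, 0, control$jitter_sd)
    }
  }
  best <- NULL
  for (s in seq_along(starts)) {
    o <- try(stats::optim(starts[[s]], nll$fn, nll$gr, method = "BFGS",
                          control = list(maxit = control$maxit,
                                         reltol = control$reltol)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("all optimisation starts failed")
  converged <- best$convergence == 0
  if (!converged && control$sann_on_failure) {
    sa <- stats::optim(best$par, nll$fn, method = "SANN",
                       control = list(maxit = control$sann_maxit))
    o <- stats::optim(sa$par, nll$fn, nll$gr, method = "BFGS",
                      control = list(maxit = control$maxit,
                                     reltol = control$reltol))
    if (o$value <= best$value) best <- o
    converged <- best$convergence == 0
  }
  # polish the winning start to a tight optimum: rank-based estimability
  # needs the flat (confounded) directions to be numerically flat
  pol <- stats::optim(best$par, nll$fn, nll$gr, method = "BFGS",
                      control = list(maxit = control$maxit,
                                     reltol = min(control$reltol, 1e-13)))
  if (pol$value <= best$value) {
    best$par <- pol$par
    best$value <- pol$value
  }

  H <- stats::optimHess(best$par, nll$fn, nll$gr)
  H <- (H + t(H)) / 2
  eg <- eigen(H, symmetric = TRUE)
  ev <- eg$values
  thr <- control$estimability_tol * max(abs(ev), .Machine$double.eps)
  keep <- ev > thr
  rank <- sum(keep)
  V <- eg$vectors
  vcov <- V[, keep, drop = FALSE] %*%
    (t(V[, keep, drop = FALSE]) / ev[keep])
  nm <- c(colnames(fit_design$X_phi), colnames(fit_design$X_p))
  beta <- stats::setNames(best$par, nm)
  dimnames(vcov) <- list(nm, nm)

  terminal <- cjs_terminal_confound(fit_design, eg, keep)

  structure(list(beta = beta, vcov = vcov, loglik = -best$value,
                 n_params = ncol(design$X_phi) + ncol(design$X_p),
                 n_estimable = rank, dropped = dropped,
                 converged = converged,
                 terminal_confound = terminal,
                 hessian_eigenvalues = ev,
                 spec = spec, design = fit_design, data = data,
                 n_released = sum(data$weights),
                 c_hat = 1, control = control),
            class = "cjs_fit")
}

# does the Hessian null space load on parameters that only act at the
# terminal interval/occasion? (the classical terminal phi*p confound)
cjs_terminal_confound <- function(design, eg, keep) {
  if (all(keep)) return(FALSE)
  n <- design$n
  K <- design$T - 1L
  terminal_rows <- seq.int((K - 1L) * n + 1L, K * n)
  col_terminal <- function(X) {
    vapply(seq_len(ncol(X)), function(j) {
      nz <- which(X[, j] != 0)
      length(nz) > 0 && all(nz %in% terminal_rows)
    }, logical(1))
  }
  term_cols <- c(col_terminal(design$X_phi), col_terminal(design$X_p))
  if (!any(term_cols)) return(FALSE)
  null_vecs <- eg$vectors[, !keep, drop = FALSE]
  any(apply(null_vecs, 2, function(v) {
    sum(v[term_cols]^2) / sum(v^2) > 0.99
  }))
}

#' Number of estimable parameters of a fit
#'
#' The numerical rank of the likelihood Hessian (eigenvalues above the
#' estimability threshold), i.e. the parameter count that enters the
#' information-criterion penalty. The attribute `terminal_confound`
#' reports whether the rank deficiency involves only the terminal
#' occasion, where survival and detection enter solely through their
#' product.
#'
#' @param fit A `cjs_fit`.
#' @return Integer with attribute `terminal_confound`.
#' @export
count_estimable <- function(fit) {
  stopifnot(inherits(fit, "cjs_fit"))
  structure(fit$n_estimable, terminal_confound = fit$terminal_confound)
}

#' @export
print.cjs_fit <- function(x, ...) {
  cat(sprintf("CJS model %s\n", format(x$spec)))
  cat(sprintf("  log-likelihood %.3f; %d parameters (%d estimable)%s\n",
              x$loglik, x$n_params, x$n_estimable,
              if (x$terminal_confound) "; terminal phi*p confounded" else ""))
  if (!x$converged) cat("  WARNING: optimiser did not report convergence\n")
  if (length(x$dropped)) {
    cat("  dropped dependent columns:", paste(x$dropped, collapse = ", "), "\n")
  }
  if (x$c_hat != 1) cat(sprintf("  SEs inflated by sqrt(c-hat = %.3f)\n", x$c_hat))
  invisible(x)
}

#' @export
coef.cjs_fit <- function(object, ...) object$beta

#' @export
vcov.cjs_fit <- function(object, ...) object$vcov

#' @export
logLik.cjs_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_estimable, class = "logLik")
}

#' Real-scale parameter estimates from a CJS fit
#'
#' Evaluates apparent survival or detection probability (with delta-method
#' standard errors) on a grid of groups, times, and covariate values. For
#' survival, `t` indexes the interval `t -> t+1` (1..T-1); for detection,
#' `t` is the occasion (2..T). Covariates not supplied in `newdata`
#' default to their (weight-averaged) data means.
#'
#' @param fit A `cjs_fit`.
#' @param par `"phi"` or `"p"`.
#' @param newdata Data frame with optional columns `group`, `t`, and
#'   covariates; defaults to all groups x all times at mean covariates.
#' @return `newdata` with columns `estimate` and `se` appended.
#' @export
cjs_reals <- function(fit, par = c("phi", "p"), newdata = NULL) {
  par <- match.arg(par)
  data <- fit$data
  K <- data$T - 1L
  lv <- fit$design$levels
  times <- if (par == "phi") seq_len(K) else seq_len(K) + 1L
  if (is.null(newdata)) {
    newdata <- expand.grid(group = lv$g, t = times,
                           stringsAsFactors = FALSE)
  }
  if (is.null(newdata$t)) newdata$t <- times[1]
  if (is.null(newdata$group)) newdata$group <- lv$g[1]
  if (par == "p" && any(newdata$t < 2 | newdata$t > K + 1)) {
    stop("detection occasions run 2..T")
  }
  if (par == "phi" && any(newdata$t < 1 | newdata$t > K)) {
    stop("survival intervals run 1..T-1")
  }
  m <- nrow(newdata)
  covs <- data$covariates
  cov_defaults <- if (!is.null(covs)) {
    lapply(covs, function(v) sum(v * data$weights) / sum(data$weights))
  } else list()
  grid_covs <- lapply(stats::setNames(nm = names(cov_defaults)), function(nm) {
    if (!is.null(newdata[[nm]])) newdata[[nm]] else rep(cov_defaults[[nm]], m)
  })
  pseudo <- cjs_data(
    histories = matrix(1L, m, data$T),
    group = factor(as.character(newdata$group), levels = lv$g),
    covariates = if (length(grid_covs)) as.data.frame(grid_covs) else NULL,
    ice = data$ice)
  pd <- build_design(fit$spec, pseudo, levels = lv)
  X <- if (par == "phi") pd$X_phi else pd$X_p
  tt <- if (par == "phi") newdata$t else newdata$t - 1L
  rows <- (tt - 1L) * m + seq_len(m)
  X <- X[rows, , drop = FALSE]
  used <- if (par == "phi") colnames(fit$design$X_phi) else colnames(fit$design$X_p)
  X <- X[, used, drop = FALSE]
  beta <- fit$beta[used]
  Vc <- fit$vcov[used, used, drop = FALSE]
  eta <- as.numeric(X %*% beta)
  se_eta <- sqrt(pmax(rowSums((X %*% Vc) * X), 0))
  est <- stats::plogis(eta)
  newdata$estimate <- est
  newdata$se <- se_eta * est * (1 - est)
  newdata
}
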