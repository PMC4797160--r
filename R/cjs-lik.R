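#' Probability of never being detected again (chi recursion)
#'
#' Backward recursion over occasions: `chi_T = 1` and
#' `chi_t = (1 - phi_t) + phi_t * (1 - p_{t+1}) * chi_{t+1}`, the
#' probability that an individual alive and present at occasion `t` is
#' never detected afterwards. The terminal value reflects that nothing is
#' observed after the last occasion.
#'
#' @param phi Survival probabilities per interval `t -> t+1`, length T-1.
#' @param p Detection probabilities at occasions 2..T, length T-1
#'   (`p[t]` is detection at occasion t+1).
#' @return Numeric vector `chi_1..chi_T` (length T).
#' @export
#' @examples
#' chi_tail(0.8, 0.6)  # c(0.52, 1)
chi_tail <- function(phi, p) {
  K <- length(phi)
  stopifnot(length(p) == K, all(phi >= 0 & phi <= 1), all(p >= 0 & p <= 1))
  chi <- numeric(K + 1)
  chi[K + 1] <- 1
  for (t in K:1) {
    chi[t] <- (1 - phi[t]) + phi[t] * (1 - p[t]) * chi[t + 1]
  }
  chi
}

#' Log-likelihood of one encounter history
#'
#' Cormack-Jolly-Seber probability of a single post-marking history,
#' conditional on the first release: survival and Bernoulli detection
#' terms up to the last detection, then the probability of never being
#' seen again. Computed in log space.
#'
#' @param history 0/1 vector over occasions (marking bit first, = 1).
#' @param phi,p Parameter vectors as in [chi_tail()].
#' @return Log-probability (scalar).
#' @export
#' @examples
#' exp(individual_loglik(c(1, 1), 0.8, 0.6))  # 0.48
#' exp(individual_loglik(c(1, 0), 0.8, 0.6))  # 0.52
individual_loglik <- function(history, phi, p) {
  T_ <- length(history)
  stopifnot(history[1] == 1, length(phi) == T_ - 1, length(p) == T_ - 1)
  l <- max(which(history == 1))
  chi <- chi_tail(phi, p)
  ll <- log(chi[l])
  if (l > 1) {
    t_ <- seq_len(l - 1)
    y <- history[t_ + 1]
    ll <- ll + sum(log(phi[t_]) + y * log(p[t_]) + (1 - y) * log1p(-p[t_]))
  }
  ll
}

# clamp logit-scale linear predictors so probabilities stay in the
# interior of (0, 1)
cjs_clamp <- 30

# closures computing the weighted negative log-likelihood and its
# analytic gradient for a design + data pair
cjs_nll_factory <- function(design, data) {
  Y <- data$histories
  w <- data$weights
  n <- nrow(Y)
  K <- ncol(Y) - 1L
  X_phi <- design$X_phi
  X_p <- design$X_p
  P_phi <- ncol(X_phi)
  Y2 <- Y[, -1L, drop = FALSE]
  l <- apply(Y, 1, function(r) max(which(r == 1L)))
  tgrid <- matrix(rep(seq_len(K), each = n), n, K)
  A <- tgrid < l            # intervals known alive (t < last detection)
  M <- tgrid >= l           # intervals entering the chi tail
  il <- cbind(seq_len(n), l)

  probs <- function(beta) {
    eta_phi <- matrix(X_phi %*% beta[seq_len(P_phi)], n, K)
    eta_p <- matrix(X_p %*% beta[-seq_len(P_phi)], n, K)
    list(phi = stats::plogis(pmin(pmax(eta_phi, -cjs_clamp), cjs_clamp)),
         p = stats::plogis(pmin(pmax(eta_p, -cjs_clamp), cjs_clamp)))
  }

  chi_mat <- function(phi, p) {
    chi <- matrix(1, n, K + 1L)
    for (t in K:1) {
      chi[, t] <- (1 - phi[, t]) + phi[, t] * (1 - p[, t]) * chi[, t + 1L]
    }
    chi
  }

  fn <- function(beta) {
    pr <- probs(beta)
    chi <- chi_mat(pr$phi, pr$p)
    open_part <- A * (log(pr$phi) + Y2 * log(pr$p) + (1 - Y2) * log1p(-pr$p))
    ll <- rowSums(open_part) + log(chi[il])
    -sum(w * ll)
  }

  gr <- function(beta) {
    pr <- probs(beta)
    phi <- pr$phi; p <- pr$p
    chi <- chi_mat(phi, p)
    chiL <- chi[il]
    # cumulative products of phi * (1 - p) along intervals, row-wise
    cp <- matrix(1, n, K + 1L)
    for (t in seq_len(K)) cp[, t + 1L] <- cp[, t] * phi[, t] * (1 - p[, t])
    cpL <- pmax(cp[il], 1e-300)   # underflow guard for long tails
    W <- (cp[, seq_len(K), drop = FALSE] / cpL) * M
    chin <- chi[, -1L, drop = FALSE]      # chi_{t+1}
    G_phi <- A * (1 - phi) +
      W * (-1 + (1 - p) * chin) * phi * (1 - phi) / chiL
    G_p <- A * (Y2 - p) +
      W * (-phi * chin) * p * (1 - p) / chiL
    -c(crossprod(X_phi, as.vector(w * G_phi)),
       crossprod(X_p, as.vector(w * G_p)))
  }

  list(fn = fn, gr = gr, n_par = P_phi + ncol(X_p), P_phi = P_phi)
}
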