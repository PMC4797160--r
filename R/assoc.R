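#' 2x2 table of maturity state against detection-history class
#'
#' Cross-tabulates spawning vs spent individuals against transient vs
#' resident fate, for the adult fish of a registry with fates assigned.
#'
#' @param registry Registry data frame with columns `maturity`
#'   (`"spawning"` / `"spent"`, others ignored) and `fate`.
#' @return A 2x2 integer matrix, rows spawning/spent, columns
#'   transient/resident.
#' @export
maturity_fate_table <- function(registry) {
  keep <- registry$maturity %in% c("spawning", "spent")
  tab <- table(factor(registry$maturity[keep], c("spawning", "spent")),
               factor(registry$fate[keep], c("transient", "resident")))
  m <- matrix(as.integer(tab), 2, 2,
              dimnames = list(maturity = c("spawning", "spent"),
                              fate = c("transient", "resident")))
  m
}

#' Mantel-Haenszel chi-squared test for a 2x2 table
#'
#' Single-stratum, continuity-corrected Mantel-Haenszel test of
#' association: `(|a - E[a]| - 1/2)^2 / Var(a)` with expectation and
#' variance of the top-left cell under the hypergeometric null, referred
#' to a chi-squared distribution with 1 df.
#'
#' @param tab 2x2 matrix of counts; all margins must be positive.
#' @return List with `statistic`, `p_value` and the table.
#' @export
mantel_haenszel <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all margins of the 2x2 table must be positive")
  }
  a <- tab[1, 1]
  n1 <- sum(tab[1, ]); n2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  N <- sum(tab)
  e_a <- n1 * c1 / N
  v_a <- n1 * n2 * c1 * c2 / (N^2 * (N - 1))
  stat <- (max(abs(a - e_a) - 0.5, 0))^2 / v_a
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       table = tab)
}

#' Risk ratio of transience between two classes
#'
#' Ratio of the row-1 to row-2 proportion of the first column, e.g. the
#' probability of spawning fish becoming transients relative to spent
#' fish.
#'
#' @param tab 2x2 matrix (rows = classes, column 1 = event).
#' @return The ratio (scalar).
#' @export
risk_ratio <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(rowSums(tab) == 0)) stop("both class totals must be positive")
  (tab[1, 1] / sum(tab[1, ])) / (tab[2, 1] / sum(tab[2, ]))
}
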