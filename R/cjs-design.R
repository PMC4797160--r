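#' Bundle capture-mark-recapture data for CJS fitting
#'
#' Holds pooled encounter histories together with everything the design
#' builder may need: the fish group, per-individual covariates, the
#' per-occasion ice covariate, and optional frequency weights (identical
#' rows may be collapsed into one weighted row).
#'
#' @param histories Integer matrix, one row per individual: marking bit
#'   (all 1) followed by the occasion bits.
#' @param group Factor (or character) of length `nrow(histories)`.
#' @param covariates Optional data frame of individual covariates
#'   (columns referenced by model terms, e.g. `cond`, `complex`, `depth`,
#'   `distance`, `length`, `weight`, `tag_burden`).
#' @param ice Optional numeric vector of the ice covariate, one value per
#'   occasion 2..T (equivalently per survival interval), typically cm.
#' @param weights Frequency weights, default 1.
#' @return A `cjs_data` object.
#' @export
cjs_data <- function(histories, group = NULL, covariates = NULL,
                     ice = NULL, weights = NULL) {
  histories <- as.matrix(histories)
  if (!all(histories %in% c(0L, 1L))) stop("histories must be 0/1")
  if (!all(histories[, 1] == 1L)) stop("first (marking) bit must be 1 for every individual")
  n <- nrow(histories)
  T_ <- ncol(histories)
  if (T_ < 2) stop("need at least two occasions")
  if (is.null(group)) group <- factor(rep("all", n))
  group <- as.factor(group)
  if (length(group) != n) stop("group length must match histories")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariates must have one row per individual")
  }
  if (!is.null(ice) && length(ice) != T_ - 1L) {
    stop("ice covariate must have one value per occasion 2..T")
  }
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights <= 0)) {
    stop("weights must be positive, one per row")
  }
  structure(list(histories = histories, group = group,
                 covariates = covariates, ice = ice, weights = weights,
                 n = n, T = T_),
            class = "cjs_data")
}

#' @export
print.cjs_data <- function(x, ...) {
  cat(sprintf("CJS data: %d individuals (%d rows), %d occasions, groups: %s\n",
              round(sum(x$weights)), x$n, x$T,
              paste(levels(x$group), collapse = ", ")))
  invisible(x)
}

cjs_covariate_names <- c("cond", "complex", "depth", "distance",
                         "length", "weight", "tag_burden")
cjs_term_names <- c("1", "t", "g", "ice", cjs_covariate_names)

#' Parse a CJS model string
#'
#' Model structure is written in the field's compact notation, e.g.
#' `"{phi(t x cond) p(g x ice + complex x t)}"`. The survival and
#' detection parts each hold a sum of terms; a term is a product of
#' effects joined by `x`, `*`, `:` or the multiplication sign. Recognised
#' effects: `1` (constant), `t` (occasion/interval factor), `g` (group
#' factor), `ice` (per-occasion covariate), and the individual covariates
#' `cond`, `complex`, `depth`, `distance`, `length`, `weight`,
#' `tag_burden`. The Greek letter phi is accepted for the survival part.
#'
#' @param x Model string, or an already-parsed `cjs_spec`.
#' @return A `cjs_spec`: lists `phi` and `p` of character vectors (one per
#'   term), with a canonical string form via `format()`.
#' @export
#' @examples
#' parse_model_spec("phi(1)p(1)")
#' parse_model_spec("{phi(t x cond)p(g x ice + complex x t)}")
parse_model_spec <- function(x) {
  if (inherits(x, "cjs_spec")) return(x)
  stopifnot(is.character(x), length(x) == 1)
  s <- x
  s <- gsub("φ|ϕ|Phi|PHI", "phi", s)
  s <- gsub("×", "*", s)
  s <- gsub("\\bx\\b", "*", s)
  s <- gsub("[{}[:space:]]", "", s)
  m_phi <- regmatches(s, regexec("phi\\(([^()]*)\\)", s))[[1]]
  m_p <- regmatches(s, regexec("(?<![a-z])p\\(([^()]*)\\)", s, perl = TRUE))[[1]]
  if (length(m_phi) < 2 || length(m_p) < 2) {
    stop("model string must contain both phi(...) and p(...): ", x)
  }
  parse_terms <- function(body, part) {
    if (body == "") stop("empty ", part, " structure in model string")
    terms <- strsplit(body, "+", fixed = TRUE)[[1]]
    lapply(terms, function(tm) {
      facs <- strsplit(tm, "[*:]")[[1]]
      bad <- setdiff(facs, cjs_term_names)
      if (length(bad)) {
        stop(sprintf("unknown effect '%s' in %s term '%s'",
                     bad[1], part, tm))
      }
      facs
    })
  }
  structure(list(phi = parse_terms(m_phi[2], "phi"),
                 p = parse_terms(m_p[2], "p")),
            class = "cjs_spec")
}

#' @export
format.cjs_spec <- function(x, ...) {
  fmt <- function(terms) paste(vapply(terms, paste, "", collapse = " x "),
                               collapse = " + ")
  sprintf("{phi(%s)p(%s)}", fmt(x$phi), fmt(x$p))
}

#' @export
print.cjs_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# values of one effect on the (individual, time) grid of a block.
# Rows are ordered column-major: individual fastest, time slowest.
cjs_effect_values <- function(name, block, data, levels) {
  n <- data$n
  K <- data$T - 1L
  if (name == "1") return(list(type = "one"))
  if (name == "g") {
    return(list(type = "cat",
                f = factor(rep(as.character(data$group), K),
                           levels = levels$g)))
  }
  if (name == "t") {
    lev <- if (block == "phi") levels$t_phi else levels$t_p
    return(list(type = "cat",
                f = factor(rep(lev, each = n), levels = lev)))
  }
  if (name == "ice") {
    if (is.null(data$ice)) stop("model uses 'ice' but no ice covariate supplied")
    return(list(type = "cont", v = rep(data$ice, each = n)))
  }
  if (is.null(data$covariates) || is.null(data$covariates[[name]])) {
    stop("model uses individual covariate '", name,
         "' which is missing from the data")
  }
  list(type = "cont", v = rep(data$covariates[[name]], K))
}

# expand one term (product of effects) into design columns.
# Categorical effects are crossed and coded as full (one-hot) cell
# indicators; continuous effects multiply into a single product. A term
# with categoricals and a continuous product contributes both the cell
# indicators and the cell-wise slopes; a purely continuous term
# contributes an intercept and the slope.
cjs_expand_term <- function(facs, block, data, levels) {
  vals <- lapply(facs, cjs_effect_values, block = block, data = data,
                 levels = levels)
  types <- vapply(vals, `[[`, "", "type")
  N <- data$n * (data$T - 1L)
  cats <- vals[types == "cat"]
  conts <- vals[types == "cont"]
  cont_names <- facs[types == "cont"]
  if (length(cats)) {
    f <- if (length(cats) == 1) cats[[1]]$f else {
      interaction(lapply(cats, `[[`, "f"), sep = ".", lex.order = TRUE)
    }
    cells <- stats::model.matrix(~ 0 + f)
    colnames(cells) <- sub("^f", "", colnames(cells))
  } else {
    cells <- matrix(1, N, 1, dimnames = list(NULL, "1"))
  }
  if (length(conts) == 0) return(cells)
  v <- Reduce(`*`, lapply(conts, `[[`, "v"))
  slopes <- cells * v
  colnames(slopes) <- paste(colnames(cells),
                            paste(cont_names, collapse = "."), sep = ":")
  if (length(cats)) cbind(cells, slopes) else {
    colnames(slopes) <- paste(cont_names, collapse = ".")
    cbind(cells, slopes)
  }
}

cjs_block_design <- function(terms, block, data, levels) {
  X <- do.call(cbind, lapply(terms, cjs_expand_term, block = block,
                             data = data, levels = levels))
  colnames(X) <- paste(block, colnames(X), sep = ".")
  if (anyDuplicated(colnames(X))) {
    colnames(X) <- make.unique(colnames(X))
  }
  X
}

#' Build CJS design matrices from a model specification
#'
#' Expands a parsed model into one design matrix for the survival part
#' (rows ordered individual-fastest over intervals 1..T-1) and one for the
#' detection part (occasions 2..T). Group and time enter as full one-hot
#' cell indicators within their terms; continuous covariates crossed with
#' a categorical produce one slope per cell ("a linear temporal constraint"
#' such as ice crossed with group yields one ice slope per group).
#' Overlapping terms may produce linearly dependent columns; estimability
#' is resolved at fitting time, not here.
#'
#' @param spec Model string or `cjs_spec`.
#' @param data A [cjs_data()].
#' @param levels Factor levels to use (from a previous design, to align a
#'   prediction grid); defaults derived from `data`.
#' @return A `cjs_design`: `X_phi`, `X_p`, the `levels`, and dimensions.
#' @export
build_design <- function(spec, data, levels = NULL) {
  spec <- parse_model_spec(spec)
  stopifnot(inherits(data, "cjs_data"))
  K <- data$T - 1L
  if (is.null(levels)) {
    levels <- list(g = levels(data$group),
                   t_phi = sprintf("t%d", seq_len(K)),
                   t_p = sprintf("t%d", seq_len(K) + 1L))
  }
  structure(list(X_phi = cjs_block_design(spec$phi, "phi", data, levels),
                 X_p = cjs_block_design(spec$p, "p", data, levels),
                 levels = levels, spec = spec, n = data$n, T = data$T),
            class = "cjs_design")
}

#' @export
print.cjs_design <- function(x, ...) {
  cat(sprintf("CJS design for %s\n  phi: %d columns; p: %d columns; %d individuals x %d occasions\n",
              format(x$spec), ncol(x$X_phi), ncol(x$X_p), x$n, x$T))
  invisible(x)
}
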