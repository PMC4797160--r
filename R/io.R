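#' Read a fish registry file
#'
#' Delimited text with columns `fish_id`, `group`, `length_mm`,
#' `weight_g`, `tag_length_mm`, `tag_weight_g`, `subreach_id`,
#' `maturity`, `spring_recaptured`.
#'
#' @param path CSV path.
#' @return Registry data frame.
#' @export
read_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fish_id", "group", "length_mm", "weight_g", "tag_weight_g",
            "subreach_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("registry file misses columns: ",
                         paste(miss, collapse = ", "))
  if (any(df$length_mm <= 0)) stop("non-positive fish lengths in registry")
  if (is.null(df$spring_recaptured)) df$spring_recaptured <- FALSE
  df$spring_recaptured <- as.logical(df$spring_recaptured)
  if (is.null(df$maturity)) df$maturity <- NA_character_
  df$group <- factor(df$group,
                     levels = intersect(c("sculpin", "juvenile_trout",
                                          "adult_trout"),
                                        unique(df$group)))
  df
}

#' Read weekly tracking records
#'
#' Delimited text with columns `fish_id`, `occasion`, `detected`,
#' `position` (NA when not detected) and optionally `lateral`.
#'
#' @param path CSV path.
#' @return Tracking data frame.
#' @export
read_tracking <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fish_id", "occasion", "detected", "position")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("tracking file misses columns: ",
                         paste(miss, collapse = ", "))
  df$detected <- as.logical(df$detected)
  if (!is.null(df$lateral)) df$lateral <- as.logical(df$lateral)
  df
}

#' Read a daily weather file into a winter series
#'
#' Delimited text with columns `date`, `air_temp_c`, `snow_depth_m`.
#'
#' @param path CSV path.
#' @param shoveling_dates Snow-clearing dates (coerced to `Date`).
#' @return A [winter_series()].
#' @export
read_weather <- function(path, shoveling_dates = character()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "air_temp_c", "snow_depth_m")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("weather file misses columns: ",
                         paste(miss, collapse = ", "))
  winter_series(as.Date(df$date), df$air_temp_c, df$snow_depth_m,
                as.Date(shoveling_dates))
}

#' Read a subreach table file
#'
#' Delimited text with columns `subreach_id`, `length_m`, `depth_cm`,
#' `complexity`, ordered from the downstream reach end.
#'
#' @param path CSV path.
#' @return A [reach_table()].
#' @export
read_reach_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("length_m", "depth_cm", "complexity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("reach file misses columns: ",
                         paste(miss, collapse = ", "))
  reach_table(df$length_m, df$depth_cm, df$complexity,
              df$subreach_id %||% seq_len(nrow(df)))
}

#' Write encounter histories in the MARK-style .inp dialect
#'
#' One line per individual: the history bit string, a space, one 0/1
#' dummy column per group (in `levels(group)` order), the individual
#' covariates space-separated, and a terminal `";"`. This enables
#' cross-checks against external capture-mark-recapture software.
#'
#' @param histories History matrix (marking bit first).
#' @param group Factor of group membership.
#' @param covariates Optional data frame of numeric covariates.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_inp <- function(histories, group, covariates = NULL, path) {
  histories <- as.matrix(histories)
  group <- as.factor(group)
  stopifnot(length(group) == nrow(histories))
  hist_str <- apply(histories, 1, paste, collapse = "")
  dummies <- vapply(levels(group), function(l) as.integer(group == l),
                    integer(length(group)))
  if (length(group) == 1) dummies <- matrix(dummies, nrow = 1)
  parts <- cbind(hist_str, apply(dummies, 2, as.character))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    parts <- cbind(parts, vapply(covariates, function(v) sprintf("%.10g", v),
                                 character(nrow(histories))))
  }
  lines <- paste(apply(parts, 1, paste, collapse = " "), ";")
  writeLines(lines, path)
  invisible(path)
}

#' Read encounter histories from the .inp dialect
#'
#' Inverse of [write_inp()].
#'
#' @param path Input path.
#' @param group_levels Group names matching the dummy columns.
#' @param covariate_names Names for the trailing covariate columns.
#' @return List with `histories`, `group`, `covariates`.
#' @export
read_inp <- function(path, group_levels, covariate_names = character()) {
  lines <- readLines(path)
  lines <- trimws(sub(";\\s*$", "", lines))
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "\\s+")
  n_g <- length(group_levels)
  n_c <- length(covariate_names)
  out <- lapply(toks, function(tk) {
    if (length(tk) != 1 + n_g + n_c) stop("malformed .inp line: ", paste(tk, collapse = " "))
    tk
  })
  histories <- do.call(rbind, lapply(out, function(tk) {
    as.integer(strsplit(tk[1], "")[[1]])
  }))
  dummies <- do.call(rbind, lapply(out, function(tk) {
    as.integer(tk[2:(1 + n_g)])
  }))
  if (any(rowSums(dummies) != 1)) stop("each .inp line must carry exactly one group dummy")
  group <- factor(group_levels[apply(dummies, 1, which.max)],
                  levels = group_levels)
  covariates <- NULL
  if (n_c) {
    covariates <- as.data.frame(do.call(rbind, lapply(out, function(tk) {
      as.numeric(tk[(2 + n_g):(1 + n_g + n_c)])
    })))
    names(covariates) <- covariate_names
  }
  list(histories = histories, group = group, covariates = covariates)
}
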