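#' Subreach description table
#'
#' Describes the subreaches a study reach is divided into: their length
#' along the stream, a representative (median) water depth, and structural
#' complexity expressed as the coefficient of variation of the maximal
#' depths within the subreach. Subreach 1 starts at the downstream reach
#' end; the along-stream coordinate increases upstream from 0 at the
#' downstream end.
#'
#' @param length_m Subreach lengths, m (ordered from downstream).
#' @param depth_cm Representative water depth per subreach, cm.
#' @param complexity Structural complexity (CV of maximal depths), unitless.
#' @param subreach_id Optional ids; defaults to 1..n.
#' @return A `reach_table` data frame with derived columns `upstream_end_m`
#'   (cumulative boundary) and `mid_distance_m` (distance of the subreach
#'   midpoint to the closest reach end).
#' @export
reach_table <- function(length_m, depth_cm, complexity,
                        subreach_id = seq_along(length_m)) {
  stopifnot(length(depth_cm) == length(length_m),
            length(complexity) == length(length_m))
  if (any(length_m <= 0)) stop("subreach lengths must be positive")
  if (any(complexity < 0)) stop("structural complexity must be >= 0")
  upper <- cumsum(length_m)
  total <- upper[length(upper)]
  mid <- upper - length_m / 2
  structure(
    data.frame(subreach_id = subreach_id, length_m = length_m,
               depth_cm = depth_cm, complexity = complexity,
               upstream_end_m = upper,
               mid_distance_m = pmin(mid, total - mid)),
    reach_length_m = total,
    class = c("reach_table", "data.frame"))
}

#' Example subreach table
#'
#' An 11-subreach description of a ~550-m boreal stream reach, bundled for
#' examples and tests.
#'
#' @return A [reach_table()].
#' @export
example_reach <- function() {
  path <- system.file("extdata", "example_subreaches.csv",
                      package = "winterpit", mustWork = TRUE)
  df <- utils::read.csv(path)
  reach_table(df$length_m, df$depth_cm, df$complexity, df$subreach_id)
}

#' Map along-stream positions to subreaches
#'
#' @param position Along-stream coordinates, m (0 = downstream reach end).
#' @param reach A [reach_table()].
#' @return Integer subreach indices (row numbers of `reach`).
#' @export
subreach_of <- function(position, reach) {
  stopifnot(inherits(reach, "reach_table"))
  total <- attr(reach, "reach_length_m")
  if (any(position < 0 | position > total, na.rm = TRUE)) {
    stop("positions outside the reach")
  }
  idx <- findInterval(position, reach$upstream_end_m, left.open = TRUE) + 1L
  idx[idx > nrow(reach)] <- nrow(reach)
  idx
}

#' Classify movements between successive detections
#'
#' Positions are accurate only to the tracking accuracy (0.5 m); a
#' displacement within that accuracy is not a discernible move. Larger
#' displacements are classified by sign, with the along-stream coordinate
#' increasing upstream.
#'
#' @param records Tracking records for one fish: a data frame with columns
#'   `occasion` and `position`, detections only, sorted by occasion.
#' @param accuracy Tracking accuracy, m.
#' @return A data frame with one row per pair of successive detections:
#'   `from`, `to` (occasions), `displacement_m` and
#'   `direction` in `c("upstream", "downstream", "none")`. Zero rows with
#'   fewer than two detections.
#' @export
discernible_moves <- function(records, accuracy = 0.5) {
  stopifnot(is.data.frame(records),
            all(c("occasion", "position") %in% names(records)))
  records <- records[!is.na(records$position), , drop = FALSE]
  if (nrow(records) < 2) {
    return(data.frame(from = integer(), to = integer(),
                      displacement_m = numeric(), direction = character()))
  }
  if (is.unsorted(records$occasion, strictly = TRUE)) {
    stop("records must be sorted by occasion with one row per detection")
  }
  d <- diff(records$position)
  dir <- ifelse(abs(d) <= accuracy, "none",
                ifelse(d > 0, "upstream", "downstream"))
  data.frame(from = records$occasion[-nrow(records)],
             to = records$occasion[-1],
             displacement_m = d, direction = dir)
}

#' Classify the fate of a tagged fish
#'
#' A fish is classified a transient -- an individual that permanently left
#' the sampled reach after release, or whose tag signal cannot be told
#' apart from a shed or dead tag -- when it was never detected after
#' release, or when it showed no discernible activity beyond downstream
#' displacement and was not recaptured in the spring survey. Discernible
#' upstream or lateral movement, or a spring recapture, qualifies a fish
#' as resident.
#'
#' @param records Tracking rows for the fish (detections only) with columns
#'   `occasion`, `position`, and optionally a logical `lateral` flag set on
#'   detections with cross-channel displacement beyond accuracy.
#' @param spring_recaptured Logical: recaptured at the spring survey.
#' @param accuracy Tracking accuracy, m.
#' @return `"transient"` or `"resident"`.
#' @export
classify_fate <- function(records, spring_recaptured = FALSE,
                          accuracy = 0.5) {
  det <- records[!is.na(records$position), , drop = FALSE]
  if (nrow(det) == 0) return("transient")
  lateral <- if ("lateral" %in% names(det)) isTRUE(any(det$lateral)) else FALSE
  moves <- discernible_moves(det, accuracy)
  upstream <- any(moves$direction == "upstream")
  if (upstream || lateral) return("resident")
  # no activity at all, or only downstream displacement
  if (!isTRUE(spring_recaptured)) "transient" else "resident"
}

#' Classify fates for a whole registry
#'
#' @param registry Fish registry data frame with columns `fish_id` and
#'   `spring_recaptured`.
#' @param tracking Tracking records with columns `fish_id`, `occasion`,
#'   `detected`, `position` (and optionally `lateral`).
#' @param accuracy Tracking accuracy, m.
#' @return Character vector of fates aligned with `registry` rows.
#' @export
classify_fates <- function(registry, tracking, accuracy = 0.5) {
  det <- tracking[tracking$detected, , drop = FALSE]
  split_det <- split(det, factor(det$fish_id, levels = registry$fish_id))
  vapply(seq_len(nrow(registry)), function(i) {
    classify_fate(split_det[[i]][order(split_det[[i]]$occasion), , drop = FALSE],
                  spring_recaptured = isTRUE(registry$spring_recaptured[i]),
                  accuracy = accuracy)
  }, character(1))
}

#' Build weekly encounter histories
#'
#' One row per fish: a marking bit (always 1) followed by one bit per
#' weekly tracking occasion, 1 for a detection anywhere within the study
#' reach and 0 for a missing detection.
#'
#' @param registry Fish registry with `fish_id`.
#' @param tracking Tracking records with `fish_id`, `occasion`, `detected`.
#' @param n_occasions Number of weekly tracking occasions.
#' @return Integer matrix `n x (n_occasions + 1)` with fish ids as row
#'   names; attribute `pooled` is `FALSE`.
#' @export
build_histories <- function(registry, tracking, n_occasions = 26L) {
  if (nrow(tracking) == 0) stop("no tracking records supplied")
  if (any(tracking$occasion < 1 | tracking$occasion > n_occasions)) {
    stop("tracking occasion outside 1..n_occasions")
  }
  H <- matrix(0L, nrow(registry), n_occasions + 1L,
              dimnames = list(registry$fish_id, NULL))
  H[, 1L] <- 1L
  det <- tracking[tracking$detected, , drop = FALSE]
  ri <- match(det$fish_id, registry$fish_id)
  if (anyNA(ri)) stop("tracking records refer to unknown fish ids")
  H[cbind(ri, det$occasion + 1L)] <- 1L
  attr(H, "pooled") <- FALSE
  H
}

#' Truncate an encounter history at death
#'
#' For a fish judged dead within the reach (prolonged cessation of
#' movement, confirmed at the spring survey -- the judgement is supplied
#' by the caller), detections after the last occasion with discernible
#' upstream movement are attributed to the stationary shed or dead tag and
#' removed from the history.
#'
#' @param history Integer bit vector (marking bit + weekly bits).
#' @param records Detection rows for the fish (`occasion`, `position`).
#' @param dead Logical flag supplied by the caller.
#' @param accuracy Tracking accuracy, m.
#' @return The (possibly truncated) history.
#' @export
truncate_mortality <- function(history, records, dead = FALSE,
                               accuracy = 0.5) {
  if (!isTRUE(dead)) return(history)
  moves <- discernible_moves(records[order(records$occasion), , drop = FALSE],
                             accuracy)
  up <- moves$to[moves$direction == "upstream"]
  if (length(up) == 0) {
    warning("dead fish with no upstream movement on record; history zeroed after marking")
    last_occ <- 0L
  } else {
    last_occ <- max(up)
  }
  # bit index of weekly occasion k is k + 1 (marking bit first)
  if (last_occ + 2L <= length(history)) {
    history[(last_occ + 2L):length(history)] <- 0L
  }
  history
}

#' Pool weekly encounter histories into wider occasions
#'
#' Trackings from `width` adjacent weeks are pooled into a single
#' occasion: a fish detected in any of the pooled weeks is coded 1, a fish
#' missed in all of them 0. The marking bit is kept as its own occasion.
#'
#' @param histories Integer matrix from [build_histories()] (or a single
#'   history vector).
#' @param width Number of weeks per pooled occasion.
#' @return Pooled history matrix with `1 + n_weeks / width` columns and
#'   attribute `pooled = TRUE`.
#' @export
pool_occasions <- function(histories, width = 2L) {
  if (is.vector(histories)) histories <- matrix(histories, nrow = 1)
  n_weeks <- ncol(histories) - 1L
  if (n_weeks %% width != 0) {
    stop("number of weekly occasions must be a multiple of the pooling width")
  }
  blocks <- rep(seq_len(n_weeks / width), each = width)
  pooled <- vapply(seq_len(n_weeks / width), function(b) {
    cols <- 1L + which(blocks == b)
    as.integer(rowSums(histories[, cols, drop = FALSE]) > 0)
  }, integer(nrow(histories)))
  if (nrow(histories) == 1) pooled <- matrix(pooled, nrow = 1)
  out <- cbind(histories[, 1L, drop = FALSE], pooled)
  dimnames(out) <- list(rownames(histories), NULL)
  attr(out, "pooled") <- TRUE
  out
}

#' Per-occasion return rate and its variability
#'
#' The return rate at an occasion is the proportion of tagged individuals
#' detected. Computed over the supplied histories (typically the residents
#' of one group), with summary statistics for its temporal variability:
#' the coefficient of variation over occasions and the max/min factor.
#'
#' @param histories History matrix (marking bit + occasion bits).
#' @param na_factor_warn Warn when the factor is undefined (a zero rate).
#' @return List with `rates` (per tracking occasion), `cv`, and `factor`
#'   (`NA` when the minimum rate is 0).
#' @export
return_rate <- function(histories, na_factor_warn = TRUE) {
  if (is.vector(histories)) histories <- matrix(histories, nrow = 1)
  if (nrow(histories) < 1) stop("at least one history required")
  rates <- colMeans(histories[, -1L, drop = FALSE])
  cv <- stats::sd(rates) / mean(rates)
  if (min(rates) == 0) {
    if (na_factor_warn) warning("minimum return rate is 0; max/min factor undefined")
    fac <- NA_real_
  } else {
    fac <- max(rates) / min(rates)
  }
  list(rates = as.numeric(rates), cv = cv, factor = fac)
}

#' Fulton's condition index
#'
#' `K = 100 * W / L^3` with weight in g and length in cm (lengths are
#' supplied in mm and converted). A fish of 100 mm and 10 g has K = 1.
#'
#' @param length_mm Total length, mm.
#' @param weight_g Weight, g.
#' @return Condition index, dimensionless.
#' @export
fulton_condition <- function(length_mm, weight_g) {
  if (any(length_mm <= 0) || any(weight_g <= 0)) {
    stop("length and weight must be positive")
  }
  100 * weight_g / (length_mm / 10)^3
}

#' Individual covariates for survival and detection modelling
#'
#' Summarises the biometry and the habitat used by one fish over the
#' study: body condition at tagging, the representative depth and
#' structural complexity of the subreaches it was detected in, its mean
#' distance to the closest reach end, and the tag burden.
#'
#' @param fish One registry row (`length_mm`, `weight_g`, `tag_weight_g`,
#'   `subreach_id`).
#' @param records Detection rows for the fish (`position`).
#' @param reach A [reach_table()].
#' @return A one-row data frame with `cond`, `depth`, `distance`,
#'   `complex` and `tag_burden`. With no detected positions the tagging
#'   subreach is used, with a warning, and `distance` is the tagging
#'   subreach midpoint distance.
#' @export
fish_covariates <- function(fish, records, reach) {
  stopifnot(inherits(reach, "reach_table"))
  total <- attr(reach, "reach_length_m")
  pos <- records$position[!is.na(records$position)]
  if (length(pos) == 0) {
    warning("fish without detected positions; covariates from tagging subreach")
    sr <- match(fish$subreach_id, reach$subreach_id)
    if (is.na(sr)) stop("unknown tagging subreach")
    depth <- reach$depth_cm[sr]
    complex <- reach$complexity[sr]
    distance <- reach$mid_distance_m[sr]
  } else {
    sr <- subreach_of(pos, reach)
    depth <- mean(reach$depth_cm[sr])
    complex <- mean(reach$complexity[sr])
    distance <- mean(pmin(pos, total - pos))
  }
  data.frame(cond = fulton_condition(fish$length_mm, fish$weight_g),
             depth = depth, distance = distance, complex = complex,
             tag_burden = fish$tag_weight_g / fish$weight_g)
}

#' Covariate table for a registry
#'
#' Applies [fish_covariates()] to every fish, alongside length and weight.
#'
#' @param registry Fish registry.
#' @param tracking Tracking records.
#' @param reach A [reach_table()].
#' @return Data frame, one row per registry row.
#' @export
covariate_table <- function(registry, tracking, reach) {
  det <- tracking[tracking$detected, , drop = FALSE]
  split_det <- split(det, factor(det$fish_id, levels = registry$fish_id))
  rows <- lapply(seq_len(nrow(registry)), function(i) {
    cv <- suppressWarnings(
      fish_covariates(registry[i, , drop = FALSE], split_det[[i]], reach))
    cv
  })
  out <- do.call(rbind, rows)
  out$length <- registry$length_mm
  out$weight <- registry$weight_g
  rownames(out) <- registry$fish_id
  out
}
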