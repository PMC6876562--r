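#' Field-formula crown area
#'
#' Ground crews estimate crown area from two tape-measured diameters
#' assuming a circular outline: `pi * ((d1 + d2) / 4)^2`, where `d1` is the
#' widest horizontal length of the canopy through its center and `d2` the
#' width perpendicular to it. Symmetric in its arguments.
#'
#' @param d1,d2 Crown diameters (m), both > 0.
#' @return Area in m^2.
#' @export
#' @examples
#' field_crown_area(1.2, 0.8)  # pi * 0.25
field_crown_area <- function(d1, d2) {
  if (any(d1 <= 0) || any(d2 <= 0))
    stop2("olivecloud_domain", "crown diameters must be > 0")
  pi * ((d1 + d2) / 4)^2
}

#' Field-formula crown volume
#'
#' Cone-shaped crown assumption: volume is the field crown area times the
#' measured canopy height over three. For equal diameters `d` this gives
#' `pi * d^2 * h / 12` exactly.
#'
#' @param area Field crown area (m^2), >= 0.
#' @param height Measured canopy height (m), >= 0.
#' @return Volume in m^3.
#' @export
field_crown_volume <- function(area, height) {
  if (any(area < 0) || any(height < 0))
    stop2("olivecloud_domain", "area and height must be >= 0")
  area * height / 3
}

#' Estimation bias
#'
#' Relative difference between the mean estimated and mean observed values,
#' as a percentage: `(ym - xm) / xm * 100`. Negative values indicate that
#' the automatic estimate underestimates the field truth (the usual
#' direction for photogrammetric canopy traits, since thin apexes and inner
#' branches reconstruct poorly).
#'
#' @param estimated_mean Mean of the estimated values (`ym`).
#' @param observed_mean Mean of the observed values (`xm`), non-zero.
#' @return Bias in percent (unrounded; round to 1 decimal for reporting).
#' @export
#' @examples
#' round(bias_percent(2.29, 2.51), 1)  # -8.8
bias_percent <- function(estimated_mean, observed_mean) {
  if (observed_mean == 0)
    stop2("olivecloud_domain", "observed mean must be non-zero")
  (estimated_mean - observed_mean) / observed_mean * 100
}

#' Agreement statistics between estimated and observed values
#'
#' Ordinary least squares of `estimated ~ observed` supplies the coefficient
#' of determination (R^2), slope and intercept. RMSE defaults to the
#' residuals about the 1:1 identity line (`estimated - observed`), the
#' quantity of interest when the estimator is meant to reproduce the
#' measurement, and nRMSE normalizes it by the mean of the observed values
#' (in percent). Set `rmse_about = "fit"` for the residual standard error
#' about the regression line instead (used for terrain-model comparison,
#' where a constant vertical datum offset should land in the intercept).
#'
#' @param observed,estimated Equal-length numeric vectors, `n >= 3`.
#' @param rmse_about `"identity"` (default) or `"fit"`.
#' @return A `regression_stats` object: list with `r_squared`, `rmse`,
#'   `nrmse`, `n`, `slope`, `intercept`.
#' @export
#' @examples
#' regression_stats(c(1, 2, 3), c(1.1, 1.9, 3.2))
regression_stats <- function(observed, estimated,
                             rmse_about = c("identity", "fit")) {
  rmse_about <- match.arg(rmse_about)
  if (length(observed) != length(estimated))
    stop2("olivecloud_invalid", "observed and estimated lengths differ")
  n <- length(observed)
  if (n < 3L)
    stop2("olivecloud_insufficient", "need at least 3 paired values")
  if (stats::var(observed) > 0) {
    # closed-form simple OLS (quiet on degenerate perfect fits)
    slope <- stats::cov(observed, estimated) / stats::var(observed)
    intercept <- mean(estimated) - slope * mean(observed)
    res_fit <- estimated - (intercept + slope * observed)
    sst <- sum((estimated - mean(estimated))^2)
    r2 <- if (sst > 0) 1 - sum(res_fit^2) / sst else 1
  } else {
    # degenerate reference (all observed equal): fall back to a flat fit
    slope <- 0; intercept <- mean(estimated); r2 <- NA_real_
    res_fit <- estimated - mean(estimated)
  }
  res <- if (rmse_about == "identity") estimated - observed else res_fit
  rmse <- sqrt(mean(res^2))
  nrmse <- if (mean(observed) != 0) rmse / mean(observed) * 100 else NA_real_
  structure(list(r_squared = r2, rmse = rmse, nrmse = nrmse, n = n,
                 slope = slope, intercept = intercept),
            class = "regression_stats")
}

#' @export
print.regression_stats <- function(x, ...) {
  cat(sprintf("<regression_stats> n = %d, R^2 = %s, RMSE = %.4f, nRMSE = %s%%\n",
              x$n,
              if (is.na(x$r_squared)) "NA" else sprintf("%.3f", x$r_squared),
              x$rmse,
              if (is.na(x$nrmse)) "NA" else sprintf("%.1f", x$nrmse)))
  cat(sprintf("  fit: estimated = %.3f + %.3f * observed\n",
              x$intercept, x$slope))
  invisible(x)
}

#' Summary statistics for a trait
#'
#' Minimum, maximum, range, mean, and sample (n - 1) standard deviation, the
#' summary reported per campaign and training system in field trials. For a
#' single value the standard deviation is 0 by convention.
#'
#' @param values Non-empty numeric vector.
#' @return A `summary_stats` object: list with `minimum`, `maximum`,
#'   `range`, `average`, `standard_deviation`, `n`.
#' @export
#' @examples
#' summary_stats(c(1.15, 3.25))  # range 2.10
summary_stats <- function(values) {
  if (length(values) == 0L || !is.numeric(values))
    stop2("olivecloud_invalid", "values must be a non-empty numeric vector")
  s <- if (length(values) > 1L) stats::sd(values) else 0
  structure(list(minimum = min(values), maximum = max(values),
                 range = max(values) - min(values), average = mean(values),
                 standard_deviation = s, n = length(values)),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> n = %d: min %.2f, max %.2f, range %.2f, mean %.2f, sd %.2f\n",
              x$n, x$minimum, x$maximum, x$range, x$average,
              x$standard_deviation))
  invisible(x)
}

#' Pair detected trees with field-measured trees
#'
#' Pairs each detected tree record with a field measurement, by `tree_id`
#' when the two tables share ids, otherwise by one-to-one nearest-neighbor
#' matching of positions within `max_distance` (greedy on increasing
#' distance, so each tree is used at most once). Field tables carry
#' `tree_id`, measured height and the two crown diameters.
#'
#' @param records A `tree_records` data frame ([characterize_trees()]).
#' @param field Data frame of field measurements with `tree_id` and, for
#'   position matching, `x`, `y`.
#' @param max_distance Maximum pairing distance (m) for position matching.
#' @return List with `pairs` (merged data frame), `unmatched_records`,
#'   `unmatched_field` (tree id vectors).
#' @export
match_trees <- function(records, field, max_distance = 2) {
  if (nrow(records) == 0L || nrow(field) == 0L)
    stop2("olivecloud_invalid", "records and field must be non-empty")
  shared <- intersect(records$tree_id, field$tree_id)
  if (length(shared) > 0) {
    pairs <- merge(as.data.frame(records), field, by = "tree_id",
                   suffixes = c("", "_field"))
    pairs <- pairs[order(pairs$tree_id), , drop = FALSE]
    return(list(pairs = pairs,
                unmatched_records = setdiff(records$tree_id, shared),
                unmatched_field = setdiff(field$tree_id, shared)))
  }
  if (!all(c("x", "y") %in% names(field)))
    stop2("olivecloud_invalid",
          "no shared tree ids and field table has no x, y positions")
  d <- outer(records$x, field$x, "-")^2 + outer(records$y, field$y, "-")^2
  cand <- which(d <= max_distance^2, arr.ind = TRUE)
  cand <- cand[order(d[cand]), , drop = FALSE]
  used_r <- logical(nrow(records)); used_f <- logical(nrow(field))
  take <- matrix(0L, 0, 2)
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (!used_r[i] && !used_f[j]) {
      used_r[i] <- TRUE; used_f[j] <- TRUE
      take <- rbind(take, c(i, j))
    }
  }
  pairs <- if (nrow(take) > 0)
    cbind(as.data.frame(records)[take[, 1], , drop = FALSE],
          setNames(field[take[, 2], setdiff(names(field), c("x", "y")),
                         drop = FALSE],
                   paste0(setdiff(names(field), c("x", "y")), "_field")))
  else records[0, ]
  list(pairs = pairs,
       unmatched_records = records$tree_id[!used_r],
       unmatched_field = field$tree_id[!used_f])
}

#' Validation report for a trait table
#'
#' Convenience wrapper: pairs detected records with field measurements
#' ([match_trees()]), derives field crown area and volume from the measured
#' diameters (Eq.-style circle/cone formulas), and computes per-trait
#' agreement statistics, bias and summaries.
#'
#' @param records A `tree_records` data frame.
#' @param field Field table with `tree_id`, `height_m` and optionally
#'   `d1_m`, `d2_m`.
#' @param max_distance Pairing distance for position matching (m).
#' @return List with `pairs`, `n_matched`, and per-trait entries (`height`,
#'   `area`, `volume`) each holding `stats` ([regression_stats()]), `bias`
#'   and `summary` of observed/estimated.
#' @export
validate_traits <- function(records, field, max_distance = 2) {
  m <- match_trees(records, field, max_distance)
  p <- m$pairs
  out <- list(pairs = p, n_matched = nrow(p),
              unmatched_records = m$unmatched_records,
              unmatched_field = m$unmatched_field)
  fld <- function(nm) p[[paste0(nm, "_field")]] %||% p[[nm]]
  if (!is.null(p$height_m) && nrow(p) >= 3) {
    obs <- fld("height_m")
    out$height <- list(stats = regression_stats(obs, p$height_m),
                       bias = bias_percent(mean(p$height_m), mean(obs)),
                       observed = summary_stats(obs),
                       estimated = summary_stats(p$height_m))
  }
  if (all(c("d1_m", "d2_m") %in% names(p)) && nrow(p) >= 3) {
    fa <- field_crown_area(p$d1_m, p$d2_m)
    fv <- field_crown_volume(fa, fld("height_m"))
    out$area <- list(stats = regression_stats(fa, p$area_m2),
                     bias = bias_percent(mean(p$area_m2), mean(fa)))
    out$volume <- list(stats = regression_stats(fv, p$volume_m3),
                       bias = bias_percent(mean(p$volume_m3), mean(fv)))
  }
  out
}
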