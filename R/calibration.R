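#' Weighted least squares line fit
#'
#' Minimises \eqn{\sum_i w_i (y_i - a - b x_i)^2} by the weighted normal
#' equations; the coefficient of determination is
#' \eqn{R^2 = 1 - \mathrm{wRSS}/\mathrm{wTSS}} with the total sum of squares
#' taken about the weighted mean of `y`, clipped to [0, 1]. In the emission
#' calibration the weights are the square root of the observed load.
#'
#' @param x explanatory values (load proxy).
#' @param y response values (observed loads, ng/s).
#' @param w positive weights; defaults to `sqrt(y)`.
#' @return list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
wls_fit <- function(x, y, w = sqrt(y)) {
  ok <- is.finite(x) & is.finite(y) & is.finite(w)
  x <- x[ok]; y <- y[ok]; w <- w[ok]
  if (length(x) < 3L) stop("wls_fit needs at least 3 points")
  if (any(w <= 0)) stop("weights must be positive")
  sw <- sum(w)
  xb <- sum(w * x) / sw
  yb <- sum(w * y) / sw
  sxx <- sum(w * (x - xb)^2)
  if (sxx <= 0) stop("degenerate proxy: zero variance in x")
  sxy <- sum(w * (x - xb) * (y - yb))
  slope <- sxy / sxx
  intercept <- yb - slope * xb
  tss <- sum(w * (y - yb)^2)
  r2 <- if (tss > 0) 1 - sum(w * (y - intercept - slope * x)^2) / tss else 0
  list(slope = slope, intercept = intercept,
       r_squared = min(max(r2, 0), 1), n = length(x))
}

#' Default DT50 grid (days)
#'
#' The nine dissipation half-lives at which load proxies are evaluated.
#' @export
dt50_grid_default <- function() c(1, 3, 5, 7, 10, 20, 50, 100, 1000)

#' Build the grid of load proxies
#'
#' One load proxy per (emission pattern, DT50) combination: the decayed
#' catchment accumulation of the pattern field ([accumulate_decayed()]).
#' Proxies carry the pattern's own units (persons, km2, ...), so the slope of
#' a load-vs-proxy regression is an emission factor in ng/s per pattern unit.
#' The four standard patterns with the nine-value grid give 36 proxies; an
#' optional uniform pattern `"U"` (catchment area alone) can be added.
#'
#' @param network a [stream_network] with pattern columns filled.
#' @param patterns pattern column names; default the network's registered
#'   patterns.
#' @param dt50_grid half-lives in days, default [dt50_grid_default()].
#' @param include_uniform add pattern `"U"` = local area (km2)?
#' @return A `proxy_grid`: numeric matrix (reaches x proxies) with
#'   `rownames` = reach ids and a `grid` attribute, a data.frame with one row
#'   per proxy (`pattern`, `dt50`, `column`).
#' @export
build_proxy_grid <- function(network, patterns = network$patterns,
                             dt50_grid = dt50_grid_default(),
                             include_uniform = FALSE) {
  stopifnot(inherits(network, "stream_network"), length(dt50_grid) >= 1)
  unknown <- setdiff(patterns, names(network$reaches))
  if (length(unknown))
    stop("unknown pattern(s): ", paste(unknown, collapse = ", "))
  fields <- lapply(patterns, function(p) as.numeric(network$reaches[[p]]))
  names(fields) <- patterns
  if (include_uniform) fields$U <- unname(local_area(network))
  grid <- expand.grid(pattern = names(fields), dt50 = dt50_grid,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$pattern, names(fields)), grid$dt50), ]
  grid$column <- paste0(grid$pattern, "_dt", grid$dt50)
  mat <- vapply(seq_len(nrow(grid)), function(i)
    unname(accumulate_decayed(network, fields[[grid$pattern[i]]],
                              grid$dt50[i])),
    numeric(nrow(network$reaches)))
  colnames(mat) <- grid$column
  rownames(mat) <- network$reaches$reach_id
  structure(mat, grid = grid[, c("pattern", "dt50", "column")],
            class = c("proxy_grid", "matrix", "array"))
}

# distance from the ideal point (R^2 = 1, intercept = 0) in the
# intercept/R^2 plane; the intercept axis is made dimensionless by a
# normaliser (mean observed load by default)
.ideal_distance <- function(r2, intercept, norm) {
  sqrt((1 - r2)^2 + (intercept / norm)^2)
}

#' Grid calibration of emission factors
#'
#' Fits, by weighted least squares with weights `sqrt(load)`, the observed
#' loads against every load proxy of the grid, then selects the proxy whose
#' fit is closest to the ideal point (R^2 = 100%, intercept = 0) in the
#' normalised intercept/R^2 plane:
#' \deqn{d = \sqrt{(1 - R^2)^2 + (b_0/\bar y)^2}.}
#' Ties are broken by higher R^2, then smaller DT50. The slope of the
#' selected fit is the emission factor estimate; its intercept is ignored
#' when emissions are computed.
#'
#' @param proxies a `proxy_grid` from [build_proxy_grid()].
#' @param observed_loads data.frame with `reach_id` and `load_ng_s` (one row
#'   per record; records at the same station are not averaged). Zero loads
#'   are dropped (their weight is undefined).
#' @param normalizer `"mean_load"` (default) or `"sd_load"`: the scale that
#'   makes the intercept axis dimensionless.
#' @param assumed_pattern optional pattern assumed a priori for the
#'   substance (e.g. population for urban chemicals, agricultural land for
#'   pesticides). When given, the modelled DT50 and the emission factor are
#'   read from the ideal-point-best fit *within that pattern*, while the
#'   best pattern overall is still reported (`best_pattern`); when `NULL`
#'   (default) the selection is free across all proxies.
#' @return A `calibration_result`: list with `fits` (data.frame of ProxyFit
#'   rows: pattern, dt50, slope, intercept, r_squared, distance, n),
#'   `selected` (row index of the selected fit), `best_pattern` (pattern of
#'   the overall ideal-point optimum), `modelled_dt50`, `selected_dt50`,
#'   `pattern`, `emission_factor`, `n_points`.
#' @export
grid_calibrate <- function(proxies, observed_loads,
                           normalizer = c("mean_load", "sd_load"),
                           assumed_pattern = NULL) {
  normalizer <- match.arg(normalizer)
  stopifnot(inherits(proxies, "proxy_grid"),
            all(c("reach_id", "load_ng_s") %in% names(observed_loads)))
  grid <- attr(proxies, "grid")
  obs <- observed_loads[is.finite(observed_loads$load_ng_s) &
                          observed_loads$load_ng_s > 0, , drop = FALSE]
  idx <- match(as.character(obs$reach_id), rownames(proxies))
  if (anyNA(idx))
    stop("observed load on reach '",
         obs$reach_id[which(is.na(idx))[1]], "' absent from proxy grid")
  y <- obs$load_ng_s
  if (length(y) < 3L)
    stop("fewer than 3 usable (positive-load) observations")
  w <- sqrt(y)
  norm <- if (normalizer == "mean_load") mean(y) else stats::sd(y)
  if (!is.finite(norm) || norm <= 0) stop("degenerate observed loads")

  fits <- lapply(seq_len(nrow(grid)), function(i) {
    f <- wls_fit(proxies[idx, grid$column[i]], y, w)
    data.frame(pattern = grid$pattern[i], dt50 = grid$dt50[i],
               slope = f$slope, intercept = f$intercept,
               r_squared = f$r_squared,
               distance = .ideal_distance(f$r_squared, f$intercept, norm),
               n = f$n)
  })
  fits <- do.call(rbind, fits)
  # minimal distance; ties -> higher r2, then smaller dt50
  best <- order(fits$distance, -fits$r_squared, fits$dt50)[1L]
  if (is.null(assumed_pattern)) {
    sel <- best
  } else {
    if (!assumed_pattern %in% fits$pattern)
      stop("assumed pattern '", assumed_pattern, "' is not on the grid")
    cand <- which(fits$pattern == assumed_pattern)
    sel <- cand[order(fits$distance[cand], -fits$r_squared[cand],
                      fits$dt50[cand])[1L]]
  }
  structure(list(fits = fits, selected = sel,
                 best_pattern = fits$pattern[best],
                 pattern = fits$pattern[sel],
                 modelled_dt50 = fits$dt50[sel],
                 selected_dt50 = fits$dt50[sel],
                 emission_factor = fits$slope[sel],
                 normalizer = norm, n_points = fits$n[sel],
                 observed_loads = obs[, c("reach_id", "load_ng_s")]),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  f <- x$fits[x$selected, ]
  cat("<calibration_result>\n",
      "  selected proxy : ", x$pattern, " @ DT50 = ", x$selected_dt50,
      " d (modelled ", x$modelled_dt50, " d)\n",
      "  emission factor: ", format(x$emission_factor, digits = 6),
      " ng/s per unit of '", x$pattern, "'\n",
      "  R^2 = ", round(f$r_squared, 4), ", intercept = ",
      format(f$intercept, digits = 4), " ng/s, distance = ",
      format(f$distance, digits = 4), ", n = ", f$n, "\n", sep = "")
  invisible(x)
}

#' Explained-variance class used in reporting
#'
#' `"high"` if R^2 >= 0.6, `"medium"` if R^2 > 0.4, `"low"` otherwise.
#' @param r2 numeric vector of R^2 values.
#' @return character vector of classes.
#' @export
r2_class <- function(r2) {
  ifelse(r2 >= 0.6, "high", ifelse(r2 > 0.4, "medium", "low"))
}

#' Bootstrap uncertainty of a weighted line fit
#'
#' Resamples load records with replacement (record level: every
#' concentration-discharge record is one unit of the statistical population),
#' refits the weighted least squares line each time, and returns percentile
#' confidence intervals for slope and intercept. Degenerate resamples (zero
#' proxy variance) are redrawn and counted.
#'
#' @param x proxy values, one per record.
#' @param y observed loads, one per record (positive).
#' @param n_boot number of bootstrap iterations (default 1000).
#' @param seed integer seed; same seed, same intervals.
#' @param level confidence level (default 0.95 -> 2.5/97.5 percentiles).
#' @return list with `slope_ci`, `intercept_ci` (length-2 vectors),
#'   `slope_boot`, `intercept_boot` (the resampled estimates), `n_redrawn`.
#' @export
bootstrap_uncertainty <- function(x, y, n_boot = 1000, seed = 1L,
                                  level = 0.95) {
  stopifnot(length(x) == length(y), n_boot >= 2)
  n <- length(x)
  slopes <- numeric(n_boot)
  intercepts <- numeric(n_boot)
  n_redrawn <- 0L
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        i <- sample.int(n, n, replace = TRUE)
        f <- tryCatch(wls_fit(x[i], y[i], sqrt(y[i])), error = function(e) NULL)
        if (!is.null(f)) break
        n_redrawn <- n_redrawn + 1L
      }
      slopes[b] <- f$slope
      intercepts[b] <- f$intercept
    }
  })
  a <- (1 - level) / 2
  list(slope_ci = unname(stats::quantile(slopes, c(a, 1 - a))),
       intercept_ci = unname(stats::quantile(intercepts, c(a, 1 - a))),
       slope_boot = slopes, intercept_boot = intercepts,
       n_redrawn = n_redrawn)
}

#' Override the modelled DT50 with an expert-judgment value
#'
#' When the statistically optimal DT50 is physically implausible, a more
#' realistic grid value may be assigned ad hoc; the emission factor is then
#' re-read as the slope of the same-pattern fit at the override DT50, and
#' the drop in explained variance relative to the modelled optimum is
#' reported so the caller can check the fit did not deteriorate
#' significantly. Both the modelled and the selected DT50 are retained.
#'
#' @param result a `calibration_result`.
#' @param override_dt50 a value of the DT50 grid.
#' @return The updated `calibration_result`, with `selected_dt50`,
#'   `emission_factor` replaced and an `r2_drop` field added.
#' @export
apply_dt50_override <- function(result, override_dt50) {
  stopifnot(inherits(result, "calibration_result"))
  fits <- result$fits
  row <- which(fits$pattern == result$pattern & fits$dt50 == override_dt50)
  if (!length(row))
    stop("override DT50 ", override_dt50, " is not on the calibration grid ",
         "for pattern '", result$pattern, "'")
  result$selected_dt50 <- override_dt50
  result$emission_factor <- fits$slope[row]
  result$r2_drop <- fits$r_squared[result$selected] - fits$r_squared[row]
  result$selected_override <- row
  result
}
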