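#' Percentile comparison of modelled and observed concentrations
#'
#' Because emission factors are uniform scaling constants, modelled
#' concentrations cannot be compared with observations pointwise, only as
#' frequency distributions. This compares the 10th/50th/90th percentiles of
#' the modelled concentration population against those of the observed
#' records, restricting the modelled population to stream segments in the
#' same drainage-area range as the segments carrying observations.
#'
#' @param modelled per-reach modelled concentrations (ug/L), reach-table
#'   order.
#' @param network a [stream_network] (supplies drainage areas).
#' @param observed data.frame with `reach_id` and `concentration_ug_L`, one
#'   row per record.
#' @param probs percentiles to compare, default `c(0.1, 0.5, 0.9)`.
#' @return data.frame with columns `prob`, `modelled`, `observed`, `ratio`
#'   (= modelled/observed), plus attribute `n` = c(modelled, observed).
#' @export
percentile_comparison <- function(modelled, network, observed,
                                  probs = c(0.1, 0.5, 0.9)) {
  stopifnot(inherits(network, "stream_network"))
  r <- network$reaches
  if (!nrow(observed)) stop("no observations to compare against")
  idx <- match(as.character(observed$reach_id), r$reach_id)
  if (anyNA(idx)) stop("observation on unknown reach")
  a_rng <- range(r$drainage_area_km2[unique(idx)])
  keep <- r$drainage_area_km2 >= a_rng[1] & r$drainage_area_km2 <= a_rng[2] &
    is.finite(modelled)
  if (!any(keep)) stop("no modelled reaches in the observed area range")
  oc <- observed$concentration_ug_L
  oc <- oc[is.finite(oc)]
  if (!length(oc)) stop("no usable observed concentrations")
  qm <- stats::quantile(modelled[keep], probs, names = FALSE)
  qo <- stats::quantile(oc, probs, names = FALSE)
  out <- data.frame(prob = probs, modelled = qm, observed = qo,
                    ratio = qm / qo)
  attr(out, "n") <- c(modelled = sum(keep), observed = length(oc))
  out
}

#' Prediction-rate (ROC) curve of exceedances against concentration
#'
#' Sorts sub-basins by decreasing concentration and accumulates the fraction
#' of reported quality-standard exceedances captured along the sorted list.
#' A curve above the 1:1 line means concentration predicts exceedances
#' better than a random draw. Sub-basins with identical concentration form
#' one tie block whose exceedances accrue proportionally across the block
#' (average-rank treatment), so the curve does not depend on input order;
#' with all concentrations tied the curve is the diagonal by construction.
#'
#' The area under the curve is reported as the standard rank-based ROC AUC
#' (probability that a flagged sub-basin has higher concentration than an
#' unflagged one, ties counting one half): 1 for a perfect predictor, 0.5
#' under independence. Prediction rates at fixed fractions (10/20/50% by
#' default) are linear interpolations of the cumulative curve.
#'
#' @param conc concentration per sub-basin (one value each).
#' @param flags logical/0-1 exceedance flag per sub-basin.
#' @param rate_fractions fractions at which prediction rates are read off.
#' @return A `prediction_rate_curve`: list with `curve` (data.frame
#'   `fraction`, `cumulative`, vertices from (0,0) to (1,1)), `rates` (named
#'   vector), `auc`, `n`, `n_exceedances`; or a no-curve object (`curve =
#'   NULL`, `n_exceedances = 0`) when there are no flagged sub-basins.
#' @export
prediction_rate_curve <- function(conc, flags,
                                  rate_fractions = c(0.1, 0.2, 0.5)) {
  stopifnot(length(conc) == length(flags))
  ok <- is.finite(conc) & !is.na(flags)
  conc <- conc[ok]; flags <- as.logical(flags[ok])
  n <- length(conc)
  E <- sum(flags)
  if (E == 0L || n == 0L)
    return(structure(list(curve = NULL, rates = NULL, auc = NA_real_,
                          n = n, n_exceedances = 0L),
                     class = "prediction_rate_curve"))
  o <- order(conc, decreasing = TRUE)
  cs <- conc[o]; fs <- flags[o]
  # tie blocks: runs of equal concentration
  block <- cumsum(c(TRUE, cs[-1] != cs[-n]))
  nb <- tabulate(block)                       # sub-basins per block
  eb <- as.numeric(tapply(fs, block, sum))    # exceedances per block
  xv <- cumsum(nb) / n
  yv <- cumsum(eb) / E
  curve <- data.frame(fraction = c(0, xv), cumulative = c(0, yv))
  rates <- stats::approx(curve$fraction, curve$cumulative,
                         xout = rate_fractions, rule = 2)$y
  names(rates) <- paste0("rate_", rate_fractions * 100)
  # rank AUC (Mann-Whitney with midranks); 0.5 if one class is absent
  auc <- if (E < n) {
    rk <- rank(cs)  # ties -> midranks
    (sum(rk[fs]) - E * (E + 1) / 2) / (E * (n - E))
  } else 0.5
  structure(list(curve = curve, rates = rates, auc = auc,
                 n = n, n_exceedances = E),
            class = "prediction_rate_curve")
}

#' @export
print.prediction_rate_curve <- function(x, ...) {
  if (is.null(x$curve)) {
    cat("<prediction_rate_curve> no curve (0 exceedances among ", x$n,
        " sub-basins)\n", sep = "")
  } else {
    cat("<prediction_rate_curve> n = ", x$n, ", exceedances = ",
        x$n_exceedances, ", AUC = ", round(x$auc, 3), "\n  rates: ",
        paste(names(x$rates), "=", round(100 * x$rates, 1), "%",
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Prediction-rate curve for observed concentrations
#'
#' Same construction as [prediction_rate_curve()] but restricted to the
#' sub-basins that actually carry an observed concentration; exceedances
#' reported in unmonitored sub-basins are dropped from the cumulate, so the
#' number of exceedances used may be much smaller than the total and may be
#' zero, in which case no curve is drawn.
#'
#' @param observed data.frame `reach_id`, `concentration_ug_L`; multiple
#'   records per sub-basin are reduced to their mean concentration.
#' @param flags named logical vector (reach id -> exceedance flag) or a
#'   data.frame `reach_id`, `flag`.
#' @inheritParams prediction_rate_curve
#' @return A `prediction_rate_curve` (possibly the no-curve object).
#' @export
observed_concentration_roc <- function(observed, flags,
                                       rate_fractions = c(0.1, 0.2, 0.5)) {
  if (is.data.frame(flags))
    flags <- stats::setNames(as.logical(flags$flag),
                             as.character(flags$reach_id))
  agg <- tapply(observed$concentration_ug_L,
                as.character(observed$reach_id), mean)
  ids <- names(agg)
  fl <- flags[ids]
  fl[is.na(fl)] <- FALSE
  prediction_rate_curve(as.numeric(agg), fl, rate_fractions)
}

#' Qualitative prediction-performance label
#'
#' Maps a prediction rate at a reference fraction to a high/medium/low
#' label. Defaults: high if the rate is at least 3x the fraction
#' considered, medium if above 1.5x, low otherwise (a rate equal to the
#' fraction is what a random ranking achieves).
#'
#' @param rate prediction rate in [0,1] at `fraction`.
#' @param fraction fraction of sub-basins considered.
#' @param thresholds multipliers of `fraction` separating low/medium/high.
#' @return character label.
#' @export
performance_label <- function(rate, fraction = 0.1,
                              thresholds = c(medium = 1.5, high = 3)) {
  ifelse(rate >= thresholds[["high"]] * fraction, "H",
         ifelse(rate >= thresholds[["medium"]] * fraction, "M", "L"))
}
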