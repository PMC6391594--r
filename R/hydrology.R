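#' Budyko annual water balance
#'
#' Annual actual evapotranspiration from precipitation and potential
#' evapotranspiration by the classic Budyko curve,
#' \deqn{\mathrm{AET}/P = \sqrt{\varphi\,\tanh(1/\varphi)\,(1 - e^{-\varphi})},
#'   \qquad \varphi = \mathrm{PET}/P,}
#' and annual runoff as `P - AET`. Runoff is bounded in `[0, P]`; `P = 0`
#' gives zero runoff, `PET = 0` gives runoff `P` (energy-unlimited limit),
#' and runoff tends to 0 as the aridity index grows (water-limited limit).
#'
#' @param P annual precipitation, mm/y (>= 0), vectorised.
#' @param PET annual potential evapotranspiration, mm/y (>= 0).
#' @return Annual runoff, mm/y.
#' @export
budyko_runoff <- function(P, PET) {
  if (any(P < 0, na.rm = TRUE) || any(PET < 0, na.rm = TRUE))
    stop("P and PET must be nonnegative")
  n <- max(length(P), length(PET))
  P <- rep_len(P, n); PET <- rep_len(PET, n)
  runoff <- numeric(n)
  pos <- P > 0
  phi <- PET[pos] / P[pos]
  aet_ratio <- ifelse(phi == 0, 0,
                      sqrt(phi * tanh(1 / phi) * (1 - exp(-phi))))
  runoff[pos] <- P[pos] * (1 - pmin(aet_ratio, 1))
  pmin(pmax(runoff, 0), P)
}

#' Accumulate annual-average discharge along the network
#'
#' Converts per-reach annual runoff to a local volume
#' (`mm/y * km2 -> m3/s`, 1 mm km2/y = 1e3 m3/y) on the reach's local
#' (incremental) area, then accumulates it downstream without decay (the
#' `dt50 = Inf` path of [accumulate_decayed()]), so discharge is conserved at
#' every confluence and nondecreasing downstream.
#'
#' @param network a [stream_network].
#' @param runoff_mm per-reach annual runoff, mm/y. If `NULL`, the reach
#'   table's `local_runoff_m3s` column is accumulated directly; failing that,
#'   runoff is computed from `precip_mm`/`pet_mm` via [budyko_runoff()].
#' @return Named numeric vector Q (m3/s) per reach.
#' @export
accumulate_discharge <- function(network, runoff_mm = NULL) {
  stopifnot(inherits(network, "stream_network"))
  r <- network$reaches
  if (!is.null(runoff_mm)) {
    local_q <- runoff_mm * unname(local_area(network)) *
      unit_constants[["mmkm2y_to_m3s"]]
  } else if ("local_runoff_m3s" %in% names(r)) {
    local_q <- as.numeric(r$local_runoff_m3s)
  } else if (all(c("precip_mm", "pet_mm") %in% names(r))) {
    local_q <- budyko_runoff(r$precip_mm, r$pet_mm) *
      unname(local_area(network)) * unit_constants[["mmkm2y_to_m3s"]]
  } else {
    stop("no runoff information: supply runoff_mm, a local_runoff_m3s ",
         "column, or precip_mm/pet_mm columns")
  }
  accumulate_decayed(network, local_q, Inf)
}

#' Convert loads to concentrations
#'
#' `C [ug/L] = load [ng/s] / Q [m3/s] * 1e-6`, the inverse of the observed
#' load construction. Loads are assumed stationary, so with annual-average
#' flow these are annual-average concentrations. Reaches with zero flow get
#' `NA` (flagged, no value).
#'
#' @param load per-reach load, ng/s.
#' @param Q per-reach discharge, m3/s (>= 0).
#' @return Concentrations, ug/L.
#' @export
concentration <- function(load, Q) {
  if (any(Q < 0, na.rm = TRUE)) stop("negative discharge")
  out <- ifelse(Q > 0, load / Q * unit_constants[["ugL_per_ngs_m3s"]],
                NA_real_)
  out
}
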