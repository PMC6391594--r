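#' Unit conversion constants
#'
#' Fixed conversion constants used throughout the package. Internally all
#' loads are ng/s, concentrations ug/L and discharges m3/s; reports use kg/y
#' (emissions, loads) and tonnes/y (sea loads).
#'
#' * 1 year = 3.15576e7 s (365.25 d)
#' * 1 ng/s = 3.15576e-5 kg/y
#' * 1 ug/L = 1e6 ng/s per m3/s of flow
#' * 1 mm/y of runoff on 1 km2 = 1e3 m3/y
#'
#' @format Named numeric vector.
#' @export
unit_constants <- c(
  seconds_per_year = 3.15576e7,
  ngs_to_kgy       = 3.15576e-5,   # ng/s -> kg/y
  kgy_to_tonnesy   = 1e-3,
  ugL_per_ngs_m3s  = 1e-6,         # (ng/s) / (m3/s) -> ug/L
  mmkm2y_to_m3s    = 1e3 / 3.15576e7  # mm/y * km2 -> m3/s
)
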