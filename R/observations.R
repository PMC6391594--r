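#' Build observed loads from concentration and discharge records
#'
#' Each monitoring record (station, reach, date, dissolved-phase
#' concentration, discharge) yields one "observed load",
#' `load_ng_s = concentration_ug_L * discharge_m3s * 1e6`. Loads are never
#' averaged per station: every record is one member of a single statistical
#' population for the calibration.
#'
#' @param records data.frame with columns `concentration_ug_L` and
#'   `discharge_m3s`; optional `station_id`, `reach_id`, `date`, `substance`,
#'   `below_loq` (0/1) and `loq_ug_L`.
#' @param loq_action treatment of below-LOQ records: `"exclude"` (default,
#'   calibration uses quantifiable observations only), `"half"` (substitute
#'   LOQ/2, requires `loq_ug_L`), or `"zero"`.
#' @return data.frame of usable records with a `load_ng_s` column. Records
#'   with nonpositive discharge are skipped with a warning. Attribute
#'   `counts` reports `c(usable, skipped, censored)`; the three always sum to
#'   the input row count (censored counts below-LOQ rows removed under
#'   `"exclude"`).
#' @export
compute_observed_loads <- function(records,
                                   loq_action = c("exclude", "half", "zero")) {
  loq_action <- match.arg(loq_action)
  stopifnot(is.data.frame(records),
            all(c("concentration_ug_L", "discharge_m3s") %in% names(records)))
  n_in <- nrow(records)
  bad_q <- !is.finite(records$discharge_m3s) | records$discharge_m3s <= 0
  if (any(bad_q))
    warning(sum(bad_q), " record(s) with nonpositive discharge skipped")
  records <- records[!bad_q, , drop = FALSE]
  if (any(records$concentration_ug_L < 0, na.rm = TRUE))
    stop("negative concentration in records")

  censored <- 0L
  loq <- if ("below_loq" %in% names(records)) records$below_loq %in% c(1, TRUE)
         else rep(FALSE, nrow(records))
  if (loq_action == "exclude") {
    censored <- sum(loq)
    records <- records[!loq, , drop = FALSE]
  } else if (loq_action == "half") {
    if (any(loq) && !"loq_ug_L" %in% names(records))
      stop("loq_action = 'half' requires a loq_ug_L column")
    records$concentration_ug_L[loq] <- records$loq_ug_L[loq] / 2
  } else {
    records$concentration_ug_L[loq] <- 0
  }

  records$load_ng_s <- records$concentration_ug_L * records$discharge_m3s * 1e6
  attr(records, "counts") <- c(usable = nrow(records),
                               skipped = sum(bad_q), censored = censored)
  records
}

#' Snap monitoring stations to the nearest network reach
#'
#' Assigns each station to the reach whose representative node (columns `x`,
#' `y` of the reach table) is nearest in the Euclidean sense; exact distance
#' ties are broken in favour of the reach with the larger drainage area.
#' Networks here are topological, not geometric, so snapping uses node
#' coordinates only.
#'
#' @param stations data.frame with columns `station_id`, `x`, `y`.
#' @param network a [stream_network] whose reach table has `x`, `y` columns.
#' @return data.frame `station_id`, `reach_id`, `snap_distance`.
#' @export
snap_stations <- function(stations, network) {
  stopifnot(inherits(network, "stream_network"))
  r <- network$reaches
  if (nrow(r) == 0L) stop("empty network")
  if (!all(c("x", "y") %in% names(r)))
    stop("network has no node coordinates (columns x, y)")
  out <- lapply(seq_len(nrow(stations)), function(i) {
    d <- sqrt((r$x - stations$x[i])^2 + (r$y - stations$y[i])^2)
    cand <- which(d == min(d))
    if (length(cand) > 1L)
      cand <- cand[which.max(r$drainage_area_km2[cand])]
    data.frame(station_id = stations$station_id[i],
               reach_id = r$reach_id[cand],
               snap_distance = d[cand])
  })
  do.call(rbind, out)
}

#' Read observation records from CSV
#'
#' Columns: `station_id`, `reach_id`, `date` (ISO-8601), `substance`,
#' `concentration_ug_L`, `below_loq` (0/1), `discharge_m3s`, optionally
#' `loq_ug_L`.
#' @param path file path.
#' @return data.frame of records.
#' @export
read_observations_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(reach_id = "character"))
}
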