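#' Emission inventory by reporting district
#'
#' Diffuse emissions of a substance in a district are the sum of its
#' emission pattern over the district's reaches times the calibrated
#' emission factor; point emissions are the facility emissions located in
#' the district. No in-stream decay is applied: decay acts on loads during
#' transport, not on emissions at the source.
#'
#' @param network a [stream_network] with `district_id` and pattern columns.
#' @param substances data.frame with `substance`, `pattern` (a pattern
#'   column of the network) and `emission_factor` (ng/s per pattern unit).
#' @param point_emissions optional data.frame `substance`, `reach_id`,
#'   `emission_ng_s`.
#' @return data.frame with one row per (district, substance):
#'   `district_id`, `substance`, `diffuse_kg_y`, `point_kg_y`, `total_kg_y`.
#' @export
build_inventory <- function(network, substances, point_emissions = NULL) {
  stopifnot(inherits(network, "stream_network"),
            all(c("substance", "pattern", "emission_factor") %in%
                  names(substances)))
  r <- network$reaches
  if (!"district_id" %in% names(r)) stop("network has no district labels")
  k <- unit_constants[["ngs_to_kgy"]]
  dist <- as.character(r$district_id)
  out <- lapply(seq_len(nrow(substances)), function(i) {
    s <- substances$substance[i]
    p <- substances$pattern[i]
    ef <- substances$emission_factor[i]
    if (is.na(ef)) stop("missing emission factor for substance '", s, "'")
    if (!p %in% names(r)) stop("unknown pattern '", p, "' for substance '",
                               s, "'")
    diffuse <- tapply(as.numeric(r[[p]]) * ef * k, dist, sum)
    point <- stats::setNames(numeric(length(diffuse)), names(diffuse))
    if (!is.null(point_emissions)) {
      pe <- point_emissions[point_emissions$substance == s, , drop = FALSE]
      if (nrow(pe)) {
        idx <- match(as.character(pe$reach_id), r$reach_id)
        if (anyNA(idx)) stop("point emission on unknown reach")
        agg <- tapply(pe$emission_ng_s * k, dist[idx], sum)
        point[names(agg)] <- agg
      }
    }
    data.frame(district_id = names(diffuse), substance = s,
               diffuse_kg_y = as.numeric(diffuse),
               point_kg_y = as.numeric(point[names(diffuse)]),
               total_kg_y = as.numeric(diffuse) +
                 as.numeric(point[names(diffuse)]),
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Loads delivered to the regional seas
#'
#' Per receiving sea: the sum, over the outlet reaches labelled with that
#' sea, of the (diffuse plus point) load reaching the outlet, converted to
#' tonnes per year. Because loads decay in transit, sea loads never exceed
#' total emissions; they are equal only with an infinite half-life and zero
#' travel times.
#'
#' @param network a [stream_network]; outlets should carry `sea_id`.
#' @param loads named list (substance -> per-reach total load vector, ng/s,
#'   reach-table order), typically diffuse plus point loads.
#' @return data.frame `sea_id`, `substance`, `load_tonnes_y`. Outlets
#'   without a sea label are grouped under `"unassigned"` with a warning.
#' @export
sea_loads <- function(network, loads) {
  stopifnot(inherits(network, "stream_network"))
  r <- network$reaches
  outlet <- is.na(network$down)
  sea <- if ("sea_id" %in% names(r)) as.character(r$sea_id)
         else rep(NA_character_, nrow(r))
  if (any(outlet & (is.na(sea) | sea == ""))) {
    warning("outlet(s) without sea_id grouped under 'unassigned'")
    sea[outlet & (is.na(sea) | sea == "")] <- "unassigned"
  }
  k <- unit_constants[["ngs_to_kgy"]] * unit_constants[["kgy_to_tonnesy"]]
  out <- lapply(names(loads), function(s) {
    L <- loads[[s]][outlet]
    agg <- tapply(L * k, sea[outlet], sum)
    data.frame(sea_id = names(agg), substance = s,
               load_tonnes_y = as.numeric(agg), row.names = NULL)
  })
  do.call(rbind, out)
}
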