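#' Point-source loads along the network
#'
#' Propagates point emissions (industrial facilities located on reaches)
#' downstream with the same first-order dissipation as diffuse loads: the
#' emission field is zero everywhere except the facility reaches, and
#' [accumulate_decayed()] provides the catchment integral.
#'
#' @param network a [stream_network].
#' @param point_emissions data.frame with `reach_id` and `emission_ng_s`
#'   (>= 0); several facilities on one reach are summed. May carry a
#'   `substance` column, ignored here (filter before calling).
#' @param dt50 dissipation half-life in days, or `Inf`.
#' @return Named numeric vector of point loads (ng/s) per reach.
#' @export
point_loads <- function(network, point_emissions, dt50) {
  stopifnot(inherits(network, "stream_network"),
            all(c("reach_id", "emission_ng_s") %in% names(point_emissions)))
  if (any(point_emissions$emission_ng_s < 0)) stop("negative point emission")
  ids <- as.character(point_emissions$reach_id)
  idx <- match(ids, network$reaches$reach_id)
  if (anyNA(idx))
    stop("point emission on unknown reach '", ids[which(is.na(idx))[1]], "'")
  field <- numeric(nrow(network$reaches))
  for (k in seq_along(idx))
    field[idx[k]] <- field[idx[k]] + point_emissions$emission_ng_s[k]
  accumulate_decayed(network, field, dt50)
}

#' Point-source impact indicators Z and W
#'
#' Per reach, across substances: `Z` is the maximum ratio of point load to
#' diffuse load, and `W` counts the substances whose ratio strictly exceeds
#' the threshold (25% by default). The denominator is the diffuse load, as
#' the indicator definition writes it. Reaches with zero diffuse load and a
#' positive point load get `Z = Inf` and are flagged rather than dropped, so
#' point-source hot spots are not silently lost; zero point load over zero
#' diffuse load contributes a ratio of 0.
#'
#' @param diffuse_loads named list (substance -> per-reach diffuse load
#'   vector, ng/s).
#' @param point_loads named list (substance -> per-reach point load vector),
#'   same substances and reach count.
#' @param threshold ratio above which a substance counts into `W`.
#' @return data.frame `reach_id`, `Z`, `W`, `zero_diffuse_flag`.
#' @export
impact_indicators <- function(diffuse_loads, point_loads, threshold = 0.25) {
  if (!setequal(names(diffuse_loads), names(point_loads)))
    stop("diffuse and point load sets cover different substances")
  subs <- names(diffuse_loads)
  n <- length(diffuse_loads[[1]])
  ratio <- sapply(subs, function(s) {
    L <- diffuse_loads[[s]]; Lp <- point_loads[[s]]
    if (length(Lp) != n) stop("reach sets differ between substances")
    ifelse(L > 0, Lp / L, ifelse(Lp > 0, Inf, 0))
  })
  ratio <- matrix(ratio, nrow = n)
  Z <- apply(ratio, 1, max)
  W <- apply(ratio, 1, function(r) sum(r > threshold))
  ids <- names(diffuse_loads[[1]])
  data.frame(reach_id = if (is.null(ids)) as.character(seq_len(n)) else ids,
             Z = Z, W = as.integer(W),
             zero_diffuse_flag = is.infinite(Z))
}

#' District-level point-to-diffuse emission shares
#'
#' Sums point and diffuse emissions within each reporting district and
#' summarises, across the districts with nonzero point emissions, the
#' distribution of the point:diffuse ratio (5th, 50th, 95th percentiles) and
#' the count of districts with any point emission.
#'
#' @param network a [stream_network] with a `district_id` column.
#' @param point_emissions data.frame `substance`, `reach_id`,
#'   `emission_ng_s`.
#' @param diffuse_emissions named list (substance -> per-reach diffuse
#'   emission vector, ng/s, in reach-table order).
#' @return data.frame, one row per substance: `substance`, `p5`, `p50`,
#'   `p95` (ratios), `n_districts_positive`, `n_districts`. Substances with
#'   no point emissions get `NA` percentiles and a zero count.
#' @export
district_point_share <- function(network, point_emissions,
                                 diffuse_emissions) {
  r <- network$reaches
  if (!"district_id" %in% names(r) || all(is.na(r$district_id)))
    stop("network has no district labels")
  districts <- sort(unique(as.character(r$district_id)))
  out <- lapply(names(diffuse_emissions), function(s) {
    diff_d <- tapply(diffuse_emissions[[s]], as.character(r$district_id), sum)
    pe <- point_emissions[point_emissions$substance == s, , drop = FALSE]
    point_d <- stats::setNames(numeric(length(districts)), districts)
    if (nrow(pe)) {
      idx <- match(as.character(pe$reach_id), r$reach_id)
      if (anyNA(idx)) stop("point emission on unknown reach")
      agg <- tapply(pe$emission_ng_s, as.character(r$district_id[idx]), sum)
      point_d[names(agg)] <- agg
    }
    pos <- point_d[districts] > 0
    ratio <- point_d[districts][pos] / diff_d[districts][pos]
    q <- if (any(pos)) stats::quantile(ratio, c(0.05, 0.5, 0.95), names = FALSE)
         else rep(NA_real_, 3)
    data.frame(substance = s, p5 = q[1], p50 = q[2], p95 = q[3],
               n_districts_positive = sum(pos),
               n_districts = length(districts))
  })
  do.call(rbind, out)
}
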