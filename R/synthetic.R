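#' Synthetic scenario description
#'
#' Bundles every knob of the synthetic world: network size and shape,
#' travel-time and sub-basin-area distributions, emission-pattern
#' distributions, the true substances (pattern, emission factor, DT50, EQS
#' pair), the observation design (stations, samples, multiplicative noise,
#' LOQ censoring) and the point-source design. All generators are
#' deterministic given `seed` (Mersenne-Twister; per-stage sub-seeds are
#' derived from it so stages can be re-run independently).
#'
#' Defaults emulate the statistical structure of the pan-European inputs at
#' desk scale: a 500-reach in-tree with sub-basins of ~7 km2, per-reach
#' travel times lognormal with mean 0.2 d, lognormal spatially clustered
#' population, patchy agricultural land as a fraction of local area,
#' multiplicative lognormal noise (sigma = 0.3) on observed concentrations,
#' sparse stations weighted toward large drainage areas, sparse facilities,
#' and EQS values in the 0.1-2 ug/L range typical of priority substances.
#'
#' @param seed integer master seed.
#' @param n_reaches number of reaches (>= 1).
#' @param travel_time_mean,travel_time_sdlog lognormal per-reach travel time
#'   (days): arithmetic mean and log-sd.
#' @param area_mean_km2,area_sdlog lognormal local sub-basin area (km2).
#' @param pop_meanlog,pop_sdlog lognormal per-reach population.
#' @param urban_fraction,urban_factor fraction of reaches scaled up as
#'   "urban" clusters and their multiplier (factor 1 or fraction 0 leaves
#'   the marginal lognormal untouched).
#' @param agri_fraction_range range of the uniform fraction of local area
#'   that is agricultural.
#' @param livestock_per_km2,livestock_sdlog livestock units per km2 of
#'   agriculture and the log-sd of their multiplicative noise.
#' @param connection_rate,connection_sdlog fraction of population connected
#'   to treatment and its noise (connected population never exceeds
#'   population).
#' @param precip_range,pet_range uniform ranges for annual precipitation and
#'   potential evapotranspiration (mm/y).
#' @param substances data.frame `name`, `pattern`, `true_ef`, `true_dt50`,
#'   `eqs_aa`, `eqs_mac`.
#' @param n_stations,samples_per_station observation design.
#' @param noise_sigma log-sd of the multiplicative (median-unbiased)
#'   concentration error.
#' @param discharge_sdlog log-sd of the per-sample discharge day factor
#'   (mean-unbiased; 0 switches the day factor off).
#' @param loq_fraction fraction of lowest concentrations flagged below the
#'   limit of quantification.
#' @param n_facilities,facility_meanlog,facility_sdlog point-source design
#'   (lognormal emission magnitudes, ng/s).
#' @param include_points_in_truth add point loads to the true loads and
#'   concentrations? Default `FALSE`: calibration sites are assumed free of
#'   point-source influence.
#' @param peak_factor multiplier turning the annual-average concentration
#'   into a peak value checked against the MAC standard.
#' @param label_noise probability that an exceedance flag is flipped, to
#'   emulate reporting inconsistency.
#' @param n_districts number of reporting districts carved out of the tree.
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(seed = 1L,
                               n_reaches = 500L,
                               travel_time_mean = 0.2,
                               travel_time_sdlog = 0.8,
                               area_mean_km2 = 7,
                               area_sdlog = 0.5,
                               pop_meanlog = log(350),
                               pop_sdlog = 1.2,
                               urban_fraction = 0.05,
                               urban_factor = 20,
                               agri_fraction_range = c(0.1, 0.6),
                               livestock_per_km2 = 50,
                               livestock_sdlog = 0.4,
                               connection_rate = 0.75,
                               connection_sdlog = 0.2,
                               precip_range = c(500, 1500),
                               pet_range = c(400, 1000),
                               substances = data.frame(
                                 name = c("popchem", "agrichem"),
                                 pattern = c("pop", "agri_km2"),
                                 true_ef = c(10, 200),
                                 true_dt50 = c(10, 20),
                                 eqs_aa = c(0.2, 0.6),
                                 eqs_mac = c(1.8, 2.0)),
                               n_stations = 60L,
                               samples_per_station = 8L,
                               noise_sigma = 0.3,
                               discharge_sdlog = 0.3,
                               loq_fraction = 0.05,
                               n_facilities = 10L,
                               facility_meanlog = log(2e4),
                               facility_sdlog = 1.5,
                               include_points_in_truth = FALSE,
                               peak_factor = 3,
                               label_noise = 0,
                               n_districts = 5L) {
  stopifnot(n_reaches >= 1, travel_time_mean > 0, area_mean_km2 > 0,
            noise_sigma >= 0, loq_fraction >= 0, loq_fraction <= 1,
            all(substances$true_dt50 > 0), all(substances$true_ef >= 0))
  sc <- as.list(environment())
  class(sc) <- "synthetic_scenario"
  sc
}

# deterministic per-stage sub-seed below 2^31
.stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Generate a random stream network
#'
#' Grows a random in-tree: reach 1 is the single outlet; each subsequent
#' reach attaches upstream of an existing reach chosen with probability
#' proportional to `1/(1 + upstream degree)^2`, which favours low-order
#' reaches and yields realistic dendritic branching. Travel times and local
#' sub-basin areas are i.i.d. lognormal; drainage areas accumulate the local
#' increments downstream. Node coordinates for station snapping come from a
#' planar embedding (children scattered around their downstream parent).
#' Districts are contiguous upstream regions grown from seed reaches (the
#' outlet is always a seed); the single outlet drains to sea `"sea_1"`.
#' Annual precipitation and potential evapotranspiration are drawn per
#' reach and converted to a local runoff volume with [budyko_runoff()].
#'
#' @param scenario a [synthetic_scenario].
#' @return A [stream_network] (patterns not yet filled).
#' @export
generate_network <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  n <- as.integer(scenario$n_reaches)
  withr::with_seed(.stage_seed(scenario$seed, "network"), {
    down <- rep(NA_integer_, n)
    nup <- integer(n)
    if (n > 1L) for (i in 2:n) {
      w <- 1 / (1 + nup[1:(i - 1)])^2
      j <- sample.int(i - 1L, 1L, prob = w)
      down[i] <- j
      nup[j] <- nup[j] + 1L
    }
    mulog <- log(scenario$travel_time_mean) - scenario$travel_time_sdlog^2 / 2
    tt <- stats::rlnorm(n, mulog, scenario$travel_time_sdlog)
    la <- stats::rlnorm(n, log(scenario$area_mean_km2) -
                          scenario$area_sdlog^2 / 2, scenario$area_sdlog)
    area <- la
    if (n > 1L) for (i in n:2) area[down[i]] <- area[down[i]] + area[i]
    # planar embedding: child scattered around its parent
    x <- numeric(n); y <- numeric(n)
    if (n > 1L) for (i in 2:n) {
      ang <- stats::runif(1, 0, 2 * pi)
      step <- sqrt(la[i]) * stats::runif(1, 0.8, 1.2)
      x[i] <- x[down[i]] + step * cos(ang)
      y[i] <- y[down[i]] + step * sin(ang)
    }
    # contiguous districts grown from seeds; outlet is always a seed
    nd <- min(scenario$n_districts, n)
    seeds <- if (nd > 1L)
      c(1L, sample(2:n, nd - 1L, prob = area[2:n])) else 1L
    district <- character(n)
    lab <- stats::setNames(paste0("D", seq_len(nd)), seeds)
    for (i in seq_len(n)) {
      district[i] <- if (i %in% seeds) lab[[as.character(i)]]
                     else district[down[i]]
    }
    precip <- stats::runif(n, scenario$precip_range[1], scenario$precip_range[2])
    pet <- stats::runif(n, scenario$pet_range[1], scenario$pet_range[2])
    runoff_q <- budyko_runoff(precip, pet) * la *
      unit_constants[["mmkm2y_to_m3s"]]
    ids <- sprintf("R%04d", seq_len(n))
    stream_network(data.frame(
      reach_id = ids,
      downstream_id = ifelse(is.na(down), "", ids[pmax(down, 1L)]),
      travel_time_days = tt,
      drainage_area_km2 = area,
      district_id = district,
      sea_id = "sea_1",
      local_runoff_m3s = runoff_q,
      precip_mm = precip,
      pet_mm = pet,
      x = x, y = y,
      stringsAsFactors = FALSE), patterns = character(0))
  })
}

#' Fill the emission-pattern columns of a synthetic network
#'
#' Population is lognormal with a random "urban" subset scaled up
#' (clustering); agricultural area is a uniform random fraction of the local
#' sub-basin area; livestock is a noisy multiplicative transform of
#' agricultural area, and connected population a noisy transform of
#' population capped at the population itself.
#'
#' @param network a [stream_network] from [generate_network()].
#' @param scenario the [synthetic_scenario].
#' @return The network with columns `pop`, `agri_km2`, `livestock`,
#'   `pop_connected` filled and registered as patterns.
#' @export
generate_patterns <- function(network, scenario) {
  stopifnot(inherits(network, "stream_network"),
            inherits(scenario, "synthetic_scenario"))
  n <- nrow(network$reaches)
  la <- unname(local_area(network))
  withr::with_seed(.stage_seed(scenario$seed, "patterns"), {
    pop <- stats::rlnorm(n, scenario$pop_meanlog, scenario$pop_sdlog)
    n_urban <- round(scenario$urban_fraction * n)
    if (n_urban > 0 && scenario$urban_factor != 1) {
      urban <- sample.int(n, n_urban)
      pop[urban] <- pop[urban] * scenario$urban_factor
    }
    agri <- la * stats::runif(n, scenario$agri_fraction_range[1],
                              scenario$agri_fraction_range[2])
    livestock <- agri * scenario$livestock_per_km2 *
      stats::rlnorm(n, -scenario$livestock_sdlog^2 / 2, scenario$livestock_sdlog)
    connected <- pmin(pop, pop * scenario$connection_rate *
                        stats::rlnorm(n, -scenario$connection_sdlog^2 / 2,
                                      scenario$connection_sdlog))
    df <- network$reaches
    df$pop <- pop
    df$agri_km2 <- agri
    df$livestock <- livestock
    df$pop_connected <- connected
    stream_network(df)
  })
}

#' True loads and concentrations of the synthetic substances
#'
#' For each substance: the true diffuse load is the true emission factor
#' times the decayed accumulation of its true pattern at its true DT50;
#' optionally point loads are added. Concentrations follow from the
#' annual-average discharge accumulated from local runoff.
#'
#' @param network a [stream_network] with patterns filled.
#' @param scenario the [synthetic_scenario].
#' @param point_emissions optional data.frame `substance`, `reach_id`,
#'   `emission_ng_s`, added to the truth when the scenario's
#'   `include_points_in_truth` is `TRUE`.
#' @return A `true_state` list: `network`, `Q` (m3/s), `loads` and `conc`
#'   (named lists substance -> per-reach vector), `loads_point`,
#'   `substances`.
#' @export
generate_true_state <- function(network, scenario, point_emissions = NULL) {
  stopifnot(inherits(network, "stream_network"))
  subs <- scenario$substances
  unknown <- setdiff(subs$pattern, names(network$reaches))
  if (length(unknown))
    stop("substance references unknown pattern '", unknown[1], "'")
  Q <- accumulate_discharge(network)
  loads <- list(); loads_point <- list(); conc <- list()
  for (i in seq_len(nrow(subs))) {
    s <- subs$name[i]
    L <- subs$true_ef[i] *
      accumulate_decayed(network, subs$pattern[i], subs$true_dt50[i])
    Lp <- rep(0, length(L)); names(Lp) <- names(L)
    if (!is.null(point_emissions) && isTRUE(scenario$include_points_in_truth)) {
      pe <- point_emissions[point_emissions$substance == s, , drop = FALSE]
      if (nrow(pe)) Lp <- point_loads(network, pe, subs$true_dt50[i])
    }
    loads[[s]] <- L
    loads_point[[s]] <- Lp
    conc[[s]] <- concentration(L + Lp, Q)
  }
  structure(list(network = network, Q = Q, loads = loads,
                 loads_point = loads_point, conc = conc,
                 substances = subs),
            class = "true_state")
}

#' Sample noisy monitoring observations from the synthetic truth
#'
#' Stations are reaches sampled without replacement with probability
#' proportional to drainage area (monitoring favours larger rivers). Each
#' station yields `samples_per_station` records per substance: observed
#' concentration = true concentration times a median-unbiased lognormal
#' error `exp(N(0, noise_sigma^2))`; per-sample discharge = annual mean
#' times a mean-unbiased lognormal day factor. The lowest `loq_fraction` of
#' concentrations (per substance) are flagged below the limit of
#' quantification, carrying the LOQ value.
#'
#' @param state a `true_state` from [generate_true_state()].
#' @param scenario the [synthetic_scenario].
#' @return data.frame `station_id`, `reach_id`, `date`, `substance`,
#'   `concentration_ug_L`, `below_loq`, `loq_ug_L`, `discharge_m3s`.
#' @export
generate_observations <- function(state, scenario) {
  stopifnot(inherits(state, "true_state"))
  net <- state$network
  n <- nrow(net$reaches)
  ns <- as.integer(scenario$n_stations)
  if (ns > n) stop("n_stations (", ns, ") exceeds number of reaches (", n, ")")
  withr::with_seed(.stage_seed(scenario$seed, "observations"), {
    st_idx <- sample.int(n, ns, prob = net$reaches$drainage_area_km2)
    k <- as.integer(scenario$samples_per_station)
    dates <- format(seq(as.Date("2019-01-15"), by = "1 month",
                        length.out = k))
    rows <- list()
    for (s in state$substances$name) {
      tc <- state$conc[[s]][st_idx]
      m <- ns * k
      err <- if (scenario$noise_sigma > 0)
        exp(stats::rnorm(m, 0, scenario$noise_sigma)) else rep(1, m)
      dayf <- if (scenario$discharge_sdlog > 0)
        stats::rlnorm(m, -scenario$discharge_sdlog^2 / 2,
                      scenario$discharge_sdlog) else rep(1, m)
      obs <- data.frame(
        station_id = rep(sprintf("S%03d", seq_len(ns)), each = k),
        reach_id = rep(net$reaches$reach_id[st_idx], each = k),
        date = rep(dates, ns),
        substance = s,
        concentration_ug_L = rep(tc, each = k) * err,
        below_loq = 0L,
        loq_ug_L = NA_real_,
        discharge_m3s = rep(state$Q[st_idx], each = k) * dayf,
        stringsAsFactors = FALSE)
      n_cens <- floor(scenario$loq_fraction * m)
      if (n_cens > 0) {
        low <- order(obs$concentration_ug_L)[seq_len(n_cens)]
        loq <- max(obs$concentration_ug_L[low])
        obs$below_loq[low] <- 1L
        obs$loq_ug_L[low] <- loq
      }
      rows[[s]] <- obs
    }
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

#' Random point-source facilities
#'
#' For each substance, `n_facilities` facilities on distinct reaches chosen
#' uniformly, with lognormal emission magnitudes.
#'
#' @param network a [stream_network].
#' @param scenario the [synthetic_scenario].
#' @return data.frame `substance`, `reach_id`, `emission_ng_s`.
#' @export
generate_point_sources <- function(network, scenario) {
  n <- nrow(network$reaches)
  nf <- min(as.integer(scenario$n_facilities), n)
  if (nf == 0L)
    return(data.frame(substance = character(), reach_id = character(),
                      emission_ng_s = numeric()))
  withr::with_seed(.stage_seed(scenario$seed, "points"), {
    out <- lapply(scenario$substances$name, function(s) {
      data.frame(substance = s,
                 reach_id = network$reaches$reach_id[sample.int(n, nf)],
                 emission_ng_s = stats::rlnorm(nf, scenario$facility_meanlog,
                                               scenario$facility_sdlog),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

#' Exceedance reports derived from the synthetic truth
#'
#' The annual-average flag compares the true annual-average concentration
#' with the AA quality standard; the peak flag compares the concentration
#' scaled by `peak_factor` with the MAC standard. An optional label-noise
#' rate flips flags at random to emulate reporting inconsistency.
#'
#' @param state a `true_state`.
#' @param scenario the [synthetic_scenario].
#' @return data.frame `reach_id`, `substance`, `exceed_aa`, `exceed_mac`
#'   (0/1).
#' @export
generate_exceedances <- function(state, scenario) {
  stopifnot(inherits(state, "true_state"))
  subs <- scenario$substances
  withr::with_seed(.stage_seed(scenario$seed, "exceedances"), {
    out <- lapply(seq_len(nrow(subs)), function(i) {
      s <- subs$name[i]
      conc <- state$conc[[s]]
      aa <- conc > subs$eqs_aa[i]
      mac <- conc * scenario$peak_factor > subs$eqs_mac[i]
      if (scenario$label_noise > 0) {
        flip <- stats::runif(length(aa)) < scenario$label_noise
        aa <- xor(aa, flip)
        flip <- stats::runif(length(mac)) < scenario$label_noise
        mac <- xor(mac, flip)
      }
      data.frame(reach_id = state$network$reaches$reach_id,
                 substance = s,
                 exceed_aa = as.integer(aa), exceed_mac = as.integer(mac),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}

#' Run every generator of a scenario
#'
#' @param scenario a [synthetic_scenario].
#' @return list `network`, `state` (`true_state`), `observations`,
#'   `point_sources`, `exceedances`.
#' @export
simulate_scenario <- function(scenario) {
  net <- generate_patterns(generate_network(scenario), scenario)
  points <- generate_point_sources(net, scenario)
  state <- generate_true_state(net, scenario, points)
  list(network = net,
       state = state,
       observations = generate_observations(state, scenario),
       point_sources = points,
       exceedances = generate_exceedances(state, scenario))
}
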