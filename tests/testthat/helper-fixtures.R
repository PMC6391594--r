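# Small fixture builders shared across test files. Everything is generated
# in code; no stored data.

# a downstream chain r1 -> r2 -> ... -> rn
chain_network <- function(travel_times, field = NULL) {
  n <- length(travel_times)
  ids <- paste0("r", seq_len(n))
  df <- data.frame(
    reach_id = ids,
    downstream_id = c(ids[-1], NA)[seq_len(n)],
    travel_time_days = travel_times,
    drainage_area_km2 = cumsum(rep(1, n)),
    stringsAsFactors = FALSE)
  # chain drains r1 -> r2 -> ... so drainage area grows along the chain
  stream_network(df, patterns = character(0))
}

# Y-shaped confluence: a and b join into c
confluence_network <- function(tt = c(a = 1, b = 2, c = 0.5)) {
  df <- data.frame(
    reach_id = c("a", "b", "c"),
    downstream_id = c("c", "c", NA),
    travel_time_days = unname(tt[c("a", "b", "c")]),
    drainage_area_km2 = c(1, 1, 3),
    stringsAsFactors = FALSE)
  stream_network(df, patterns = character(0))
}

# random in-tree with lognormal travel times; independent of the package's
# synthetic generator (direct data.frame construction)
random_tree <- function(n, seed) {
  withr::with_seed(seed, {
    down <- c(NA_integer_, if (n > 1) sapply(2:n, function(i)
      sample.int(i - 1L, 1L)))
    ids <- paste0("t", seq_len(n))
    la <- stats::rlnorm(n, log(5), 0.6)
    area <- la
    if (n > 1) for (i in n:2) area[down[i]] <- area[down[i]] + area[i]
    stream_network(data.frame(
      reach_id = ids,
      downstream_id = ifelse(is.na(down), NA, ids[pmax(down, 1L)]),
      travel_time_days = stats::rlnorm(n, log(0.5), 0.7),
      drainage_area_km2 = area,
      stringsAsFactors = FALSE), patterns = character(0))
  })
}

# per-source walk-down oracle: full-network decayed accumulation without the
# topological recursion (adds each source's decayed contribution to every
# reach on its downstream path)
walkdown_oracle <- function(net, field, dt50) {
  n <- nrow(net$reaches)
  tt <- net$reaches$travel_time_days
  out <- numeric(n)
  for (src in seq_len(n)) {
    v <- src; ptime <- 0
    while (!is.na(v)) {
      ptime <- ptime + tt[v]
      out[v] <- out[v] + field[src] *
        (if (is.infinite(dt50)) 1 else 2^(-ptime / dt50))
      v <- net$down[v]
    }
  }
  stats::setNames(out, net$reaches$reach_id)
}

# scenario small enough for fast tests
small_scenario <- function(seed = 1, ...) {
  synthetic_scenario(seed = seed, n_reaches = 120, n_stations = 25,
                     samples_per_station = 4, ...)
}
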