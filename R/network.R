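#' Stream network objects
#'
#' A `stream_network` is a forest of river reaches: every reach drains to at
#' most one downstream reach and the downstream graph is acyclic. Each reach
#' carries a travel time (days, inclusive of any lake or reservoir residence
#' on the reach), an upstream-inclusive drainage area (km2), per-reach
#' emission-pattern quantities local to its sub-basin (persons, km2 of
#' agricultural land, livestock units, connected persons), a local runoff
#' volume, and reporting labels (district, receiving sea for outlets).
#'
#' @param reaches data.frame with at least columns `reach_id`,
#'   `downstream_id` (`NA` or `""` for an outlet), `travel_time_days` and
#'   `drainage_area_km2`. Optional columns: `district_id`, `sea_id`,
#'   `local_runoff_m3s`, `precip_mm`, `pet_mm`, node coordinates `x`, `y`,
#'   and one numeric column per emission pattern.
#' @param patterns character vector naming the pattern columns present in
#'   `reaches` (may be empty; `generate_patterns()` fills the standard four).
#'
#' @return An object of class `stream_network`: a list with elements
#'   `reaches` (the validated data.frame), `down` (integer index of the
#'   downstream reach, `NA` at outlets), `topo` (integer permutation, every
#'   reach after all its upstream reaches) and `patterns`.
#'
#' @details Reach ids are coerced to character. Validation rejects duplicate
#'   ids, dangling `downstream_id` references, negative travel times and
#'   cycles (naming one reach on the cycle).
#' @export
stream_network <- function(reaches, patterns = intersect(
                             c("pop", "agri_km2", "livestock", "pop_connected"),
                             names(reaches))) {
  stopifnot(is.data.frame(reaches))
  req <- c("reach_id", "downstream_id", "travel_time_days", "drainage_area_km2")
  miss <- setdiff(req, names(reaches))
  if (length(miss))
    stop("network table is missing column(s): ", paste(miss, collapse = ", "))
  reaches$reach_id <- as.character(reaches$reach_id)
  ds <- as.character(reaches$downstream_id)
  ds[!is.na(ds) & ds == ""] <- NA_character_
  reaches$downstream_id <- ds
  if (anyDuplicated(reaches$reach_id))
    stop("duplicate reach_id: ",
         reaches$reach_id[duplicated(reaches$reach_id)][1])
  down <- match(ds, reaches$reach_id)
  bad <- which(!is.na(ds) & is.na(down))
  if (length(bad))
    stop("downstream_id '", ds[bad[1]], "' of reach '",
         reaches$reach_id[bad[1]], "' does not exist")
  if (any(!is.na(down) & down == seq_along(down)))
    stop("reach '", reaches$reach_id[which(down == seq_along(down))[1]],
         "' drains to itself")
  if (any(reaches$travel_time_days < 0)) stop("negative travel_time_days")
  for (p in patterns)
    if (any(reaches[[p]] < 0, na.rm = TRUE))
      stop("negative values in pattern column '", p, "'")
  net <- structure(list(reaches = reaches, down = down,
                        topo = NULL, patterns = patterns),
                   class = "stream_network")
  net$topo <- .topo_index(net)
  net
}

#' @export
print.stream_network <- function(x, ...) {
  n <- nrow(x$reaches)
  cat("<stream_network> ", n, " reaches, ", sum(is.na(x$down)),
      " outlet(s), patterns: ",
      if (length(x$patterns)) paste(x$patterns, collapse = ", ") else "(none)",
      "\n", sep = "")
  invisible(x)
}

#' @export
length.stream_network <- function(x) nrow(x$reaches)

# Kahn's algorithm on the downstream pointers; headwaters first.
# Errors on a cycle, naming one reach on it.
.topo_index <- function(net) {
  down <- net$down
  n <- length(down)
  indeg <- tabulate(down[!is.na(down)], nbins = n)  # number of upstream reaches
  queue <- which(indeg == 0L)
  order <- integer(n)
  k <- 0L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    k <- k + 1L; order[k] <- v
    d <- down[v]
    if (!is.na(d)) {
      indeg[d] <- indeg[d] - 1L
      if (indeg[d] == 0L) queue <- c(queue, d)
    }
  }
  if (k < n) {
    on_cycle <- setdiff(seq_len(n), order[seq_len(k)])
    stop("cycle detected in downstream graph involving reach '",
         net$reaches$reach_id[on_cycle[1]], "'")
  }
  order
}

#' Topological order of a stream network
#'
#' @param network a [stream_network].
#' @return Character vector of reach ids, headwaters first: every reach
#'   appears after all of its upstream reaches.
#' @export
topological_order <- function(network) {
  stopifnot(inherits(network, "stream_network"))
  network$reaches$reach_id[network$topo]
}

# Resolve a field argument (named vector, unnamed vector in table order, or a
# pattern column name) to a numeric vector aligned with network$reaches.
.resolve_field <- function(network, field) {
  r <- network$reaches
  if (is.character(field) && length(field) == 1L) {
    if (!field %in% names(r)) stop("unknown field column '", field, "'")
    return(as.numeric(r[[field]]))
  }
  nm <- names(field)
  field <- as.numeric(field)
  if (!is.null(nm)) {
    out <- field[match(r$reach_id, nm)]
    out[is.na(out)] <- 0
    return(unname(out))
  }
  if (length(field) != nrow(r))
    stop("field must have one value per reach (", nrow(r), ")")
  field
}

#' Decayed accumulation of a per-reach field along the network
#'
#' Core catchment integral of the load model: the load at a reach outlet is
#' the sum, over every reach of its catchment, of the local field decayed
#' exponentially over the water travel time from that reach,
#' \deqn{L(x) = \sum_{i \in A(x)} f(i)\, e^{-\ln 2\, T(i \to x)/\mathrm{DT50}}.}
#' The path time \eqn{T(i\to x)} sums `travel_time_days` over the downstream
#' path from `i` to `x` inclusive of both endpoints; a reach's own
#' contribution is decayed over its own travel time (emissions enter at the
#' reach's upstream end, values are evaluated at its downstream node).
#'
#' With `dt50 = Inf` the decay term is exactly 1 and the result is the plain
#' catchment sum (used for discharge accumulation and the uniform pattern).
#'
#' @param network a [stream_network].
#' @param field per-reach emission intensity: a numeric vector in table order,
#'   a named vector keyed by reach id (missing reaches count as 0), or the
#'   name of a column of the reach table.
#' @param dt50 dissipation half-life in days (> 0), or `Inf` for no decay.
#' @return Named numeric vector (reach id -> accumulated value), same units
#'   as `field`, in reach-table order. Computed in one topological pass, O(n).
#' @seealso [brute_force_load()] for the path-enumeration oracle.
#' @export
accumulate_decayed <- function(network, field, dt50) {
  stopifnot(inherits(network, "stream_network"))
  if (length(dt50) != 1L || is.na(dt50) || dt50 <= 0)
    stop("dt50 must be a single positive value (or Inf)")
  f <- .resolve_field(network, field)
  tt <- network$reaches$travel_time_days
  decay <- if (is.infinite(dt50)) rep(1, length(tt)) else 2^(-tt / dt50)
  down <- network$down
  acc <- numeric(length(f))
  inflow <- numeric(length(f))
  for (v in network$topo) {
    acc[v] <- decay[v] * (f[v] + inflow[v])
    d <- down[v]
    if (!is.na(d)) inflow[d] <- inflow[d] + acc[v]
  }
  names(acc) <- network$reaches$reach_id
  acc
}

#' Brute-force decayed load at one reach (test oracle)
#'
#' Explicit enumeration of every source reach in the catchment of
#' `target_reach`, walking each source's downstream path and summing travel
#' times, with the same inclusive-endpoint convention as
#' [accumulate_decayed()]. Independent of the topological pass; intended as
#' an oracle on small networks.
#'
#' @inheritParams accumulate_decayed
#' @param target_reach reach id at which to evaluate the load.
#' @return Scalar accumulated value.
#' @export
brute_force_load <- function(network, field, dt50, target_reach) {
  stopifnot(inherits(network, "stream_network"))
  if (length(dt50) != 1L || is.na(dt50) || dt50 <= 0)
    stop("dt50 must be a single positive value (or Inf)")
  r <- network$reaches
  tgt <- match(as.character(target_reach), r$reach_id)
  if (is.na(tgt)) stop("target reach '", target_reach, "' not in network")
  f <- .resolve_field(network, field)
  tt <- r$travel_time_days
  total <- 0
  for (src in seq_len(nrow(r))) {
    # walk downstream from src; accumulate path time if we hit the target
    v <- src
    ptime <- 0
    repeat {
      ptime <- ptime + tt[v]
      if (v == tgt) {
        dec <- if (is.infinite(dt50)) 1 else 2^(-ptime / dt50)
        total <- total + f[src] * dec
        break
      }
      v <- network$down[v]
      if (is.na(v)) break  # drained past an outlet without meeting target
    }
  }
  total
}

#' Local (incremental) drainage area of each reach
#'
#' `drainage_area_km2` is upstream-inclusive; the local sub-basin area is the
#' drainage area minus the drainage areas of the immediate upstream reaches.
#' Negative increments (inconsistent inputs) are clipped to zero with a
#' warning.
#'
#' @param network a [stream_network].
#' @return Named numeric vector of local areas (km2).
#' @export
local_area <- function(network) {
  r <- network$reaches
  up_sum <- numeric(nrow(r))
  has_down <- !is.na(network$down)
  if (any(has_down)) {
    s <- tapply(r$drainage_area_km2[has_down], network$down[has_down], sum)
    up_sum[as.integer(names(s))] <- s
  }
  la <- r$drainage_area_km2 - up_sum
  if (any(la < -1e-9 * pmax(r$drainage_area_km2, 1))) {
    warning("drainage areas decrease downstream for some reaches; ",
            "local areas clipped to 0")
  }
  la <- pmax(la, 0)
  names(la) <- r$reach_id
  la
}

#' Read / write a stream network as a CSV edge list
#'
#' One row per reach; columns `reach_id`, `downstream_id` (empty for an
#' outlet), `travel_time_days`, `drainage_area_km2`, optionally
#' `district_id`, `sea_id`, `local_runoff_m3s`, climate columns and one
#' column per emission pattern. UTF-8, header required, '.' decimal.
#'
#' @param path file path.
#' @param patterns pattern columns to register; by default the standard four
#'   that are present.
#' @return [read_network_csv()] returns a [stream_network];
#'   [write_network_csv()] returns `path` invisibly.
#' @export
read_network_csv <- function(path, patterns = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(reach_id = "character"))
  df$downstream_id <- as.character(df$downstream_id)
  if (is.null(patterns))
    patterns <- intersect(c("pop", "agri_km2", "livestock", "pop_connected"),
                          names(df))
  stream_network(df, patterns = patterns)
}

#' @rdname read_network_csv
#' @param network a [stream_network].
#' @export
write_network_csv <- function(network, path) {
  df <- network$reaches
  df$downstream_id[is.na(df$downstream_id)] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
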