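test_that("generate_network produces a valid single-outlet tree, deterministically", {
  sc <- synthetic_scenario(seed = 10, n_reaches = 1)
  net1 <- generate_network(sc)
  expect_equal(nrow(net1$reaches), 1L)
  expect_true(is.na(net1$down))

  sc <- synthetic_scenario(seed = 21, n_reaches = 500)
  a <- generate_network(sc)
  b <- generate_network(sc)
  expect_identical(a$reaches, b$reaches)  # same seed, identical network
  expect_equal(nrow(a$reaches), 500L)
  expect_equal(sum(is.na(a$down)), 1L)    # exactly one outlet
  expect_silent(topological_order(a))     # acyclic by construction
  # drainage area consistency: area >= sum of immediate upstream areas
  la <- local_area(a)
  expect_true(all(la > 0))
  # districts are contiguous: every non-seed reach shares its downstream's
  # district unless it starts a new one; here just check full labelling
  expect_true(all(nzchar(a$reaches$district_id)))
  expect_equal(length(unique(a$reaches$district_id)), 5L)
})

test_that("different seeds give different networks", {
  n1 <- generate_network(synthetic_scenario(seed = 1, n_reaches = 100))
  n2 <- generate_network(synthetic_scenario(seed = 2, n_reaches = 100))
  expect_false(identical(n1$reaches$travel_time_days,
                         n2$reaches$travel_time_days))
})

test_that("generate_patterns fills nonnegative, imperfectly correlated patterns", {
  sc <- small_scenario(3)
  net <- generate_patterns(generate_network(sc), sc)
  expect_setequal(net$patterns,
                  c("pop", "agri_km2", "livestock", "pop_connected"))
  p <- net$reaches[net$patterns]
  expect_true(all(p >= 0))
  expect_true(all(net$reaches$pop_connected <= net$reaches$pop))
  cm <- stats::cor(p)
  off <- cm[upper.tri(cm)]
  expect_true(all(off > -1 & off < 1))

  # zero agricultural fraction range -> zero agriculture everywhere
  sc0 <- small_scenario(3, agri_fraction_range = c(0, 0))
  net0 <- generate_patterns(generate_network(sc0), sc0)
  expect_true(all(net0$reaches$agri_km2 == 0))
})

test_that("true state is linear in the emission factor and matches closed form", {
  sc <- small_scenario(8)
  net <- generate_patterns(generate_network(sc), sc)
  st <- generate_true_state(net, sc)
  sc2 <- sc; sc2$substances$true_ef <- 2 * sc$substances$true_ef
  st2 <- generate_true_state(net, sc2)
  for (s in sc$substances$name)
    expect_equal(st2$loads[[s]], 2 * st$loads[[s]], tolerance = 1e-12)

  sc0 <- sc; sc0$substances$true_ef <- c(0, 0)
  st0 <- generate_true_state(net, sc0)
  expect_true(all(st0$loads[["popchem"]] == 0))

  # single-reach closed form: load = EF * EP * 2^(-t/DT50)
  sc1 <- synthetic_scenario(seed = 4, n_reaches = 1)
  net1 <- generate_patterns(generate_network(sc1), sc1)
  st1 <- generate_true_state(net1, sc1)
  i <- 1
  expect_equal(unname(st1$loads[["popchem"]]),
               sc1$substances$true_ef[i] * net1$reaches$pop *
                 2^(-net1$reaches$travel_time_days /
                      sc1$substances$true_dt50[i]),
               tolerance = 1e-12)

  sc_bad <- sc; sc_bad$substances$pattern[1] <- "unicorn"
  expect_error(generate_true_state(net, sc_bad), "unknown pattern")
})

test_that("observations reproduce the truth when noise is off", {
  sc <- small_scenario(5, noise_sigma = 0, discharge_sdlog = 0,
                       loq_fraction = 0)
  net <- generate_patterns(generate_network(sc), sc)
  st <- generate_true_state(net, sc)
  obs <- generate_observations(st, sc)
  loads <- compute_observed_loads(obs[obs$substance == "popchem", ])
  truth <- st$loads[["popchem"]][loads$reach_id]
  expect_equal(loads$load_ng_s, unname(truth), tolerance = 1e-9)
  # and the same seed yields identical records
  obs2 <- generate_observations(st, sc)
  expect_identical(obs, obs2)
})

test_that("observation noise has the configured log-sd", {
  sc <- synthetic_scenario(seed = 6, n_reaches = 300, n_stations = 100,
                           samples_per_station = 5, noise_sigma = 0.3,
                           discharge_sdlog = 0, loq_fraction = 0)
  net <- generate_patterns(generate_network(sc), sc)
  st <- generate_true_state(net, sc)
  obs <- generate_observations(st, sc)
  o <- obs[obs$substance == "popchem", ]
  truth <- st$conc[["popchem"]][o$reach_id]
  sd_log <- stats::sd(log(o$concentration_ug_L / unname(truth)))
  expect_lt(abs(sd_log - 0.3) / 0.3, 0.15)  # 500 samples, within 15%
})

test_that("LOQ censoring flags the configured fraction, lowest first", {
  sc <- small_scenario(9, loq_fraction = 1)
  sim <- simulate_scenario(sc)
  expect_true(all(sim$observations$below_loq == 1))

  sc2 <- small_scenario(9, loq_fraction = 0.2)
  sim2 <- simulate_scenario(sc2)
  o <- sim2$observations[sim2$observations$substance == "popchem", ]
  expect_equal(sum(o$below_loq), floor(0.2 * nrow(o)))
  expect_true(max(o$concentration_ug_L[o$below_loq == 1]) <=
                min(o$concentration_ug_L[o$below_loq == 0]))
  sc_many <- sc2; sc_many$n_stations <- 10000L
  expect_error(generate_observations(
    generate_true_state(generate_patterns(generate_network(sc2), sc2), sc2),
    sc_many), "exceeds")
})

test_that("exceedance flags threshold the truth; label noise flips ~rate", {
  sc <- synthetic_scenario(seed = 12, n_reaches = 1000, n_stations = 10)
  net <- generate_patterns(generate_network(sc), sc)
  st <- generate_true_state(net, sc)
  # EQS above every concentration -> no flags; EQS 0 -> all flagged
  sc_hi <- sc; sc_hi$substances$eqs_aa <- rep(1e9, 2)
  expect_true(all(generate_exceedances(st, sc_hi)$exceed_aa == 0))
  sc_lo <- sc; sc_lo$substances$eqs_aa <- rep(0, 2)
  expect_true(all(generate_exceedances(st, sc_lo)$exceed_aa == 1))
  # label noise flips about the configured share
  base <- generate_exceedances(st, sc)
  sc_fl <- sc; sc_fl$label_noise <- 0.1
  noisy <- generate_exceedances(st, sc_fl)
  frac <- mean(base$exceed_aa != noisy$exceed_aa)
  expect_gt(frac, 0.07)  # binomial(2000, 0.1) band
  expect_lt(frac, 0.13)
})

test_that("point sources land on known reaches with positive magnitudes", {
  sc <- small_scenario(2, n_facilities = 6)
  net <- generate_network(sc)
  ps <- generate_point_sources(net, sc)
  expect_equal(nrow(ps), 6 * nrow(sc$substances))
  expect_true(all(ps$reach_id %in% net$reaches$reach_id))
  expect_true(all(ps$emission_ng_s > 0))
  sc0 <- small_scenario(2, n_facilities = 0)
  expect_equal(nrow(generate_point_sources(net, sc0)), 0L)
})
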