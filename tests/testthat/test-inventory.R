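test_that("inventory unit arithmetic and partition invariance", {
  # EF 1 ng/ind/s on 1e6 persons is about 31.56 kg/y
  one <- stream_network(data.frame(
    reach_id = "a", downstream_id = NA, travel_time_days = 1,
    drainage_area_km2 = 1, district_id = "D1", pop = 1e6), patterns = "pop")
  inv <- build_inventory(one, data.frame(substance = "s", pattern = "pop",
                                         emission_factor = 1))
  expect_equal(inv$diffuse_kg_y, 31.5576, tolerance = 1e-12)
  expect_equal(inv$total_kg_y, inv$diffuse_kg_y + inv$point_kg_y)

  # zero-population district contributes nothing
  sc <- small_scenario(6)
  net <- generate_patterns(generate_network(sc), sc)
  df <- net$reaches
  d1 <- df$district_id == df$district_id[1]
  df$pop[d1] <- 0
  net0 <- stream_network(df)
  inv0 <- build_inventory(net0, data.frame(substance = "s", pattern = "pop",
                                           emission_factor = 2))
  expect_equal(inv0$diffuse_kg_y[inv0$district_id == df$district_id[1]], 0)

  # district totals partition the whole-network emission
  subs <- data.frame(substance = c("s1", "s2"),
                     pattern = c("pop", "agri_km2"),
                     emission_factor = c(5, 100))
  ps <- generate_point_sources(net, small_scenario(6, n_facilities = 8))
  ps$substance <- rep(c("s1", "s2"), each = 8)
  inv2 <- build_inventory(net, subs, ps)
  for (s in subs$substance) {
    rows <- inv2[inv2$substance == s, ]
    ef <- subs$emission_factor[subs$substance == s]
    p <- subs$pattern[subs$substance == s]
    expect_equal(sum(rows$diffuse_kg_y),
                 sum(net$reaches[[p]]) * ef * 3.15576e-5, tolerance = 1e-12)
    expect_equal(sum(rows$point_kg_y),
                 sum(ps$emission_ng_s[ps$substance == s]) * 3.15576e-5,
                 tolerance = 1e-12)
  }
  # relabelling districts conserves substance totals
  df2 <- net$reaches
  df2$district_id <- rep_len(c("X", "Y", "Z"), nrow(df2))
  inv3 <- build_inventory(stream_network(df2), subs, ps)
  expect_equal(tapply(inv3$total_kg_y, inv3$substance, sum),
               tapply(inv2$total_kg_y, inv2$substance, sum),
               tolerance = 1e-12)
  expect_error(build_inventory(net, data.frame(
    substance = "s", pattern = "pop", emission_factor = NA_real_)),
    "missing emission factor")
})

test_that("sea loads conserve emissions at infinite DT50 and dissipate otherwise", {
  sc <- small_scenario(14)
  net <- generate_patterns(generate_network(sc), sc)
  ef <- 3
  emis_total_kg <- sum(net$reaches$pop) * ef * 3.15576e-5
  # infinite half-life: the outlet receives every emitted nanogram
  L_inf <- ef * accumulate_decayed(net, "pop", Inf)
  sea_inf <- sea_loads(net, list(s = L_inf))
  expect_equal(sea_inf$load_tonnes_y, emis_total_kg * 1e-3, tolerance = 1e-12)
  # finite half-life: strictly less; the gap is the in-stream dissipation
  L_10 <- ef * accumulate_decayed(net, "pop", 10)
  sea_10 <- sea_loads(net, list(s = L_10))
  expect_lt(sea_10$load_tonnes_y, sea_inf$load_tonnes_y)
  # cross-check by summing per-source decayed contributions to the outlet
  outlet <- net$reaches$reach_id[is.na(net$down)]
  oracle <- brute_force_load(net, ef * net$reaches$pop, 10, outlet)
  expect_equal(sea_10$load_tonnes_y, oracle * 3.15576e-8, tolerance = 1e-10)
  # single outlet: sea load equals the outlet load
  expect_equal(sea_10$load_tonnes_y,
               unname(L_10[outlet]) * 3.15576e-8, tolerance = 1e-12)
  # unlabelled outlets fall into 'unassigned' with a warning
  df <- net$reaches; df$sea_id <- NULL
  expect_warning(s2 <- sea_loads(stream_network(df), list(s = L_10)),
                 "unassigned")
  expect_equal(s2$sea_id, "unassigned")
})

test_that("the full pipeline runs end to end, deterministically", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- default_config(11)
  cfg$scenario$n_reaches <- 150
  cfg$scenario$n_stations <- 30
  cfg$calibration$n_boot <- 50
  res <- suppressMessages(run_pipeline(cfg, outdir = out1, log_level = "error"))
  expected <- c("network.csv", "observations.csv", "point_sources.csv",
                "exceedances.csv", "truth.csv", "proxies.csv",
                "calibration.csv", "concentrations.csv", "indicators.csv",
                "roc_rates.csv", "inventory.csv", "sea_loads.csv",
                "manifest.json", "run.log")
  expect_true(all(expected %in% list.files(out1)))
  # manifest checksums describe the files actually written
  man <- jsonlite::fromJSON(file.path(out1, "manifest.json"))
  expect_equal(man$seed, 11)
  expect_true(all(names(man$outputs) %in% list.files(out1)))
  # rerun: numeric outputs byte-identical
  suppressMessages(run_pipeline(cfg, outdir = out2, log_level = "error"))
  for (f in setdiff(expected, c("run.log", "manifest.json")))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  # calibration table carries the expected columns
  cal <- utils::read.csv(file.path(out1, "calibration.csv"))
  expect_true(all(c("substance", "pattern", "best_pattern", "modelled_dt50",
                    "selected_dt50", "emission_factor", "r2_class",
                    "slope_ci_lo", "slope_ci_hi") %in% names(cal)))
})

test_that("cli_main dispatches stages and rejects bad usage", {
  out <- withr::local_tempdir()
  cfgfile <- file.path(out, "cfg.json")
  jsonlite::write_json(list(scenario = list(seed = 5, n_reaches = 80,
                                            n_stations = 20),
                            calibration = list(n_boot = 20)),
                       cfgfile, auto_unbox = TRUE, digits = NA)
  suppressMessages(cli_main(c("simulate", "--config", cfgfile,
                              "--outdir", file.path(out, "sim"),
                              "--log-level", "error")))
  expect_true(file.exists(file.path(out, "sim", "network.csv")))
  expect_false(file.exists(file.path(out, "sim", "calibration.csv")))
  suppressMessages(cli_main(c("calibrate", "--config", cfgfile,
                              "--outdir", file.path(out, "cal"),
                              "--log-level", "error")))
  expect_true(file.exists(file.path(out, "cal", "calibration.csv")))
  expect_error(cli_main(c("frobnicate")), "usage")
  expect_error(cli_main(c("run", "--bogus", "1")), "unknown option")
  # a config without observations for the calibrate stage fails with a
  # stage-named diagnostic
  badcfg <- file.path(out, "bad.json")
  jsonlite::write_json(list(scenario = list(seed = 5, n_reaches = 40,
                                            n_stations = 10,
                                            samples_per_station = 1,
                                            loq_fraction = 1)),
                       badcfg, auto_unbox = TRUE, digits = NA)
  expect_error(suppressMessages(
    cli_main(c("calibrate", "--config", badcfg, "--outdir",
               file.path(out, "bad"), "--log-level", "error"))),
    "stage 'calibrate'")
})
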