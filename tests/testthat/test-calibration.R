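test_that("wls_fit matches trivial closed forms", {
  x <- c(1, 2, 3, 4)
  f <- wls_fit(x, 2 * x, w = c(1, 5, 2, 0.5))
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  fc <- wls_fit(x, rep(3, 4), w = rep(1, 4))
  expect_equal(fc$slope, 0, tolerance = 1e-12)
  expect_equal(fc$r_squared, 0)

  expect_error(wls_fit(rep(1, 5), 1:5), "degenerate proxy")
  expect_error(wls_fit(1:2, 1:2), "at least 3")
  expect_error(wls_fit(1:4, 1:4, w = c(1, 1, 0, 1)), "positive")
})

test_that("wls_fit equals the stats::lm oracle, sqrt-load weights included", {
  # a small hand-checkable case x=(1,2,3), y=(1,3,4), w=sqrt(y), then
  # random instances
  check_against_lm <- function(x, y, w) {
    f <- wls_fit(x, y, w)
    m <- stats::lm(y ~ x, weights = w)
    expect_equal(f$slope, unname(stats::coef(m)[2]), tolerance = 1e-10)
    expect_equal(f$intercept, unname(stats::coef(m)[1]), tolerance = 1e-10)
    expect_equal(f$r_squared, summary(m)$r.squared, tolerance = 1e-10)
  }
  check_against_lm(c(1, 2, 3), c(1, 3, 4), sqrt(c(1, 3, 4)))
  withr::with_seed(42, {
    for (i in 1:50) {
      n <- sample(5:60, 1)
      x <- stats::rlnorm(n, 2, 1)
      y <- stats::rlnorm(n, 1, 1)
      check_against_lm(x, y, sqrt(y))
    }
  })
})

test_that("the proxy grid has one column per pattern x DT50 combination", {
  sc <- small_scenario(1)
  net <- generate_patterns(generate_network(sc), sc)
  px <- build_proxy_grid(net)
  expect_equal(ncol(px), 36L)  # 4 patterns x 9 half-lives
  g <- attr(px, "grid")
  expect_equal(nrow(unique(g[c("pattern", "dt50")])), 36L)

  one <- build_proxy_grid(net, patterns = "pop", dt50_grid = 10)
  expect_equal(ncol(one), 1L)

  withU <- build_proxy_grid(net, include_uniform = TRUE)
  expect_equal(ncol(withU), 45L)
  expect_true("U" %in% attr(withU, "grid")$pattern)
  # uniform pattern accumulates catchment area: at infinite DT50 it would be
  # the drainage area itself; at finite DT50 it is bounded by it
  expect_true(all(withU[, "U_dt1000"] <= net$reaches$drainage_area_km2 + 1e-9))
  expect_error(build_proxy_grid(net, patterns = "nope"), "unknown pattern")
})

test_that("noiseless synthetic loads are recovered exactly", {
  sc <- small_scenario(17, noise_sigma = 0, discharge_sdlog = 0,
                       loq_fraction = 0)
  net <- generate_patterns(generate_network(sc), sc)
  st <- generate_true_state(net, sc)
  obs <- generate_observations(st, sc)
  px <- build_proxy_grid(net)
  for (i in seq_len(nrow(sc$substances))) {
    o <- obs[obs$substance == sc$substances$name[i], ]
    cal <- grid_calibrate(px, compute_observed_loads(o))
    expect_equal(cal$pattern, sc$substances$pattern[i])
    expect_equal(cal$selected_dt50, sc$substances$true_dt50[i])
    expect_equal(cal$emission_factor, sc$substances$true_ef[i],
                 tolerance = 1e-6)
    expect_lt(cal$fits$distance[cal$selected], 1e-9)
  }
})

test_that("degenerate observations are rejected", {
  sc <- small_scenario(1)
  net <- generate_patterns(generate_network(sc), sc)
  px <- build_proxy_grid(net)
  zero <- data.frame(reach_id = net$reaches$reach_id[1:5],
                     load_ng_s = rep(0, 5))
  expect_error(grid_calibrate(px, zero), "fewer than 3")
})

test_that("ideal-point distance is zero iff the fit is ideal; ties break as documented", {
  expect_equal(riverload:::.ideal_distance(1, 0, 100), 0)
  expect_gt(riverload:::.ideal_distance(1, 1e-6, 100), 0)
  expect_gt(riverload:::.ideal_distance(0.999, 0, 100), 0)
  # constructed tie: two fits with identical distance, different r2
  fits <- data.frame(pattern = c("a", "b"), dt50 = c(1, 1),
                     distance = c(0.5, 0.5), r_squared = c(0.6, 0.9))
  sel <- order(fits$distance, -fits$r_squared, fits$dt50)[1]
  expect_equal(fits$pattern[sel], "b")
  # equal distance and r2 -> smaller dt50
  fits2 <- data.frame(pattern = "a", dt50 = c(100, 5),
                      distance = c(0.5, 0.5), r_squared = c(0.8, 0.8))
  expect_equal(fits2$dt50[order(fits2$distance, -fits2$r_squared,
                                fits2$dt50)[1]], 5)
})

test_that("assumed-pattern calibration reads the EF from that pattern's fits", {
  sc <- small_scenario(23, noise_sigma = 0, discharge_sdlog = 0,
                       loq_fraction = 0)
  net <- generate_patterns(generate_network(sc), sc)
  st <- generate_true_state(net, sc)
  obs <- generate_observations(st, sc)
  px <- build_proxy_grid(net)
  o <- obs[obs$substance == "popchem", ]
  loads <- compute_observed_loads(o)
  cal <- grid_calibrate(px, loads, assumed_pattern = "agri_km2")
  expect_equal(cal$pattern, "agri_km2")
  expect_equal(cal$best_pattern, "pop")  # the truth still wins overall
  in_pattern <- cal$fits[cal$fits$pattern == "agri_km2", ]
  expect_equal(cal$fits$distance[cal$selected], min(in_pattern$distance))
  expect_error(grid_calibrate(px, loads, assumed_pattern = "nope"),
               "not on the grid")
})

test_that("bootstrap CIs are deterministic, tight on exact data, and record-level", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- 3 * x
  b1 <- bootstrap_uncertainty(x, y, n_boot = 100, seed = 5)
  b2 <- bootstrap_uncertainty(x, y, n_boot = 100, seed = 5)
  expect_identical(b1, b2)
  expect_lt(diff(b1$slope_ci), 1e-9)  # exact-linear data -> zero-width CI
  expect_equal(unname(b1$slope_ci[1]), 3, tolerance = 1e-9)
  b3 <- bootstrap_uncertainty(x, y, n_boot = 100, seed = 6)
  expect_false(identical(b1$slope_boot, b3$slope_boot))
})

test_that("DT50 override re-reads the slope and reports the R2 drop", {
  sc <- small_scenario(31, noise_sigma = 0.2, loq_fraction = 0)
  net <- generate_patterns(generate_network(sc), sc)
  st <- generate_true_state(net, sc)
  obs <- generate_observations(st, sc)
  px <- build_proxy_grid(net)
  o <- obs[obs$substance == "popchem", ]
  cal <- grid_calibrate(px, compute_observed_loads(o),
                        assumed_pattern = "pop")
  same <- apply_dt50_override(cal, cal$modelled_dt50)
  expect_equal(same$emission_factor, cal$emission_factor)
  expect_equal(same$r2_drop, 0)
  # grid-extreme override: slope comes from that fit, r2 drop is reported
  over <- apply_dt50_override(cal, 1000)
  row <- cal$fits[cal$fits$pattern == "pop" & cal$fits$dt50 == 1000, ]
  expect_equal(over$emission_factor, row$slope)
  expect_equal(over$r2_drop,
               cal$fits$r_squared[cal$selected] - row$r_squared)
  expect_equal(over$modelled_dt50, cal$modelled_dt50)  # both retained
  expect_equal(over$selected_dt50, 1000)
  expect_error(apply_dt50_override(cal, 12), "not on the calibration grid")
})

test_that("r2 classes follow the reporting thresholds", {
  expect_equal(r2_class(c(0.6, 0.59, 0.41, 0.4, 0.2)),
               c("high", "medium", "medium", "low", "low"))
})
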