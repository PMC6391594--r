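#' Default pipeline configuration
#'
#' Nested list mirroring [synthetic_scenario()] plus stage options, stored
#' and exchanged as JSON. Sections: `scenario` (arguments to
#' [synthetic_scenario()]; `substances` as a data.frame/records),
#' `calibration` (`dt50_grid`, `include_uniform`, `normalizer`, `n_boot`),
#' `indicators` (`threshold`), `verification` (`rate_fractions`,
#' `flag_type`), `stages` (logical toggles).
#'
#' @param seed master seed, forwarded to the scenario.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    scenario = list(seed = seed),
    calibration = list(dt50_grid = dt50_grid_default(),
                       include_uniform = FALSE,
                       normalizer = "mean_load",
                       n_boot = 200),
    indicators = list(threshold = 0.25),
    verification = list(rate_fractions = c(0.1, 0.2, 0.5),
                        flag_type = "exceed_aa"),
    stages = list(simulate = TRUE, calibrate = TRUE, concentrations = TRUE,
                  indicators = TRUE, roc = TRUE, inventory = TRUE)
  )
}

#' Read a JSON pipeline configuration
#'
#' Missing keys fall back to [default_config()] values.
#' @param path JSON file path (or a list already parsed).
#' @param seed seed overriding the config's `scenario$seed` when not `NULL`.
#' @return Configuration list.
#' @export
read_config <- function(path, seed = NULL) {
  cfg <- if (is.character(path))
    jsonlite::fromJSON(path, simplifyVector = TRUE) else path
  base <- default_config()
  merge_lists <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]) &&
                       !is.data.frame(over[[k]]))
        merge_lists(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  cfg <- merge_lists(base, cfg)
  if (!is.null(seed)) cfg$scenario$seed <- as.integer(seed)
  cfg
}

.log_line <- function(con, level, msg, min_level = "info") {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  line <- sprintf("[%s] %s", level, msg)
  if (!is.null(con)) writeLines(line, con)
  if (levels[[level]] >= levels[[min_level]]) message(line)
  invisible(NULL)
}

.write_csv <- function(df, outdir, name) {
  path <- file.path(outdir, name)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

#' Run the full pipeline
#'
#' Simulates (or loads) the inputs, then runs, per the stage toggles:
#' proxy-grid calibration of each substance, modelled concentrations,
#' point-source impact indicators and district shares, prediction-rate
#' curves against the exceedance reports, the district emission inventory
#' and the loads to sea. Every stage failure aborts with a stage-named
#' diagnostic. All outputs are CSV; a `manifest.json` records the config,
#' package version, seed and the MD5 checksum of every file written, and a
#' `run.log` records progress. Reruns with the same config produce
#' byte-identical numeric outputs.
#'
#' @param config a configuration list (see [default_config()]) or the path
#'   of a JSON config file.
#' @param outdir output directory (created if needed).
#' @param seed optional seed override.
#' @param log_level minimum console log level (`"debug"`, `"info"`,
#'   `"warn"`, `"error"`).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(), outdir = "riverload_out",
                         seed = NULL, log_level = "info") {
  cfg <- read_config(config, seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(outdir, "run.log"), open = "wt")
  on.exit(close(logcon), add = TRUE)
  logf <- function(level, ...) .log_line(logcon, level, paste0(...), log_level)
  logf("info", "riverload pipeline started, seed = ", cfg$scenario$seed)
  stage <- function(name, enabled, fun) {
    if (!isTRUE(enabled)) { logf("info", "stage ", name, ": skipped"); return(NULL) }
    logf("info", "stage ", name, ": running")
    tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  res <- list(config = cfg)
  written <- character(0)

  sim <- stage("simulate", cfg$stages$simulate, function() {
    sc_args <- cfg$scenario
    if (!is.null(sc_args$substances) && !is.data.frame(sc_args$substances))
      sc_args$substances <- as.data.frame(sc_args$substances)
    sc <- do.call(synthetic_scenario, sc_args)
    out <- simulate_scenario(sc)
    written <<- c(written,
      write_network_csv(out$network, file.path(outdir, "network.csv")),
      .write_csv(out$observations, outdir, "observations.csv"),
      .write_csv(out$point_sources, outdir, "point_sources.csv"),
      .write_csv(out$exceedances, outdir, "exceedances.csv"),
      .write_csv(do.call(rbind, lapply(names(out$state$loads), function(s)
        data.frame(reach_id = out$network$reaches$reach_id, substance = s,
                   true_load_ng_s = unname(out$state$loads[[s]]),
                   true_conc_ug_L = unname(out$state$conc[[s]])))),
        outdir, "truth.csv"))
    out$scenario <- sc
    out
  })
  if (is.null(sim)) stop("stage 'simulate' is required by the current ",
                         "pipeline configuration")
  res$sim <- sim
  net <- sim$network

  calib <- stage("calibrate", cfg$stages$calibrate, function() {
    proxies <- build_proxy_grid(net, dt50_grid = cfg$calibration$dt50_grid,
                                include_uniform =
                                  isTRUE(cfg$calibration$include_uniform))
    grid_df <- attr(proxies, "grid")
    written <<- c(written, .write_csv(
      cbind(reach_id = rownames(proxies), as.data.frame(proxies)),
      outdir, "proxies.csv"))
    rows <- list(); results <- list()
    subs_cfg <- sim$scenario$substances
    for (s in unique(sim$observations$substance)) {
      obs <- sim$observations[sim$observations$substance == s, , drop = FALSE]
      loads <- compute_observed_loads(obs)
      assumed <- subs_cfg$pattern[match(s, subs_cfg$name)]
      cal <- grid_calibrate(proxies, loads,
                            normalizer = cfg$calibration$normalizer,
                            assumed_pattern = assumed)
      selfit <- cal$fits[cal$selected, ]
      px <- proxies[match(cal$observed_loads$reach_id, rownames(proxies)),
                    grid_df$column[grid_df$pattern == cal$pattern &
                                     grid_df$dt50 == cal$selected_dt50]]
      boot <- bootstrap_uncertainty(px, cal$observed_loads$load_ng_s,
                                    n_boot = cfg$calibration$n_boot,
                                    seed = .stage_seed(cfg$scenario$seed,
                                                       paste0("boot_", s)))
      results[[s]] <- cal
      rows[[s]] <- data.frame(
        substance = s, pattern = cal$pattern, best_pattern = cal$best_pattern,
        modelled_dt50 = cal$modelled_dt50, selected_dt50 = cal$selected_dt50,
        emission_factor = cal$emission_factor,
        r_squared = selfit$r_squared, r2_class = r2_class(selfit$r_squared),
        intercept = selfit$intercept, distance = selfit$distance,
        n = selfit$n,
        slope_ci_lo = boot$slope_ci[1], slope_ci_hi = boot$slope_ci[2],
        intercept_ci_lo = boot$intercept_ci[1],
        intercept_ci_hi = boot$intercept_ci[2])
    }
    written <<- c(written, .write_csv(do.call(rbind, c(rows,
      list(make.row.names = FALSE))), outdir, "calibration.csv"))
    list(results = results, table = do.call(rbind, c(rows,
      list(make.row.names = FALSE))), proxies = proxies)
  })
  res$calibration <- calib

  conc_stage <- stage("concentrations",
                      cfg$stages$concentrations && !is.null(calib), function() {
    Q <- accumulate_discharge(net)
    conc <- list()
    rows <- list()
    for (s in names(calib$results)) {
      cal <- calib$results[[s]]
      L <- cal$emission_factor *
        accumulate_decayed(net, cal$pattern, cal$selected_dt50)
      conc[[s]] <- concentration(L, Q)
      rows[[s]] <- data.frame(reach_id = net$reaches$reach_id, substance = s,
                              load_ng_s = unname(L), Q_m3s = unname(Q),
                              conc_ug_L = unname(conc[[s]]))
    }
    written <<- c(written, .write_csv(do.call(rbind, c(rows,
      list(make.row.names = FALSE))), outdir, "concentrations.csv"))
    list(Q = Q, conc = conc)
  })
  res$concentrations <- conc_stage

  ind <- stage("indicators", cfg$stages$indicators, function() {
    subs <- sim$scenario$substances
    diffuse <- sim$state$loads
    point <- lapply(seq_len(nrow(subs)), function(i) {
      pe <- sim$point_sources[sim$point_sources$substance == subs$name[i], ,
                              drop = FALSE]
      if (nrow(pe)) point_loads(net, pe, subs$true_dt50[i])
      else stats::setNames(rep(0, nrow(net$reaches)), net$reaches$reach_id)
    })
    names(point) <- subs$name
    zw <- impact_indicators(diffuse, point,
                            threshold = cfg$indicators$threshold)
    diffuse_emis <- lapply(seq_len(nrow(subs)), function(i)
      subs$true_ef[i] * as.numeric(net$reaches[[subs$pattern[i]]]))
    names(diffuse_emis) <- subs$name
    shares <- district_point_share(net, sim$point_sources, diffuse_emis)
    written <<- c(written, .write_csv(zw, outdir, "indicators.csv"),
                  .write_csv(shares, outdir, "district_point_share.csv"))
    list(zw = zw, shares = shares, point_loads = point)
  })
  res$indicators <- ind

  roc <- stage("roc", cfg$stages$roc && !is.null(conc_stage), function() {
    flag_col <- cfg$verification$flag_type
    rows <- list(); curves <- list()
    for (s in names(conc_stage$conc)) {
      ex <- sim$exceedances[sim$exceedances$substance == s, , drop = FALSE]
      flags <- stats::setNames(ex[[flag_col]] == 1, ex$reach_id)
      flags <- flags[net$reaches$reach_id]
      prc <- prediction_rate_curve(unname(conc_stage$conc[[s]]), unname(flags),
                                   cfg$verification$rate_fractions)
      obs <- sim$observations[sim$observations$substance == s, , drop = FALSE]
      orc <- observed_concentration_roc(obs, data.frame(
        reach_id = ex$reach_id, flag = ex[[flag_col]] == 1),
        cfg$verification$rate_fractions)
      curves[[s]] <- list(modelled = prc, observed = orc)
      if (!is.null(prc$curve))
        written <<- c(written, .write_csv(prc$curve, outdir,
                                          paste0("roc_curve_", s, ".csv")))
      rate_row <- function(p, which) if (is.null(p$curve)) NULL else
        data.frame(substance = s, population = which,
                   t(as.matrix(p$rates)), auc = p$auc,
                   n_exceedances = p$n_exceedances,
                   label = performance_label(p$rates[[1]],
                                             cfg$verification$rate_fractions[1]))
      rows[[s]] <- rbind(rate_row(prc, "modelled"), rate_row(orc, "observed"))
    }
    tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (!is.null(tab))
      written <<- c(written, .write_csv(tab, outdir, "roc_rates.csv"))
    list(curves = curves, rates = tab)
  })
  res$roc <- roc

  inv <- stage("inventory", cfg$stages$inventory, function() {
    subs_tab <- if (!is.null(calib))
      data.frame(substance = calib$table$substance,
                 pattern = calib$table$pattern,
                 emission_factor = calib$table$emission_factor)
    else
      data.frame(substance = sim$scenario$substances$name,
                 pattern = sim$scenario$substances$pattern,
                 emission_factor = sim$scenario$substances$true_ef)
    inv_tab <- build_inventory(net, subs_tab, sim$point_sources)
    subs <- sim$scenario$substances
    total_loads <- lapply(seq_len(nrow(subs_tab)), function(i) {
      s <- subs_tab$substance[i]
      L <- subs_tab$emission_factor[i] *
        accumulate_decayed(net, subs_tab$pattern[i],
                           if (!is.null(calib))
                             calib$table$selected_dt50[i]
                           else subs$true_dt50[i])
      pe <- sim$point_sources[sim$point_sources$substance == s, , drop = FALSE]
      if (nrow(pe)) L <- L + point_loads(net, pe,
        if (!is.null(calib)) calib$table$selected_dt50[i]
        else subs$true_dt50[i])
      L
    })
    names(total_loads) <- subs_tab$substance
    sea_tab <- sea_loads(net, total_loads)
    written <<- c(written, .write_csv(inv_tab, outdir, "inventory.csv"),
                  .write_csv(sea_tab, outdir, "sea_loads.csv"))
    list(inventory = inv_tab, sea = sea_tab)
  })
  res$inventory <- inv

  manifest <- list(
    package = "riverload",
    version = as.character(utils::packageVersion("riverload")),
    seed = cfg$scenario$seed,
    config = cfg,
    outputs = as.list(stats::setNames(unname(tools::md5sum(written)),
                                      basename(written))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  logf("info", "pipeline finished: ", length(written), " output file(s)")
  invisible(res)
}

#' Command-line entry point
#'
#' Dispatcher behind `inst/cli/riverload.R`. Subcommands: `simulate`,
#' `proxy`, `calibrate`, `concentrations`, `indicators`, `roc`, `inventory`
#' run the corresponding stage (plus the simulation they depend on); `run`
#' executes the whole pipeline. Global flags: `--config <json>`,
#' `--seed <int>`, `--outdir <dir>`, `--log-level <level>`.
#'
#' @param args character vector of command-line arguments (subcommand
#'   first).
#' @return Invisibly, the [run_pipeline()] result.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  subcommands <- c("simulate", "proxy", "calibrate", "concentrations",
                   "indicators", "roc", "inventory", "run")
  if (!length(args) || !args[1] %in% subcommands)
    stop("usage: riverload <", paste(subcommands, collapse = "|"),
         "> [--config FILE] [--seed INT] [--outdir DIR] [--log-level LEVEL]")
  sub <- args[1]
  opts <- list(config = NULL, seed = NULL, outdir = "riverload_out",
               log_level = "info")
  rest <- args[-1]
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    key <- gsub("-", "_", key)
    if (!key %in% names(opts)) stop("unknown option '", rest[i], "'")
    if (i == length(rest)) stop("option '", rest[i], "' needs a value")
    opts[[key]] <- rest[i + 1L]
    i <- i + 2L
  }
  cfg <- if (is.null(opts$config)) default_config() else read_config(opts$config)
  # a single stage subcommand: run simulate plus that stage only
  if (sub != "run") {
    stage_of <- c(simulate = NA, proxy = "calibrate", calibrate = "calibrate",
                  concentrations = "concentrations", indicators = "indicators",
                  roc = "roc", inventory = "inventory")
    for (s in names(cfg$stages)) cfg$stages[[s]] <- FALSE
    cfg$stages$simulate <- TRUE
    tgt <- stage_of[[sub]]
    if (!is.na(tgt)) cfg$stages[[tgt]] <- TRUE
    if (sub %in% c("concentrations", "roc")) cfg$stages$calibrate <- TRUE
    if (sub == "roc") cfg$stages$concentrations <- TRUE
  }
  run_pipeline(cfg, outdir = opts$outdir, seed = opts$seed,
               log_level = opts$log_level)
}
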