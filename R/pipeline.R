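# Pipeline orchestration: a single declarative YAML config drives
# simulate -> validate -> prepare -> fit -> report, with JSON-lines
# logging and provenance (config hash + seed) embedded in every output.

#' Read a pipeline run configuration
#'
#' The config is a single YAML file with keys `seed` (required), `outdir`,
#' `overwrite`, and either `simulate:` (world-config fields for on-the-fly
#' synthetic data) or `data:` (paths `manta`, `catch`, `transects`);
#' optional `sampler:` (`chains`, `warmup`, `iter`) and `priors:`
#' overrides.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("run config must set a seed", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$outdir)) cfg$outdir <- "reefcots_out"
  if (is.null(cfg$overwrite)) cfg$overwrite <- FALSE
  sampler <- cfg$sampler
  if (is.null(sampler)) sampler <- list()
  if (is.null(sampler$chains)) sampler$chains <- 2L
  if (is.null(sampler$warmup)) sampler$warmup <- 500L
  if (is.null(sampler$iter)) sampler$iter <- 1000L
  cfg$sampler <- sampler
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "hash")])
  structure(cfg, class = "run_config")
}

provenance_line <- function(config) {
  sprintf("# reefcots provenance: config_hash=%s seed=%d", config$hash,
          config$seed)
}

#' Write a table as CSV with an embedded provenance header
#'
#' @param x Data frame.
#' @param path Output path.
#' @param config A `run_config` (provides hash and seed).
#' @return `path`, invisibly.
#' @export
write_output_csv <- function(x, path, config) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(provenance_line(config), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Read a provenance-headed CSV written by [write_output_csv()]
#' @param path File path.
#' @return Tibble.
#' @export
read_output_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}

#' JSON-lines run logger
#'
#' @param path Log file (appended to).
#' @return A function `log(level, event, ...)` writing one JSON object per
#'   call with a timestamp.
#' @export
jsonl_logger <- function(path) {
  function(level, event, ...) {
    rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  level = level, event = event), list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", file = path,
        append = TRUE, sep = "")
    invisible(NULL)
  }
}

ensure_outdir <- function(config) {
  d <- config$outdir
  if (dir.exists(d) && length(list.files(d)) > 0 && !isTRUE(config$overwrite)) {
    stop("output directory ", d,
         " is not empty; set overwrite: true to replace its contents",
         call. = FALSE)
  }
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

load_world <- function(config, log) {
  if (!is.null(config$simulate)) {
    wc_args <- config$simulate
    wc_args$seed <- config$seed
    wc <- do.call(world_config, wc_args)
    log("info", "simulate", seed = config$seed)
    simulate_world(wc)
  } else if (!is.null(config$data)) {
    log("info", "load_data", manta = config$data$manta)
    list(manta = read_manta_csv(config$data$manta),
         catch = read_catch_csv(config$data$catch),
         transects = read_transects_csv(config$data$transects),
         truth = NULL)
  } else {
    stop("run config needs either a simulate: or a data: section", call. = FALSE)
  }
}

#' Prepare model-ready datasets from the raw tables
#'
#' @param world List with `manta`, `catch`, `transects` tables (and
#'   optionally `truth` carrying length-weight coefficients).
#' @param lw Length-weight coefficient table; defaults to the synthetic
#'   fixture table in `world$truth`.
#' @return List with `reef_year`, `cots_open` (fisheries stream),
#'   `cots_all`, `catch_sy`, `reserve_sites` and a combined audit tibble.
#' @export
prepare_datasets <- function(world, lw = NULL) {
  if (is.null(lw)) {
    if (is.null(world$truth)) {
      stop("length-weight coefficients required (lw) when no truth table is present",
           call. = FALSE)
    }
    lw <- world$truth$lw_coeffs
  }
  reef_year <- summarise_tows(world$manta)
  cots_open <- resolve_duplicates(reef_year, fisheries_stream = TRUE)
  cots_all <- resolve_duplicates(reef_year, fisheries_stream = FALSE)
  catch_sy <- aggregate_catch(world$catch)
  reserve_sites <- prepare_reserve_sites(world$transects, lw)
  audit <- dplyr::bind_rows(
    dplyr::mutate(audit_log(cots_open), stage = "resolve_duplicates_fisheries"),
    dplyr::mutate(audit_log(cots_all), stage = "resolve_duplicates"),
    dplyr::mutate(audit_log(catch_sy), stage = "aggregate_catch"),
    dplyr::mutate(audit_log(reserve_sites), stage = "reserve_sites"))
  list(reef_year = reef_year, cots_open = cots_open, cots_all = cots_all,
       catch_sy = catch_sy, reserve_sites = reserve_sites, audit = audit)
}

#' Run the full pipeline from a config
#'
#' Stages: simulate (or load), validate, prepare, fit the zoning model,
#' the fisheries-lag grid and the reserve fish models, then write tidy
#' results tables, figures and logs under `outdir`.
#'
#' @param config A `run_config` from [read_run_config()].
#' @param stages Subset of
#'   `c("prepare", "fit-zoning", "fit-lag", "fit-reserve", "report")`.
#' @return Invisibly, a list with the prepared data and fitted results.
#' @export
run_pipeline <- function(config,
                         stages = c("prepare", "fit-zoning", "fit-lag",
                                    "fit-reserve", "report")) {
  d <- ensure_outdir(config)
  log <- jsonl_logger(file.path(d, "run_log.jsonl"))
  log("info", "start", config_hash = config$hash, seed = config$seed)
  world <- load_world(config, log)
  validate_manta(world$manta)
  validate_catch(world$catch)
  validate_transects(world$transects)
  log("info", "validated", manta_rows = nrow(world$manta),
      catch_rows = nrow(world$catch), transect_rows = nrow(world$transects))
  out <- list(world = world)

  if ("prepare" %in% stages) {
    prep <- prepare_datasets(world)
    out$prep <- prep
    write_output_csv(prep$cots_open, file.path(d, "cots_siteyear_open.csv"), config)
    write_output_csv(prep$catch_sy, file.path(d, "catch_siteyear.csv"), config)
    rs <- prep$reserve_sites
    write_output_csv(rs, file.path(d, "reserve_sites.csv"), config)
    ad <- prep$audit
    con <- file(file.path(d, "prepare_audit.jsonl"), "wt")
    for (i in seq_len(nrow(ad))) {
      writeLines(jsonlite::toJSON(as.list(ad[i, ]), auto_unbox = TRUE), con)
    }
    close(con)
    log("info", "prepared", site_years_open = nrow(prep$cots_open),
        audit_entries = nrow(ad))
  }
  sm <- config$sampler
  if ("fit-zoning" %in% stages) {
    z <- run_cots_zoning_model(world$manta, chains = sm$chains,
                               warmup = sm$warmup, iter = sm$iter,
                               seed = config$seed)
    out$zoning <- z
    write_output_csv(z$summary, file.path(d, "zoning_parameters.csv"), config)
    write_output_csv(z$derived, file.path(d, "zoning_derived_effects.csv"), config)
    write_draws(z$fit, file.path(d, "zoning"))
    log(if (z$fit$converged) "info" else "warning", "fit_zoning",
        converged = z$fit$converged)
  }
  if ("fit-lag" %in% stages) {
    if (is.null(out$prep)) out$prep <- prepare_datasets(world)
    grid <- run_fisheries_lag_grid(out$prep$cots_open, out$prep$catch_sy,
                                   chains = sm$chains, warmup = sm$warmup,
                                   iter = sm$iter, seed = config$seed)
    out$lag_grid <- grid
    write_output_csv(grid, file.path(d, "fisheries_lag_grid.csv"), config)
    log("info", "fit_lag_grid", cells = nrow(grid),
        failed = sum(!is.na(grid$error)))
  }
  if ("fit-reserve" %in% stages) {
    if (is.null(out$prep)) out$prep <- prepare_datasets(world)
    rsv <- run_reserve_fish_models(out$prep$reserve_sites,
                                   chains = sm$chains, warmup = sm$warmup,
                                   iter = sm$iter, seed = config$seed)
    out$reserve <- rsv
    write_output_csv(rsv, file.path(d, "reserve_fish_effects.csv"), config)
    log("info", "fit_reserve", cells = nrow(rsv))
  }
  if ("report" %in% stages) {
    write_report(out, d, config)
    log("info", "report")
  }
  log("info", "done")
  invisible(out)
}

#' Posterior interval plot for the fisheries-lag grid
#'
#' @param grid Result table from [run_fisheries_lag_grid()].
#' @return A ggplot object.
#' @export
plot_lag_grid <- function(grid) {
  g <- dplyr::filter(grid, !is.na(.data$median))
  ggplot2::ggplot(g, ggplot2::aes(x = .data$median, y = factor(.data$lag))) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$l95, xmax = .data$u95),
                            height = 0, colour = "steelblue3") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$l60, xmax = .data$u60),
                            height = 0, linewidth = 1.2, colour = "steelblue4") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "biomass-removal scaling exponent (median, 60% and 95% CI)",
                  y = "time lag (years)") +
    ggplot2::theme_minimal()
}

#' Fold-change plot for the reserve fish models
#'
#' @param rsv Result table from [run_reserve_fish_models()].
#' @return A ggplot object.
#' @export
plot_reserve_folds <- function(rsv) {
  g <- dplyr::filter(rsv, !is.na(.data$fold_median))
  ggplot2::ggplot(g, ggplot2::aes(x = .data$fold_median, y = .data$group)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$fold_l95,
                                         xmax = .data$fold_u95), height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~response) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "unfished : fished fold change (median, 95% CI)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

write_report <- function(out, d, config) {
  lines <- c("reefcots pipeline report", provenance_line(config), "")
  if (!is.null(out$zoning)) {
    s <- out$zoning$summary
    dv <- out$zoning$derived
    zf <- dv[dv$quantity == "zoning_fold", ]
    rf <- dv[dv$quantity == "reefyear_range_factor", ]
    lines <- c(lines, "Zoning model (tow-level CoTS counts):",
      sprintf("  open:closed fold ratio %.3g [%.3g, %.3g]",
              zf$median, zf$l95, zf$u95),
      sprintf("  reef-year range factor %.3g [%.3g, %.3g]",
              rf$median, rf$l95, rf$u95),
      sprintf("  coral-cover slope %.3g [%.3g, %.3g] (%s)",
              s$median[s$parameter == "b2"], s$l95[s$parameter == "b2"],
              s$u95[s$parameter == "b2"], s$class[s$parameter == "b2"]), "")
    ggplot2::ggsave(file.path(d, "zoning_effects.pdf"), width = 5, height = 4,
                    plot = plot_derived_effects(out$zoning$derived))
  }
  if (!is.null(out$lag_grid)) {
    n95 <- sum(out$lag_grid$class == ">95%", na.rm = TRUE)
    lines <- c(lines, sprintf(
      "Fisheries-lag grid: %d cells, %d classified >95%% (expected false signals under no effect: ~%.1f)",
      nrow(out$lag_grid), n95, 0.05 * nrow(out$lag_grid)), "")
    ggplot2::ggsave(file.path(d, "lag_grid.pdf"), width = 8, height = 6,
                    plot = plot_lag_grid(out$lag_grid))
  }
  if (!is.null(out$reserve)) {
    lines <- c(lines, "Reserve fish models (unfished:fished folds):",
      sprintf("  %s %s: %.2f [%.2f, %.2f] (%s)", out$reserve$group,
              out$reserve$response, out$reserve$fold_median,
              out$reserve$fold_l95, out$reserve$fold_u95,
              out$reserve$class), "")
    ggplot2::ggsave(file.path(d, "reserve_folds.pdf"), width = 7, height = 5,
                    plot = plot_reserve_folds(out$reserve))
  }
  writeLines(lines, file.path(d, "report.txt"))
}

#' Posterior interval plot for derived zoning effects
#'
#' @param derived Table from [derive_fold_effects()].
#' @return A ggplot object.
#' @export
plot_derived_effects <- function(derived) {
  g <- dplyr::filter(derived, .data$quantity %in%
                       c("zoning_fold", "reefyear_range_factor"))
  ggplot2::ggplot(g, ggplot2::aes(x = .data$median, y = .data$quantity)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$l95, xmax = .data$u95),
                            height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "fold (median, 95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
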