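# Synthetic reef world generator. Stands in for the restricted long-term
# monitoring (manta tow, belt transect) and fisheries logbook extracts:
# every downstream stage of the pipeline can be exercised against tables
# whose generating parameters are known exactly.

sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 11 + 1009 * k) %% 2147483629)
}

#' Configuration of a synthetic reef world
#'
#' @param n_grid_sites Number of 6x6 nautical-mile fisheries logbook
#'   reporting sites.
#' @param reefs_per_site Reefs surveyed per grid site.
#' @param years Integer vector of consecutive reporting years (1 July - 30
#'   June, labelled by end year).
#' @param fish_groups Fish group labels (default the six study groups).
#' @param frac_unfished Proportion of reefs zoned closed (no-take).
#' @param tows_per_reef_year Manta tows per reef per year (0 allowed, gives
#'   an empty survey table).
#' @param transects_per_reef Belt transects per reef per survey year,
#'   divided over three sites (default 15 = 3 sites x 5 transects).
#' @param n_reef_pairs Number of paired (one open, one closed) reefs in the
#'   fish survey design.
#' @param fish_years Years in which the paired-reef fish surveys run
#'   (default every second year of `years`).
#' @param seed Integer seed; all three tables derive their own sub-seed
#'   from it so each is independently reproducible.
#' @return A `world_config` list.
#' @export
world_config <- function(n_grid_sites = 8,
                         reefs_per_site = 2,
                         years = 1994:2008,
                         fish_groups = cots_fish_groups(),
                         frac_unfished = 0.3,
                         tows_per_reef_year = 10,
                         transects_per_reef = 15,
                         n_reef_pairs = 8,
                         fish_years = NULL,
                         seed = 1L) {
  stopifnot(n_grid_sites >= 1, reefs_per_site >= 1, length(years) >= 1,
            all(diff(years) == 1), frac_unfished >= 0, frac_unfished <= 1,
            tows_per_reef_year >= 0, transects_per_reef >= 1,
            transects_per_reef %% 3 == 0, n_reef_pairs >= 1,
            length(fish_groups) >= 1)
  if (is.null(fish_years)) fish_years <- years[seq(1, length(years), by = 2)]
  structure(list(n_grid_sites = as.integer(n_grid_sites),
                 reefs_per_site = as.integer(reefs_per_site),
                 years = as.integer(years),
                 fish_groups = fish_groups,
                 frac_unfished = frac_unfished,
                 tows_per_reef_year = as.integer(tows_per_reef_year),
                 transects_per_reef = as.integer(transects_per_reef),
                 n_reef_pairs = as.integer(n_reef_pairs),
                 fish_years = as.integer(fish_years),
                 seed = as.integer(seed)),
            class = "world_config")
}

default_zoning_multipliers <- function(groups) {
  # density and length fold effects of no-take zoning per group; the
  # implied biomass folds (density x length^3 under the fixture
  # length-weight exponent) span roughly 1.4 to 2.1
  d <- c(1.25, 1.35, 1.40, 1.30, 1.45, 1.50)
  l <- c(1.04, 1.06, 1.08, 1.05, 1.09, 1.12)
  tibble::tibble(group = groups,
                 density = rep_len(d, length(groups)),
                 length = rep_len(l, length(groups)))
}

default_catch_correlation <- function(groups) {
  k <- length(groups)
  r <- matrix(0.5, k, k)
  diag(r) <- 1
  rownames(r) <- colnames(r) <- groups
  hi <- function(a, b, v) {
    if (all(c(a, b) %in% groups)) r[a, b] <<- r[b, a] <<- v
  }
  hi("Serranidae", "Plectropomus_Variola", 0.95)
  hi("Lethrinidae", "Lethrinus_miniatus_nebulosus", 0.92)
  r
}

#' Ground-truth parameters of a synthetic reef world
#'
#' Houses the generative twins of the quantities the analyses estimate:
#' the biomass-removal scaling exponents b(g, x), the zoning log fold
#' effect on CoTS density, the coral-cover slope, the reef-year intercept
#' SD, and the per-group no-take multipliers on fish density and length.
#'
#' @param biomass_slopes Tibble with columns `group`, `lag`, `slope`
#'   giving nonzero b(g, x) values (default: all zero).
#' @param cots_intercept Log mean CoTS count per 2-min tow on closed reefs
#'   at coral cover 0. The default places most reef-years near zero while
#'   outbreak reef-years reach large counts, matching the zero-heavy,
#'   hugely overdispersed structure of manta-tow data.
#' @param zoning_log_ratio Log fold effect of open zoning on CoTS density
#'   (default `log(2.8)`).
#' @param coral_slope_cots Coral-cover slope on log CoTS density
#'   (default -0.45).
#' @param sigma_reefyear SD of reef-year intercepts on the log scale
#'   (default 3.77).
#' @param nb_dispersion Negative-binomial size of tow counts.
#' @param coral_slope_zero,coral_slope_pos Coral-cover slopes on the zero
#'   (logit) and positive (log) components of the site-year hurdle twin
#'   used by [simulate_lag_siteyears()].
#' @param hurdle_zero_intercept Baseline logit probability of a zero
#'   site-year density in the hurdle twin (default 0: zero-heavy once the
#'   positive coral slope is added). Tow-level surveys are unaffected:
#'   their zeros arise from the count process alone.
#' @param hurdle_pos_intercept Log mean positive site-year density
#'   (individuals per minute) at coral cover 0 and centred catch.
#' @param hurdle_gamma_shape Gamma shape of positive site-year densities.
#' @param sigma_site SD of grid-site intercepts in the hurdle twin.
#' @param zoning_fish_multipliers Tibble `group`, `density`, `length` of
#'   fold effects of no-take zoning on fish transect counts and lengths.
#' @param catch_correlation Cross-group correlation matrix of log catch.
#' @param catch_meanlog,catch_sdlog Log-normal parameters of annual
#'   retained catch (kg) per grid-site and group.
#' @param site_catch_sd SD of persistent per-site log-catch offsets.
#' @param fishery_shares Named shares splitting group catch across the
#'   four fisheries.
#' @param coral_shape1,coral_shape2 Beta parameters of the latent reef-year
#'   coral cover.
#' @param cover_kappa Concentration of tow-level cover around the
#'   reef-year latent cover.
#' @param fish_count_mu Mean fish count per 250 m2 transect on fished
#'   reefs.
#' @param fish_count_size Negative-binomial size of transect counts.
#' @param fish_effect_sds Named numeric vector of SDs for lognormal
#'   pair/reef/site/year effects on transect counts.
#' @param length_median_cm Median total length (cm) on fished reefs.
#' @param length_sdlog Log-scale SD of individual lengths.
#' @param lw_coeffs Length-weight coefficient table (`group`, `a`, `b`);
#'   the defaults are synthetic test fixtures, not literature values.
#' @param groups Group labels the defaults are built for.
#' @return A `truth_params` list.
#' @export
truth_params <- function(biomass_slopes = tibble::tibble(group = character(0),
                                                         lag = integer(0),
                                                         slope = numeric(0)),
                         cots_intercept = -8.2,
                         zoning_log_ratio = log(2.8),
                         coral_slope_cots = -0.45,
                         sigma_reefyear = 3.77,
                         nb_dispersion = 0.6,
                         coral_slope_zero = 1.0,
                         coral_slope_pos = -0.45,
                         hurdle_zero_intercept = 0,
                         hurdle_pos_intercept = log(0.15),
                         hurdle_gamma_shape = 1.2,
                         sigma_site = 0.4,
                         zoning_fish_multipliers = NULL,
                         catch_correlation = NULL,
                         catch_meanlog = log(500),
                         catch_sdlog = 1.5,
                         site_catch_sd = 0.7,
                         fishery_shares = c(commercial_line = 0.70,
                                            commercial_net = 0.10,
                                            commercial_trawl = 0.05,
                                            charter = 0.15),
                         coral_shape1 = 2,
                         coral_shape2 = 4,
                         cover_kappa = 30,
                         fish_count_mu = 5,
                         fish_count_size = 3,
                         fish_effect_sds = c(pair = 0.3, reef = 0.2,
                                             site = 0.2, year = 0.2),
                         length_median_cm = 30,
                         length_sdlog = 0.25,
                         lw_coeffs = NULL,
                         groups = cots_fish_groups()) {
  if (is.null(zoning_fish_multipliers)) {
    zoning_fish_multipliers <- default_zoning_multipliers(groups)
  }
  if (is.null(catch_correlation)) {
    catch_correlation <- default_catch_correlation(groups)
  }
  if (is.null(lw_coeffs)) {
    lw_coeffs <- tibble::tibble(group = groups, a = 0.02, b = 3)
  }
  stopifnot(sigma_reefyear >= 0, nb_dispersion > 0,
            all(zoning_fish_multipliers$density > 0),
            all(zoning_fish_multipliers$length > 0),
            abs(sum(fishery_shares) - 1) < 1e-8)
  check_correlation_matrix(catch_correlation)
  structure(list(biomass_slopes = biomass_slopes,
                 cots_intercept = cots_intercept,
                 zoning_log_ratio = zoning_log_ratio,
                 coral_slope_cots = coral_slope_cots,
                 sigma_reefyear = sigma_reefyear,
                 nb_dispersion = nb_dispersion,
                 coral_slope_zero = coral_slope_zero,
                 coral_slope_pos = coral_slope_pos,
                 hurdle_zero_intercept = hurdle_zero_intercept,
                 hurdle_pos_intercept = hurdle_pos_intercept,
                 hurdle_gamma_shape = hurdle_gamma_shape,
                 sigma_site = sigma_site,
                 zoning_fish_multipliers = zoning_fish_multipliers,
                 catch_correlation = catch_correlation,
                 catch_meanlog = catch_meanlog,
                 catch_sdlog = catch_sdlog,
                 site_catch_sd = site_catch_sd,
                 fishery_shares = fishery_shares,
                 coral_shape1 = coral_shape1,
                 coral_shape2 = coral_shape2,
                 cover_kappa = cover_kappa,
                 fish_count_mu = fish_count_mu,
                 fish_count_size = fish_count_size,
                 fish_effect_sds = fish_effect_sds,
                 length_median_cm = length_median_cm,
                 length_sdlog = length_sdlog,
                 lw_coeffs = lw_coeffs),
            class = "truth_params")
}

check_correlation_matrix <- function(r) {
  if (!is.matrix(r) || nrow(r) != ncol(r)) {
    stop("catch correlation must be a square matrix", call. = FALSE)
  }
  if (max(abs(r - t(r))) > 1e-10) {
    stop("catch correlation matrix is not symmetric", call. = FALSE)
  }
  if (max(abs(diag(r) - 1)) > 1e-10) {
    stop("catch correlation matrix must have unit diagonal", call. = FALSE)
  }
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf(
      "catch correlation matrix is not positive semi-definite (smallest eigenvalue = %.6g)",
      min(ev)), call. = FALSE)
  }
  invisible(r)
}

grid_site_labels <- function(config) {
  sprintf("S%02d", seq_len(config$n_grid_sites))
}

world_reefs <- function(config) {
  sites <- grid_site_labels(config)
  reefs <- expand.grid(grid_site = sites,
                       reef_no = seq_len(config$reefs_per_site),
                       stringsAsFactors = FALSE)
  reefs$reef_id <- sprintf("%s_R%d", reefs$grid_site, reefs$reef_no)
  n_closed <- round(config$frac_unfished * nrow(reefs))
  closed <- sample(nrow(reefs), n_closed)
  reefs$zoning <- "open"
  reefs$zoning[closed] <- "closed"
  tibble::as_tibble(reefs[c("grid_site", "reef_id", "zoning")])
}

#' Simulate fisheries retained-catch tables
#'
#' Annual retained catch (kg) per grid-site, year, fish group and fishery.
#' Log catch across groups follows a multivariate normal with the
#' configured cross-group correlation, a persistent per-site offset, and
#' fixed shares splitting the group total across the four fisheries.
#'
#' @param config A [world_config()].
#' @param truth A [truth_params()].
#' @return Catch tibble with columns `grid_site`, `year`, `fishery`,
#'   `group`, `retained_kg`.
#' @export
simulate_catch_tables <- function(config, truth) {
  stopifnot(inherits(config, "world_config"), inherits(truth, "truth_params"))
  groups <- config$fish_groups
  r <- truth$catch_correlation[groups, groups, drop = FALSE]
  check_correlation_matrix(r)
  set.seed(sub_seed(config$seed, 1))
  sites <- grid_site_labels(config)
  # catch records extend back far enough to support the longest lag
  years <- (min(config$years) - 6L):max(config$years)
  ch <- chol_psd(r)
  # persistent site offsets share the cross-group correlation structure so
  # the realized log-catch correlation equals catch_correlation exactly
  site_eff <- (matrix(rnorm(length(sites) * length(groups)),
                      length(sites)) %*% ch) * truth$site_catch_sd
  dimnames(site_eff) <- list(sites, groups)
  rows <- list()
  for (s in sites) {
    z <- matrix(rnorm(length(years) * length(groups)), length(years))
    logkg <- truth$catch_meanlog +
      rep(site_eff[s, ], each = length(years)) +
      truth$catch_sdlog * (z %*% ch)
    for (gi in seq_along(groups)) {
      total <- exp(logkg[, gi])
      for (f in names(truth$fishery_shares)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          grid_site = s, year = years, fishery = f, group = groups[gi],
          retained_kg = total * truth$fishery_shares[[f]])
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$grid_site, .data$year, .data$group, .data$fishery)
}

chol_psd <- function(r) {
  # upper Cholesky factor, tolerating semi-definite matrices
  e <- eigen(r, symmetric = TRUE)
  v <- pmax(e$values, 0)
  t(e$vectors %*% (sqrt(v) * t(e$vectors)))
}

catch_effect_table <- function(config, truth, catch) {
  slopes <- truth$biomass_slopes
  sites <- grid_site_labels(config)
  eff <- expand.grid(grid_site = sites, year = config$years,
                     stringsAsFactors = FALSE)
  eff$catch_effect <- 0
  if (nrow(slopes) == 0) return(tibble::as_tibble(eff))
  if (is.null(catch)) {
    stop("nonzero biomass slopes require a catch table", call. = FALSE)
  }
  agg <- catch |>
    dplyr::group_by(.data$grid_site, .data$year, .data$group) |>
    dplyr::summarise(kg = sum(.data$retained_kg), .groups = "drop")
  need_year <- min(config$years) - max(slopes$lag)
  if (min(agg$year) > need_year) {
    stop(sprintf(
      "lag window needs catch from year %d but catch table starts at %d",
      need_year, min(agg$year)), call. = FALSE)
  }
  for (i in seq_len(nrow(slopes))) {
    g <- slopes$group[i]; x <- slopes$lag[i]; b <- slopes$slope[i]
    lagged <- agg |>
      dplyr::filter(.data$group == g) |>
      dplyr::transmute(grid_site = .data$grid_site,
                       year = .data$year + x,
                       term = b * log1p(.data$kg))
    eff <- dplyr::left_join(eff, lagged, by = c("grid_site", "year"))
    eff$catch_effect <- eff$catch_effect + dplyr::coalesce(eff$term, 0)
    eff$term <- NULL
  }
  tibble::as_tibble(eff)
}

#' Simulate manta-tow CoTS surveys
#'
#' Tow-level CoTS counts follow a negative binomial whose log mean is
#' intercept + zoning effect + coral-cover slope x tow cover + reef-year
#' intercept (Normal with SD `sigma_reefyear`) + the lagged catch term
#' summed over any nonzero biomass slopes. Coral cover is drawn as a
#' latent Beta proportion per reef-year, jittered per tow, and recorded as
#' the nearest manta-tow category code. Zeros arise from the count process
#' itself: there is no separate zero inflation.
#'
#' @inheritParams simulate_catch_tables
#' @param catch Catch table from [simulate_catch_tables()]; required when
#'   any biomass slope is nonzero, must cover the longest lag.
#' @return Manta-tow tibble with columns `reef_id`, `grid_site`, `year`,
#'   `tow_index`, `cots_count`, `cover_code`, `zoning`.
#' @export
simulate_cots_surveys <- function(config, truth, catch = NULL) {
  stopifnot(inherits(config, "world_config"), inherits(truth, "truth_params"))
  set.seed(sub_seed(config$seed, 2))
  reefs <- world_reefs(config)
  eff <- catch_effect_table(config, truth, catch)
  nt <- config$tows_per_reef_year
  empty <- tibble::tibble(reef_id = character(0), grid_site = character(0),
                          year = integer(0), tow_index = integer(0),
                          cots_count = integer(0), cover_code = character(0),
                          zoning = character(0))
  if (nt == 0) return(empty)
  rows <- list()
  for (i in seq_len(nrow(reefs))) {
    for (yr in config$years) {
      zeta <- rnorm(1, 0, truth$sigma_reefyear)
      p_reef <- rbeta(1, truth$coral_shape1, truth$coral_shape2)
      k <- truth$cover_kappa
      tow_p <- rbeta(nt, k * p_reef, k * (1 - p_reef))
      code <- snap_cover_to_category(tow_p)
      cover <- convert_cover_category(code)
      ce <- eff$catch_effect[eff$grid_site == reefs$grid_site[i] &
                               eff$year == yr]
      mu <- exp(truth$cots_intercept +
                  truth$zoning_log_ratio * (reefs$zoning[i] == "open") +
                  truth$coral_slope_cots * cover + zeta + ce)
      cnt <- rnbinom(nt, mu = mu, size = truth$nb_dispersion)
      rows[[length(rows) + 1]] <- tibble::tibble(
        reef_id = reefs$reef_id[i], grid_site = reefs$grid_site[i],
        year = as.integer(yr), tow_index = seq_len(nt),
        cots_count = as.integer(cnt), cover_code = code,
        zoning = reefs$zoning[i])
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate site-year CoTS densities from the hurdle-gamma twin
#'
#' Generates the fisheries-lag dataset for one fish group and lag directly
#' from the model family the lag analysis fits: a site-year density is
#' exactly zero with logit-linear probability in coral cover, and positive
#' densities are gamma with log mean linear in coral cover, lagged
#' log(catch + 1) and a grid-site intercept. This is the generative twin
#' used for parameter recovery of the biomass-removal scaling exponent;
#' tow-level surveys from [simulate_cots_surveys()] remain the twin of the
#' zoning count model.
#'
#' @inheritParams simulate_catch_tables
#' @param catch Catch table covering `config$years - lag`.
#' @param group Fish group whose catch drives the density.
#' @param lag Lag in years between catch and density.
#' @return Site-year tibble with columns `grid_site`, `year`,
#'   `cots_density`, `coral_cover` (plus `biomass_kg` of the driving
#'   catch), ready for [build_lagged_pairs()] / [run_fisheries_lag_grid()].
#' @export
simulate_lag_siteyears <- function(config, truth, catch, group, lag = 1L) {
  stopifnot(inherits(config, "world_config"), inherits(truth, "truth_params"))
  set.seed(sub_seed(config$seed, 4))
  agg <- catch |>
    dplyr::filter(.data$group == !!group) |>
    dplyr::group_by(.data$grid_site, .data$year) |>
    dplyr::summarise(kg = sum(.data$retained_kg), .groups = "drop")
  if (min(agg$year) > min(config$years) - lag) {
    stop(sprintf("lag window needs catch from year %d but catch table starts at %d",
                 min(config$years) - lag, min(agg$year)), call. = FALSE)
  }
  sites <- grid_site_labels(config)
  u <- setNames(rnorm(length(sites), 0, truth$sigma_site), sites)
  d <- expand.grid(grid_site = sites, year = config$years,
                   stringsAsFactors = FALSE)
  lagged <- dplyr::transmute(agg, grid_site = .data$grid_site,
                             year = .data$year + lag, kg = .data$kg)
  d <- dplyr::inner_join(d, lagged, by = c("grid_site", "year"))
  d$coral_cover <- convert_cover_category(snap_cover_to_category(
    rbeta(nrow(d), truth$coral_shape1, truth$coral_shape2)))
  slopes <- truth$biomass_slopes
  b <- slopes$slope[slopes$group == group & slopes$lag == lag]
  b <- if (length(b) == 0) 0 else sum(b)
  pz <- plogis(truth$hurdle_zero_intercept +
                 truth$coral_slope_zero * d$coral_cover)
  mu <- exp(truth$hurdle_pos_intercept +
              truth$coral_slope_pos * d$coral_cover +
              b * log1p(d$kg) + u[d$grid_site])
  d$cots_density <- rhurdle_gamma(nrow(d), pz, mu, truth$hurdle_gamma_shape)
  tibble::as_tibble(d[c("grid_site", "year", "cots_density", "coral_cover")]) |>
    dplyr::mutate(biomass_kg = d$kg)
}

#' Simulate paired-reef belt-transect fish surveys
#'
#' Each reef pair holds one fished (open) and one unfished (closed) reef,
#' surveyed in `fish_years` on three sites of five 50 x 5 m transects.
#' Counts per transect per group are negative binomial; no-take reefs are
#' scaled by the configured density multiplier, individual log-normal
#' total lengths by the length multiplier. Biomass fold effects emerge
#' downstream through the length-weight computation.
#'
#' @inheritParams simulate_catch_tables
#' @return Transect tibble with columns `reef_pair_id`, `reef_id`,
#'   `zoning`, `site`, `year`, `transect`, `group`, `count` and
#'   list-column `lengths`.
#' @export
simulate_fish_transects <- function(config, truth) {
  stopifnot(inherits(config, "world_config"), inherits(truth, "truth_params"))
  set.seed(sub_seed(config$seed, 3))
  groups <- config$fish_groups
  mult <- truth$zoning_fish_multipliers
  miss <- setdiff(groups, mult$group)
  if (length(miss) > 0) {
    stop("no zoning multipliers for group(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  md <- setNames(mult$density, mult$group)
  ml <- setNames(mult$length, mult$group)
  sds <- truth$fish_effect_sds
  n_tr <- config$transects_per_reef / 3L
  P <- config$n_reef_pairs
  grid <- expand.grid(group = groups, transect = seq_len(n_tr),
                      year = config$fish_years, site = 1:3,
                      zoning = c("open", "closed"), pair = seq_len(P),
                      stringsAsFactors = FALSE)
  # shared lognormal survey effects: pair, reef, site-within-reef, year
  pair_eff <- rnorm(P, 0, sds[["pair"]])
  reef_eff <- matrix(rnorm(2 * P, 0, sds[["reef"]]), P)     # [pair, zoning]
  site_eff <- array(rnorm(2 * 3 * P, 0, sds[["site"]]), c(P, 2, 3))
  year_eff <- array(rnorm(2 * 3 * P * length(config$fish_years), 0,
                          sds[["year"]]),
                    c(P, 2, 3, length(config$fish_years)))
  zi <- ifelse(grid$zoning == "open", 1L, 2L)
  yi <- match(grid$year, config$fish_years)
  eff <- pair_eff[grid$pair] + reef_eff[cbind(grid$pair, zi)] +
    site_eff[cbind(grid$pair, zi, grid$site)] +
    year_eff[cbind(grid$pair, zi, grid$site, yi)]
  unf <- grid$zoning == "closed"
  mu <- truth$fish_count_mu * ifelse(unf, md[grid$group], 1) * exp(eff)
  cnt <- rnbinom(nrow(grid), mu = mu, size = truth$fish_count_size)
  meanlog <- log(truth$length_median_cm) + ifelse(unf, log(ml[grid$group]), 0)
  lens <- mapply(function(n, m) rlnorm(n, m, truth$length_sdlog),
                 cnt, meanlog, SIMPLIFY = FALSE)
  out <- tibble::tibble(
    reef_pair_id = sprintf("P%02d", grid$pair),
    reef_id = sprintf("P%02d_%s", grid$pair, ifelse(unf, "U", "F")),
    zoning = grid$zoning, site = grid$site, year = as.integer(grid$year),
    transect = grid$transect, group = grid$group, count = as.integer(cnt),
    lengths = lens)
  dplyr::arrange(out, .data$reef_pair_id, .data$zoning, .data$site,
                 .data$year, .data$transect, .data$group)
}

#' Simulate a complete synthetic world
#'
#' @inheritParams simulate_catch_tables
#' @return List with elements `catch`, `manta`, `transects`, `config`,
#'   `truth`.
#' @export
simulate_world <- function(config, truth = truth_params(groups = config$fish_groups)) {
  catch <- simulate_catch_tables(config, truth)
  manta <- simulate_cots_surveys(config, truth, catch)
  transects <- simulate_fish_transects(config, truth)
  list(catch = catch, manta = manta, transects = transects,
       config = config, truth = truth)
}

#' Write a synthetic world to CSV plus a truth-parameters file
#'
#' The three observation tables are written as headered CSV (transect
#' lengths as a semicolon-separated field); the ground-truth parameters go
#' to `truth.yml` for parameter-recovery studies.
#'
#' @param world A list from [simulate_world()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(world$catch, file.path(dir, "catch.csv"), row.names = FALSE)
  utils::write.csv(world$manta, file.path(dir, "manta.csv"), row.names = FALSE)
  tr <- world$transects
  tr$lengths <- vapply(tr$lengths, function(x) paste(signif(x, 8), collapse = ";"),
                       character(1))
  utils::write.csv(tr, file.path(dir, "transects.csv"), row.names = FALSE)
  tp <- world$truth
  tp$zoning_fish_multipliers <- as.data.frame(tp$zoning_fish_multipliers)
  tp$biomass_slopes <- as.data.frame(tp$biomass_slopes)
  tp$lw_coeffs <- as.data.frame(tp$lw_coeffs)
  tp$catch_correlation <- apply(tp$catch_correlation, 1, as.list, simplify = FALSE)
  yaml::write_yaml(unclass(tp), file.path(dir, "truth.yml"))
  cfg <- unclass(world$config)
  yaml::write_yaml(cfg, file.path(dir, "world.yml"))
  invisible(dir)
}

#' Read the observation tables written by [write_world()]
#'
#' @param path CSV file path.
#' @return A tibble with the schema the validators expect.
#' @export
read_manta_csv <- function(path) {
  x <- utils::read.csv(path, colClasses = c(cover_code = "character"))
  tibble::as_tibble(x)
}

#' @rdname read_manta_csv
#' @export
read_catch_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' @rdname read_manta_csv
#' @export
read_transects_csv <- function(path) {
  x <- utils::read.csv(path, colClasses = c(lengths = "character"))
  x$lengths <- lapply(strsplit(x$lengths, ";", fixed = TRUE),
                      function(s) as.numeric(s[nzchar(s)]))
  tibble::as_tibble(x)
}
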