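test_that("identical config and seed reproduce byte-identical worlds", {
  cfg <- world_config(n_grid_sites = 3, years = 2000:2003,
                      tows_per_reef_year = 4, n_reef_pairs = 2, seed = 99)
  w1 <- simulate_world(cfg)
  w2 <- simulate_world(cfg)
  expect_identical(w1$catch, w2$catch)
  expect_identical(w1$manta, w2$manta)
  expect_identical(w1$transects, w2$transects)
  w3 <- simulate_world(world_config(n_grid_sites = 3, years = 2000:2003,
                                    tows_per_reef_year = 4, n_reef_pairs = 2,
                                    seed = 100))
  expect_false(identical(w1$manta, w3$manta))
})

test_that("catch tables realize the configured cross-group correlation", {
  groups <- c("A", "B")
  cfg <- world_config(n_grid_sites = 42, years = 1997:2008,
                      fish_groups = groups, seed = 5)
  # independent groups: sample correlation near zero at ~500 site-years
  tr0 <- truth_params(groups = groups, catch_correlation = two_group_corr(0))
  agg <- aggregate_catch(simulate_catch_tables(cfg, tr0))
  wide <- tidyr::pivot_wider(
    dplyr::mutate(agg, l = log(biomass_kg)),
    id_cols = c("grid_site", "year"), names_from = "group",
    values_from = "l")
  expect_gte(nrow(wide), 500)
  expect_lt(abs(cor(wide$A, wide$B)), 0.2)
  # strongly coupled groups reproduce the >0.9 coupling seen between
  # coral trout and Serranidae catches
  tr95 <- truth_params(groups = groups, catch_correlation = two_group_corr(0.95))
  agg <- aggregate_catch(simulate_catch_tables(cfg, tr95))
  wide <- tidyr::pivot_wider(
    dplyr::mutate(agg, l = log(biomass_kg)),
    id_cols = c("grid_site", "year"), names_from = "group",
    values_from = "l")
  expect_gt(cor(wide$A, wide$B), 0.9)
})

test_that("invalid correlation matrices are rejected naming the eigenvalue", {
  bad <- matrix(c(1, 2, 2, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(truth_params(groups = c("A", "B"), catch_correlation = bad),
               "eigenvalue")
  asym <- two_group_corr(0.5); asym[1, 2] <- 0.4
  expect_error(truth_params(groups = c("A", "B"), catch_correlation = asym),
               "symmetric")
})

test_that("with all effects off, tow counts are iid negative binomial", {
  cfg <- world_config(n_grid_sites = 6, reefs_per_site = 2,
                      years = 2000:2004, tows_per_reef_year = 40, seed = 21)
  tr <- truth_params(cots_intercept = log(2), zoning_log_ratio = 0,
                     coral_slope_cots = 0, sigma_reefyear = 0,
                     nb_dispersion = 1)
  manta <- simulate_cots_surveys(cfg, tr)
  n <- nrow(manta)
  mu <- 2
  se <- sqrt((mu + mu^2 / 1) / n)
  expect_lt(abs(mean(manta$cots_count) - mu), 3 * se)
})

test_that("the zoning log-ratio yields the configured open:closed density ratio", {
  cfg <- world_config(n_grid_sites = 30, reefs_per_site = 2,
                      years = 2000:2005, tows_per_reef_year = 10,
                      frac_unfished = 0.5, seed = 33)
  tr <- truth_params(cots_intercept = 0, coral_slope_cots = 0,
                     sigma_reefyear = 0, nb_dispersion = 2)
  manta <- simulate_cots_surveys(cfg, tr)
  mo <- manta$cots_count[manta$zoning == "open"]
  mc <- manta$cots_count[manta$zoning == "closed"]
  ratio <- mean(mo) / mean(mc)
  se_ratio <- ratio * sqrt(var(mo) / (length(mo) * mean(mo)^2) +
                             var(mc) / (length(mc) * mean(mc)^2))
  expect_lt(abs(ratio - 2.8), 3 * se_ratio)
})

test_that("zero tows per reef-year gives an empty survey, not an error", {
  cfg <- world_config(tows_per_reef_year = 0, seed = 1)
  manta <- simulate_cots_surveys(cfg, truth_params())
  expect_equal(nrow(manta), 0)
})

test_that("a lag window reaching before the first catch year is an error", {
  cfg <- world_config(n_grid_sites = 2, years = 2000:2002, seed = 3)
  tr <- truth_params(biomass_slopes = tibble::tibble(
    group = "Serranidae", lag = 2L, slope = 0.3))
  catch <- simulate_catch_tables(cfg, tr)
  short <- dplyr::filter(catch, year >= 2000)
  expect_error(simulate_cots_surveys(cfg, tr, short), "1998")
  expect_silent(x <- simulate_cots_surveys(cfg, tr, catch))
})

test_that("the site-year hurdle twin has the configured zero and slope structure", {
  groups <- "Lethrinidae"
  cfg <- world_config(n_grid_sites = 40, years = 1994:2005,
                      fish_groups = groups, seed = 17)
  corr <- matrix(1, 1, 1, dimnames = list(groups, groups))
  tru <- truth_params(groups = groups, catch_correlation = corr,
                      biomass_slopes = tibble::tibble(group = groups,
                                                      lag = 1L, slope = 0.3),
                      sigma_site = 0)
  catch <- simulate_catch_tables(cfg, tru)
  d <- simulate_lag_siteyears(cfg, tru, catch, group = groups, lag = 1)
  expect_identical(d, simulate_lag_siteyears(cfg, tru, catch, groups, 1))
  expect_equal(nrow(d), 40 * 12)
  # zero-heavy: zero fraction matches the logit-linear zero process
  pz <- plogis(tru$hurdle_zero_intercept +
                 tru$coral_slope_zero * d$coral_cover)
  expect_lt(abs(mean(d$cots_density == 0) - mean(pz)),
            4 * sqrt(mean(pz) / nrow(d)))
  # positive part scales with lagged log catch at the configured exponent
  pos <- d[d$cots_density > 0, ]
  sl <- coef(lm(log(cots_density) ~ coral_cover + log1p(biomass_kg),
                data = pos))[["log1p(biomass_kg)"]]
  expect_lt(abs(sl - 0.3), 0.1)
  # lag window validation names the missing year
  late <- dplyr::filter(catch, year >= 1994)
  expect_error(simulate_lag_siteyears(cfg, tru, late, groups, 1), "1993")
})

test_that("transect counts honour null and non-null zoning multipliers", {
  groups <- "Serranidae"
  cfg <- world_config(fish_groups = groups, n_reef_pairs = 40,
                      years = 2000:2005, seed = 13)
  null_mult <- tibble::tibble(group = groups, density = 1, length = 1.2)
  tr <- truth_params(groups = groups, zoning_fish_multipliers = null_mult,
                     fish_effect_sds = c(pair = 0, reef = 0, site = 0, year = 0))
  tt <- simulate_fish_transects(cfg, tr)
  co <- tt$count[tt$zoning == "open"]
  cc <- tt$count[tt$zoning == "closed"]
  se <- sqrt(var(co) / length(co) + var(cc) / length(cc))
  expect_lt(abs(mean(cc) - mean(co)), 3 * se)  # null density effect
  lo <- unlist(tt$lengths[tt$zoning == "open"])
  lc <- unlist(tt$lengths[tt$zoning == "closed"])
  r <- mean(lc) / mean(lo)
  se_r <- r * sqrt(var(lc) / (length(lc) * mean(lc)^2) +
                     var(lo) / (length(lo) * mean(lo)^2))
  expect_lt(abs(r - 1.2), 3 * se_r)            # 1.2-fold length effect
})

test_that("transect bookkeeping matches the survey design", {
  cfg <- world_config(fish_groups = "Serranidae", n_reef_pairs = 5,
                      years = 2000:2007, transects_per_reef = 15, seed = 2)
  expect_length(cfg$fish_years, 4)  # biennial
  tt <- simulate_fish_transects(cfg, truth_params(groups = "Serranidae"))
  expect_equal(nrow(tt), 5 * 2 * 15 * 4)
  expect_equal(length(unique(tt$reef_id)), 10)
  expect_true(all(table(tt$reef_id, tt$year) == 15))
  # counts always equal the number of simulated lengths
  expect_equal(tt$count, vapply(tt$lengths, length, integer(1)))
})

test_that("generated tables satisfy their own schemas and round-trip CSV", {
  w <- small_world(seed = 4)
  expect_silent(validate_manta(w$manta))
  expect_silent(validate_catch(w$catch))
  expect_silent(validate_transects(w$transects))
  d <- withr::local_tempdir()
  write_world(w, d)
  expect_true(file.exists(file.path(d, "truth.yml")))
  m2 <- read_manta_csv(file.path(d, "manta.csv"))
  expect_equal(as.data.frame(m2), as.data.frame(w$manta))
  t2 <- read_transects_csv(file.path(d, "transects.csv"))
  expect_equal(t2$count, w$transects$count)
  expect_equal(unlist(t2$lengths), unlist(w$transects$lengths),
               tolerance = 1e-6)
})

test_that("generated moments match closed forms at large n", {
  set.seed(8)
  # negative-binomial tow counts
  cfg <- world_config(n_grid_sites = 5, reefs_per_site = 2,
                      years = 2000:2009, tows_per_reef_year = 100, seed = 12)
  tr <- truth_params(cots_intercept = log(1.5), zoning_log_ratio = 0,
                     coral_slope_cots = 0, sigma_reefyear = 0,
                     nb_dispersion = 0.8)
  cnt <- simulate_cots_surveys(cfg, tr)$cots_count
  expect_gte(length(cnt), 1e4)
  mu <- 1.5; v <- mu + mu^2 / 0.8
  expect_lt(abs(mean(cnt) - mu), 4 * sqrt(v / length(cnt)))
  expect_lt(abs(var(cnt) - v) / v, 0.1)
  # log-normal lengths
  tr2 <- truth_params(groups = "G", length_median_cm = 30, length_sdlog = 0.25,
                      zoning_fish_multipliers = tibble::tibble(
                        group = "G", density = 1, length = 1),
                      fish_effect_sds = c(pair = 0, reef = 0, site = 0, year = 0),
                      fish_count_mu = 10)
  cfg2 <- world_config(fish_groups = "G", n_reef_pairs = 20,
                       years = 2000:2005, seed = 3)
  lens <- unlist(simulate_fish_transects(cfg2, tr2)$lengths)
  expect_gte(length(lens), 1e4)
  m_true <- 30 * exp(0.25^2 / 2)
  sd_true <- m_true * sqrt(exp(0.25^2) - 1)
  expect_lt(abs(mean(lens) - m_true), 4 * sd_true / sqrt(length(lens)))
})
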