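# The three study analyses, as configured drivers over the model layer:
# (1) the 6 fish groups x 6 lags grid of hurdle-gamma models for the
#     biomass-removal scaling exponent of CoTS density,
# (2) paired-reef reserve comparisons of fish biomass, density and length,
# (3) the zoning + coral-cover negative-binomial model of tow-level CoTS
#     counts with reef-year hierarchical intercepts.

#' Fisheries-lag model grid
#'
#' Fits one hurdle-gamma model per fish group and lag: the zero part on
#' coral cover, the positive part on coral cover plus log(catch kg + 1)
#' with a grid-site hierarchical intercept, using open-zone CoTS site-year
#' densities only. Each cell yields the evidence summary of the biomass
#' slope (the scaling exponent of CoTS density on catch); a cell whose
#' sampler fails convergence is flagged, never dropped silently.
#'
#' @param cots_sy Open-zone site-year CoTS table from
#'   [resolve_duplicates()] with `fisheries_stream = TRUE`.
#' @param catch_sy Aggregated site-year catch table from
#'   [aggregate_catch()] (column `group` present).
#' @param groups Fish groups to model (default: all in `catch_sy`).
#' @param lags Integer lags (default 1:6).
#' @param chains,warmup,iter Sampler settings per cell.
#' @param seed Integer seed; each cell derives its own sub-seed.
#' @param min_pairs Cells with fewer paired observations than this are
#'   recorded as failed rather than fitted.
#' @return Tibble with one row per (group, lag): the biomass-slope
#'   evidence summary, pair count, convergence flag and any error message.
#' @export
run_fisheries_lag_grid <- function(cots_sy, catch_sy, groups = NULL,
                                   lags = 1:6, chains = 2, warmup = 500,
                                   iter = 500, seed = 1, min_pairs = 10) {
  if (is.null(groups)) groups <- sort(unique(catch_sy$group))
  empty <- tibble::tibble(group = character(0), lag = integer(0),
                          n_pairs = integer(0), median = numeric(0),
                          l60 = numeric(0), u60 = numeric(0),
                          l95 = numeric(0), u95 = numeric(0),
                          pct_above_zero = numeric(0), class = character(0),
                          converged = logical(0), error = character(0))
  if (length(groups) == 0) return(empty)
  rows <- list()
  cell <- 0
  for (g in groups) {
    cg <- dplyr::filter(catch_sy, .data$group == g)
    for (x in lags) {
      cell <- cell + 1
      pairs <- build_lagged_pairs(
        cots_sy, cg[c("grid_site", "year", "biomass_kg")], x)
      row <- tibble::tibble(group = g, lag = as.integer(x),
                            n_pairs = nrow(pairs), median = NA_real_,
                            l60 = NA_real_, u60 = NA_real_, l95 = NA_real_,
                            u95 = NA_real_, pct_above_zero = NA_real_,
                            class = NA_character_, converged = NA,
                            error = NA_character_)
      res <- tryCatch({
        if (nrow(pairs) < min_pairs) {
          stop(sprintf("only %d paired observations", nrow(pairs)))
        }
        # covariates are centred so the weakly-informative intercept prior
        # does not leak into the slope; the scaling exponent is unchanged
        pairs$log_catch <- log1p(pairs$biomass_kg)
        pairs$log_catch <- pairs$log_catch - mean(pairs$log_catch)
        pairs$coral_cover_c <- pairs$coral_cover - mean(pairs$coral_cover)
        mod <- build_model("hurdle_gamma", pairs, response = "cots_density",
                           terms = c("coral_cover_c", "log_catch"),
                           zero_terms = "coral_cover_c", re = "grid_site")
        fit <- suppressWarnings(
          fit_model(mod, chains = chains, warmup = warmup, iter = iter,
                    seed = sub_seed(seed, cell), monitor_re = FALSE))
        s <- summarise_evidence(fit, "b_log_catch",
                                min_draws = min(1000, chains * iter))
        row$median <- s$median; row$l60 <- s$l60; row$u60 <- s$u60
        row$l95 <- s$l95; row$u95 <- s$u95
        row$pct_above_zero <- s$pct_above_zero; row$class <- s$class
        row$converged <- fit$converged
        row
      }, error = function(e) {
        row$error <- conditionMessage(e)
        row
      })
      rows[[cell]] <- res
    }
  }
  dplyr::bind_rows(rows)
}

#' Paired-reef reserve models for fish biomass, density and length
#'
#' For each fish group, fits biomass and density (kg and individuals per
#' 1000 m2, site level) with a hurdle-gamma model whose logistic part
#' depends on zoning, and site-level mean total length with a gamma model;
#' all responses take zoning as the fixed effect (fished = reference) with
#' hierarchical intercepts for site, reef pair, reef and year. The
#' unfished:fished contrast is computed draw by draw: for hurdle responses
#' as the ratio of expected values (occupancy times conditional mean), for
#' length as exp of the zoning coefficient, and expressed both as a fold
#' change and as a percent difference of the fished value.
#'
#' @param sites Site-year response table from [prepare_reserve_sites()].
#' @param groups Fish groups (default: all present; absent requested
#'   groups are skipped with a warning).
#' @param responses Subset of `c("biomass", "density", "length")`.
#' @param chains,warmup,iter,seed Sampler settings.
#' @return Tibble with one row per group x response: fold-change summary
#'   (median and 95% CI), percent difference, probability of a positive
#'   zoning effect, evidence class and convergence flag.
#' @export
run_reserve_fish_models <- function(sites, groups = NULL,
                                    responses = c("biomass", "density", "length"),
                                    chains = 2, warmup = 500, iter = 500,
                                    seed = 1) {
  responses <- match.arg(responses, several.ok = TRUE)
  present <- unique(sites$group)
  if (is.null(groups)) groups <- sort(present)
  skip <- setdiff(groups, present)
  if (length(skip) > 0) {
    warning("group(s) absent from data, skipped: ",
            paste(skip, collapse = ", "), call. = FALSE)
    groups <- intersect(groups, present)
  }
  rows <- list()
  cell <- 0
  for (g in groups) {
    dg <- dplyr::filter(sites, .data$group == g)
    dg$unfished <- as.integer(dg$zoning == "closed")
    dg$site_id <- paste(dg$reef_id, dg$site, sep = ":")
    for (resp in responses) {
      cell <- cell + 1
      row <- tibble::tibble(group = g, response = resp, n = NA_integer_,
                            fold_median = NA_real_, fold_l95 = NA_real_,
                            fold_u95 = NA_real_, pct_diff_median = NA_real_,
                            pct_above_zero = NA_real_, class = NA_character_,
                            converged = NA, error = NA_character_)
      res <- tryCatch({
        re <- c("site_id", "reef_pair_id", "reef_id", "year")
        if (resp == "length") {
          d <- dg[!is.na(dg$mean_length), ]
          row$n <- nrow(d)
          # site-mean lengths have a very small coefficient of variation,
          # so the gamma shape sits in the hundreds; widen its prior scale
          mod <- build_model("gamma", d, response = "mean_length",
                             terms = "unfished", re = re,
                             priors = default_priors(shape_scale = 1000),
                             re_centred = TRUE)
          fit <- suppressWarnings(
            fit_model(mod, chains = chains, warmup = warmup, iter = iter,
                      seed = sub_seed(seed, cell), monitor_re = FALSE))
          fold <- exp(draws_of(fit, "b_unfished"))
        } else {
          d <- dg
          d$y <- if (resp == "biomass") d$biomass_kg else d$density
          row$n <- nrow(d)
          mod <- build_model("hurdle_gamma", d, response = "y",
                             terms = "unfished", zero_terms = "unfished",
                             re = re, re_centred = TRUE)
          fit <- suppressWarnings(
            fit_model(mod, chains = chains, warmup = warmup, iter = iter,
                      seed = sub_seed(seed, cell), monitor_re = FALSE))
          a0 <- draws_of(fit, "a_intercept")
          a1 <- draws_of(fit, "a_unfished")
          # expected-value ratio: occupancy ratio x conditional-mean ratio
          fold <- (1 - plogis(a0 + a1)) / (1 - plogis(a0)) *
            exp(draws_of(fit, "b_unfished"))
        }
        pct_diff <- (fold - 1) * 100
        pct <- 100 * mean(log(fold) > 0)
        q <- quantile(fold, c(0.025, 0.5, 0.975), names = FALSE)
        row$fold_median <- q[2]; row$fold_l95 <- q[1]; row$fold_u95 <- q[3]
        row$pct_diff_median <- median(pct_diff)
        row$pct_above_zero <- pct
        row$class <- evidence_class(pct)
        row$converged <- fit$converged
        row
      }, error = function(e) {
        row$error <- conditionMessage(e)
        row
      })
      rows[[cell]] <- res
    }
  }
  dplyr::bind_rows(rows)
}

#' Zoning and coral-cover model of tow-level CoTS counts
#'
#' Negative-binomial model of CoTS count per 2-min tow with zoning status
#' (closed = reference, so the intercept is the unfished baseline) and
#' tow-level coral-cover proportion as fixed effects and a reef-year
#' hierarchical intercept. Returns the fit, parameter evidence summaries
#' (intercept `b0`, open-zoning effect `b1`, coral slope `b2`, reef-year
#' SD `sigma_zeta`) and the derived fold effects.
#'
#' @param manta Manta-tow table (cover codes still categorical).
#' @param chains,warmup,iter,seed Sampler settings.
#' @param monitor_re Keep reef-year intercept draws (needed for
#'   [ppc_zero_fraction()]).
#' @return List with elements `fit`, `summary` (tibble), `derived` (from
#'   [derive_fold_effects()]).
#' @export
run_cots_zoning_model <- function(manta, chains = 2, warmup = 500,
                                  iter = 1000, seed = 1, monitor_re = TRUE) {
  validate_manta(manta)
  d <- manta |>
    dplyr::mutate(cover = convert_cover_category(.data$cover_code),
                  open = as.integer(.data$zoning == "open"),
                  reef_year = paste(.data$reef_id, .data$year, sep = ":"))
  if (length(unique(d$reef_year)) < 2) {
    stop("need at least two reef-year combinations to identify the reef-year intercept SD",
         call. = FALSE)
  }
  mod <- build_model("negbin", d, response = "cots_count",
                     terms = c("open", "cover"), re = "reef_year")
  fit <- fit_model(mod, chains = chains, warmup = warmup, iter = iter,
                   seed = seed, monitor_re = monitor_re)
  s <- summarise_evidence(fit, c("b_intercept", "b_open", "b_cover",
                                 "sd_reef_year"),
                          min_draws = min(1000, chains * iter))
  s$parameter <- c("b0", "b1", "b2", "sigma_zeta")[match(
    s$parameter, c("b_intercept", "b_open", "b_cover", "sd_reef_year"))]
  list(fit = fit, summary = s, derived = derive_fold_effects(fit))
}

#' Derived fold effects from a zoning-model fit
#'
#' Draw-wise transforms of the zoning-model posterior: the open:closed
#' fold ratio `exp(b1)` (with its percent difference), the reef-year range
#' factor `exp(2 * sigma_zeta)` describing the multiplicative spread of
#' CoTS density across reef-years, and the coral-cover slope. Medians and
#' 95% equal-tailed intervals are taken after transforming each draw
#' (transforming a posterior summary instead would be wrong for skewed
#' posteriors, and the tests pin that down).
#'
#' @param fit A `cots_fit` from the zoning model, or a named list with
#'   draw vectors `b_open` and `sd_reef_year` (optionally `b_cover`).
#' @return Tibble with columns `quantity`, `median`, `l95`, `u95`.
#' @export
derive_fold_effects <- function(fit) {
  g <- function(p) {
    if (inherits(fit, "cots_fit")) {
      if (p %in% colnames(fit$draws)) draws_of(fit, p) else NULL
    } else {
      fit[[p]]
    }
  }
  b1 <- g("b_open"); sz <- g("sd_reef_year")
  if (is.null(b1) || is.null(sz)) {
    stop("draws for b_open and sd_reef_year are required", call. = FALSE)
  }
  qrow <- function(quantity, d) {
    q <- quantile(d, c(0.025, 0.5, 0.975), names = FALSE)
    tibble::tibble(quantity = quantity, median = q[2], l95 = q[1], u95 = q[3])
  }
  out <- dplyr::bind_rows(
    qrow("zoning_fold", exp(b1)),
    qrow("zoning_pct_diff", (exp(b1) - 1) * 100),
    qrow("reefyear_range_factor", reefyear_range_factor(sz)))
  b2 <- g("b_cover")
  if (!is.null(b2)) out <- dplyr::bind_rows(out, qrow("coral_slope", b2))
  out
}

#' Reef-year range factor
#'
#' `exp(2 * sigma)`: the fold difference in expected CoTS density between
#' a reef-year one SD above and one SD below the mean of the reef-year
#' intercept distribution.
#'
#' @param sigma Reef-year intercept SD (draw vector or scalar).
#' @return `exp(2 * sigma)`, elementwise.
#' @export
reefyear_range_factor <- function(sigma) {
  stopifnot(all(sigma >= 0))
  exp(2 * sigma)
}
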