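# Posterior summarisation: evidence classes from the probability of
# direction, and a posterior predictive check on the zero fraction.

#' Classify an effect by its posterior mass above zero
#'
#' @param pct_above Percentage (0-100) of posterior mass above zero.
#' @return `">95%"`, `">80%"` or `"none"` (strict thresholds).
#' @export
evidence_class <- function(pct_above) {
  dplyr::case_when(pct_above > 95 ~ ">95%",
                   pct_above > 80 ~ ">80%",
                   TRUE ~ "none")
}

#' Summarise posterior evidence for one or more parameters
#'
#' For each parameter: posterior median, 60% and 95% equal-tailed credible
#' intervals, the percentage of draws above zero, and the evidence class
#' assigned by strict >80% / >95% thresholds on that percentage.
#'
#' @param fit A `cots_fit`, or a named list / data frame of draw vectors.
#' @param parameters Parameter names (default: all non-hierarchical ones).
#' @param min_draws Minimum pooled draws required (default 1000).
#' @return Tibble with one row per parameter: `parameter`, `median`,
#'   `l60`, `u60`, `l95`, `u95`, `pct_above_zero`, `class`.
#' @export
summarise_evidence <- function(fit, parameters = NULL, min_draws = 1000) {
  if (inherits(fit, "cots_fit")) {
    if (is.null(parameters)) {
      parameters <- setdiff(colnames(fit$draws),
                            grep("^u_", colnames(fit$draws), value = TRUE))
    }
    draws <- lapply(parameters, function(p) draws_of(fit, p))
    names(draws) <- parameters
  } else {
    draws <- as.list(fit)
    if (!is.null(parameters)) draws <- draws[parameters]
  }
  rows <- lapply(names(draws), function(p) {
    d <- draws[[p]]
    if (length(d) < min_draws) {
      stop(sprintf("only %d draws for %s; need at least %d", length(d), p,
                   min_draws), call. = FALSE)
    }
    q <- quantile(d, c(0.025, 0.2, 0.5, 0.8, 0.975), names = FALSE)
    pct <- 100 * mean(d > 0)
    tibble::tibble(parameter = p, median = q[3], l60 = q[2], u60 = q[4],
                   l95 = q[1], u95 = q[5], pct_above_zero = pct,
                   class = evidence_class(pct))
  })
  dplyr::bind_rows(rows)
}

#' Posterior predictive check of the zero fraction
#'
#' For a fitted count (negative binomial) model, draws replicate datasets
#' from the posterior (using the sampled hierarchical intercepts) and
#' compares the replicated zero fractions with the observed one. A
#' observed fraction deep in either tail of the replicated distribution
#' indicates zero inflation (or deflation) the model cannot express.
#'
#' @param fit A `cots_fit` for a `negbin` model fitted with
#'   `monitor_re = TRUE`.
#' @param n_rep Number of replicate datasets.
#' @param seed Seed for the replicate simulation.
#' @return List with `observed` zero fraction, `replicated` vector,
#'   `prob_ge` / `prob_le` (replicate tail masses) and `tail_prob`
#'   (smaller of the two).
#' @export
ppc_zero_fraction <- function(fit, n_rep = 200, seed = 1) {
  stopifnot(inherits(fit, "cots_fit"))
  mod <- fit$model
  if (mod$family != "negbin") {
    stop("zero-fraction PPC is defined for the negative-binomial model",
         call. = FALSE)
  }
  if (length(mod$y) == 0) stop("model data is empty", call. = FALSE)
  set.seed(seed)
  b_names <- paste0("b_", colnames(mod$X))
  u_names <- unlist(lapply(names(mod$re_levels), function(f) {
    sprintf("u_%s[%s]", f, mod$re_levels[[f]])
  }))
  if (length(u_names) > 0 && !all(u_names %in% colnames(fit$draws))) {
    stop("hierarchical intercept draws missing; refit with monitor_re = TRUE",
         call. = FALSE)
  }
  idx <- sample(nrow(fit$draws), min(n_rep, nrow(fit$draws)))
  n <- length(mod$y)
  zero_frac <- vapply(idx, function(i) {
    b <- fit$draws[i, b_names]
    eta <- drop(mod$X %*% b)
    for (k in seq_along(mod$re_idx)) {
      f <- names(mod$re_idx)[k]
      u <- fit$draws[i, sprintf("u_%s[%s]", f, mod$re_levels[[f]])]
      eta <- eta + u[mod$re_idx[[k]]]
    }
    phi <- fit$draws[i, "phi"]
    yr <- rnbinom(n, mu = exp(eta), size = phi)
    mean(yr == 0)
  }, numeric(1))
  obs <- mean(mod$y == 0)
  list(observed = obs, replicated = zero_frac,
       prob_ge = mean(zero_frac >= obs), prob_le = mean(zero_frac <= obs),
       tail_prob = min(mean(zero_frac >= obs), mean(zero_frac <= obs)))
}
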