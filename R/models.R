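# Hierarchical model construction and MCMC fitting.
#
# build_model() turns one of the analysis shapes (hurdle-gamma, gamma,
# negative binomial, plus a gaussian shape used for sampler validation)
# into (a) a joint log-posterior callable over a named parameter vector
# and (b) an equivalent directed-graph program handed to JAGS, which does
# the actual sampling in fit_model(). The two representations share the
# same likelihood and priors; unit tests hold them to that.

#' Default weakly-informative priors
#'
#' Normal(0, `coef_scale`) on slopes, Student-t(`intercept_df`, 0,
#' `intercept_scale`) on intercepts, half-Normal(0, `sd_scale`) on
#' hierarchical intercept SDs and half-Normal(0, `shape_scale`) on the
#' gamma shape / negative-binomial dispersion.
#'
#' @param coef_scale,intercept_scale,intercept_df,sd_scale,shape_scale
#'   Prior scales (and intercept degrees of freedom).
#' @return A named list of prior settings.
#' @export
default_priors <- function(coef_scale = 2.5, intercept_scale = 2.5,
                           intercept_df = 3, sd_scale = 2, shape_scale = 5) {
  list(coef_scale = coef_scale, intercept_scale = intercept_scale,
       intercept_df = intercept_df, sd_scale = sd_scale,
       shape_scale = shape_scale)
}

sanitize_term <- function(x) {
  x <- sub("^\\(Intercept\\)$", "intercept", x)
  gsub("[^A-Za-z0-9_.]", "_", x)
}

design_matrix <- function(data, terms, part) {
  miss <- setdiff(terms, names(data))
  if (length(miss) > 0) {
    stop(sprintf("%s part refers to missing column(s): %s", part,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  f <- if (length(terms) == 0) ~1 else stats::reformulate(terms)
  X <- stats::model.matrix(f, data = data)
  if (ncol(X) > 1) {
    const <- apply(X[, -1, drop = FALSE], 2, function(v) sd(v) == 0)
    if (any(const)) {
      warning(sprintf("constant covariate(s) in %s part: %s", part,
                      paste(names(const)[const], collapse = ", ")),
              call. = FALSE)
    }
  }
  colnames(X) <- sanitize_term(colnames(X))
  X
}

coef_prior_lines <- function(vec, n, priors) {
  prec_c <- 1 / priors$coef_scale^2
  prec_i <- 1 / priors$intercept_scale^2
  lines <- sprintf("  %s[1] ~ dt(0, %.10g, %d)", vec, prec_i,
                   priors$intercept_df)
  if (n > 1) {
    lines <- c(lines, sprintf("  for (p in 2:%d) { %s[p] ~ dnorm(0, %.10g) }",
                              n, vec, prec_c))
  }
  lines
}

#' Build a hierarchical model for one of the analysis shapes
#'
#' @param family One of `"hurdle_gamma"` (logit-link zero part plus
#'   log-link mean-parameterised gamma for positives), `"gamma"`,
#'   `"negbin"` (NB2 with log link) or `"gaussian"` (identity link; used
#'   for sampler validation against conjugate results).
#' @param data Data frame holding the response and covariates.
#' @param response Name of the response column.
#' @param terms Character vector of covariate columns for the mean (count
#'   / positive) part; the intercept is implicit.
#' @param zero_terms Covariate columns for the hurdle zero (logit) part;
#'   hurdle family only.
#' @param re Character vector of grouping-factor columns receiving
#'   hierarchical (random) intercepts on the mean part.
#' @param priors Prior settings from [default_priors()].
#' @param re_centred Parameterisation of the hierarchical intercepts:
#'   non-centred (`FALSE`, default; mixes well when group-level data are
#'   weak) or centred (`TRUE`; required when the data pin the intercepts
#'   tightly, as in the reserve fish models).
#' @param prior_only Drop the likelihood so [fit_model()] samples the
#'   prior; used for prior-recovery checks.
#' @return A `cots_model` object holding the JAGS program, its data, and
#'   `$log_posterior(theta)` / `$loglik_parts(theta)` callables over a
#'   named parameter vector (hierarchical intercepts on the centred
#'   scale, named `u_<factor>[<level>]`).
#' @export
build_model <- function(family = c("hurdle_gamma", "gamma", "negbin", "gaussian"),
                        data, response, terms = character(0),
                        zero_terms = character(0), re = character(0),
                        priors = default_priors(), re_centred = FALSE,
                        prior_only = FALSE) {
  family <- match.arg(family)
  if (!response %in% names(data)) {
    stop("response column not found: ", response, call. = FALSE)
  }
  y <- data[[response]]
  if (length(y) == 0) stop("model data is empty", call. = FALSE)
  if (any(is.na(y))) stop("response contains missing values", call. = FALSE)
  for (f in re) {
    if (!f %in% names(data)) {
      stop("grouping factor column not found: ", f, call. = FALSE)
    }
    if (length(unique(data[[f]])) < 1) stop("empty grouping factor: ", f)
  }
  X <- design_matrix(data, terms, "mean")
  re_fac <- lapply(re, function(f) factor(data[[f]]))
  names(re_fac) <- re
  re_levels <- lapply(re_fac, levels)
  re_idx <- lapply(re_fac, as.integer)

  jd <- list()
  code <- c("model {")
  monitors <- character(0)
  pos_rows <- NULL

  re_sum <- function(suffix) {
    if (length(re) == 0) return("")
    paste0(" + ", paste(sprintf("u%d[g%d%s[i]]", seq_along(re), seq_along(re),
                                suffix), collapse = " + "))
  }

  if (family == "hurdle_gamma") {
    if (any(y < 0)) stop("hurdle-gamma response must be non-negative", call. = FALSE)
    Xz <- design_matrix(data, zero_terms, "zero")
    pos_rows <- which(y > 0)
    if (length(pos_rows) == 0) {
      stop("hurdle-gamma model needs at least one positive response", call. = FALSE)
    }
    jd$zy <- as.integer(y == 0)
    jd$Xz <- Xz
    jd$N <- length(y)
    jd$yp <- y[pos_rows]
    jd$Xp <- X[pos_rows, , drop = FALSE]
    jd$Np <- length(pos_rows)
    for (k in seq_along(re)) jd[[sprintf("g%dp", k)]] <- re_idx[[k]][pos_rows]
    lik <- c(
      "  for (i in 1:N) {",
      "    zy[i] ~ dbern(pz[i])",
      "    logit(pz[i]) <- inprod(Xz[i,], bz[])",
      "  }",
      "  for (i in 1:Np) {",
      "    yp[i] ~ dgamma(shape, shape / mup[i])",
      sprintf("    log(mup[i]) <- inprod(Xp[i,], bp[])%s", re_sum("p")),
      "  }")
    code <- c(code, if (!prior_only) lik,
      coef_prior_lines("bp", ncol(X), priors),
      coef_prior_lines("bz", ncol(Xz), priors),
      sprintf("  shape ~ dnorm(0, %.10g) T(0,)", 1 / priors$shape_scale^2))
    monitors <- c("bp", "bz", "shape")
  } else {
    if (family == "gamma" && any(y <= 0)) {
      stop("gamma response must be positive", call. = FALSE)
    }
    if (family == "negbin" && (any(y < 0) || any(y != round(y)))) {
      stop("negative-binomial response must be non-negative integer", call. = FALSE)
    }
    jd$y <- if (family == "negbin") as.integer(y) else y
    jd$X <- X
    jd$N <- length(y)
    for (k in seq_along(re)) jd[[sprintf("g%d", k)]] <- re_idx[[k]]
    lik <- switch(family,
      gamma = c("    y[i] ~ dgamma(shape, shape / mu[i])",
                sprintf("    log(mu[i]) <- inprod(X[i,], bp[])%s", re_sum(""))),
      negbin = c("    y[i] ~ dnegbin(pnb[i], phi)",
                 "    pnb[i] <- phi / (phi + mu[i])",
                 sprintf("    log(mu[i]) <- inprod(X[i,], bp[])%s", re_sum(""))),
      gaussian = c("    y[i] ~ dnorm(mu[i], pow(sigma_res, -2))",
                   sprintf("    mu[i] <- inprod(X[i,], bp[])%s", re_sum(""))))
    code <- c(code, if (!prior_only) c("  for (i in 1:N) {", lik, "  }"),
              coef_prior_lines("bp", ncol(X), priors))
    disp_line <- switch(family,
      gamma = sprintf("  shape ~ dnorm(0, %.10g) T(0,)", 1 / priors$shape_scale^2),
      negbin = sprintf("  phi ~ dnorm(0, %.10g) T(0,)", 1 / priors$shape_scale^2),
      gaussian = sprintf("  sigma_res ~ dnorm(0, %.10g) T(0,)",
                         1 / priors$shape_scale^2))
    code <- c(code, disp_line)
    monitors <- c("bp", switch(family, gamma = "shape", negbin = "phi",
                               gaussian = "sigma_res"))
  }

  for (k in seq_along(re)) {
    jd[[sprintf("J%d", k)]] <- length(re_levels[[k]])
    re_line <- if (re_centred) {
      sprintf("  for (j in 1:J%d) { u%d[j] ~ dnorm(0, pow(sd%d, -2)) }",
              k, k, k)
    } else {
      sprintf("  for (j in 1:J%d) { zr%d[j] ~ dnorm(0, 1); u%d[j] <- sd%d * zr%d[j] }",
              k, k, k, k, k)
    }
    code <- c(code, re_line,
      sprintf("  sd%d ~ dnorm(0, %.10g) T(0,)", k, 1 / priors$sd_scale^2))
    monitors <- c(monitors, sprintf("sd%d", k), sprintf("u%d", k))
  }
  code <- c(code, "}")
  if (prior_only) {
    jd <- jd[grepl("^J\\d+$", names(jd))]
  }

  mod <- structure(list(
    family = family, response = response, terms = terms,
    zero_terms = zero_terms, re = re, priors = priors,
    X = X, Xz = if (family == "hurdle_gamma") design_matrix(data, zero_terms, "zero") else NULL,
    y = y, pos_rows = pos_rows, re_levels = re_levels, re_idx = re_idx,
    re_centred = re_centred, prior_only = prior_only,
    jags_code = paste(code, collapse = "\n"), jags_data = jd,
    monitors = monitors), class = "cots_model")
  mod$par_names <- model_par_names(mod)
  mod$loglik_parts <- make_loglik_parts(mod)
  mod$log_posterior <- function(theta) {
    p <- mod$loglik_parts(theta)
    unname(p$logprior + p$loglik_zero + p$loglik_mean)
  }
  mod
}

model_par_names <- function(mod) {
  nm <- paste0("b_", colnames(mod$X))
  if (mod$family == "hurdle_gamma") nm <- c(nm, paste0("a_", colnames(mod$Xz)))
  nm <- c(nm, switch(mod$family, hurdle_gamma = "shape", gamma = "shape",
                     negbin = "phi", gaussian = "sigma_res"))
  for (f in names(mod$re_levels)) {
    nm <- c(nm, paste0("sd_", f),
            sprintf("u_%s[%s]", f, mod$re_levels[[f]]))
  }
  nm
}

half_normal_lpdf <- function(x, scale) {
  ifelse(x > 0, dnorm(x, 0, scale, log = TRUE) + log(2), -Inf)
}

scaled_t_lpdf <- function(x, scale, df) {
  dt(x / scale, df = df, log = TRUE) - log(scale)
}

make_loglik_parts <- function(mod) {
  pr <- mod$priors
  force(mod)
  function(theta) {
    stopifnot(!is.null(names(theta)))
    get1 <- function(nm) {
      if (!nm %in% names(theta)) stop("parameter missing from theta: ", nm)
      unname(theta[[nm]])
    }
    b <- vapply(paste0("b_", colnames(mod$X)), get1, numeric(1))
    lp_prior <- scaled_t_lpdf(b[1], pr$intercept_scale, pr$intercept_df)
    if (length(b) > 1) {
      lp_prior <- lp_prior + sum(dnorm(b[-1], 0, pr$coef_scale, log = TRUE))
    }
    # hierarchical intercepts (centred scale in this callable)
    u <- list(); sds <- numeric(0)
    for (f in names(mod$re_levels)) {
      sdf <- get1(paste0("sd_", f))
      uf <- vapply(sprintf("u_%s[%s]", f, mod$re_levels[[f]]), get1, numeric(1))
      lp_prior <- lp_prior + half_normal_lpdf(sdf, pr$sd_scale)
      lp_prior <- lp_prior + if (sdf > 0) sum(dnorm(uf, 0, sdf, log = TRUE)) else -Inf
      u[[f]] <- uf; sds[f] <- sdf
    }
    re_eta <- function(rows) {
      eta <- 0
      for (k in seq_along(mod$re_idx)) {
        f <- names(mod$re_idx)[k]
        eta <- eta + u[[f]][mod$re_idx[[k]][rows]]
      }
      eta
    }
    ll_zero <- 0; ll_mean <- 0
    if (isTRUE(mod$prior_only)) {
      # zero-part coefficient / dispersion priors still apply
      if (mod$family == "hurdle_gamma") {
        a <- vapply(paste0("a_", colnames(mod$Xz)), get1, numeric(1))
        lp_prior <- lp_prior + scaled_t_lpdf(a[1], pr$intercept_scale, pr$intercept_df)
        if (length(a) > 1) {
          lp_prior <- lp_prior + sum(dnorm(a[-1], 0, pr$coef_scale, log = TRUE))
        }
      }
      disp <- switch(mod$family, gaussian = "sigma_res", negbin = "phi", "shape")
      lp_prior <- lp_prior + half_normal_lpdf(get1(disp), pr$shape_scale)
    } else if (mod$family == "hurdle_gamma") {
      a <- vapply(paste0("a_", colnames(mod$Xz)), get1, numeric(1))
      lp_prior <- lp_prior + scaled_t_lpdf(a[1], pr$intercept_scale, pr$intercept_df)
      if (length(a) > 1) {
        lp_prior <- lp_prior + sum(dnorm(a[-1], 0, pr$coef_scale, log = TRUE))
      }
      shape <- get1("shape")
      lp_prior <- lp_prior + half_normal_lpdf(shape, pr$shape_scale)
      pz <- plogis(drop(mod$Xz %*% a))
      zy <- as.numeric(mod$y == 0)
      ll_zero <- sum(zy * log(pz) + (1 - zy) * log1p(-pz))
      rows <- mod$pos_rows
      mu <- exp(drop(mod$X[rows, , drop = FALSE] %*% b) + re_eta(rows))
      yp <- mod$y[rows]
      if (shape <= 0) {
        ll_mean <- -Inf
      } else {
        ll_mean <- sum(dgamma(yp, shape = shape, rate = shape / mu, log = TRUE))
      }
    } else {
      rows <- seq_along(mod$y)
      eta <- drop(mod$X %*% b) + re_eta(rows)
      if (mod$family == "gamma") {
        shape <- get1("shape")
        lp_prior <- lp_prior + half_normal_lpdf(shape, pr$shape_scale)
        ll_mean <- if (shape <= 0) -Inf else
          sum(dgamma(mod$y, shape = shape, rate = shape / exp(eta), log = TRUE))
      } else if (mod$family == "negbin") {
        phi <- get1("phi")
        lp_prior <- lp_prior + half_normal_lpdf(phi, pr$shape_scale)
        ll_mean <- if (phi <= 0) -Inf else
          sum(negbin_logpmf(mod$y, exp(eta), phi))
      } else {
        sr <- get1("sigma_res")
        lp_prior <- lp_prior + half_normal_lpdf(sr, pr$shape_scale)
        ll_mean <- if (sr <= 0) -Inf else
          sum(dnorm(mod$y, eta, sr, log = TRUE))
      }
    }
    list(logprior = unname(lp_prior), loglik_zero = unname(ll_zero),
         loglik_mean = unname(ll_mean))
  }
}

# moment-based starting values: intercept at the (log) mean response,
# shape / dispersion from method-of-moments, zero part at the empirical
# logit; keeps the chains out of degenerate modes far from the data
init_values <- function(mod) {
  y <- mod$y
  pos <- if (mod$family == "hurdle_gamma") y[mod$pos_rows] else y
  m <- mean(pos)
  v <- var(pos)
  ini <- list()
  if (mod$family == "gaussian") {
    ini$b1 <- m
    ini$sigma_res <- max(sd(y), 1e-3)
  } else {
    ini$b1 <- log(max(m, 1e-6))
    if (mod$family %in% c("gamma", "hurdle_gamma")) {
      ini$shape <- min(max(m^2 / max(v, 1e-12), 0.1), 1e4)
    } else {
      # NB2: var = mu + mu^2/phi
      ini$phi <- min(max(m^2 / max(v - m, m / 10), 0.05), 1e4)
    }
  }
  if (mod$family == "hurdle_gamma") {
    ini$a1 <- qlogis(min(max(mean(y == 0), 0.02), 0.98))
  }
  ini
}

init_theta <- function(mod) {
  theta <- setNames(rep(0, length(mod$par_names)), mod$par_names)
  iv <- init_values(mod)
  theta[grepl("^(shape|phi|sigma_res)$", names(theta))] <-
    iv$shape %||% iv$phi %||% iv$sigma_res
  theta[grepl("^sd_", names(theta))] <- 0.5
  theta[paste0("b_", colnames(mod$X)[1])] <- iv$b1
  if (mod$family == "hurdle_gamma") {
    theta[paste0("a_", colnames(mod$Xz)[1])] <- iv$a1
  }
  theta
}

`%||%` <- function(a, b) if (is.null(a)) b else a

jags_inits <- function(mod, chain_seed) {
  iv <- init_values(mod)
  ini <- list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = chain_seed,
              bp = c(iv$b1, rep(0, ncol(mod$X) - 1)))
  if (mod$family == "hurdle_gamma") {
    ini$bz <- c(iv$a1, rep(0, ncol(mod$Xz) - 1))
    ini$shape <- iv$shape
  } else if (mod$family == "gamma") {
    ini$shape <- iv$shape
  } else if (mod$family == "negbin") {
    ini$phi <- iv$phi
  } else {
    ini$sigma_res <- iv$sigma_res
  }
  for (k in seq_along(mod$re_levels)) {
    nm <- if (isTRUE(mod$re_centred)) "u%d" else "zr%d"
    ini[[sprintf(nm, k)]] <- rep(0, length(mod$re_levels[[k]]))
    ini[[sprintf("sd%d", k)]] <- 0.5
  }
  ini
}

#' Split-chain potential scale reduction factor
#'
#' Each chain is split in half before computing the classic
#' between/within-variance R-hat, so non-stationarity within chains also
#' inflates the statistic.
#'
#' @param x Matrix of draws, iterations x chains.
#' @return Split R-hat (NaN for zero-variance parameters).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- floor(n / 2)
  halves <- cbind(x[seq_len(h), , drop = FALSE],
                  x[(n - h + 1):n, , drop = FALSE])
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  W <- mean(vars)
  B <- h * var(means)
  sqrt(((h - 1) / h * W + B / h) / W)
}

rename_jags_pars <- function(cn, mod) {
  out <- cn
  map_vec <- function(prefix, new_prefix, labels) {
    for (j in seq_along(labels)) {
      out[out == sprintf("%s[%d]", prefix, j)] <<-
        sprintf("%s%s", new_prefix, labels[j])
    }
    out[out == prefix] <<- sprintf("%s%s", new_prefix, labels[1])
  }
  map_vec("bp", "b_", colnames(mod$X))
  if (mod$family == "hurdle_gamma") map_vec("bz", "a_", colnames(mod$Xz))
  for (k in seq_along(mod$re_levels)) {
    f <- names(mod$re_levels)[k]
    out[out == sprintf("sd%d", k)] <- paste0("sd_", f)
    lv <- mod$re_levels[[k]]
    for (j in seq_along(lv)) {
      out[out == sprintf("u%d[%d]", k, j)] <- sprintf("u_%s[%s]", f, lv[j])
    }
  }
  out
}

#' Fit a model by MCMC
#'
#' Runs the model's JAGS program with `chains` parallel chains (fixed
#' per-chain RNG seeds derived from `seed`, so runs are reproducible),
#' discards `warmup` iterations after `adapt` adaptation steps, and
#' retains `iter` iterations per chain. Convergence is assessed with
#' split R-hat and effective sample size for every monitored parameter;
#' if any split R-hat exceeds 1.01 or any ESS falls below 400 the fit is
#' returned with `converged = FALSE` and a prominent warning rather than
#' silently.
#'
#' @param model A `cots_model` from [build_model()].
#' @param chains,warmup,iter,adapt Sampler settings.
#' @param seed Integer seed (mandatory).
#' @param monitor_re Monitor the hierarchical intercept values themselves
#'   (needed for posterior predictive checks).
#' @param quiet Suppress JAGS progress output.
#' @return A `cots_fit` with elements `draws` (matrix, one row per
#'   chain-iteration), `diagnostics` (per-parameter split R-hat and ESS),
#'   `converged`, and sampler metadata.
#' @export
fit_model <- function(model, chains = 4, warmup = 1000, iter = 1000,
                      seed, adapt = 500, monitor_re = TRUE, quiet = TRUE) {
  stopifnot(inherits(model, "cots_model"))
  if (missing(seed)) stop("seed is mandatory for fit_model()", call. = FALSE)
  th0 <- init_theta(model)
  lp0 <- model$log_posterior(th0)
  if (!is.finite(lp0)) {
    stop("log-posterior is not finite at initialization; theta0 = ",
         paste(sprintf("%s=%.3g", names(th0), th0), collapse = ", "),
         call. = FALSE)
  }
  inits <- lapply(seq_len(chains), function(ch) {
    jags_inits(model, sub_seed(seed, 100 + ch))
  })
  monitors <- model$monitors
  if (!monitor_re) {
    monitors <- setdiff(monitors, sprintf("u%d", seq_along(model$re_levels)))
  }
  jm <- rjags::jags.model(textConnection(model$jags_code),
                          data = model$jags_data, inits = inits,
                          n.chains = chains, n.adapt = adapt, quiet = quiet)
  if (warmup > 0) {
    stats::update(jm, n.iter = warmup, progress.bar = "none")
  }
  samp <- rjags::coda.samples(jm, variable.names = monitors, n.iter = iter,
                              progress.bar = "none")
  cn <- rename_jags_pars(colnames(samp[[1]]), model)
  for (i in seq_along(samp)) colnames(samp[[i]]) <- cn
  draws <- do.call(rbind, lapply(samp, as.matrix))
  chain_id <- rep(seq_len(chains), each = iter)

  rhat <- vapply(cn, function(p) {
    split_rhat(sapply(samp, function(s) as.numeric(s[, p])))
  }, numeric(1))
  ess <- tryCatch(coda::effectiveSize(samp), error = function(e) {
    setNames(rep(NA_real_, length(cn)), cn)
  })
  diag_tbl <- tibble::tibble(parameter = cn, rhat = unname(rhat[cn]),
                             ess = unname(as.numeric(ess[cn])))
  converged <- all(diag_tbl$rhat <= 1.01, na.rm = TRUE) &&
    all(diag_tbl$ess >= 400, na.rm = TRUE)
  fit <- structure(list(draws = draws, chain = chain_id, chains = chains,
                        warmup = warmup, iter = iter, seed = seed,
                        diagnostics = diag_tbl, converged = converged,
                        model = model), class = "cots_fit")
  if (!converged) {
    worst <- diag_tbl[which.max(diag_tbl$rhat), ]
    warning(sprintf(
      "MCMC convergence check FAILED (worst split R-hat %.3f for %s, min ESS %.0f); treat this fit as unreliable",
      worst$rhat, worst$parameter, min(diag_tbl$ess, na.rm = TRUE)),
      call. = FALSE)
  }
  fit
}

#' @export
print.cots_fit <- function(x, ...) {
  cat(sprintf("<cots_fit> %s model: %d chains x %d iterations (%d warmup)\n",
              x$model$family, x$chains, x$iter, x$warmup))
  cat(sprintf("  %d parameters; converged: %s\n", ncol(x$draws),
              x$converged))
  invisible(x)
}

#' Extract draws of one parameter
#'
#' @param fit A `cots_fit`.
#' @param parameter Parameter name.
#' @return Numeric vector of pooled posterior draws.
#' @export
draws_of <- function(fit, parameter) {
  if (!parameter %in% colnames(fit$draws)) {
    stop("no such parameter in fit: ", parameter, call. = FALSE)
  }
  as.numeric(fit$draws[, parameter])
}

#' Posterior draws as a tidy table
#'
#' @param fit A `cots_fit`.
#' @return Tibble with `.chain`, `.iteration` and one column per parameter.
#' @export
posterior_draws <- function(fit) {
  tibble::as_tibble(as.data.frame(fit$draws)) |>
    dplyr::mutate(.chain = fit$chain,
                  .iteration = rep(seq_len(fit$iter), fit$chains),
                  .before = 1)
}

#' Persist draws and diagnostics
#'
#' Writes the chain-iteration draw table as CSV and a diagnostics sidecar
#' (split R-hat, ESS, sampler settings, seed) as JSON.
#'
#' @param fit A `cots_fit`.
#' @param prefix Output path prefix; writes `<prefix>_draws.csv` and
#'   `<prefix>_diagnostics.json`.
#' @return The two paths, invisibly.
#' @export
write_draws <- function(fit, prefix) {
  p1 <- paste0(prefix, "_draws.csv")
  p2 <- paste0(prefix, "_diagnostics.json")
  utils::write.csv(posterior_draws(fit), p1, row.names = FALSE)
  jsonlite::write_json(list(
    chains = fit$chains, iter = fit$iter, warmup = fit$warmup,
    seed = fit$seed, converged = fit$converged,
    diagnostics = fit$diagnostics), p2, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2))
}
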