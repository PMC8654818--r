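test_that("model construction validates its inputs", {
  d <- data.frame(y = rpois(20, 2), x = rnorm(20), g = rep(1:4, 5))
  expect_error(build_model("negbin", d, "y", terms = "nope"), "nope")
  expect_error(build_model("negbin", d, "z"), "z")
  expect_error(build_model("negbin", d, "y", re = "h"), "h")
  expect_error(build_model("negbin", d[0, ], "y"), "empty")
  d$const <- 1
  expect_warning(build_model("negbin", d, "y", terms = "const"), "constant")
  d$y[1] <- 0.5
  expect_error(build_model("negbin", d, "y"), "integer")
})

test_that("the joint log-posterior equals an independently summed oracle", {
  set.seed(2)
  n <- 25
  d <- data.frame(y = rpois(n, 3), x = rnorm(n),
                  g = rep(c("u", "v", "w", "x", "y"), 5))
  mod <- build_model("negbin", d, "y", terms = "x", re = "g")
  theta <- c(b_intercept = 0.7, b_x = -0.3, phi = 1.4, sd_g = 0.6,
             `u_g[u]` = 0.1, `u_g[v]` = -0.2, `u_g[w]` = 0.05,
             `u_g[x]` = 0.3, `u_g[y]` = -0.15)
  # oracle written out term by term, independent of the model code
  u <- theta[5:9][match(d$g, c("u", "v", "w", "x", "y"))]
  eta <- theta["b_intercept"] + theta["b_x"] * d$x + u
  ll <- sum(dnbinom(d$y, mu = exp(eta), size = theta["phi"], log = TRUE))
  lp <- dt(0.7 / 2.5, df = 3, log = TRUE) - log(2.5) +
    dnorm(-0.3, 0, 2.5, log = TRUE) +
    dnorm(1.4, 0, 5, log = TRUE) + log(2) +
    dnorm(0.6, 0, 2, log = TRUE) + log(2) +
    sum(dnorm(theta[5:9], 0, 0.6, log = TRUE))
  expect_equal(mod$log_posterior(theta), ll + lp, tolerance = 1e-10)
  parts <- mod$loglik_parts(theta)
  expect_equal(parts$loglik_mean, ll, tolerance = 1e-10)
})

test_that("the hurdle log-likelihood decomposes as the hurdle-gamma density", {
  set.seed(3)
  n <- 40
  d <- data.frame(y = rhurdle_gamma(n, 0.3, 2, 1.5), x = runif(n))
  mod <- build_model("hurdle_gamma", d, "y", terms = "x", zero_terms = "x")
  theta <- c(b_intercept = 0.4, b_x = 0.2, a_intercept = -0.5, a_x = 0.8,
             shape = 1.2)
  parts <- mod$loglik_parts(theta)
  pz <- plogis(-0.5 + 0.8 * d$x)
  mu <- exp(0.4 + 0.2 * d$x)
  want <- sum(hurdle_gamma_logdensity(d$y, pz, mu, 1.2))
  expect_equal(parts$loglik_zero + parts$loglik_mean, want, tolerance = 1e-10)
})

test_that("a zero-part-only covariate has zero gradient on the gamma part", {
  set.seed(4)
  n <- 30
  d <- data.frame(y = rgamma(n, 2, 1) + 0.01, zoning = rep(0:1, 15))
  mod <- build_model("hurdle_gamma", d, "y", zero_terms = "zoning")
  base <- c(b_intercept = 0.3, a_intercept = -2, a_zoning = 0.5, shape = 1.5)
  bump <- base; bump["a_zoning"] <- base["a_zoning"] + 1e-4
  g_mean <- (mod$loglik_parts(bump)$loglik_mean -
               mod$loglik_parts(base)$loglik_mean) / 1e-4
  g_zero <- (mod$loglik_parts(bump)$loglik_zero -
               mod$loglik_parts(base)$loglik_zero) / 1e-4
  expect_equal(g_mean, 0)
  expect_false(g_zero == 0)
})

test_that("the sampler reproduces conjugate posterior moments on a gaussian toy", {
  set.seed(5)
  n <- 200
  d <- data.frame(y = rnorm(n, 1.5, 1))
  mod <- build_model("gaussian", d, "y")
  fit <- suppressWarnings(
    fit_model(mod, chains = 2, warmup = 300, iter = 700, seed = 11))
  post <- draws_of(fit, "b_intercept")
  # with n = 200 the weak prior is negligible: posterior ~ N(ybar, s/sqrt(n))
  expect_lt(abs(mean(post) - mean(d$y)), 0.04)
  expect_lt(abs(sd(post) - sd(d$y) / sqrt(n)) / (sd(d$y) / sqrt(n)), 0.25)
})

test_that("fits are deterministic given the seed", {
  set.seed(6)
  d <- data.frame(y = rnorm(50, 2, 1))
  mod <- build_model("gaussian", d, "y")
  f1 <- suppressWarnings(fit_model(mod, chains = 2, warmup = 100, iter = 150,
                                   seed = 42))
  f2 <- suppressWarnings(fit_model(mod, chains = 2, warmup = 100, iter = 150,
                                   seed = 42))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(fit_model(mod, chains = 2, warmup = 100, iter = 150,
                                   seed = 43))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("a non-finite log-posterior at initialization is an informative error", {
  d <- data.frame(y = rnorm(10))
  mod <- build_model("gaussian", d, "y")
  mod$log_posterior <- function(theta) -Inf
  expect_error(fit_model(mod, chains = 1, warmup = 10, iter = 10, seed = 1),
               "not finite at initialization")
  expect_error(fit_model(build_model("gaussian", d, "y"), chains = 1,
                         warmup = 10, iter = 10),
               "seed")
})

test_that("a single-level grouping factor reduces to the fixed-intercept fit", {
  set.seed(7)
  d <- data.frame(y = rnorm(80, 1 + 0.5 * rep(0:1, 40), 1),
                  x = rep(0:1, 40), g = "only")
  m0 <- build_model("gaussian", d, "y", terms = "x")
  m1 <- build_model("gaussian", d, "y", terms = "x", re = "g")
  f0 <- suppressWarnings(fit_model(m0, chains = 2, warmup = 300, iter = 700,
                                   seed = 2))
  f1 <- suppressWarnings(fit_model(m1, chains = 2, warmup = 300, iter = 700,
                                   seed = 2))
  expect_lt(abs(mean(draws_of(f0, "b_x")) - mean(draws_of(f1, "b_x"))), 0.08)
})

test_that("prior-only sampling recovers the prior quantiles", {
  d <- data.frame(y = rpois(20, 2), x = rnorm(20))
  mod <- build_model("negbin", d, "y", terms = "x", prior_only = TRUE)
  fit <- suppressWarnings(fit_model(mod, chains = 2, warmup = 200, iter = 3000,
                                    seed = 8))
  slope <- draws_of(fit, "b_x")
  expect_lt(abs(sd(slope) - 2.5) / 2.5, 0.1)
  expect_lt(abs(mean(slope)), 0.15)
  phi <- draws_of(fit, "phi")
  # half-Normal(0, 5) quartiles
  expect_lt(abs(median(phi) - 5 * qnorm(0.75)) / (5 * qnorm(0.75)), 0.15)
})

test_that("split R-hat flags separated chains and passes identical ones", {
  set.seed(9)
  good <- matrix(rnorm(4000), ncol = 4)
  expect_lt(split_rhat(good), 1.02)
  bad <- good; bad[, 1] <- bad[, 1] + 3
  expect_gt(split_rhat(bad), 1.5)
})

test_that("evidence summaries classify by strict posterior-mass thresholds", {
  expect_equal(evidence_class(c(100, 96, 95, 90, 81, 80, 50)),
               c(">95%", ">95%", ">80%", ">80%", ">80%", "none", "none"))
  s <- summarise_evidence(list(p = rep(c(2, 1), 600)), min_draws = 1000)
  expect_equal(s$pct_above_zero, 100)
  expect_equal(s$class, ">95%")
  s <- summarise_evidence(list(p = c(-1, 1, 2, 3)), min_draws = 4)
  expect_equal(s$pct_above_zero, 75)
  expect_equal(s$class, "none")
  set.seed(10)
  s <- summarise_evidence(list(p = rnorm(4000)), min_draws = 1000)
  expect_lt(abs(s$pct_above_zero - 50), 4)
  expect_equal(s$class, "none")
  expect_error(summarise_evidence(list(p = rnorm(10))), "at least")
})

test_that("fit summaries expose medians and ordered equal-tailed intervals", {
  set.seed(11)
  d <- data.frame(y = rnorm(60, 2, 1))
  fit <- suppressWarnings(fit_model(build_model("gaussian", d, "y"),
                                    chains = 2, warmup = 200, iter = 600,
                                    seed = 3))
  s <- summarise_evidence(fit, "b_intercept", min_draws = 1000)
  expect_true(s$l95 < s$l60 && s$l60 < s$median &&
                s$median < s$u60 && s$u60 < s$u95)
  expect_equal(s$median, median(draws_of(fit, "b_intercept")))
})

test_that("the zero-fraction PPC is well calibrated for the count model", {
  set.seed(12)
  n <- 150
  ok <- 0
  for (trial in 1:5) {
    d <- data.frame(y = rnbinom(n, mu = 1.2, size = 0.8),
                    g = rep(paste0("g", 1:10), 15))
    fit <- suppressWarnings(fit_model(
      build_model("negbin", d, "y", re = "g"),
      chains = 1, warmup = 300, iter = 400, seed = 20 + trial))
    p <- ppc_zero_fraction(fit, n_rep = 200, seed = trial)
    if (p$tail_prob > 0.025) ok <- ok + 1
  }
  expect_gte(ok, 4)
  # all-positive data with essentially zero zero-probability: the observed
  # zero fraction sits in the central region of the replicates, not a tail
  d <- data.frame(y = pmax(rnbinom(n, mu = 20, size = 5), 1L))
  fit <- suppressWarnings(fit_model(build_model("negbin", d, "y"),
                                    chains = 1, warmup = 300, iter = 400,
                                    seed = 30))
  p <- ppc_zero_fraction(fit, n_rep = 200, seed = 1)
  expect_equal(p$observed, 0)
  expect_gt(p$tail_prob, 0.2)
})

test_that("shifting a covariate moves only the intercept, not the slope", {
  set.seed(13)
  n <- 250
  d <- data.frame(x = runif(n))
  d$y <- rnbinom(n, mu = exp(0.5 - 0.8 * d$x), size = 1.5)
  f1 <- suppressWarnings(fit_model(build_model("negbin", d, "y", terms = "x"),
                                   chains = 2, warmup = 300, iter = 500,
                                   seed = 4))
  d2 <- d; d2$x <- d2$x + 1
  f2 <- suppressWarnings(fit_model(build_model("negbin", d2, "y", terms = "x"),
                                   chains = 2, warmup = 300, iter = 500,
                                   seed = 4))
  s1 <- mean(draws_of(f1, "b_x")); s2 <- mean(draws_of(f2, "b_x"))
  mcse <- sd(draws_of(f1, "b_x")) / sqrt(200)
  expect_lt(abs(s1 - s2), 6 * mcse + 0.02)
  i1 <- mean(draws_of(f1, "b_intercept")); i2 <- mean(draws_of(f2, "b_intercept"))
  expect_lt(abs((i1 - i2) - mean(c(s1, s2))), 0.1)
})

test_that("draw persistence round-trips with its diagnostics sidecar", {
  set.seed(14)
  d <- data.frame(y = rnorm(40))
  fit <- suppressWarnings(fit_model(build_model("gaussian", d, "y"),
                                    chains = 2, warmup = 100, iter = 200,
                                    seed = 5))
  dir <- withr::local_tempdir()
  write_draws(fit, file.path(dir, "toy"))
  back <- utils::read.csv(file.path(dir, "toy_draws.csv"))
  expect_equal(nrow(back), 400)
  expect_equal(back$b_intercept, unname(fit$draws[, "b_intercept"]))
  meta <- jsonlite::read_json(file.path(dir, "toy_diagnostics.json"))
  expect_equal(meta$seed, 5)
  expect_equal(length(meta$diagnostics), ncol(fit$draws))
})
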