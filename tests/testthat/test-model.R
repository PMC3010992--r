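# The state-space model: densities, derived quantities, and the MCMC fit.

test_that("circle-of-confusion radius follows the stationary-scale formula", {
  expect_equal(coc_radius(5, 0), 5)
  expect_equal(coc_radius(13.6, 0.99), 13.6 / sqrt(1 - 0.99^2))
  expect_equal(coc_radius(13.6, 0.99), 96.408, tolerance = 1e-3)
  expect_true(is.finite(coc_radius(1, 0.999999)))
  expect_error(coc_radius(1, 1), "gamma")
  expect_error(coc_radius(-1, 0.5), "sigma")
  # variance-corrected version needs nu > 2
  expect_equal(coc_radius(5, 0, nu = 4, corrected = TRUE),
               5 * sqrt(2))
  expect_error(coc_radius(5, 0, nu = 2, corrected = TRUE), "nu > 2")
})

test_that("confidence-radius conversion uses normal quantiles", {
  expect_equal(coc_interval(100), 195.9964, tolerance = 1e-4)
  expect_equal(coc_interval(100, 2 * pnorm(1) - 1), 100, tolerance = 1e-10)
  lv <- seq(0.1, 0.99, by = 0.05)
  expect_true(all(diff(coc_interval(100, lv[1]) * 0 +
                         vapply(lv, coc_interval, 0, coc = 100)) > 0))
  expect_error(coc_interval(-1), "coc")
  expect_error(coc_interval(10, 1.2), "level")
})

test_that("log joint density matches hand computation on a tiny case", {
  y <- c(0, 1, 0)
  x <- c(0.2, 0.8, 0.1)
  gamma <- 0.5; sigma <- 2; a <- 3; b <- 2; theta <- 1; tau <- 4
  nu <- 5; se <- 1.5
  pr <- coc_priors(sigma_eps_mean = 2, sigma_eps_sd = 1)
  got <- coc_log_joint(y, x, gamma, sigma, a, b, theta, tau, nu, se, pr)
  # independent arithmetic, term by term
  want <- sum(dnorm(y, x, se, log = TRUE)) +
    dnorm(x[1], y[1], 10 * se, log = TRUE) +
    (dt((x[2] - gamma * x[1]) / sigma, nu, log = TRUE) - log(sigma)) +
    (dt((x[3] - gamma * x[2]) / sigma, nu, log = TRUE) - log(sigma)) +
    dbeta((1 + gamma) / 2, a, b, log = TRUE) + log(0.5) +
    dnorm(sigma, theta, tau, log = TRUE) - pnorm(theta / tau, log.p = TRUE) +
    dnorm(se, 2, 1, log = TRUE) - pnorm(2 / 1, log.p = TRUE) -
    log(diff(pr$a_range)) - log(diff(pr$b_range)) -
    log(diff(pr$theta_range)) - log(diff(pr$tau_range)) -
    log(diff(pr$nu_range))
  expect_equal(got, want, tolerance = 1e-12)
  # outside support
  expect_identical(coc_log_joint(y, x, 1.2, sigma, a, b, theta, tau, nu,
                                 se, pr), -Inf)
  expect_identical(coc_log_joint(y, x, gamma, -1, a, b, theta, tau, nu,
                                 se, pr), -Inf)
})

test_that("t process terms converge to the Gaussian limit in nu", {
  y <- c(0, 1, 0, -1, 2)
  x <- c(0.1, 0.9, 0.2, -0.8, 1.5)
  pr <- coc_priors(nu_range = c(1.5, 1e7))
  lt <- coc_log_joint(y, x, 0.6, 1.3, 2, 2, 1, 5, 1e6, 1, pr)
  lg <- coc_log_joint(y, x, 0.6, 1.3, 2, 2, 1, 5, Inf, 1, pr)
  # remove the nu hyper-prior constant present only in the finite case
  expect_equal(lt + log(diff(pr$nu_range)), lg, tolerance = 1e-3)
})

test_that("Gaussian forward-filter likelihood matches a dense MVN oracle", {
  set.seed(71)
  for (i in 1:20) {
    g <- runif(1, -0.9, 0.98)
    s <- runif(1, 0.5, 10)
    se <- runif(1, 0.5, 3)
    y <- simulate_deviations(g, s, Inf, se, 8)$y
    expect_equal(coc_loglik_gaussian(y, g, s, se),
                 oracle_gauss_loglik(y, g, s, se), tolerance = 1e-8)
  }
  # missing observations marginalize out
  y <- simulate_deviations(0.8, 3, Inf, 1, 10)$y
  y[c(4, 7)] <- NA
  expect_equal(coc_loglik_gaussian(y, 0.8, 3, 1),
               oracle_gauss_loglik(y, 0.8, 3, 1), tolerance = 1e-8)
})

test_that("fit honours the retention protocol and is seed-reproducible", {
  set.seed(73)
  sim <- simulate_population(coc_sim_spec(n_per_group = 2, n_days = 30,
                                          seed = 73))
  ctl <- coc_control(n_chains = 2, n_iter = 600, n_burnin = 300, thin = 3,
                     seed = 5)
  f1 <- suppressWarnings(coc_fit(sim$series, control = ctl))
  expect_equal(f1$n_draws, 2 * (600 - 300) / 3)
  expect_equal(nrow(f1$draws$gamma), 200)
  f2 <- suppressWarnings(coc_fit(sim$series, control = ctl))
  expect_identical(f1$draws$gamma, f2$draws$gamma)
  expect_identical(f1$draws$sigma_eps, f2$draws$sigma_eps)
  # default protocol arithmetic: 2 x (40000 - 20000)/5 retained draws
  expect_equal(with(coc_control(), n_chains * (n_iter - n_burnin) / thin),
               8000)
})

test_that("fit output is structurally complete", {
  sim <- simulate_population(coc_sim_spec(n_per_group = 2, n_days = 40,
                                          seed = 79))
  fit <- quick_fit(sim$series, sex = sim$params$sex, grouping = "by_sex",
                   chains = 2, seed = 79)
  expect_s3_class(fit, "coc_fit")
  # by_sex: one hyper column per sex, shared measurement SD
  expect_equal(colnames(fit$draws$a), c("female", "male"))
  expect_equal(ncol(fit$draws$coc_mean), 2)
  expect_true(is.numeric(fit$draws$sigma_eps))
  expect_true(all(fit$draws$coc > 0))
  expect_true(all(abs(fit$draws$gamma) < 1))
  expect_true(all(is.finite(fit$rhat)))

  # methods
  cf <- coef(fit)
  expect_equal(dim(cf), c(4L, 3L))
  s <- summary(fit)
  expect_true(all(c("coc_mean[male]", "coc_pred[female]", "sigma_eps",
                    "nu[male]") %in% s$parameter))
  expect_true(all(s$q2.5 <= s$q50 & s$q50 <= s$q97.5))
  expect_output(print(fit), "circle-of-confusion")
  res <- residuals(fit)
  expect_equal(lengths(res), lengths(sim$series))
  reps <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(length(reps), 2)
  expect_equal(lengths(reps[[1]]), lengths(sim$series))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("summary quantiles follow the default quantile rule", {
  sim <- simulate_population(coc_sim_spec(n_per_group = 1, n_days = 30,
                                          seed = 83))
  fit <- quick_fit(sim$series)
  s <- summary(fit)
  g <- fit$draws$gamma[, 1]
  expect_equal(s$q50[s$parameter == "gamma[M1]"],
               unname(quantile(g, 0.5, type = 7)))
  expect_equal(s$q2.5[s$parameter == "gamma[M1]"],
               unname(quantile(g, 0.025, type = 7)))
  # the documented rule on a known vector
  expect_equal(unname(quantile(1:100, c(0.025, 0.5, 0.975))),
               c(3.475, 50.5, 97.525))
})

test_that("missing observation days are carried through the fit", {
  set.seed(89)
  y <- simulate_deviations(0.9, 5, 4, 2, 40)$y
  y[c(10:13, 25)] <- NA
  fit <- quick_fit(list(A = y), store_states = TRUE)
  expect_equal(ncol(fit$states$A), 40)
  expect_true(all(is.finite(fit$states$A)))
  r <- residuals(fit)$A
  expect_true(all(is.na(r[c(10:13, 25)])))
})

test_that("predictive distribution requires a hierarchical fit", {
  set.seed(97)
  y <- simulate_deviations(0.9, 5, 4, 2, 30)$y
  nh <- quick_fit(list(A = y),
                  fix = list(hyper = list(a = 2, b = 2, theta = 5,
                                          tau = 10)))
  expect_error(predictive_coc(nh), "hierarchical")
  sim <- simulate_population(coc_sim_spec(n_per_group = 2, n_days = 30,
                                          seed = 97))
  h <- quick_fit(sim$series)
  pc <- predictive_coc(h)
  expect_equal(length(pc), h$n_draws)
  expect_true(all(pc > 0))
  expect_equal(predict(h), pc)
  # near-degenerate hyper draws concentrate gamma* at zero
  hf <- h
  hf$draws$a[] <- 1e6
  hf$draws$b[] <- 1e6
  pd <- cocnav:::.predictive_draws(hf)
  expect_lt(max(abs(pd$gamma)), 0.01)
  expect_equal(pd$coc, pd$sigma, tolerance = 1e-4)
})

test_that("fixed-parameter fits pin the requested values", {
  set.seed(101)
  y <- simulate_deviations(0.8, 4, Inf, 1, 30)$y
  fit <- quick_fit(list(A = y),
                   fix = list(gamma = 0, nu = Inf, sigma_eps = 1,
                              hyper = list(a = 2, b = 2, theta = 0,
                                           tau = 10)))
  expect_true(all(fit$draws$gamma == 0))
  expect_true(all(fit$draws$sigma_eps == 1))
  expect_true(all(!is.finite(fit$draws$nu)))
})
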