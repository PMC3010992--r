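# The hierarchical Bayesian AR(1) state-space model of cross-track
# deviations ("circle of confusion" model) and its MCMC fit.
#
# Observation equation:  y_t = x_t + eps_t,  eps_t ~ N(0, sigma_eps^2)
# Process equation:      x_t = gamma_j x_{t-1} + w_t,
#                        w_t ~ sigma_j * t_nu (scaled t)
# Individual level:      (1 + gamma_j)/2 ~ Beta(a, b)
#                        sigma_j ~ N(theta, tau^2) truncated to (0, Inf)
# Hyper level:           a, b, theta, tau, nu ~ uniform; sigma_eps shared
#                        across animals with an informative truncated-normal
#                        prior.
#
# The circle of confusion is the stationary scale of the deviation process,
# coc_j = sigma_j / sqrt(1 - gamma_j^2). Note sigma_j is the SCALE of the t
# shock, not its standard deviation: the fitted degrees of freedom are
# routinely near or below 2, where the t variance is infinite, so the
# scale-based definition is the meaningful (and finite) one. A
# variance-corrected radius is available via coc_radius(..., corrected =).

#' Prior specification for the circle-of-confusion model
#'
#' @param sigma_eps_mean,sigma_eps_sd Mean and SD (km) of the informative
#'   truncated-normal prior on the shared measurement SD. Defaults 2 km and
#'   0.02 km, the magnitude implied by published Argos error estimates after
#'   MCD regularization.
#' @param a_range,b_range Uniform hyper-prior bounds for the beta shape
#'   parameters of the (transformed) prior on `gamma`. The default `U(1, 20)`
#'   bounds cap the population concentration `a + b`: individual `gamma`
#'   likelihoods are one-sidedly flat toward 1, and an unbounded
#'   concentration lets the population distribution degenerate to a spike on
#'   that ridge, over-shrinking every individual (see the methods vignette).
#' @param theta_range,tau_range Uniform bounds (km) for the truncated-normal
#'   hyper-parameters of the process-error scales.
#' @param nu_range Uniform bounds for the process-error degrees of freedom.
#' @return A list of class `"coc_priors"`.
#' @export
coc_priors <- function(sigma_eps_mean = 2, sigma_eps_sd = 0.02,
                       a_range = c(1, 150), b_range = c(0.3, 20),
                       theta_range = c(0, 50), tau_range = c(0.01, 50),
                       nu_range = c(1.5, 50)) {
  chk <- function(r, nm) {
    if (length(r) != 2 || r[1] >= r[2] || any(!is.finite(r)))
      stop(nm, " must be finite bounds with lower < upper")
  }
  chk(a_range, "a_range"); chk(b_range, "b_range")
  chk(theta_range, "theta_range"); chk(tau_range, "tau_range")
  chk(nu_range, "nu_range")
  if (sigma_eps_sd <= 0) stop("sigma_eps_sd must be positive")
  structure(list(sigma_eps_mean = sigma_eps_mean,
                 sigma_eps_sd = sigma_eps_sd,
                 a_range = a_range, b_range = b_range,
                 theta_range = theta_range, tau_range = tau_range,
                 nu_range = nu_range),
            class = "coc_priors")
}

#' MCMC protocol settings
#'
#' Defaults follow the standard protocol for this model: 2 chains of 40,000
#' iterations, the first 20,000 discarded as burn-in and every 5th retained
#' thereafter, yielding 8,000 posterior draws.
#'
#' @param n_chains Number of chains.
#' @param n_iter Iterations per chain.
#' @param n_burnin Burn-in iterations discarded per chain.
#' @param thin Retain every `thin`-th post-burn-in draw.
#' @param seed Integer seed; all chain streams derive from it
#'   deterministically.
#' @return A list of class `"coc_control"`.
#' @export
coc_control <- function(n_chains = 2, n_iter = 40000, n_burnin = 20000,
                        thin = 5, seed = 1L) {
  if (n_burnin >= n_iter) stop("n_burnin must be smaller than n_iter")
  if (thin < 1) stop("thin must be >= 1")
  if (n_chains < 1) stop("need at least one chain")
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "coc_control")
}

#' Circle-of-confusion radius
#'
#' The stationary scale of the AR(1) deviation process,
#' `sigma / sqrt(1 - gamma^2)`: the radius (km) around the animal's
#' position within which it cannot determine its location. `sigma` is the
#' scale of the t-distributed process error; with `corrected = TRUE` and
#' `nu > 2` the variance-based radius
#' `sqrt(nu / (nu - 2)) * sigma / sqrt(1 - gamma^2)` is returned instead.
#'
#' @param sigma Process-error scale(s), km, positive.
#' @param gamma AR(1) coefficient(s), strictly inside (-1, 1).
#' @param nu Degrees of freedom, needed only when `corrected = TRUE`.
#' @param corrected Return the variance-corrected radius (requires
#'   `nu > 2`).
#' @return Radius in km.
#' @export
coc_radius <- function(sigma, gamma, nu = NULL, corrected = FALSE) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(abs(gamma) >= 1))
    stop("|gamma| must be < 1 (stationary process)")
  r <- sigma / sqrt(1 - gamma^2)
  if (corrected) {
    if (is.null(nu)) stop("corrected radius requires nu")
    if (any(nu <= 2))
      stop("variance correction requires nu > 2")
    r <- r * sqrt(nu / (nu - 2))
  }
  r
}

#' Confidence-radius interpretation of the circle of confusion
#'
#' Half-width (km) of the central `level` interval of a normal positional
#' uncertainty with scale `coc`: `qnorm((1 + level)/2) * coc`. At the
#' default level 0.95 this is 1.96 times the circle of confusion.
#'
#' @param coc Circle-of-confusion radius (km), positive.
#' @param level Coverage level in (0, 1).
#' @return Half-width in km.
#' @export
coc_interval <- function(coc, level = 0.95) {
  if (any(coc <= 0)) stop("coc must be positive")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  stats::qnorm((1 + level) / 2) * coc
}

# log density of a truncated normal on (0, Inf)
.ldtnorm <- function(x, mean, sd) {
  ifelse(x > 0,
         stats::dnorm(x, mean, sd, log = TRUE) -
           stats::pnorm(mean / sd, log.p = TRUE),
         -Inf)
}

#' Joint log density of the circle-of-confusion model
#'
#' Sum of observation, process, initial-state, individual-prior and
#' hyper-prior log-density terms for a complete configuration of latent
#' states and parameters; `-Inf` outside the joint support. Primarily a
#' validation surface: the MCMC sampler is checked against it and against
#' the exact Gaussian-case likelihood.
#'
#' @param y List of observed deviation series (km; `NA` = missing day), or
#'   a single numeric vector.
#' @param x Latent state series matching `y` in structure (no missing
#'   values).
#' @param gamma,sigma Per-animal AR coefficients and process scales.
#' @param a,b,theta,tau,nu,sigma_eps Hyper-parameters (scalars; single
#'   group).
#' @param priors A [coc_priors()] specification.
#' @return Log joint density (scalar).
#' @export
coc_log_joint <- function(y, x, gamma, sigma, a, b, theta, tau, nu,
                          sigma_eps, priors = coc_priors()) {
  if (is.numeric(y)) y <- list(y)
  if (is.numeric(x)) x <- list(x)
  J <- length(y)
  if (length(x) != J || length(gamma) != J || length(sigma) != J)
    stop("y, x, gamma, sigma must describe the same number of animals")
  inb <- function(v, r) v >= r[1] & v <= r[2]
  if (any(abs(gamma) >= 1) || any(sigma <= 0) || sigma_eps <= 0 ||
      !inb(a, priors$a_range) || !inb(b, priors$b_range) ||
      !inb(theta, priors$theta_range) || !inb(tau, priors$tau_range) ||
      (is.finite(nu) && !inb(nu, priors$nu_range)))
    return(-Inf)
  lp <- 0
  for (j in seq_len(J)) {
    yj <- y[[j]]
    xj <- x[[j]]
    if (length(yj) != length(xj))
      stop("series ", j, ": x and y lengths differ")
    obs <- !is.na(yj)
    if (!any(obs)) stop("series ", j, " has no observations")
    lp <- lp + sum(stats::dnorm(yj[obs], xj[obs], sigma_eps, log = TRUE))
    lp <- lp + stats::dnorm(xj[1], yj[which(obs)[1]], 10 * sigma_eps,
                            log = TRUE)
    e <- xj[-1] - gamma[j] * xj[-length(xj)]
    if (is.finite(nu)) {
      lp <- lp + sum(stats::dt(e / sigma[j], df = nu, log = TRUE) -
                       log(sigma[j]))
    } else {
      lp <- lp + sum(stats::dnorm(e, 0, sigma[j], log = TRUE))
    }
    v <- (1 + gamma[j]) / 2
    lp <- lp + stats::dbeta(v, a, b, log = TRUE) + log(0.5)
    lp <- lp + .ldtnorm(sigma[j], theta, tau)
  }
  lp <- lp + .ldtnorm(sigma_eps, priors$sigma_eps_mean,
                      priors$sigma_eps_sd)
  lp <- lp - log(diff(priors$a_range)) - log(diff(priors$b_range)) -
    log(diff(priors$theta_range)) - log(diff(priors$tau_range))
  if (is.finite(nu)) lp <- lp - log(diff(priors$nu_range))
  lp
}

#' Exact marginal log likelihood in the Gaussian special case
#'
#' With Gaussian process errors (`nu = Inf`) the latent states integrate
#' out analytically; this forward (Kalman) filter returns the exact
#' marginal log likelihood of an observed deviation series given
#' `(gamma, sigma, sigma_eps)`. Used as an independent oracle for the MCMC
#' sampler.
#'
#' @param y Observed deviation series (km; `NA` = missing).
#' @param gamma,sigma AR coefficient and Gaussian process SD.
#' @param sigma_eps Measurement SD (km).
#' @param init_mean,init_sd Initial-state prior; defaults to the first
#'   observed value and `10 * sigma_eps`, matching the fitted model.
#' @return Log likelihood (scalar).
#' @export
coc_loglik_gaussian <- function(y, gamma, sigma, sigma_eps,
                                init_mean = NULL, init_sd = NULL) {
  obs <- !is.na(y)
  if (!any(obs)) stop("no observations")
  if (is.null(init_mean)) init_mean <- y[which(obs)[1]]
  if (is.null(init_sd)) init_sd <- 10 * sigma_eps
  m <- init_mean
  P <- init_sd^2
  R <- sigma_eps^2
  q <- sigma^2
  ll <- 0
  for (t in seq_along(y)) {
    if (t > 1) {
      m <- gamma * m
      P <- gamma^2 * P + q
    }
    if (obs[t]) {
      S <- P + R
      ll <- ll + stats::dnorm(y[t], m, sqrt(S), log = TRUE)
      K <- P / S
      m <- m + K * (y[t] - m)
      P <- (1 - K) * P
    }
  }
  ll
}

# ---------------------------------------------------------------------------
# fitting

.as_dev_list <- function(deviations, sex = NULL) {
  if (is.data.frame(deviations)) {
    if (is.null(deviations$deviation_km))
      stop("data.frame input needs a deviation_km column")
    id <- if (is.null(deviations$animal_id)) rep("A1", nrow(deviations))
    else as.character(deviations$animal_id)
    sx <- if (is.null(deviations$sex)) NULL
    else as.character(deviations$sex)
    ord <- if (is.null(deviations$day_index)) seq_len(nrow(deviations))
    else order(id, deviations$day_index)
    id <- id[ord]
    dv <- deviations$deviation_km[ord]
    if (!is.null(sx)) sx <- sx[ord]
    ids <- unique(id)
    y <- lapply(ids, function(i) as.numeric(dv[id == i]))
    names(y) <- ids
    sexes <- if (is.null(sx)) rep("unknown", length(ids))
    else vapply(ids, function(i) sx[id == i][1], "")
    return(list(y = y, ids = ids, sex = unname(sexes)))
  }
  if (!is.list(deviations)) deviations <- list(deviations)
  ids <- names(deviations)
  if (is.null(ids)) ids <- paste0("A", seq_along(deviations))
  sexes <- if (!is.null(sex)) rep_len(as.character(sex), length(deviations))
  else vapply(deviations, function(d) {
    s <- attr(d, "sex")
    if (is.null(s)) "unknown" else as.character(s)
  }, "")
  list(y = lapply(deviations, as.numeric), ids = ids, sex = sexes)
}

.split_rhat <- function(draws, chain) {
  ch <- split(draws, chain)
  halves <- unlist(lapply(ch, function(v) {
    n <- length(v) %/% 2
    list(v[seq_len(n)], v[(length(v) - n + 1):length(v)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the hierarchical circle-of-confusion model by MCMC
#'
#' Fits the AR(1) state-space model with t-distributed process errors to a
#' collection of cross-track deviation series. Latent states are drawn
#' exactly by forward-filter backward-sampling under a Gamma scale-mixture
#' representation of the t shock; the remaining parameters are updated by
#' adaptive Metropolis steps (adaptation during burn-in only). Under
#' `grouping = "by_sex"` every hyper-parameter except the shared
#' measurement SD is estimated separately per sex.
#'
#' @param deviations Deviation series: a `data.frame` with columns
#'   `animal_id`, `deviation_km` and optionally `sex`, `day_index` (as
#'   produced by [deviation_series()]), or a (named) list of numeric
#'   vectors (km; `NA` = missing day).
#' @param grouping `"common"` (all animals share one set of
#'   hyper-parameters) or `"by_sex"`.
#' @param sex Optional character vector of per-animal sex labels when
#'   `deviations` is a list.
#' @param priors A [coc_priors()] specification.
#' @param control A [coc_control()] protocol.
#' @param fix Optional list pinning parameters instead of sampling them:
#'   `gamma` (scalar applied to all animals), `sigma_eps`, `nu` (may be
#'   `Inf` for Gaussian process errors), and/or `hyper = list(a, b, theta,
#'   tau)` which turns off hyper-parameter updates (a non-hierarchical
#'   fit).
#' @param store_states Keep the retained latent-state draws (needed for
#'   posterior predictive loss and residuals). Default `TRUE`.
#' @return An object of class `"coc_fit"`; see [summary.coc_fit()],
#'   [coef.coc_fit()], [predictive_coc()], [posterior_predictive_replicates()].
#' @examples
#' sim <- simulate_population(coc_sim_spec(n_per_group = 2, n_days = 40,
#'                                         seed = 1))
#' fit <- coc_fit(sim$series, sex = sim$params$sex,
#'                control = coc_control(n_chains = 2, n_iter = 600,
#'                                      n_burnin = 300, thin = 3, seed = 1))
#' fit
#' @export
coc_fit <- function(deviations, grouping = c("common", "by_sex"),
                    sex = NULL, priors = coc_priors(),
                    control = coc_control(), fix = list(),
                    store_states = TRUE) {
  grouping <- match.arg(grouping)
  dat <- .as_dev_list(deviations, sex)
  J <- length(dat$y)
  if (J < 1) stop("need at least one deviation series")
  lens <- lengths(dat$y)
  if (any(lens < 5)) stop("every series must have length >= 5")
  if (any(vapply(dat$y, function(v) sum(!is.na(v)), 0L) < 3))
    stop("every series needs at least 3 observed values")

  if (grouping == "by_sex") {
    if (any(is.na(dat$sex)) || all(dat$sex == "unknown"))
      stop("by_sex grouping requires sex labels")
    grp <- factor(dat$sex)
  } else {
    grp <- factor(rep("all", J))
  }
  G <- nlevels(grp)
  gidx <- as.integer(grp) - 1L

  fix_hyper <- !is.null(fix$hyper)
  fix_nu <- !is.null(fix$nu)
  fix_se <- !is.null(fix$sigma_eps)
  fix_gamma <- !is.null(fix$gamma)

  pr <- list(a_lo = priors$a_range[1], a_hi = priors$a_range[2],
             b_lo = priors$b_range[1], b_hi = priors$b_range[2],
             theta_lo = priors$theta_range[1],
             theta_hi = priors$theta_range[2],
             tau_lo = priors$tau_range[1], tau_hi = priors$tau_range[2],
             nu_lo = priors$nu_range[1], nu_hi = priors$nu_range[2],
             se_mean = priors$sigma_eps_mean, se_sd = priors$sigma_eps_sd)

  run_one <- function(chain_id) {
    set.seed(control$seed + 104729L * chain_id)
    g0 <- vapply(dat$y, function(v) {
      o <- !is.na(v)
      vv <- v[o]
      r <- if (length(vv) > 3) suppressWarnings(
        stats::cor(vv[-1], vv[-length(vv)])) else 0.8
      if (!is.finite(r)) r <- 0.8
      min(max(r, 0.2), 0.99)
    }, 0)
    g0 <- pmin(pmax(g0 + stats::rnorm(J, 0, 0.02), -0.99), 0.995)
    if (fix_gamma) g0 <- rep(fix$gamma, J)
    s0 <- vapply(dat$y, function(v) {
      d <- diff(v[!is.na(v)])
      max(stats::sd(d), 0.5)
    }, 0) * stats::runif(J, 0.6, 1.4)
    x0 <- lapply(dat$y, .na_fill)
    se0 <- if (fix_se) fix$sigma_eps else
      priors$sigma_eps_mean * stats::runif(1, 0.99, 1.01)
    if (fix_hyper) {
      a0 <- rep(fix$hyper$a, G); b0 <- rep(fix$hyper$b, G)
      th0 <- rep(fix$hyper$theta, G); tau0 <- rep(fix$hyper$tau, G)
    } else {
      a0 <- stats::runif(G, 2, 20)
      b0 <- stats::runif(G, max(0.5, priors$b_range[1]),
                         min(3, priors$b_range[2]))
      th0 <- pmin(pmax(rep(mean(s0), G), priors$theta_range[1]),
                  priors$theta_range[2])
      tau_base <- if (J > 1) stats::sd(s0) else s0 / 2
      tau0 <- pmin(pmax(rep(tau_base + 1, G), priors$tau_range[1] * 2),
                   priors$tau_range[2])
    }
    nu0 <- if (fix_nu) rep(fix$nu, G) else stats::runif(G, 3, 10)
    init <- list(gamma = g0, sigma = s0, a = a0, b = b0, theta = th0,
                 tau = tau0, nu = nu0, sigma_eps = se0, x = x0)
    stopifnot(all(vapply(init[c("gamma", "sigma", "a", "b", "theta",
                                "tau", "sigma_eps")],
                         function(v) all(is.finite(v)), TRUE)))
    fixl <- list(hyper = fix_hyper, nu = fix_nu, sigma_eps = fix_se,
                 gamma = fix_gamma)
    coc_run_chain(dat$y, gidx, G, pr, init, fixl,
                  control$n_iter, control$n_burnin, control$thin,
                  store_states)
  }

  chains <- lapply(seq_len(control$n_chains), run_one)
  ndraw <- chains[[1]]$n_retained
  bindm <- function(name) do.call(rbind, lapply(chains, `[[`, name))
  draws <- list(gamma = bindm("gamma"), sigma = bindm("sigma"),
                a = bindm("a"), b = bindm("b"), theta = bindm("theta"),
                tau = bindm("tau"), nu = bindm("nu"),
                sigma_eps = unlist(lapply(chains, `[[`, "sigma_eps")))
  colnames(draws$gamma) <- colnames(draws$sigma) <- dat$ids
  for (nm in c("a", "b", "theta", "tau", "nu"))
    colnames(draws[[nm]]) <- levels(grp)
  chain_id <- rep(seq_len(control$n_chains), each = ndraw)

  draws$coc <- draws$sigma / sqrt(1 - draws$gamma^2)
  colnames(draws$coc) <- dat$ids
  draws$coc_mean <- vapply(levels(grp), function(g)
    rowMeans(draws$coc[, grp == g, drop = FALSE]), numeric(nrow(draws$coc)))
  draws$gamma_mean <- vapply(levels(grp), function(g)
    rowMeans(draws$gamma[, grp == g, drop = FALSE]),
    numeric(nrow(draws$gamma)))
  if (G == 1) {
    draws$coc_mean <- matrix(draws$coc_mean, ncol = 1,
                             dimnames = list(NULL, levels(grp)))
    draws$gamma_mean <- matrix(draws$gamma_mean, ncol = 1,
                               dimnames = list(NULL, levels(grp)))
  }

  states <- NULL
  if (store_states) {
    states <- lapply(seq_len(J), function(j)
      do.call(rbind, lapply(chains, function(ch) ch$states[[j]])))
    names(states) <- dat$ids
  }

  # convergence: split-chain diagnostic on every free scalar parameter
  rhat <- c()
  if (!fix_gamma)
    rhat <- c(rhat, stats::setNames(
      apply(draws$gamma, 2, .split_rhat, chain = chain_id),
      paste0("gamma[", dat$ids, "]")))
  rhat <- c(rhat, stats::setNames(
    apply(draws$sigma, 2, .split_rhat, chain = chain_id),
    paste0("sigma[", dat$ids, "]")))
  if (!fix_hyper)
    for (nm in c("a", "b", "theta", "tau"))
      rhat <- c(rhat, stats::setNames(
        apply(draws[[nm]], 2, .split_rhat, chain = chain_id),
        paste0(nm, "[", levels(grp), "]")))
  if (!fix_nu && !fix_hyper)
    rhat <- c(rhat, stats::setNames(
      apply(draws$nu, 2, .split_rhat, chain = chain_id),
      paste0("nu[", levels(grp), "]")))
  if (!fix_se)
    rhat <- c(rhat, sigma_eps = .split_rhat(draws$sigma_eps, chain_id))
  bad <- rhat[is.finite(rhat) & rhat > 1.1]
  if (length(bad) && control$n_chains > 1)
    warning("possible non-convergence (split-chain diagnostic > 1.1): ",
            paste0(names(bad), " = ", sprintf("%.3f", bad),
                   collapse = ", "))

  fit <- structure(list(
    draws = draws, states = states, chain = chain_id,
    data = list(y = dat$y, ids = dat$ids, sex = dat$sex, group = grp),
    grouping = grouping, priors = priors, control = control, fix = fix,
    fix_hyper = fix_hyper, rhat = rhat, n_draws = length(chain_id)),
    class = "coc_fit")

  # predictive ("induced prior") draws for unobserved individuals,
  # deterministic given the fit's seed
  if (!fix_hyper) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(control$seed + 999983L)
    pd <- .predictive_draws(fit)
    fit$draws$gamma_pred <- pd$gamma
    fit$draws$sigma_pred <- pd$sigma
    fit$draws$coc_pred <- pd$coc
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  }
  fit
}

# draw a new individual's parameters from each retained hyper draw
.predictive_draws <- function(fit) {
  d <- fit$draws
  G <- ncol(d$a)
  n <- nrow(d$a)
  gam <- sig <- matrix(NA_real_, n, G, dimnames = list(NULL,
                                                       colnames(d$a)))
  for (g in seq_len(G)) {
    gam[, g] <- 2 * stats::rbeta(n, d$a[, g], d$b[, g]) - 1
    # truncated normal on (0, Inf) via inverse-CDF
    plo <- stats::pnorm(0, d$theta[, g], d$tau[, g])
    u <- stats::runif(n, plo, 1)
    sig[, g] <- stats::qnorm(pmin(u, 1 - 1e-16), d$theta[, g], d$tau[, g])
    sig[, g] <- pmax(sig[, g], 1e-12)
  }
  list(gamma = gam, sigma = sig, coc = sig / sqrt(1 - gam^2))
}

#' Posterior predictive circle of confusion for an unobserved individual
#'
#' For every retained draw of the hyper-parameters, a new individual's
#' `gamma` and `sigma` are drawn from the fitted population distributions
#' and converted to a circle-of-confusion radius. This predictive
#' distribution quantifies population-level variability in navigation
#' ability.
#'
#' @param fit A hierarchical [coc_fit()] (errors for fits with fixed
#'   hyper-parameters).
#' @param group Optional group (sex) label; default all groups.
#' @return Matrix of predictive CoC draws (rows = retained draws, one
#'   column per group), or a vector when a single group is selected.
#' @export
predictive_coc <- function(fit, group = NULL) {
  stopifnot(inherits(fit, "coc_fit"))
  if (fit$fix_hyper || is.null(fit$draws$coc_pred))
    stop("predictive distribution requires a hierarchical fit ",
         "(hyper-parameters sampled, not fixed)")
  out <- fit$draws$coc_pred
  if (!is.null(group)) {
    if (!group %in% colnames(out)) stop("unknown group: ", group)
    out <- out[, group]
  } else if (ncol(out) == 1) out <- out[, 1]
  out
}
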