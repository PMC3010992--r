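# S3 methods for fitted circle-of-confusion models.

.qtab <- function(x, probs = c(0.025, 0.5, 0.975)) {
  stats::quantile(x, probs = probs, names = FALSE, type = 7)
}

#' @export
print.coc_fit <- function(x, ...) {
  d <- x$draws
  cat("Hierarchical circle-of-confusion state-space model\n")
  cat(sprintf("  %d animal%s, grouping = %s\n", length(x$data$ids),
              if (length(x$data$ids) > 1) "s" else "", x$grouping))
  cat(sprintf(
    "  %d chains x %d iterations (burn-in %d, thin %d): %d draws\n",
    x$control$n_chains, x$control$n_iter, x$control$n_burnin,
    x$control$thin, x$n_draws))
  for (g in colnames(d$coc_mean)) {
    q <- .qtab(d$coc_mean[, g])
    lab <- if (ncol(d$coc_mean) > 1) paste0(" (", g, ")") else ""
    cat(sprintf("  mean circle of confusion%s: %.1f km (95%% CrI %.1f-%.1f)\n",
                lab, q[2], q[1], q[3]))
  }
  if (length(x$rhat)) {
    mx <- max(x$rhat, na.rm = TRUE)
    cat(sprintf("  max split-chain diagnostic: %.3f\n", mx))
  }
  invisible(x)
}

#' Posterior quantile table for a fitted model
#'
#' One row per parameter with the 2.5, 50 and 97.5 percent posterior
#' quantiles: per-animal `gamma`, `sigma` and `coc`, then for each group
#' the hierarchical means, hyper-parameters and the predictive
#' (new-individual) quantities `gamma_pred`, `sigma_pred`, `coc_pred`, and
#' finally the shared measurement SD.
#'
#' @param object A [coc_fit()].
#' @param probs Quantile probabilities; default `c(0.025, 0.5, 0.975)`.
#' @param ... Unused.
#' @return A `data.frame` (class `"summary.coc_fit"`) with columns
#'   `parameter`, `q2.5`, `q50`, `q97.5` (or analogous for other `probs`).
#' @export
summary.coc_fit <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  d <- object$draws
  nms <- character()
  rows <- list()
  add <- function(name, draws) {
    rows[[length(rows) + 1]] <<- .qtab(draws, probs)
    nms[length(nms) + 1] <<- name
  }
  for (j in seq_along(object$data$ids)) {
    id <- object$data$ids[j]
    add(paste0("gamma[", id, "]"), d$gamma[, j])
    add(paste0("sigma[", id, "]"), d$sigma[, j])
    add(paste0("coc[", id, "]"), d$coc[, j])
  }
  for (g in colnames(d$coc_mean)) {
    sfx <- if (ncol(d$coc_mean) > 1) paste0("[", g, "]") else ""
    add(paste0("gamma_mean", sfx), d$gamma_mean[, g])
    add(paste0("coc_mean", sfx), d$coc_mean[, g])
    add(paste0("a", sfx), d$a[, g])
    add(paste0("b", sfx), d$b[, g])
    add(paste0("theta", sfx), d$theta[, g])
    add(paste0("tau", sfx), d$tau[, g])
    add(paste0("nu", sfx), d$nu[, g])
    if (!is.null(d$coc_pred)) {
      add(paste0("gamma_pred", sfx), d$gamma_pred[, g])
      add(paste0("sigma_pred", sfx), d$sigma_pred[, g])
      add(paste0("coc_pred", sfx), d$coc_pred[, g])
    }
  }
  add("sigma_eps", d$sigma_eps)
  qm <- do.call(rbind, rows)
  out <- data.frame(parameter = nms, qm, stringsAsFactors = FALSE)
  names(out) <- c("parameter", paste0("q", format(100 * probs,
                                                  trim = TRUE)))
  rownames(out) <- NULL
  class(out) <- c("summary.coc_fit", "data.frame")
  out
}

#' @export
print.summary.coc_fit <- function(x, digits = 4, ...) {
  y <- x
  class(y) <- "data.frame"
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], signif, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Posterior median parameter estimates per animal
#'
#' @param object A [coc_fit()].
#' @param ... Unused.
#' @return Matrix with one row per animal and columns `gamma`, `sigma`,
#'   `coc` (posterior medians).
#' @export
coef.coc_fit <- function(object, ...) {
  d <- object$draws
  cbind(gamma = apply(d$gamma, 2, stats::median),
        sigma = apply(d$sigma, 2, stats::median),
        coc = apply(d$coc, 2, stats::median))
}

#' Predictive circle-of-confusion draws
#'
#' `predict` on a fitted model returns the posterior predictive
#' distribution of the circle of confusion for an unobserved individual
#' (see [predictive_coc()]).
#'
#' @param object A hierarchical [coc_fit()].
#' @param group Optional group label.
#' @param ... Unused.
#' @return Vector or matrix of predictive CoC draws (km).
#' @export
predict.coc_fit <- function(object, group = NULL, ...) {
  predictive_coc(object, group = group)
}

#' Observation residuals
#'
#' Observed deviations minus the posterior mean of the latent states.
#'
#' @param object A [coc_fit()] with stored states.
#' @param ... Unused.
#' @return List of numeric vectors, one per animal (`NA` on missing days).
#' @export
residuals.coc_fit <- function(object, ...) {
  if (is.null(object$states))
    stop("fit was run with store_states = FALSE")
  out <- lapply(seq_along(object$data$y), function(j)
    object$data$y[[j]] - colMeans(object$states[[j]]))
  names(out) <- object$data$ids
  out
}

#' Simulate posterior predictive deviation series
#'
#' Draws complete replicate observation series from the fitted model:
#' for a randomly chosen retained draw, states are re-simulated from the
#' sampled initial state forward with the drawn `(gamma, sigma, nu)` and
#' observation noise is added.
#'
#' @param object A [coc_fit()] with stored states.
#' @param nsim Number of replicate datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List of `nsim` datasets, each a named list of numeric series.
#' @export
simulate.coc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(object$states))
    stop("fit was run with store_states = FALSE")
  d <- object$draws
  gidx <- as.integer(object$data$group)
  reps <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    k <- sample.int(object$n_draws, 1)
    one <- lapply(seq_along(object$data$y), function(j) {
      Tt <- length(object$data$y[[j]])
      nu <- d$nu[k, gidx[j]]
      g <- d$gamma[k, j]
      sg <- d$sigma[k, j]
      se <- d$sigma_eps[k]
      x <- numeric(Tt)
      x[1] <- object$states[[j]][k, 1]
      shock <- if (is.finite(nu)) sg * stats::rt(Tt, df = nu)
      else stats::rnorm(Tt, 0, sg)
      for (t in 2:Tt) x[t] <- g * x[t - 1] + shock[t]
      x + stats::rnorm(Tt, 0, se)
    })
    names(one) <- object$data$ids
    reps[[s]] <- one
  }
  reps
}

#' Plot per-animal and population circles of confusion
#'
#' Horizontal posterior medians with 95% credible intervals for each
#' animal's circle of confusion, followed by the hierarchical mean(s) and
#' the predictive distribution(s) for an unobserved individual.
#'
#' @param x A [coc_fit()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.coc_fit <- function(x, ...) {
  d <- x$draws
  qs <- apply(d$coc, 2, .qtab)
  labs <- colnames(qs)
  extra <- NULL
  for (g in colnames(d$coc_mean)) {
    sfx <- if (ncol(d$coc_mean) > 1) paste0(" (", g, ")") else ""
    qs <- cbind(qs, .qtab(d$coc_mean[, g]))
    labs <- c(labs, paste0("mean", sfx))
    if (!is.null(d$coc_pred)) {
      qs <- cbind(qs, .qtab(d$coc_pred[, g]))
      labs <- c(labs, paste0("predictive", sfx))
    }
  }
  n <- ncol(qs)
  yy <- rev(seq_len(n))
  op <- par(mar = c(4.5, 7, 1, 1))
  on.exit(par(op))
  plot(NA, xlim = c(0, max(qs)), ylim = c(0.5, n + 0.5),
       xlab = "circle of confusion (km)", ylab = "", yaxt = "n", ...)
  segments(qs[1, ], yy, qs[3, ], yy, col = "grey40")
  points(qs[2, ], yy, pch = 19)
  axis(2, at = yy, labels = labs, las = 1, cex.axis = 0.8)
  invisible(x)
}

#' Write posterior draws and the summary table to CSV
#'
#' @param fit A [coc_fit()].
#' @param draws_file,summary_file Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_fit <- function(fit, draws_file = NULL, summary_file = NULL) {
  if (!is.null(draws_file)) {
    d <- fit$draws
    flat <- data.frame(chain = fit$chain)
    for (nm in c("gamma", "sigma", "coc")) {
      m <- d[[nm]]
      colnames(m) <- paste0(nm, "[", colnames(m), "]")
      flat <- cbind(flat, m)
    }
    for (nm in c("a", "b", "theta", "tau", "nu", "coc_mean")) {
      m <- d[[nm]]
      colnames(m) <- if (ncol(m) > 1) paste0(nm, "[", colnames(m), "]")
      else nm
      flat <- cbind(flat, m)
    }
    flat$sigma_eps <- d$sigma_eps
    utils::write.csv(flat, draws_file, row.names = FALSE)
  }
  if (!is.null(summary_file))
    utils::write.csv(summary(fit), summary_file, row.names = FALSE)
  invisible(c(draws_file, summary_file))
}
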