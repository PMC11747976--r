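#' Fit configuration for the two-state estimation pipeline
#'
#' Bundles the published optimisation settings: per-parameter box bounds
#' (`Af` 0.25--0.75, `As` 0.93--1.0, `Bf` 0--0.2, `Bs` 0--0.2), the
#' initial point (`Af` 0.775, `Bf` 0.06, `As` 0.992, `Bs` 0.02), the
#' regularisation constant `lambda = 0.05` and 2,000 bootstrap
#' replicates. The published initial `Af` lies above its published upper
#' bound; initial points are clipped into the box before bounded
#' optimisation and the clip is recorded on the fit.
#'
#' @param bounds Named list of `c(lower, upper)` per parameter.
#' @param init Named numeric initial point.
#' @param lambda Regularisation constant (>= 0).
#' @param n_boot Number of bootstrap replicates (>= 1).
#' @param seed Integer seed for the bootstrap resampling.
#' @param include_baseline If `TRUE`, the model is propagated from the
#'   start of the schedule (baseline trials included as `f = 0`); the
#'   default fits the training block only, starting from zero state.
#' @return A `fit_config` list.
#' @export
fit_config <- function(bounds = list(Af = c(0.25, 0.75), As = c(0.93, 1.0),
                                     Bf = c(0.0, 0.2), Bs = c(0.0, 0.2)),
                       init = c(Af = 0.775, As = 0.992, Bf = 0.06, Bs = 0.02),
                       lambda = 0.05, n_boot = 2000, seed = 1L,
                       include_baseline = FALSE) {
  par_names <- c("Af", "As", "Bf", "Bs")
  stopifnot(all(par_names %in% names(bounds)),
            all(par_names %in% names(init)),
            lambda >= 0, n_boot >= 1)
  for (nm in par_names) {
    b <- bounds[[nm]]
    if (length(b) != 2 || b[1] > b[2]) {
      stop("bounds for ", nm, " must be an ordered pair", call. = FALSE)
    }
  }
  structure(list(bounds = bounds[par_names],
                 init = init[par_names],
                 lambda = lambda, n_boot = as.integer(n_boot),
                 seed = as.integer(seed),
                 include_baseline = isTRUE(include_baseline)),
            class = "fit_config")
}

# --- internal fast path -----------------------------------------------------
# The optimiser evaluates the model thousands of times; these helpers avoid
# data-frame overhead by working on raw type/gain vectors.

# the trial window the model is propagated over, and where it is scored
fit_window <- function(schedule, include_baseline = FALSE) {
  keep <- if (include_baseline) {
    schedule$block %in% c("baseline", "training")
  } else {
    schedule$block == "training"
  }
  type <- schedule$trial_type[keep]
  list(type = type,
       f = schedule$ff_gain[keep],
       ec_pos = which(type == "EC" &
                        schedule$block[keep] == "training"),
       ec_trial = schedule$index[keep][type == "EC" &
                                         schedule$block[keep] == "training"])
}

# net output x at the training EC probes for parameter vector
# par = c(Af, As, Bf, Bs), zero initial state
predict_ec_ac <- function(par, window) {
  Af <- par[1]; As <- par[2]; Bf <- par[3]; Bs <- par[4]
  is_ec <- window$type == "EC"
  f <- window$f
  n <- length(f)
  x <- numeric(n)
  cf <- 0; cs <- 0
  for (i in seq_len(n)) {
    x[i] <- cf + cs
    if (is_ec[i]) {
      cf <- Af * cf; cs <- As * cs
    } else {
      e <- f[i] - (cf + cs)
      cf <- Af * cf + Bf * e
      cs <- As * cs + Bs * e
    }
  }
  x[window$ec_pos]
}

# prediction plus its Jacobian wrt (Af, As, Bf, Bs) by forward
# sensitivity recursion; exact gradients keep the bounded optimiser from
# stalling in the strongly correlated (Af, Bf) valley
predict_ec_ac_grad <- function(par, window) {
  Af <- par[1]; As <- par[2]; Bf <- par[3]; Bs <- par[4]
  is_ec <- window$type == "EC"
  f <- window$f
  n <- length(f)
  x <- numeric(n)
  J <- matrix(0, n, 4)
  cf <- 0; cs <- 0
  dcf <- numeric(4); dcs <- numeric(4)
  for (i in seq_len(n)) {
    x[i] <- cf + cs
    J[i, ] <- dcf + dcs
    if (is_ec[i]) {
      dcf <- Af * dcf; dcf[1] <- dcf[1] + cf
      dcs <- As * dcs; dcs[2] <- dcs[2] + cs
      cf <- Af * cf; cs <- As * cs
    } else {
      e <- f[i] - (cf + cs)
      de <- -(dcf + dcs)
      ncf <- Af * dcf + Bf * de; ncf[1] <- ncf[1] + cf; ncf[3] <- ncf[3] + e
      ncs <- As * dcs + Bs * de; ncs[2] <- ncs[2] + cs; ncs[4] <- ncs[4] + e
      dcf <- ncf; dcs <- ncs
      cf <- Af * cf + Bf * e
      cs <- As * cs + Bs * e
    }
  }
  list(x = x[window$ec_pos], J = J[window$ec_pos, , drop = FALSE])
}

# MSE objective and its exact gradient for observations y on the window
mse_fn_gr <- function(y, window, lambda = 0, ref = NULL) {
  m <- length(y)
  fn <- function(p) {
    v <- mean((y - predict_ec_ac(p, window))^2)
    if (lambda > 0) v <- v + lambda * sum(((p - ref) / ref)^2)
    v
  }
  gr <- function(p) {
    pr <- predict_ec_ac_grad(p, window)
    g <- as.numeric((-2 / m) * crossprod(pr$J, y - pr$x))
    if (lambda > 0) g <- g + 2 * lambda * (p - ref) / ref^2
    g
  }
  list(fn = fn, gr = gr)
}

# coerce observations to a numeric vector aligned with the training ECs
align_observed <- function(observed, window) {
  if (is.data.frame(observed)) {
    stopifnot(all(c("trial", "ac") %in% names(observed)))
    obs <- observed[observed$trial %in% window$ec_trial, ]
    if (nrow(obs) != length(window$ec_trial) ||
        any(obs$trial != window$ec_trial)) {
      stop("observed AC series is not aligned with the schedule's ",
           "training error-clamp trials", call. = FALSE)
    }
    obs$ac
  } else {
    if (length(observed) != length(window$ec_trial)) {
      stop("observed AC series length (", length(observed),
           ") does not match the training EC count (",
           length(window$ec_trial), ")", call. = FALSE)
    }
    as.numeric(observed)
  }
}

par_vec <- function(p) c(p[["Af"]], p[["As"]], p[["Bf"]], p[["Bs"]])

# --- objectives -------------------------------------------------------------

#' Least-mean-squared-error objective
#'
#' Mean squared error between an observed adaptation-coefficient series and
#' the two-state model prediction at the training-block error-clamp trials,
#' the model being propagated across all intervening trials.
#'
#' @param params [twostate_params()] or named vector.
#' @param observed Observed ACs: a data frame with `trial` and `ac`
#'   (trial indices must match the schedule's training EC trials) or a
#'   plain numeric vector in EC order.
#' @param schedule The [build_trial_schedule()] the observations came from.
#' @param include_baseline Propagate through baseline trials too.
#' @return Nonnegative scalar.
#' @export
objective_lmse <- function(params, observed, schedule,
                           include_baseline = FALSE) {
  window <- fit_window(schedule, include_baseline)
  y <- align_observed(observed, window)
  pred <- predict_ec_ac(par_vec(as_twostate_params(params)), window)
  mean((y - pred)^2)
}

#' Regularised bootstrap objective
#'
#' The least-squares objective plus a penalty on the relative deviation of
#' each parameter from the full-data estimate:
#' `MSE + lambda * sum_s ((theta_s - thetaLMSE_s) / thetaLMSE_s)^2`.
#' Dividing by the reference value puts all four parameters, whatever
#' their magnitude, under the same regularisation pressure.
#'
#' @inheritParams objective_lmse
#' @param theta_lmse Reference [twostate_params()] from the full-data fit;
#'   all components must be nonzero.
#' @param lambda Regularisation constant.
#' @return Nonnegative scalar.
#' @export
objective_regularized <- function(params, observed, schedule, theta_lmse,
                                  lambda = 0.05, include_baseline = FALSE) {
  ref <- par_vec(as_twostate_params(theta_lmse))
  if (any(ref == 0)) {
    stop("theta_lmse has a zero component; relative penalty undefined",
         call. = FALSE)
  }
  p <- par_vec(as_twostate_params(params))
  objective_lmse(params, observed, schedule, include_baseline) +
    lambda * sum(((p - ref) / ref)^2)
}

# --- optimisation -----------------------------------------------------------

clip_to_bounds <- function(par, lower, upper) pmin(pmax(par, lower), upper)

# Latin-hypercube starts inside the box (deterministic given RNG state)
lhs_starts <- function(n, lower, upper) {
  d <- length(lower)
  u <- vapply(seq_len(d), function(j) (sample.int(n) - stats::runif(n)) / n,
              numeric(n))
  u <- matrix(u, nrow = n)
  sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
}

# bounded minimisation with optional exact gradient; multi_start > 0 adds
# that many Latin-hypercube starts on top of the given initial point
minimize_bounded <- function(fn, init, lower, upper, gr = NULL,
                             multi_start = 0, n_fallback = 10) {
  run1 <- function(p0) {
    tryCatch(stats::optim(p0, fn, gr = gr, method = "L-BFGS-B",
                          lower = lower, upper = upper,
                          control = list(factr = 10, maxit = 500)),
             error = function(e) NULL)
  }
  best <- run1(init)
  n_starts <- 1L
  extra <- if (is.null(best) || best$convergence != 0) {
    max(multi_start, n_fallback)
  } else {
    multi_start
  }
  if (extra > 0) {
    starts <- lhs_starts(extra, lower, upper)
    for (i in seq_len(extra)) {
      n_starts <- n_starts + 1L
      cand <- run1(starts[i, ])
      if (!is.null(cand) &&
          (is.null(best) || cand$value < best$value)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    stop("bounded optimisation failed from ", n_starts, " start(s)",
         call. = FALSE)
  }
  best$n_starts <- n_starts
  best
}

#' Bounded least-squares fit of the two-state model
#'
#' Minimises [objective_lmse()] within the configured parameter box from
#' the configured initial point (clipped into the box when it lies
#' outside, as the published initial `Af` does), with a 10-point
#' Latin-hypercube multi-start fallback when the first run does not
#' converge.
#'
#' @inheritParams objective_lmse
#' @param config A [fit_config()].
#' @return A [twostate_params()] with attributes `objective`,
#'   `convergence`, `n_starts` and `init_clipped`.
#' @export
fit_lmse <- function(observed, schedule, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  window <- fit_window(schedule, config$include_baseline)
  y <- align_observed(observed, window)
  if (length(y) < 4) stop("need at least 4 observations", call. = FALSE)
  lower <- vapply(config$bounds, `[`, numeric(1), 1)
  upper <- vapply(config$bounds, `[`, numeric(1), 2)
  init <- config$init
  clipped <- any(init < lower | init > upper)
  init <- clip_to_bounds(init, lower, upper)
  obj <- mse_fn_gr(y, window)
  res <- withr_seed(config$seed,
                    minimize_bounded(obj$fn, init, lower, upper,
                                     gr = obj$gr, multi_start = 10))
  out <- suppressWarnings(twostate_params(res$par[1], res$par[2],
                                          res$par[3], res$par[4]))
  attr(out, "objective") <- res$value
  attr(out, "convergence") <- res$convergence
  attr(out, "n_starts") <- res$n_starts
  attr(out, "init_clipped") <- clipped
  out
}

#' Regularised subject-resampling bootstrap
#'
#' Step 1 fits the full-data group mean by bounded least squares
#' ([fit_lmse()]). Step 2 resamples subjects with replacement `n_boot`
#' times; each replicate averages the sampled subjects' AC series per
#' trial and minimises the regularised objective
#' ([objective_regularized()]) within the same bounds, started from the
#' full-data estimate. The 95% CI per parameter is the 2.5/97.5 empirical
#' percentile of the replicates; a Gaussian fitted to each replicate
#' distribution (mean, sd, and its 2.5/97.5 quantiles) is also reported.
#'
#' @param cohort A [simulate_cohort()] result, or a subjects-by-trials
#'   matrix of training-block ACs whose column names are schedule trial
#'   indices.
#' @param schedule The shared [build_trial_schedule()]; taken from the
#'   cohort when omitted.
#' @param config A [fit_config()].
#' @return A `bootstrap_result`: list with `theta_lmse`, `replicates`
#'   (n_boot x 4 matrix), `ci95` and `gaussian_ci95` (2 x 4), `gaussian`
#'   (mean/sd per parameter), `n_failed`, `config`.
#' @export
bootstrap_fit <- function(cohort, schedule = NULL, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  if (inherits(cohort, "cohort")) {
    if (is.null(schedule)) schedule <- cohort$schedule
    m <- cohort_ac_matrix(cohort, "training")
  } else {
    m <- as.matrix(cohort)
  }
  if (is.null(schedule)) stop("a schedule is required", call. = FALSE)
  if (nrow(m) < 2) stop("bootstrap needs at least 2 subjects", call. = FALSE)

  window <- fit_window(schedule, config$include_baseline)
  if (!is.null(colnames(m)) &&
      !identical(as.integer(colnames(m)), as.integer(window$ec_trial))) {
    stop("AC matrix columns do not match the training EC trials",
         call. = FALSE)
  }
  theta_lmse <- fit_lmse(colMeans(m), schedule, config)
  ref <- par_vec(theta_lmse)
  if (any(ref == 0)) {
    stop("full-data estimate has a zero component; cannot regularise",
         call. = FALSE)
  }
  lower <- vapply(config$bounds, `[`, numeric(1), 1)
  upper <- vapply(config$bounds, `[`, numeric(1), 2)
  init <- clip_to_bounds(ref, lower, upper)
  lam <- config$lambda
  n_sub <- nrow(m)

  reps <- matrix(NA_real_, config$n_boot, 4,
                 dimnames = list(NULL, c("Af", "As", "Bf", "Bs")))
  n_failed <- 0L
  withr_seed(config$seed, {
    for (b in seq_len(config$n_boot)) {
      draw <- sample.int(n_sub, n_sub, replace = TRUE)
      y <- colMeans(m[draw, , drop = FALSE])
      obj <- mse_fn_gr(y, window, lambda = lam, ref = ref)
      res <- tryCatch(minimize_bounded(obj$fn, init, lower, upper,
                                       gr = obj$gr),
                      error = function(e) NULL)
      if (is.null(res)) n_failed <- n_failed + 1L else reps[b, ] <- res$par
    }
  })
  if (n_failed > 0.01 * config$n_boot) {
    stop(n_failed, " of ", config$n_boot,
         " bootstrap replicates failed to converge", call. = FALSE)
  }
  if (n_failed > 0) {
    message(n_failed, " bootstrap replicate(s) dropped after optimiser ",
            "failure")
    reps <- reps[stats::complete.cases(reps), , drop = FALSE]
  }
  ci95 <- apply(reps, 2, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE)
  rownames(ci95) <- c("lower", "upper")
  mu <- colMeans(reps)
  sdv <- apply(reps, 2, stats::sd)
  gauss_ci <- rbind(lower = mu + stats::qnorm(0.025) * sdv,
                    upper = mu + stats::qnorm(0.975) * sdv)
  structure(list(theta_lmse = theta_lmse, replicates = reps,
                 ci95 = ci95, gaussian = rbind(mean = mu, sd = sdv),
                 gaussian_ci95 = gauss_ci,
                 n_failed = n_failed, config = config),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %d replicates (%d failed)\n",
              nrow(x$replicates), x$n_failed))
  est <- par_vec(x$theta_lmse)
  for (j in 1:4) {
    cat(sprintf("  %-2s = %6.4f  95%% CI [%6.4f, %6.4f]\n",
                c("Af", "As", "Bf", "Bs")[j], est[j],
                x$ci95[1, j], x$ci95[2, j]))
  }
  invisible(x)
}

#' Write a fit report as JSON
#'
#' @param result A [bootstrap_fit()] result.
#' @param path Output path for the JSON report; a replicate table CSV is
#'   written alongside it.
#' @export
write_fit_report <- function(result, path) {
  est <- par_vec(result$theta_lmse)
  names(est) <- c("Af", "As", "Bf", "Bs")
  report <- list(
    theta_lmse = as.list(est),
    objective = attr(result$theta_lmse, "objective"),
    init_clipped = attr(result$theta_lmse, "init_clipped"),
    ci95 = apply(result$ci95, 2, as.list),
    gaussian = apply(result$gaussian, 2, as.list),
    gaussian_ci95 = apply(result$gaussian_ci95, 2, as.list),
    n_replicates = nrow(result$replicates),
    n_failed = result$n_failed,
    config = list(bounds = result$config$bounds,
                  init = as.list(result$config$init),
                  lambda = result$config$lambda,
                  n_boot = result$config$n_boot,
                  seed = result$config$seed))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(result$replicates),
                   sub("\\.json$", "_replicates.csv", path),
                   row.names = FALSE)
  invisible(path)
}
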