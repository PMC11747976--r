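# Descriptive curve fits for learning and decay:
#   logistic growth  A(n) = K / (1 + ((K - A0)/A0) exp(-r n))
#   exponential decay y(x) = A exp(b x) [+ C exp(d x)],  b, d <= 0
# Nonlinear least squares by bounded quasi-Newton with data-driven and
# Latin-hypercube multi-starts; AIC model selection under a location-scale
# t likelihood on the residuals (Gaussian-SSE AIC also available).

r_squared <- function(y, fitted) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((y - fitted)^2) / sst
}

# SE of curve parameters via the Gauss-Newton approximation
# (J'J)^-1 * SSE/(n-k), J by central finite differences
curve_param_se <- function(par, fn_fitted, y) {
  n <- length(y); k <- length(par)
  if (n <= k) return(rep(NA_real_, k))
  J <- vapply(seq_len(k), function(j) {
    h <- max(1e-7, 1e-7 * abs(par[j]))
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    (fn_fitted(pp) - fn_fitted(pm)) / (2 * h)
  }, numeric(n))
  s2 <- sum((y - fn_fitted(par))^2) / (n - k)
  JtJ <- crossprod(J)
  inv <- tryCatch(solve(JtJ), error = function(e) NULL)
  if (is.null(inv)) return(rep(NA_real_, k))
  sqrt(pmax(0, diag(inv)) * s2)
}

#' Logistic growth fit of a learning curve
#'
#' Fits `A(n) = K / (1 + ((K - A0)/A0) exp(-r n))` to an adaptation
#' series by nonlinear least squares: `K` is the carrying capacity (the
#' maximum adaptation attainable), `A0` the initial adaptation and `r` the
#' per-trial growth rate. Constant series are degenerate and return an
#' unfitted result with `degenerate = TRUE`.
#'
#' @param n Trial numbers (typically the error-clamp probe ordinal within
#'   training).
#' @param ac Adaptation coefficients at those trials (group mean).
#' @param n_starts Extra Latin-hypercube starts beyond the data-driven one.
#' @return A `logistic_fit`: list with `K`, `A0`, `r`, `r2`, `ci95`
#'   (asymptotic, per parameter), `fitted`, `degenerate`.
#' @export
fit_logistic <- function(n, ac, n_starts = 10) {
  stopifnot(length(n) == length(ac), length(n) >= 5)
  if (stats::sd(ac) == 0) {
    return(structure(list(K = NA_real_, A0 = NA_real_, r = NA_real_,
                          r2 = NA_real_, ci95 = NULL, fitted = ac,
                          degenerate = TRUE), class = "logistic_fit"))
  }
  # par = (K, A0, r); require K > 0, A0 in (0, K]
  fitted_fn <- function(p) p[1] / (1 + ((p[1] - p[2]) / p[2]) * exp(-p[3] * n))
  sse <- function(p) {
    f <- fitted_fn(p)
    if (any(!is.finite(f))) return(1e12)
    sum((ac - f)^2)
  }
  ymax <- max(ac); ypos <- ac[ac > 0]
  init <- c(K = max(ymax, 1e-3),
            A0 = if (length(ypos)) max(min(ypos), 1e-4) else 1e-3,
            r = 0.3)
  lower <- c(1e-6, 1e-6, 1e-6)
  upper <- c(10 * max(abs(ac), 1), max(ymax, 1), 10)
  init <- clip_to_bounds(init, lower, upper)
  best <- withr_seed(1L, {
    b <- tryCatch(stats::optim(init, sse, method = "L-BFGS-B",
                               lower = lower, upper = upper,
                               control = list(factr = 10, maxit = 1000)),
                  error = function(e) NULL)
    starts <- lhs_starts(n_starts, lower, pmin(upper, c(2 * max(ymax, 0.1),
                                                        max(ymax, 0.1), 2)))
    for (i in seq_len(n_starts)) {
      cand <- tryCatch(stats::optim(starts[i, ], sse, method = "L-BFGS-B",
                                    lower = lower, upper = upper,
                                    control = list(factr = 10, maxit = 1000)),
                       error = function(e) NULL)
      if (!is.null(cand) && (is.null(b) || cand$value < b$value)) b <- cand
    }
    b
  })
  if (is.null(best)) stop("logistic fit failed to converge", call. = FALSE)
  p <- best$par
  # Gauss-Newton polish; scaleOffset keeps nls stable on zero-residual data
  pol <- tryCatch(suppressWarnings(
    stats::nls(ac ~ K / (1 + ((K - A0) / A0) * exp(-r * n)),
               data = data.frame(n = n, ac = ac),
               start = list(K = p[[1]], A0 = p[[2]], r = p[[3]]),
               algorithm = "port", lower = lower, upper = upper,
               control = stats::nls.control(maxiter = 500,
                                            scaleOffset = 1,
                                            warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(pol)) {
    pc <- unname(stats::coef(pol))
    if (sse(pc) <= best$value) {
      best$value <- sse(pc)
      p <- pc
    }
  }
  se <- curve_param_se(p, fitted_fn, ac)
  ci <- rbind(lower = p - 1.96 * se, upper = p + 1.96 * se)
  colnames(ci) <- c("K", "A0", "r")
  structure(list(K = p[[1]], A0 = p[[2]], r = p[[3]],
                 r2 = r_squared(ac, fitted_fn(p)), ci95 = ci,
                 fitted = fitted_fn(p), n = n, ac = ac, sse = best$value,
                 n_params = 3L, degenerate = FALSE),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<logistic_fit> degenerate (constant series), no fit\n")
  } else {
    cat(sprintf("<logistic_fit> K=%.4g A0=%.4g r=%.4g  R2=%.4f\n",
                x$K, x$A0, x$r, x$r2))
  }
  invisible(x)
}

#' One- or two-phase exponential decay fit
#'
#' Fits `y = A exp(b x)` (one phase) or `y = A exp(b x) + C exp(d x)`
#' (two phases) with nonpositive rate constants, by bounded nonlinear
#' least squares with data-driven and Latin-hypercube multi-starts. For
#' the two-phase fit the faster phase (larger `|rate|`) is always labelled
#' `(A, b)`. Rates are fitted in base e; the base-10 equivalents
#' (`rate / ln 10`) are reported alongside, as decay fits are often
#' printed that way.
#'
#' @param x Trial numbers within the decay block (0-based by convention).
#' @param y Percent-of-first-trial adaptation at those trials.
#' @param phases 1 or 2.
#' @param n_starts Extra Latin-hypercube starts.
#' @return A `decay_fit`: list with `phases`, `A`, `b`, `C`, `d` (base e),
#'   `b10`, `d10`, `r2`, `sse`, `fitted`, `n_params`.
#' @export
fit_exponential_decay <- function(x, y, phases = 2, n_starts = 10) {
  stopifnot(length(x) == length(y), phases %in% c(1, 2),
            length(x) >= 2 * phases + 1)
  if (phases == 1) {
    fitted_fn <- function(p) p[1] * exp(p[2] * x)
    amax <- 2 * max(abs(y), 1)
    lower <- c(0, -5); upper <- c(amax, 0)
    # data-driven start: amplitude from the first point, rate from a
    # log-linear fit where y > 0
    pos <- y > 0
    r0 <- if (sum(pos) >= 2) {
      min(-1e-4, stats::coef(stats::lm(log(y[pos]) ~ x[pos]))[[2]])
    } else -0.1
    inits <- list(c(max(y[1], 1e-3), max(r0, -5)))
  } else {
    fitted_fn <- function(p) p[1] * exp(p[2] * x) + p[3] * exp(p[4] * x)
    amax <- 2 * max(abs(y), 1)
    lower <- c(0, -5, 0, -5); upper <- c(amax, 0, amax, 0)
    tail_n <- max(3L, ceiling(length(y) / 4))
    tail_i <- seq(length(y) - tail_n + 1L, length(y))
    ct <- mean(y[tail_i])
    pos <- y[tail_i] > 0
    d0 <- if (sum(pos) >= 2) {
      min(-1e-4,
          stats::coef(stats::lm(log(y[tail_i][pos]) ~ x[tail_i][pos]))[[2]])
    } else -0.01
    a0 <- max(y[1] - ct, 1e-3)
    inits <- list(c(a0, -0.5, max(ct, 1e-3), max(d0, -5)),
                  c(a0, -1.5, max(ct, 1e-3), -0.005))
  }
  sse <- function(p) {
    f <- fitted_fn(p)
    if (any(!is.finite(f))) return(1e12)
    sum((y - f)^2)
  }
  best <- withr_seed(2L, {
    b <- NULL
    for (p0 in inits) {
      cand <- tryCatch(stats::optim(clip_to_bounds(p0, lower, upper), sse,
                                    method = "L-BFGS-B",
                                    lower = lower, upper = upper,
                                    control = list(factr = 10, maxit = 1000)),
                       error = function(e) NULL)
      if (!is.null(cand) && (is.null(b) || cand$value < b$value)) b <- cand
    }
    starts <- lhs_starts(n_starts, lower, upper)
    for (i in seq_len(n_starts)) {
      cand <- tryCatch(stats::optim(starts[i, ], sse, method = "L-BFGS-B",
                                    lower = lower, upper = upper,
                                    control = list(factr = 10, maxit = 1000)),
                       error = function(e) NULL)
      if (!is.null(cand) && (is.null(b) || cand$value < b$value)) b <- cand
    }
    b
  })
  if (is.null(best)) stop("exponential decay fit failed to converge",
                          call. = FALSE)
  # Gauss-Newton polish from the multi-start solution
  form <- if (phases == 1) y ~ A * exp(b * x) else
    y ~ A * exp(b * x) + C * exp(d * x)
  start <- if (phases == 1) {
    list(A = best$par[[1]], b = best$par[[2]])
  } else {
    list(A = best$par[[1]], b = best$par[[2]],
         C = best$par[[3]], d = best$par[[4]])
  }
  pol <- tryCatch(suppressWarnings(
    stats::nls(form, data = data.frame(x = x, y = y), start = start,
               algorithm = "port", lower = lower, upper = upper,
               control = stats::nls.control(maxiter = 500, scaleOffset = 1,
                                            warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(pol)) {
    pc <- unname(stats::coef(pol))
    if (sse(pc) <= best$value) {
      best$value <- sse(pc)
      best$par <- pc
    }
  }
  p <- best$par
  if (phases == 2 && abs(p[4]) > abs(p[2])) {
    p <- p[c(3, 4, 1, 2)]  # fast phase first
  }
  out <- list(phases = as.integer(phases),
              A = p[[1]], b = p[[2]],
              C = if (phases == 2) p[[3]] else NA_real_,
              d = if (phases == 2) p[[4]] else NA_real_,
              b10 = p[[2]] / log(10),
              d10 = if (phases == 2) p[[4]] / log(10) else NA_real_,
              r2 = r_squared(y, fitted_fn(best$par)),
              sse = best$value, fitted = fitted_fn(best$par),
              x = x, y = y, n_params = 2L * as.integer(phases))
  structure(out, class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$phases == 1) {
    cat(sprintf("<decay_fit> 1-phase: %.4g exp(%.4g x)  R2=%.4f\n",
                x$A, x$b, x$r2))
  } else {
    cat(sprintf(
      "<decay_fit> 2-phase: %.4g exp(%.4g x) + %.4g exp(%.4g x)  R2=%.4f\n",
      x$A, x$b, x$C, x$d, x$r2))
    cat(sprintf("  base-10 rates: b10=%.4g d10=%.4g\n", x$b10, x$d10))
  }
  invisible(x)
}

# maximised log-likelihood of residuals under a zero-location t with free
# scale and degrees of freedom
t_loglik <- function(resid, df = NULL) {
  nll <- function(theta) {
    s <- max(exp(theta[1]), 1e-12)  # scale floor: finite on zero residuals
    v <- if (is.null(df)) 1 + exp(theta[2]) else df
    -sum(stats::dt(resid / s, df = v, log = TRUE) - log(s))
  }
  init <- if (is.null(df)) c(log(stats::sd(resid) + 1e-9), log(9)) else
    log(stats::sd(resid) + 1e-9)
  opt <- stats::optim(init, nll,
                      method = if (is.null(df)) "Nelder-Mead" else "BFGS",
                      control = list(maxit = 2000))
  -opt$value
}

#' AIC model selection among decay fits
#'
#' Compares candidate fits of the same series by AIC. The default
#' likelihood treats the residuals as draws from a location-scale
#' t distribution (scale and degrees of freedom maximised per candidate;
#' `k` counts curve parameters plus the two nuisance parameters). The
#' `"gaussian"` mode is the classic SSE form `n log(SSE/n) + 2 k` with
#' `k` counting curve parameters plus the error variance. Lowest AIC wins.
#'
#' @param fits List of [fit_exponential_decay()] (or compatible) results,
#'   all fitted to identical data.
#' @param method `"t"` (default) or `"gaussian"`.
#' @param df Fixed t degrees of freedom; `NULL` (default) estimates them.
#' @return An `aic_selection`: list with `table` (data frame `model`, `k`,
#'   `sse`, `aic`, `delta_aic`), `best` (index) and `selected` (the
#'   winning fit).
#' @export
aic_select <- function(fits, method = c("t", "gaussian"), df = NULL) {
  method <- match.arg(method)
  stopifnot(length(fits) >= 2)
  y0 <- fits[[1]]$y
  for (f in fits) {
    if (!isTRUE(all.equal(f$y, y0)) || !isTRUE(all.equal(f$x, fits[[1]]$x))) {
      stop("candidates were fitted on different data", call. = FALSE)
    }
  }
  n <- length(y0)
  rows <- lapply(fits, function(f) {
    resid <- f$y - f$fitted
    if (method == "t") {
      k <- f$n_params + (if (is.null(df)) 2L else 1L)
      aic <- 2 * k - 2 * t_loglik(resid, df)
    } else {
      k <- f$n_params + 1L
      aic <- n * log(sum(resid^2) / n) + 2 * k
    }
    data.frame(model = paste0(f$phases, "-phase"), k = k,
               sse = sum(resid^2), aic = aic, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$delta_aic <- tab$aic - min(tab$aic)
  best <- which.min(tab$aic)
  structure(list(table = tab, best = best, selected = fits[[best]],
                 method = method),
            class = "aic_selection")
}

#' @export
print.aic_selection <- function(x, ...) {
  cat("<aic_selection> method:", x$method, "\n")
  print(x$table, row.names = FALSE)
  cat("selected:", x$table$model[x$best], "\n")
  invisible(x)
}
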