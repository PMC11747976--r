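#' Two-state learner parameters
#'
#' Parameter set of the multi-rate, gain-independent two-state model of
#' trial-by-trial motor adaptation: a fast process with learning rate `Bf`
#' and retention factor `Af`, and a slow process with learning rate `Bs`
#' and retention factor `As`. The canonical regime is `Bf >> Bs` (the fast
#' process responds strongly to error) and `As >> Af` (the slow process
#' retains well); violating that ordering raises a warning, not an error,
#' since bootstrap replicates may wander outside it.
#'
#' @param Af,As Retention factors in \[0, 1\] (fast, slow).
#' @param Bf,Bs Learning rates in \[0, 1\] (fast, slow).
#' @return A `twostate_params` object (named numeric vector).
#' @examples
#' twostate_params(Af = 0.705, As = 0.99, Bf = 0.18, Bs = 0.02)
#' @export
twostate_params <- function(Af, As, Bf, Bs) {
  p <- c(Af = as.numeric(Af)[1], As = as.numeric(As)[1],
         Bf = as.numeric(Bf)[1], Bs = as.numeric(Bs)[1])
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("two-state parameters must be finite and in [0, 1]", call. = FALSE)
  }
  if (Bf <= Bs || As <= Af) {
    warning("parameter ordering Bf > Bs and As > Af violated", call. = FALSE)
  }
  structure(p, class = "twostate_params")
}

as_twostate_params <- function(p) {
  if (inherits(p, "twostate_params")) return(p)
  p <- unlist(p)
  stopifnot(all(c("Af", "As", "Bf", "Bs") %in% names(p)))
  suppressWarnings(twostate_params(p[["Af"]], p[["As"]], p[["Bf"]], p[["Bs"]]))
}

#' @export
print.twostate_params <- function(x, ...) {
  cat("<twostate_params> ",
      sprintf("Af=%.4g As=%.4g Bf=%.4g Bs=%.4g", x[["Af"]], x[["As"]],
              x[["Bf"]], x[["Bs"]]), "\n")
  invisible(x)
}

#' Printed best-fit two-state parameters per group
#'
#' Group-level best-fit parameter sets used as generating values for
#' synthetic cohorts. `Bf`, `Bs` and `As` are the published point
#' estimates per condition; `Af` point values were not published, so the
#' midpoint of each group's 95% CI is used (control 0.705, 3N 0.62,
#' 7N 0.26).
#'
#' @param group Group label; one of [adaptation_groups()].
#' @return A [twostate_params()] object.
#' @export
group_params <- function(group) {
  group <- match_group(group)
  switch(group,
    control = twostate_params(Af = 0.705, As = 0.99, Bf = 0.18, Bs = 0.02),
    "3N"    = twostate_params(Af = 0.62,  As = 0.97, Bf = 0.08, Bs = 0.02),
    "7N"    = twostate_params(Af = 0.26,  As = 0.96, Bf = 0.06, Bs = 0.01)
  )
}

#' One trial of the two-state model
#'
#' Applies the error rule for the current trial and the state update:
#' on a force-field trial the error is `e = f - (xf + xs)` with `f` the
#' normalised field strength (1 when the field is on, 0 on null or
#' noise-only reaches, where the absent field actively unlearns any built-up
#' state); on an error-clamp trial lateral error is mechanically clamped,
#' `e = 0`, and the states purely decay by their retention factors.
#'
#' @param state Numeric `c(xf, xs)` before the trial.
#' @param params [twostate_params()].
#' @param ff_gain Field strength `f` for this trial, 0 or 1.
#' @param trial_type One of `"null"`, `"noise_only"`, `"FF"`, `"EC"`.
#' @return List with `xf`, `xs` (post-trial states) and `e` (this trial's
#'   error).
#' @export
twostate_step <- function(state, params, ff_gain, trial_type) {
  params <- as_twostate_params(params)
  stopifnot(length(state) == 2L, all(is.finite(state)))
  if (trial_type == "FF" && ff_gain != 1) {
    stop("FF trial requires ff_gain = 1", call. = FALSE)
  }
  if (trial_type != "FF" && ff_gain != 0) {
    stop("ff_gain must be 0 off FF trials", call. = FALSE)
  }
  e <- if (trial_type == "EC") 0 else ff_gain - (state[1] + state[2])
  list(xf = params[["Af"]] * state[1] + params[["Bf"]] * e,
       xs = params[["As"]] * state[2] + params[["Bs"]] * e,
       e = e)
}

#' Simulate the two-state model over a trial schedule
#'
#' Propagates the fast and slow states across an ordered trial list. The
#' recorded net output `x[n] = xf[n] + xs[n]` is the state *entering* trial
#' `n` (what an error-clamp probe on trial `n` would measure), and `e[n]`
#' is the error experienced on trial `n`.
#'
#' @param params [twostate_params()].
#' @param schedule A [build_trial_schedule()] result, or any data frame
#'   with `trial_type` and `ff_gain` columns.
#' @param x0 Initial `c(xf, xs)`; defaults to `c(0, 0)`.
#' @param null_mode How null / noise-only trials update the states:
#'   `"unlearn"` (default) treats them as `f = 0` so the error `-x` drives
#'   active unlearning; `"hold"` leaves the states untouched.
#' @return A `twostate_trace` data frame with columns `trial`,
#'   `trial_type`, `xf`, `xs`, `x`, `e`.
#' @examples
#' p <- group_params("control")
#' sched <- build_trial_schedule("control", seed = 1)
#' tr <- twostate_simulate(p, sched)
#' max(abs(tr$x - (tr$xf + tr$xs)))  # superposition, exactly 0
#' @export
twostate_simulate <- function(params, schedule, x0 = c(0, 0),
                              null_mode = c("unlearn", "hold")) {
  params <- as_twostate_params(params)
  null_mode <- match.arg(null_mode)
  n <- nrow(schedule)
  stopifnot(n > 0)
  Af <- params[["Af"]]; As <- params[["As"]]
  Bf <- params[["Bf"]]; Bs <- params[["Bs"]]
  type <- schedule$trial_type
  f <- schedule$ff_gain
  xf <- xs <- e <- numeric(n)
  cf <- x0[1]; cs <- x0[2]
  for (i in seq_len(n)) {
    xf[i] <- cf; xs[i] <- cs
    if (type[i] == "EC") {
      e[i] <- 0
      cf <- Af * cf; cs <- As * cs
    } else if (type[i] == "FF" || null_mode == "unlearn") {
      e[i] <- f[i] - (cf + cs)
      cf <- Af * cf + Bf * e[i]
      cs <- As * cs + Bs * e[i]
    } else {
      e[i] <- 0  # hold: no update on null / noise-only trials
    }
  }
  trial <- if ("index" %in% names(schedule)) schedule$index else seq_len(n)
  structure(data.frame(trial = trial, trial_type = type,
                       xf = xf, xs = xs, x = xf + xs, e = e,
                       stringsAsFactors = FALSE),
            class = c("twostate_trace", "data.frame"),
            params = params, null_mode = null_mode)
}

#' Closed-form asymptote under a constant force field
#'
#' Fixed point of the two-state recursion under constant `f = 1`:
#' `x* = S / (1 + S)` with `S = Bf / (1 - Af) + Bs / (1 - As)`.
#'
#' @param params [twostate_params()]; requires `Af < 1` and `As < 1`.
#' @return The asymptotic net adaptation (unitless, on the adaptation
#'   coefficient scale).
#' @export
twostate_steady_state <- function(params) {
  params <- as_twostate_params(params)
  if (params[["Af"]] >= 1 || params[["As"]] >= 1) {
    stop("no fixed point: retention factors must be < 1", call. = FALSE)
  }
  S <- params[["Bf"]] / (1 - params[["Af"]]) +
       params[["Bs"]] / (1 - params[["As"]])
  S / (1 + S)
}

#' Export a simulated trace as CSV
#'
#' @param trace A `twostate_trace`.
#' @param path File path.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
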