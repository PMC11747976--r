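profile_halfwidth_ms <- 600L

#' Construct a force profile on the canonical window
#'
#' A force profile is the lateral force (N) on a fixed 1,201-sample grid at
#' 1 ms resolution spanning -600 to +600 ms around the moment of peak reach
#' velocity (sample 601).
#'
#' @param samples Numeric vector of length 1201.
#' @param padded Logical; whether any part of the window was zero-padded
#'   because the movement was shorter than the window.
#' @return A `force_profile` object.
#' @export
force_profile <- function(samples, padded = FALSE) {
  w <- 2L * profile_halfwidth_ms + 1L
  if (length(samples) != w || any(!is.finite(samples))) {
    stop("a force profile needs ", w, " finite samples", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples),
                 t_ms = seq(-profile_halfwidth_ms, profile_halfwidth_ms),
                 t0_index = profile_halfwidth_ms + 1L,
                 padded = isTRUE(padded)),
            class = "force_profile")
}

#' @export
print.force_profile <- function(x, ...) {
  cat(sprintf("<force_profile> 1201 samples (-600..+600 ms), peak |F| %.3f N%s\n",
              max(abs(x$samples)), if (x$padded) " [padded]" else ""))
  invisible(x)
}

as_profile_samples <- function(p) {
  if (inherits(p, "force_profile")) p$samples else as.numeric(p)
}

#' Align a trial's force series to peak velocity
#'
#' Extracts the 1,200 ms (+/-600 ms) force window centred on the sample of
#' peak velocity toward the target. Ties in peak velocity resolve to the
#' earliest sample. Samples outside the recorded movement are zero-padded
#' and the profile is flagged `padded`.
#'
#' @param force Lateral force series (N) at 1 kHz.
#' @param vy Velocity series (m/s), same length as `force`.
#' @return A [force_profile()].
#' @export
align_to_peak_velocity <- function(force, vy) {
  stopifnot(length(force) == length(vy), length(force) >= 1)
  peak <- which.max(vy)[1]
  h <- profile_halfwidth_ms
  idx <- (peak - h):(peak + h)
  inside <- idx >= 1L & idx <= length(force)
  if (!any(inside)) stop("no samples fall inside the window", call. = FALSE)
  out <- numeric(2L * h + 1L)
  out[inside] <- force[idx[inside]]
  force_profile(out, padded = !all(inside))
}

#' Adaptation coefficient
#'
#' The scalar measure of adaptation on an error-clamp trial: the slope of
#' the ordinary least-squares regression of the baseline-subtracted actual
#' force profile onto the sign-flipped ideal force profile of the field.
#' Flipping the sign puts the ideal compensation and the actual force in
#' the same direction, so AC = 1 means the subject fully cancels the
#' perturbation, AC = -1 an exactly opposite force, and AC = 0 a force
#' unrelated (zero sample covariance) to the ideal profile.
#'
#' @param actual Actual applied force profile ([force_profile()] or
#'   numeric on the same grid).
#' @param ideal Ideal force profile of the field (the perturbation side;
#'   the sign flip to the compensatory direction happens internally).
#' @param baseline Baseline force profile to subtract; defaults to zero.
#' @param intercept Include an intercept in the regression (default TRUE;
#'   makes the AC invariant to constant force offsets).
#' @return The unitless adaptation coefficient.
#' @examples
#' tr <- minimum_jerk_velocity(0.10, 0.5)
#' ideal <- align_to_peak_velocity(ideal_force_profile(tr), tr$vy)
#' comp <- force_profile(-ideal$samples, padded = ideal$padded)
#' adaptation_coefficient(comp, ideal)  # exactly 1
#' @export
adaptation_coefficient <- function(actual, ideal, baseline = NULL,
                                   intercept = TRUE) {
  y <- as_profile_samples(actual)
  x <- -as_profile_samples(ideal)  # sign-flipped ideal: compensatory direction
  if (!is.null(baseline)) y <- y - as_profile_samples(baseline)
  if (length(y) != length(x)) stop("profiles on different grids", call. = FALSE)
  if (intercept) {
    sxx <- sum((x - mean(x))^2)
    if (sxx == 0) stop("ideal profile has zero variance", call. = FALSE)
    sum((x - mean(x)) * (y - mean(y))) / sxx
  } else {
    sxx <- sum(x^2)
    if (sxx == 0) stop("ideal profile is identically zero", call. = FALSE)
    sum(x * y) / sxx
  }
}

#' Mean force in a 100 ms window
#'
#' Average force over an inclusive 100 ms (101-sample) window centred at
#' -150, 0 or +150 ms relative to peak velocity — the three temporal
#' windows used to compare force profiles across training periods.
#'
#' @param profile A [force_profile()].
#' @param center_ms Window centre in ms relative to peak velocity.
#' @param width_ms Window width in ms (inclusive span; default 100).
#' @return Mean force (N).
#' @export
window_average_force <- function(profile, center_ms, width_ms = 100) {
  s <- as_profile_samples(profile)
  h <- profile_halfwidth_ms
  half <- width_ms / 2
  if (center_ms - half < -h || center_ms + half > h) {
    stop("window extends outside the profile span", call. = FALSE)
  }
  i0 <- (h + 1) + center_ms  # sample at the window centre
  mean(s[(i0 - half):(i0 + half)])
}

#' Early / middle / late training slices
#'
#' Means of the adaptation coefficient over the first 10%, middle 10% and
#' last 10% of the training-block observations. Slice size is 10% of the
#' number of observations, rounded half-up with a floor of one.
#'
#' @param ac Numeric AC series in trial order (training-block EC trials).
#' @return Named numeric `c(early, middle, late)`.
#' @export
training_period_slices <- function(ac) {
  n <- length(ac)
  if (n < 1 || any(!is.finite(ac))) stop("empty or non-finite AC series",
                                         call. = FALSE)
  k <- max(1L, floor(0.1 * n + 0.5))
  mid_start <- floor((n - k) / 2) + 1L
  c(early = mean(ac[seq_len(k)]),
    middle = mean(ac[mid_start:(mid_start + k - 1L)]),
    late = mean(ac[(n - k + 1L):n]))
}

#' Retention delta over the 1 min hold
#'
#' Difference between adaptation at the end of training (the pre-delay
#' error-clamp probe) and adaptation immediately after the 1 min delay.
#' A large positive delta reflects decay of the fast process over the
#' hold; the slowly-decaying component survives it.
#'
#' @param pre_delay_ac,post_delay_ac Adaptation coefficients before and
#'   after the hold.
#' @return `pre_delay_ac - post_delay_ac` (may be negative).
#' @export
retention_delta <- function(pre_delay_ac, post_delay_ac) {
  stopifnot(is.finite(pre_delay_ac), is.finite(post_delay_ac))
  pre_delay_ac - post_delay_ac
}

#' Normalise a decay series to percent of its first trial
#'
#' Expresses each trial's adaptation coefficient as a percentage of the
#' value on the first trial of the decay block, so the first entry is
#' 100% and curves from groups with different end-of-training adaptation
#' become comparable. Applied per subject when a subject column is
#' present. Subjects whose first-trial AC is at or below `eps` in
#' magnitude cannot be normalised and are dropped with a warning.
#'
#' @param ac Numeric AC series in decay-trial order, or a data frame with
#'   columns `subject` and `ac` (trial order within subject).
#' @param eps Magnitude threshold below which the first-trial AC is
#'   treated as degenerate.
#' @return Percent series of the same shape (degenerate subjects removed).
#' @export
normalize_decay <- function(ac, eps = 1e-8) {
  if (is.data.frame(ac)) {
    stopifnot(all(c("subject", "ac") %in% names(ac)))
    parts <- split(ac, ac$subject)
    keep <- vapply(parts, function(d) abs(d$ac[1]) > eps, logical(1))
    if (!all(keep)) {
      warning(sum(!keep), " subject(s) with near-zero first decay-trial AC ",
              "excluded from normalisation", call. = FALSE)
    }
    out <- lapply(parts[keep], function(d) {
      d$ac <- 100 * d$ac / d$ac[1]
      d
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    return(out)
  }
  stopifnot(is.numeric(ac), length(ac) >= 1)
  if (abs(ac[1]) <= eps) {
    stop("first decay-trial AC is (near) zero; cannot normalise",
         call. = FALSE)
  }
  100 * ac / ac[1]
}

#' Baseline movement variability
#'
#' Angular deviation of an unperturbed reach from the straight start-target
#' line, measured at the point of maximum lateral deviation:
#' `atan(|lateral deviation| / forward distance at that point)`, in
#' degrees. A perfectly straight path scores 0.
#'
#' @param x Lateral position series (m), relative to the straight path.
#' @param y Forward position series (m), from start (0) toward the target.
#' @return Angle in degrees.
#' @export
baseline_variability <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (max(abs(y)) == 0) stop("zero-length path", call. = FALSE)
  if (max(abs(x)) == 0) return(0)  # perfectly straight reach
  i <- which.max(abs(x))[1]
  if (y[i] <= 0) stop("maximum deviation at non-positive forward distance",
                      call. = FALSE)
  atan2(abs(x[i]), y[i]) * 180 / pi
}

#' Trial exclusion by the speed criterion
#'
#' A reach is excluded when its peak velocity toward the target falls
#' outside the 0.2--0.55 m/s acceptance range.
#'
#' @param trace A [minimum_jerk_velocity()] trace (or any list with
#'   `peak_velocity`).
#' @return `TRUE` when the trial should be excluded.
#' @export
exclude_trial <- function(trace) {
  pv <- trace$peak_velocity
  !(is.finite(pv) && pv >= 0.2 && pv <= 0.55)
}
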