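#' Cohort specification for synthetic subjects
#'
#' Describes a simulated group of subjects whose error-clamp force profiles
#' embody a two-state learner plus observation noise. Group-level
#' generating parameters default to the published per-group best fits
#' ([group_params()]); individual subjects may deviate from them by a
#' truncated-normal draw with `between_subject_sd`. Observation noise is
#' white Gaussian noise added to each error-clamp force profile, scaled so
#' that the induced standard deviation of the adaptation coefficient is
#' `ac_noise_sd`.
#'
#' @param group Group label; one of [adaptation_groups()].
#' @param n_subjects Number of subjects (the study ran 20 per group).
#' @param params Generating [twostate_params()].
#' @param between_subject_sd Per-parameter SD of subject-level deviations
#'   (single number or length-4 named vector); 0 (default) makes all
#'   subjects share the group parameters.
#' @param ac_noise_sd Observation noise on the AC scale (default 0.05).
#' @param seed Integer master seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(group, n_subjects = 20,
                        params = group_params(group),
                        between_subject_sd = 0, ac_noise_sd = 0.05,
                        seed = 1L) {
  group <- match_group(group)
  params <- as_twostate_params(params)
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (any(between_subject_sd < 0) || ac_noise_sd < 0) {
    stop("noise standard deviations must be >= 0", call. = FALSE)
  }
  sd4 <- rep(between_subject_sd, length.out = 4)
  names(sd4) <- c("Af", "As", "Bf", "Bs")
  if (!is.null(names(between_subject_sd)) &&
      all(names(between_subject_sd) %in% names(sd4))) {
    sd4[] <- 0
    sd4[names(between_subject_sd)] <- between_subject_sd
  }
  structure(list(group = group, n_subjects = as.integer(n_subjects),
                 params = params, between_subject_sd = sd4,
                 ac_noise_sd = ac_noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

# one truncated-normal draw per parameter, truncation to [0, 1] by rejection
draw_subject_params <- function(params, sd4) {
  if (all(sd4 == 0)) return(params)
  draw <- vapply(names(sd4), function(nm) {
    repeat {
      v <- stats::rnorm(1, params[[nm]], sd4[[nm]])
      if (v >= 0 && v <= 1) return(v)
    }
  }, numeric(1))
  suppressWarnings(twostate_params(draw[["Af"]], draw[["As"]],
                                   draw[["Bf"]], draw[["Bs"]]))
}

# draw a reach duration whose minimum-jerk peak velocity passes the
# speed criterion (0.2-0.55 m/s for a 0.10 m reach -> T in [0.341, 0.938] s)
draw_duration <- function(mean = 0.5, sd = 0.05) {
  repeat {
    d <- stats::rnorm(1, mean, sd)
    if (d >= 0.35 && d <= 0.9) return(d)
  }
}

# build one EC trial's profiles: ideal field profile aligned to peak
# velocity, plus the subject's applied profile for net adaptation x
ec_trial_profiles <- function(x, ac_noise_sd, ff = force_field_spec()) {
  mv <- minimum_jerk_velocity(duration = draw_duration())
  ideal <- align_to_peak_velocity(ideal_force_profile(mv, ff), mv$vy)
  comp <- -ideal$samples  # compensatory direction
  sigma <- ac_noise_sd * sqrt(sum((comp - mean(comp))^2))
  actual <- x * comp + stats::rnorm(length(comp), 0, sigma)
  list(ideal = ideal,
       actual = force_profile(actual, padded = ideal$padded))
}

#' Simulate one subject
#'
#' Propagates the two-state learner over the schedule with the subject's
#' parameters and, on every error-clamp trial, synthesises the applied
#' lateral force profile as the net adaptation `x[n]` times the ideal
#' compensatory profile of a freshly drawn reach, plus white profile noise.
#' Baseline error-clamp profiles (state effectively 0) define the baseline
#' mean profile, which is subtracted — exactly as in the analysis of real
#' data — before the adaptation coefficient is regressed out.
#'
#' @param spec A [cohort_spec()].
#' @param schedule A [build_trial_schedule()] result for `spec$group`.
#' @param subject_seed Integer seed for this subject's draws.
#' @param keep_profiles Keep the per-EC-trial force profiles on the result
#'   (memory-heavy; default `FALSE` retains only the AC series).
#' @return A `subject_dataset`: list with `ac` (data frame `trial`,
#'   `block`, `delay_after`, `ac`), `true_trace` (the hidden
#'   [twostate_simulate()] ground truth), `params`, `subject_seed`, and
#'   optionally `profiles`.
#' @export
simulate_subject <- function(spec, schedule, subject_seed,
                             keep_profiles = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr_seed(as.integer(subject_seed), {
    pars <- draw_subject_params(spec$params, spec$between_subject_sd)
    trace <- twostate_simulate(pars, schedule)
    ec <- which(schedule$trial_type == "EC")
    profs <- lapply(ec, function(i) {
      ec_trial_profiles(trace$x[i], spec$ac_noise_sd)
    })
    names(profs) <- as.character(schedule$index[ec])

    is_base <- schedule$block[ec] == "baseline"
    base_mat <- vapply(profs[is_base], function(p) p$actual$samples,
                       numeric(1201))
    baseline_mean <- force_profile(rowMeans(base_mat))

    ac <- vapply(seq_along(ec), function(j) {
      bl <- if (is_base[j]) NULL else baseline_mean
      adaptation_coefficient(profs[[j]]$actual, profs[[j]]$ideal, bl)
    }, numeric(1))

    out <- list(ac = data.frame(trial = schedule$index[ec],
                                block = schedule$block[ec],
                                delay_after = schedule$delay_after[ec],
                                ac = ac, stringsAsFactors = FALSE),
                baseline_mean = baseline_mean,
                true_trace = trace, params = pars,
                subject_seed = as.integer(subject_seed))
    if (keep_profiles) out$profiles <- profs
    structure(out, class = "subject_dataset")
  })
}

#' Simulate a cohort
#'
#' Simulates `spec$n_subjects` subjects over a shared trial schedule (the
#' default, so that error-clamp probes align across subjects and group
#' means are defined per trial) or, optionally, per-subject re-randomised
#' schedules.
#'
#' @param spec A [cohort_spec()].
#' @param schedule Optional shared schedule; built from `spec$group` and
#'   `spec$seed` when omitted.
#' @param shared_schedule If `FALSE`, each subject gets an independently
#'   randomised schedule (group means are then defined only where probes
#'   align; with per-block EC counts fixed they align by EC ordinal).
#' @return A `cohort`: list with `spec`, `schedule`, `subjects` (list of
#'   [simulate_subject()] results) and `mean_ac` (data frame `trial`,
#'   `block`, `ac` of across-subject means at each EC ordinal).
#' @examples
#' \donttest{
#' coh <- simulate_cohort(cohort_spec("control", n_subjects = 3, seed = 7))
#' head(coh$mean_ac)
#' }
#' @export
simulate_cohort <- function(spec, schedule = NULL, shared_schedule = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(schedule)) {
    schedule <- build_trial_schedule(spec$group, spec$seed)
  }
  seeds <- withr_seed(spec$seed,
                      sample.int(2147483646L, spec$n_subjects + 1L))
  subjects <- lapply(seq_len(spec$n_subjects), function(i) {
    sch_i <- if (shared_schedule) schedule else
      build_trial_schedule(spec$group, seeds[[spec$n_subjects + 1L]] + i)
    s <- simulate_subject(spec, sch_i, seeds[[i]])
    s$schedule_seed <- attr(sch_i, "seed")
    s
  })
  ac_mat <- vapply(subjects, function(s) s$ac$ac,
                   numeric(nrow(subjects[[1]]$ac)))
  ac_mat <- matrix(ac_mat, ncol = spec$n_subjects)
  mean_ac <- data.frame(trial = subjects[[1]]$ac$trial,
                        block = subjects[[1]]$ac$block,
                        ac = rowMeans(ac_mat), stringsAsFactors = FALSE)
  structure(list(spec = spec, schedule = schedule, subjects = subjects,
                 mean_ac = mean_ac),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> group %s: %d subjects, %d EC observations each\n",
              x$spec$group, length(x$subjects), nrow(x$mean_ac)))
  invisible(x)
}

#' Per-subject AC matrix for one block
#'
#' @param cohort A [simulate_cohort()] result.
#' @param block Block label.
#' @return Matrix (subjects x EC trials) of adaptation coefficients, with
#'   column names the schedule trial indices.
#' @export
cohort_ac_matrix <- function(cohort, block = "training") {
  rows <- cohort$subjects[[1]]$ac$block == block
  if (!any(rows)) stop("block '", block, "' has no EC observations",
                       call. = FALSE)
  m <- t(vapply(cohort$subjects, function(s) s$ac$ac[rows],
                numeric(sum(rows))))
  colnames(m) <- cohort$subjects[[1]]$ac$trial[rows]
  m
}

#' Tidy AC table for a cohort
#'
#' @param cohort A [simulate_cohort()] result.
#' @return Data frame with columns `subject`, `group`, `block`,
#'   `trial_index`, `ac`.
#' @export
cohort_ac_table <- function(cohort) {
  do.call(rbind, lapply(seq_along(cohort$subjects), function(i) {
    s <- cohort$subjects[[i]]
    data.frame(subject = i, group = cohort$spec$group,
               block = s$ac$block, trial_index = s$ac$trial,
               ac = s$ac$ac, delay_after = s$ac$delay_after,
               stringsAsFactors = FALSE)
  }))
}

#' Export / ingest a cohort as per-subject CSVs plus a manifest
#'
#' `write_cohort()` writes one CSV per subject (columns `subject`, `group`,
#' `block`, `trial_index`, `ac`), the shared schedule, and a
#' `manifest.json` recording group, seeds and generating parameters so that
#' downstream fits can be scored against ground truth. `ingest_external()`
#' reads any directory in that layout — including tables from a real
#' experiment — back into the structures the fitting pipeline consumes.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `write_cohort` returns `dir` invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- cohort_ac_table(cohort)
  for (i in unique(tab$subject)) {
    utils::write.csv(tab[tab$subject == i, ],
                     file.path(dir, sprintf("subject_%02d.csv", i)),
                     row.names = FALSE)
  }
  write_schedule_csv(cohort$schedule, file.path(dir, "schedule.csv"))
  manifest <- list(group = cohort$spec$group,
                   n_subjects = cohort$spec$n_subjects,
                   seed = cohort$spec$seed,
                   subject_seeds = vapply(cohort$subjects,
                                          `[[`, integer(1), "subject_seed"),
                   generating_params = as.list(unclass(cohort$spec$params)),
                   between_subject_sd = as.list(cohort$spec$between_subject_sd),
                   ac_noise_sd = cohort$spec$ac_noise_sd)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
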