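test_that("noiseless subjects round-trip the generating state exactly", {
  sched <- build_trial_schedule("control", seed = 3)
  spec <- cohort_spec("control", n_subjects = 1, ac_noise_sd = 0, seed = 3)
  subj <- simulate_subject(spec, sched, subject_seed = 99)
  expect_equal(subj$ac$trial, sched$index[sched$trial_type == "EC"])
  # computed AC at every EC probe equals the hidden net state x[n]
  truth <- subj$true_trace$x[match(subj$ac$trial, subj$true_trace$trial)]
  expect_equal(subj$ac$ac, truth, tolerance = 1e-6)
})

test_that("a learner with zero learning rates produces flat EC profiles", {
  sched <- build_trial_schedule("control", seed = 4)
  p0 <- suppressWarnings(twostate_params(0.705, 0.99, 0, 0))
  spec <- cohort_spec("control", n_subjects = 1, params = p0,
                      ac_noise_sd = 0, seed = 4)
  subj <- simulate_subject(spec, sched, 1, keep_profiles = TRUE)
  expect_true(all(abs(subj$ac$ac) < 1e-12))
  peak_f <- vapply(subj$profiles, function(p) max(abs(p$actual$samples)),
                   numeric(1))
  expect_true(all(peak_f < 1e-12))
})

test_that("simulation is bit-identical under fixed seeds", {
  sched <- build_trial_schedule("3N", seed = 6)
  spec <- cohort_spec("3N", n_subjects = 3, seed = 6)
  a <- simulate_subject(spec, sched, 123)
  b <- simulate_subject(spec, sched, 123)
  expect_identical(a$ac, b$ac)
  expect_identical(a$params, b$params)
  ca <- simulate_cohort(spec)
  cb <- simulate_cohort(spec)
  expect_identical(ca$mean_ac, cb$mean_ac)
})

test_that("group mean with one subject is that subject's series", {
  spec <- cohort_spec("control", n_subjects = 1, seed = 9)
  coh <- simulate_cohort(spec)
  expect_equal(coh$mean_ac$ac, coh$subjects[[1]]$ac$ac)
})

test_that("late-training group mean sits at the generating model's level", {
  spec <- cohort_spec("control", n_subjects = 20, seed = 21)
  coh <- simulate_cohort(spec)
  train <- coh$mean_ac[coh$mean_ac$block == "training", ]
  model <- twostate_simulate(spec$params, coh$schedule)
  late_idx <- tail(train$trial, 5)
  model_late <- mean(model$x[match(late_idx, model$trial)])
  obs_late <- mean(tail(train$ac, 5))
  # 5-trial mean of 20 subjects at noise sd 0.05 -> se ~ 0.005
  expect_equal(obs_late, model_late, tolerance = 0.03)
  # and the model's late level is governed by the closed-form asymptote
  expect_lt(abs(model_late - twostate_steady_state(spec$params)), 0.1)
})

test_that("observation noise raises across-subject AC variance", {
  sched <- build_trial_schedule("control", seed = 13)
  var_at <- function(sd, seed) {
    spec <- cohort_spec("control", n_subjects = 30, ac_noise_sd = sd,
                        seed = seed)
    coh <- simulate_cohort(spec, schedule = sched)
    m <- cohort_ac_matrix(coh, "training")
    mean(apply(m, 2, stats::var))
  }
  v_low <- var_at(0.02, 31)
  v_high <- var_at(0.10, 31)
  expect_gt(v_high, v_low)
  # the induced AC noise approaches the requested scale (baseline
  # subtraction adds a small correlated component, so allow slack)
  expect_equal(sqrt(v_high), 0.10, tolerance = 0.35)
})

test_that("group-mean AC converges to the generating trace as n grows", {
  spec <- cohort_spec("control", n_subjects = 200, seed = 17)
  coh <- simulate_cohort(spec)
  model <- twostate_simulate(spec$params, coh$schedule)
  train <- coh$mean_ac[coh$mean_ac$block == "training", ]
  pred <- model$x[match(train$trial, model$trial)]
  # per-subject AC noise is ac_noise_sd plus the small correlated component
  # from baseline subtraction (sd/sqrt(10)); 4-sigma bound across 20 trials
  sd_eff <- spec$ac_noise_sd * sqrt(1 + 1 / 10)
  tol <- 4 * sd_eff / sqrt(spec$n_subjects)
  expect_true(all(abs(train$ac - pred) < tol))
  expect_lt(mean(abs(train$ac - pred)), 0.01)
})

test_that("between-subject variability perturbs parameters within bounds", {
  sched <- build_trial_schedule("control", seed = 19)
  spec <- cohort_spec("control", n_subjects = 12, between_subject_sd = 0.05,
                      ac_noise_sd = 0, seed = 19)
  coh <- simulate_cohort(spec, schedule = sched)
  pars <- t(vapply(coh$subjects, function(s) unclass(s$params), numeric(4)))
  expect_true(all(pars >= 0 & pars <= 1))
  expect_true(all(apply(pars, 2, stats::sd) > 0))
})

test_that("cohort export round-trips through ingest_external", {
  spec <- cohort_spec("3N", n_subjects = 3, seed = 23)
  coh <- simulate_cohort(spec)
  dir <- tempfile("cohort_")
  write_cohort(coh, dir)
  back <- ingest_external(dir)
  expect_equal(length(back$subjects), 3)
  for (i in 1:3) {
    expect_equal(back$subjects[[i]]$ac$ac, coh$subjects[[i]]$ac$ac)
    expect_equal(back$subjects[[i]]$ac$trial, coh$subjects[[i]]$ac$trial)
  }
  expect_equal(back$mean_ac$ac, coh$mean_ac$ac)
  expect_equal(back$manifest$generating_params$Bf, 0.08)
  unlink(dir, recursive = TRUE)
})
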