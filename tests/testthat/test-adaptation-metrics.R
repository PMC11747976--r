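test_that("alignment centres the window on peak velocity and zero-pads", {
  # synthetic trace with a known peak location
  vy <- c(rep(0, 2000), seq(0, 1, length.out = 101),
          seq(1, 0, length.out = 101)[-1], rep(0, 2000))
  force <- seq_along(vy) * 1e-3
  peak <- which.max(vy)
  prof <- align_to_peak_velocity(force, vy)
  expect_s3_class(prof, "force_profile")
  expect_false(prof$padded)
  expect_equal(prof$samples[prof$t0_index], force[peak])

  # shifting the whole recording leaves the aligned window untouched
  shift <- 50
  prof2 <- align_to_peak_velocity(c(rep(0, shift), force),
                                  c(rep(0, shift), vy))
  expect_equal(prof2$samples, prof$samples)

  # an 800 ms movement cannot fill the 1,200 ms window: padding is flagged
  mv <- minimum_jerk_velocity(0.10, 0.8)
  short <- align_to_peak_velocity(ideal_force_profile(mv), mv$vy)
  expect_true(short$padded)
  expect_true(all(short$samples[1:100] == 0))

  expect_error(align_to_peak_velocity(numeric(0), numeric(0)))
})

test_that("adaptation coefficient hits the analytic anchor cases", {
  pr <- std_profiles()
  # equal to the ideal compensation -> 1; exact opposite -> -1; flat -> 0
  expect_equal(adaptation_coefficient(pr$comp, pr$ideal), 1)
  expect_equal(adaptation_coefficient(pr$ideal, pr$ideal), -1)
  expect_equal(adaptation_coefficient(rep(2, 1201), pr$ideal), 0)
  # half the compensation -> 0.5
  half <- force_profile(0.5 * pr$comp$samples)
  expect_equal(adaptation_coefficient(half, pr$ideal), 0.5)
})

test_that("AC recovers any scalar gain over any baseline, offset-invariant", {
  pr <- std_profiles()
  base <- force_profile(0.3 * sin(seq(0, 4 * pi, length.out = 1201)))
  for (a in c(-1, -0.25, 0, 0.37, 1.6)) {
    actual <- force_profile(a * pr$comp$samples + base$samples)
    expect_equal(adaptation_coefficient(actual, pr$ideal, base), a,
                 tolerance = 1e-12)
    # constant offsets are absorbed by the intercept
    shifted <- force_profile(actual$samples + 1.7)
    expect_equal(adaptation_coefficient(shifted, pr$ideal, base), a,
                 tolerance = 1e-12)
  }
  # the no-intercept mode still recovers the pure-gain case
  actual <- force_profile(0.4 * pr$comp$samples)
  expect_equal(adaptation_coefficient(actual, pr$ideal, intercept = FALSE),
               0.4, tolerance = 1e-12)
  expect_error(adaptation_coefficient(actual, rep(0, 1201)), "zero")
  expect_error(adaptation_coefficient(actual$samples[-1], pr$ideal),
               "grids")
})

test_that("100 ms window means behave on constant, bell and sine profiles", {
  flat <- force_profile(rep(2, 1201))
  for (c0 in c(-150, 0, 150)) {
    expect_equal(window_average_force(flat, c0), 2)
  }
  # a bell-shaped ideal profile: centre window under the peak but above
  # both flanking windows
  pr <- std_profiles()
  peak6 <- force_profile(pr$ideal$samples * 6 / max(pr$ideal$samples))
  centre <- window_average_force(peak6, 0)
  expect_lt(centre, 6)
  expect_gt(centre, window_average_force(peak6, -150))
  expect_gt(centre, window_average_force(peak6, 150))
  # a full 10 Hz period averages to zero over 100 ms
  sine <- force_profile(noise_waveform(5, seq(-0.6, 0.6, by = 1e-3)))
  expect_equal(window_average_force(sine, 0), 0, tolerance = 1e-9)
  expect_error(window_average_force(flat, 580), "outside")
})

test_that("training slices take 10% means with round-half-up and floor 1", {
  expect_equal(training_period_slices(rep(0.4, 30)),
               c(early = 0.4, middle = 0.4, late = 0.4))
  inc <- seq(0.1, 0.6, length.out = 20)  # 20 points -> 2-point slices
  sl <- training_period_slices(inc)
  expect_lt(sl[["early"]], sl[["middle"]])
  expect_lte(sl[["middle"]], sl[["late"]])
  expect_equal(sl[["early"]], mean(inc[1:2]))
  expect_equal(sl[["late"]], mean(inc[19:20]))
  expect_equal(sl[["middle"]], mean(inc[10:11]))
  # tiny series still yield one-observation slices
  expect_equal(training_period_slices(c(1, 2, 3)),
               c(early = 1, middle = 2, late = 3))
  expect_error(training_period_slices(numeric(0)))
})

test_that("retention delta is the pre-minus-post difference", {
  expect_equal(retention_delta(0.5, 0.5), 0)
  expect_equal(retention_delta(0.3, 0.4), -0.1)
  expect_equal(retention_delta(0.45, 0.2), 0.25)
})

test_that("retention delta matches the fast process under the model account", {
  # if the hold wipes the fast process and spares the slow one, the drop
  # over the delay equals the fast state at the probe
  p <- group_params("control")
  tr <- twostate_simulate(p, ff_block(100))
  n <- nrow(tr)
  pre <- tr$x[n]
  post <- tr$xs[n]  # slow component only survives the hold
  expect_equal(retention_delta(pre, post), tr$xf[n])
})

test_that("decay normalisation starts at 100%, is scale-invariant and idempotent", {
  r <- 0.9
  geo <- 0.55 * r^(0:39)
  norm <- normalize_decay(geo)
  expect_equal(norm[1], 100)
  expect_equal(norm, 100 * r^(0:39))           # closed form
  expect_equal(normalize_decay(geo / 2), norm)  # scale invariance
  expect_equal(normalize_decay(norm), norm)     # idempotent
  expect_error(normalize_decay(c(0, 1, 2)), "zero")

  # per-subject normalisation over a tidy table
  tab <- data.frame(subject = rep(1:2, each = 3),
                    ac = c(0.5, 0.25, 0.125, 0.4, 0.2, 0.1))
  out <- normalize_decay(tab)
  expect_equal(out$ac, rep(c(100, 50, 25), 2))
  # degenerate first trial: subject dropped with a warning
  tab$ac[4] <- 0
  expect_warning(out2 <- normalize_decay(tab), "excluded")
  expect_equal(unique(out2$subject), 1)
})

test_that("baseline variability is the deviation angle at maximum deviation", {
  y <- seq(0, 0.10, length.out = 101)
  expect_equal(baseline_variability(rep(0, 101), y), 0)
  # 1 cm bump at 5 cm forward -> atan(1/5) = 11.3099 degrees
  x <- rep(0, 101); x[51] <- 0.01
  expect_equal(baseline_variability(x, y), atan2(0.01, 0.05) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(baseline_variability(x, y), 11.30993, tolerance = 1e-5)
  expect_equal(baseline_variability(-x, y), baseline_variability(x, y))
  expect_error(baseline_variability(rep(0, 5), rep(0, 5)), "zero-length")
})

test_that("speed criterion excludes reaches outside 0.2-0.55 m/s", {
  expect_false(exclude_trial(list(peak_velocity = 0.375)))
  expect_false(exclude_trial(list(peak_velocity = 0.2)))
  expect_false(exclude_trial(list(peak_velocity = 0.55)))
  expect_true(exclude_trial(list(peak_velocity = 0.19)))
  expect_true(exclude_trial(list(peak_velocity = 0.56)))
  expect_true(exclude_trial(minimum_jerk_velocity(0.10, 1.2)))
})
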