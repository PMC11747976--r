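test_that("LMSE objective is zero at the truth and grows away from it", {
  coh <- noiseless_cohort()
  obs <- training_obs(coh)
  truth <- group_params("control")
  expect_equal(objective_lmse(truth, obs, coh$schedule), 0)
  # perturbing any one parameter strictly increases the objective
  for (nm in c("Af", "As", "Bf", "Bs")) {
    p <- unclass(truth)
    p[nm] <- p[nm] + if (p[nm] > 0.9) -0.02 else 0.02
    pert <- suppressWarnings(do.call(twostate_params, as.list(p)))
    expect_gt(objective_lmse(pert, obs, coh$schedule), 0)
  }
  # and it is nonnegative anywhere
  anyp <- suppressWarnings(twostate_params(0.4, 0.95, 0.11, 0.03))
  expect_gte(objective_lmse(anyp, obs, coh$schedule), 0)
  # misaligned observations are rejected
  bad <- obs
  bad$trial <- bad$trial + 1L
  expect_error(objective_lmse(truth, bad, coh$schedule), "aligned")
})

test_that("bounded least squares recovers noiseless parameters", {
  coh <- noiseless_cohort()
  fit <- fit_lmse(training_obs(coh), coh$schedule)
  truth <- group_params("control")
  expect_equal(unclass(fit), unclass(truth), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_lt(attr(fit, "objective"), 1e-12)
  # the published initial Af (0.775) lies outside its bound: clip recorded
  expect_true(attr(fit, "init_clipped"))
})

test_that("an all-zero series drives the learning rates to their floor", {
  coh <- noiseless_cohort()
  obs <- training_obs(coh)
  obs$ac <- 0
  fit <- fit_lmse(obs, coh$schedule)
  expect_lt(fit[["Bf"]], 1e-4)
  expect_lt(fit[["Bs"]], 1e-4)
})

test_that("regularised objective reduces to LMSE at lambda 0 and at the reference", {
  coh <- noiseless_cohort()
  obs <- training_obs(coh)
  ref <- group_params("control")
  other <- suppressWarnings(twostate_params(0.5, 0.95, 0.1, 0.03))
  # zero penalty exactly at the reference point
  expect_equal(objective_regularized(ref, obs, coh$schedule, ref, 0.05),
               objective_lmse(ref, obs, coh$schedule))
  # lambda 0 recovers the plain objective anywhere
  expect_equal(objective_regularized(other, obs, coh$schedule, ref, 0),
               objective_lmse(other, obs, coh$schedule))
  # doubling every parameter: penalty = lambda * 4 * 1^2 = 0.2
  pen <- objective_regularized(
    structure(c(Af = 0.5, As = 0.5, Bf = 0.5, Bs = 0.5),
              class = "twostate_params"),
    obs, coh$schedule,
    structure(c(Af = 0.25, As = 0.25, Bf = 0.25, Bs = 0.25),
              class = "twostate_params"), 0.05) -
    objective_lmse(structure(c(Af = 0.5, As = 0.5, Bf = 0.5, Bs = 0.5),
                             class = "twostate_params"), obs, coh$schedule)
  expect_equal(pen, 0.05 * 4 * 1, tolerance = 1e-12)
  # a zero reference component is rejected
  zero_ref <- suppressWarnings(twostate_params(0.5, 0.9, 0, 0.01))
  expect_error(objective_regularized(other, obs, coh$schedule, zero_ref,
                                     0.05), "zero")
})

test_that("identical noiseless subjects give a zero-width bootstrap CI", {
  coh <- noiseless_cohort(n = 2)
  m <- cohort_ac_matrix(coh, "training")
  m20 <- m[rep(1, 20), ]  # 20 copies of the same subject
  boot <- bootstrap_fit(m20, coh$schedule,
                        fit_config(n_boot = 25, seed = 7))
  expect_equal(unname(boot$ci95["upper", ] - boot$ci95["lower", ]),
               rep(0, 4), tolerance = 1e-6)
  expect_equal(unclass(boot$theta_lmse), unclass(group_params("control")),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("bootstrap is deterministic under a fixed seed and respects bounds", {
  coh <- simulate_cohort(cohort_spec("control", n_subjects = 8, seed = 41))
  cfg <- fit_config(n_boot = 30, seed = 11)
  a <- bootstrap_fit(coh, config = cfg)
  b <- bootstrap_fit(coh, config = cfg)
  expect_identical(a$replicates, b$replicates)
  expect_identical(a$ci95, b$ci95)
  lower <- vapply(cfg$bounds, `[`, numeric(1), 1)
  upper <- vapply(cfg$bounds, `[`, numeric(1), 2)
  expect_true(all(sweep(a$replicates, 2, lower, ">=")))
  expect_true(all(sweep(a$replicates, 2, upper, "<=")))
  expect_true(all(a$ci95[1, ] >= lower & a$ci95[2, ] <= upper))
  # Gaussian summary is consistent with the replicate cloud
  expect_equal(unname(a$gaussian["mean", ]), unname(colMeans(a$replicates)))
})

test_that("stronger regularisation shrinks replicates toward the reference", {
  coh <- simulate_cohort(cohort_spec("control", n_subjects = 8, seed = 43))
  dist_at <- function(lam) {
    boot <- bootstrap_fit(coh, config = fit_config(lambda = lam,
                                                   n_boot = 20, seed = 13))
    ref <- unclass(boot$theta_lmse)
    mean(sqrt(rowSums(sweep(boot$replicates, 2, ref)^2)))
  }
  d <- vapply(c(0, 0.05, 0.5), dist_at, numeric(1))
  expect_gt(d[1], d[2])
  expect_gt(d[2], d[3])
})

test_that("bootstrap rejects cohorts of fewer than two subjects", {
  coh <- noiseless_cohort(n = 2)
  m <- cohort_ac_matrix(coh, "training")
  expect_error(bootstrap_fit(m[1, , drop = FALSE], coh$schedule),
               "2 subjects")
})
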