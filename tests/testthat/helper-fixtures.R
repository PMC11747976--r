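# shared fixtures built in code at test time

# a trial sequence usable by twostate_simulate without a full schedule
ff_block <- function(n) data.frame(trial_type = rep("FF", n), ff_gain = 1)
ec_block <- function(n) data.frame(trial_type = rep("EC", n), ff_gain = 0)

# canonical 0.10 m / 0.5 s reach and its aligned profiles
std_reach <- function(duration = 0.5) minimum_jerk_velocity(0.10, duration)

std_profiles <- function(duration = 0.5) {
  mv <- std_reach(duration)
  ideal <- align_to_peak_velocity(ideal_force_profile(mv), mv$vy)
  list(mv = mv, ideal = ideal,
       comp = force_profile(-ideal$samples, padded = ideal$padded))
}

# small noiseless cohort for fitting tests
noiseless_cohort <- function(group = "control", n = 2, seed = 5) {
  simulate_cohort(cohort_spec(group, n_subjects = n, ac_noise_sd = 0,
                              seed = seed))
}

training_obs <- function(cohort) {
  cohort$mean_ac[cohort$mean_ac$block == "training", c("trial", "ac")]
}
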