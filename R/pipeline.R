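#' Retention table for a cohort
#'
#' For each subject, averages the adaptation coefficient on the pre-delay
#' error-clamp probes (the EC carrying the 60 s hold in each retention
#' repetition) and on the post-delay probes, and forms the retention
#' delta `pre - post` — the drop in adaptation over the 1 min hold,
#' attributed to decay of the fast process.
#'
#' @param cohort A [simulate_cohort()] or [ingest_external()] result.
#' @return Data frame with columns `subject`, `pre`, `post`, `delta`.
#' @export
cohort_retention_table <- function(cohort) {
  do.call(rbind, lapply(seq_along(cohort$subjects), function(i) {
    a <- cohort$subjects[[i]]$ac
    ret <- a[a$block == "retention", ]
    if (nrow(ret) == 0) stop("no retention-block EC trials", call. = FALSE)
    pre <- ret$ac[ret$delay_after > 0]
    post <- ret$ac[ret$delay_after == 0]
    data.frame(subject = i, pre = mean(pre), post = mean(post),
               delta = retention_delta(mean(pre), mean(post)))
  }))
}

#' Group-mean normalised decay curve
#'
#' Normalises each subject's decay-block AC series to percent of its first
#' decay trial ([normalize_decay()]) and averages across subjects at each
#' decay-trial ordinal.
#'
#' @param cohort A cohort.
#' @return Data frame with columns `x` (0-based decay-trial ordinal) and
#'   `pct` (group-mean percent of first-trial adaptation).
#' @export
cohort_decay_curve <- function(cohort) {
  tabs <- lapply(seq_along(cohort$subjects), function(i) {
    a <- cohort$subjects[[i]]$ac
    dec <- a[a$block == "decay", ]
    data.frame(subject = i, ord = seq_len(nrow(dec)), ac = dec$ac)
  })
  tab <- normalize_decay(do.call(rbind, tabs))
  agg <- stats::aggregate(ac ~ ord, tab, mean)
  data.frame(x = agg$ord - 1L, pct = agg$ac)
}

#' Run configuration
#'
#' Validated configuration for a full generate-measure-fit-report run.
#' Serialisable to and from JSON (`run_config_to_json()`,
#' `run_config_from_json()`), so a run is fully described by one file
#' plus the package version.
#'
#' @param groups Groups to simulate (default all three).
#' @param n_subjects Subjects per group.
#' @param ac_noise_sd Observation noise on the AC scale.
#' @param between_subject_sd Per-parameter SD of subject-level deviations.
#' @param seed Master seed; all randomness derives from it.
#' @param n_boot Bootstrap replicates for the two-state fit.
#' @param lambda Regularisation constant.
#' @return A `run_config` list.
#' @export
run_config <- function(groups = adaptation_groups(), n_subjects = 20,
                       ac_noise_sd = 0.05, between_subject_sd = 0,
                       seed = 1L, n_boot = 2000, lambda = 0.05) {
  for (g in groups) match_group(g)
  stopifnot(n_subjects >= 1, ac_noise_sd >= 0, all(between_subject_sd >= 0),
            n_boot >= 1, lambda >= 0)
  structure(list(groups = groups, n_subjects = as.integer(n_subjects),
                 ac_noise_sd = ac_noise_sd,
                 between_subject_sd = between_subject_sd,
                 seed = as.integer(seed), n_boot = as.integer(n_boot),
                 lambda = lambda),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
run_config_to_json <- function(config) {
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
}

#' @rdname run_config
#' @param json JSON string from `run_config_to_json`.
#' @export
run_config_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  run_config(groups = x$groups, n_subjects = x$n_subjects,
             ac_noise_sd = x$ac_noise_sd,
             between_subject_sd = x$between_subject_sd,
             seed = x$seed, n_boot = x$n_boot, lambda = x$lambda)
}

#' Run the full experiment pipeline
#'
#' For every configured group: simulates the cohort, writes the per-subject
#' AC tables, fits the two-state model with the regularised bootstrap,
#' fits the logistic learning curve on the group-mean training ACs, fits
#' one- and two-phase exponential decay curves to the normalised decay
#' curve with AIC selection, and writes the retention table. A
#' `manifest.json` records the package version, the config (and its MD5
#' hash), and the per-group fast learning rates with the cross-group
#' ordering. Completed groups leave a `.done` marker; re-running with
#' `resume = TRUE` skips them.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param resume Skip groups whose marker file already exists.
#' @return (Invisibly) a summary list with per-group fits and the manifest.
#' @export
run_experiment <- function(config, out_dir, resume = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(run_config_to_json(config), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  summaries <- list()
  for (gi in seq_along(config$groups)) {
    g <- config$groups[gi]
    gdir <- file.path(out_dir, gsub("N$", "n", g))
    marker <- file.path(gdir, ".done")
    if (resume && file.exists(marker)) {
      summaries[[g]] <- jsonlite::fromJSON(file.path(gdir, "summary.json"))
      next
    }
    res <- tryCatch(
      run_group(config, g, config$seed + gi - 1L, gdir),
      error = function(e) {
        stop("stage failed for group ", g, " (completed groups are ",
             "checkpointed; re-run with resume = TRUE): ",
             conditionMessage(e), call. = FALSE)
      })
    jsonlite::write_json(res, file.path(gdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    file.create(marker)
    summaries[[g]] <- res
  }

  bf <- vapply(summaries, function(s) s$theta_lmse$Bf, numeric(1))
  manifest <- list(
    package = "motoradapt",
    version = as.character(utils::packageVersion("motoradapt")),
    config = unclass(config), config_md5 = cfg_hash,
    fast_learning_rates = as.list(bf),
    bf_ordering_decreasing = !is.unsorted(rev(bf), strictly = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(groups = summaries, manifest = manifest))
}

run_group <- function(config, group, group_seed, gdir) {
  spec <- cohort_spec(group, n_subjects = config$n_subjects,
                      between_subject_sd = config$between_subject_sd,
                      ac_noise_sd = config$ac_noise_sd, seed = group_seed)
  cohort <- simulate_cohort(spec)
  write_cohort(cohort, file.path(gdir, "cohort"))
  utils::write.csv(cohort_ac_table(cohort),
                   file.path(gdir, "ac_table.csv"), row.names = FALSE)

  fc <- fit_config(lambda = config$lambda, n_boot = config$n_boot,
                   seed = group_seed)
  boot <- bootstrap_fit(cohort, config = fc)
  write_fit_report(boot, file.path(gdir, "twostate_fit.json"))

  train <- cohort$mean_ac[cohort$mean_ac$block == "training", ]
  logi <- fit_logistic(seq_len(nrow(train)), train$ac)
  jsonlite::write_json(
    list(K = logi$K, A0 = logi$A0, r = logi$r, r2 = logi$r2,
         ci95 = if (!is.null(logi$ci95)) apply(logi$ci95, 2, as.list)),
    file.path(gdir, "logistic.json"), auto_unbox = TRUE, digits = NA)

  dec <- cohort_decay_curve(cohort)
  fits <- list(fit_exponential_decay(dec$x, dec$pct, phases = 1),
               fit_exponential_decay(dec$x, dec$pct, phases = 2))
  sel <- aic_select(fits)
  jsonlite::write_json(
    list(aic_table = sel$table, selected = sel$table$model[sel$best],
         two_phase = fits[[2]][c("A", "b", "C", "d", "b10", "d10", "r2")],
         one_phase = fits[[1]][c("A", "b", "b10", "r2")]),
    file.path(gdir, "decay.json"), auto_unbox = TRUE, digits = NA)

  ret <- cohort_retention_table(cohort)
  utils::write.csv(ret, file.path(gdir, "retention.csv"), row.names = FALSE)

  est <- par_vec(boot$theta_lmse)
  list(group = group, seed = group_seed,
       theta_lmse = list(Af = est[1], As = est[2], Bf = est[3], Bs = est[4]),
       bf_ci95 = as.list(boot$ci95[, "Bf"]),
       logistic = list(K = logi$K, r = logi$r, r2 = logi$r2),
       decay_selected = sel$table$model[sel$best],
       mean_retention_delta = mean(ret$delta))
}

#' Ingest an external cohort directory
#'
#' Reads a directory of per-subject AC tables (the layout written by
#' [write_cohort()]: `subject_*.csv` with columns `subject`, `group`,
#' `block`, `trial_index`, `ac`, plus optional `schedule.csv` and
#' `manifest.json`) into the same cohort structure the synthetic generator
#' produces, so real data follow the identical downstream path. Missing
#' required columns raise a named error; unknown extra columns are dropped
#' with a warning.
#'
#' @param dir Directory path.
#' @return A `cohort` (without hidden ground-truth traces).
#' @export
ingest_external <- function(dir) {
  files <- sort(list.files(dir, pattern = "^subject_.*\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no subject_*.csv files in ", dir,
                               call. = FALSE)
  required <- c("subject", "group", "block", "trial_index", "ac")
  subjects <- lapply(files, function(f) {
    df <- utils::read.csv(f, stringsAsFactors = FALSE)
    missing <- setdiff(required, names(df))
    if (length(missing)) {
      stop("file ", basename(f), ": missing required column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    extra <- setdiff(names(df), c(required, "delay_after"))
    if (length(extra)) {
      warning("file ", basename(f), ": ignoring extra column(s): ",
              paste(extra, collapse = ", "), call. = FALSE)
    }
    if (is.null(df$delay_after)) df$delay_after <- 0
    list(ac = data.frame(trial = df$trial_index, block = df$block,
                         delay_after = df$delay_after, ac = df$ac,
                         stringsAsFactors = FALSE),
         group = df$group[1])
  })
  sched_path <- file.path(dir, "schedule.csv")
  schedule <- if (file.exists(sched_path)) read_schedule_csv(sched_path)
  man_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(man_path)) jsonlite::fromJSON(man_path)
  n_ec <- nrow(subjects[[1]]$ac)
  ac_mat <- vapply(subjects, function(s) s$ac$ac, numeric(n_ec))
  mean_ac <- data.frame(trial = subjects[[1]]$ac$trial,
                        block = subjects[[1]]$ac$block,
                        ac = rowMeans(matrix(ac_mat, nrow = n_ec)),
                        stringsAsFactors = FALSE)
  structure(list(spec = NULL, schedule = schedule, subjects = subjects,
                 mean_ac = mean_ac, manifest = manifest, group =
                   subjects[[1]]$group),
            class = "cohort")
}
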