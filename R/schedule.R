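#' Experimental groups
#'
#' The three noise conditions: a control group reaching against the
#' velocity-dependent curl field alone, and two groups for which a 10 Hz
#' sinusoidal force of 3 N or 7 N amplitude is superimposed during training.
#'
#' @return Character vector of the recognised group labels.
#' @export
adaptation_groups <- function() c("control", "3N", "7N")

#' Noise amplitude for a group
#'
#' @param group One of `"control"`, `"3N"`, `"7N"`.
#' @return Amplitude of the applied 10 Hz noise in newtons (0, 3 or 7).
#' @export
group_noise_amplitude <- function(group) {
  group <- match_group(group)
  c(control = 0, "3N" = 3, "7N" = 7)[[group]]
}

match_group <- function(group) {
  if (length(group) != 1L || !is.character(group) ||
      !group %in% adaptation_groups()) {
    stop("unknown group label: must be one of ",
         paste(adaptation_groups(), collapse = ", "),
         call. = FALSE)
  }
  group
}

block_levels <- function() c("baseline", "training", "retention", "decay")
trial_types <- function() c("null", "noise_only", "FF", "EC")

#' Build a per-group trial schedule
#'
#' Constructs the ordered trial list of the reaching experiment for one
#' group. Block structure:
#' \describe{
#'   \item{baseline}{control: 100 null trials randomly interleaved with
#'     10 error-clamp (EC) trials (110 total); noise groups: 50 noise-only
#'     plus 60 null trials randomly interleaved with 10 EC (120 total).}
#'   \item{training}{100 force-field (FF) trials with 20 EC probes: the
#'     block is 20 consecutive six-trial cells of 5 FF + 1 EC, the EC
#'     position drawn uniformly within each cell (120 total).}
#'   \item{retention}{10 repetitions of (5--7 FF trials, one EC carrying a
#'     60 s hold before the next trial, one post-delay EC probe); the FF
#'     run length is drawn uniformly from \{5, 6, 7\}.}
#'   \item{decay}{80 consecutive EC trials.}
#' }
#' The force field is present exactly on FF trials (`ff_gain = 1`); the
#' applied noise amplitude is attached to FF and noise-only trials of the
#' noise groups and is never applied on EC trials. All analysed reaches are
#' in the 270 degree (toward the body) direction.
#'
#' @param group Group label; one of [adaptation_groups()].
#' @param seed Integer seed controlling the randomised trial positions.
#' @return A `trial_schedule`: a data frame with columns `index`, `block`,
#'   `trial_type`, `ff_gain`, `noise_amplitude`, `delay_after`, `direction`
#'   and attributes `group` and `seed`.
#' @examples
#' sched <- build_trial_schedule("control", seed = 1)
#' table(sched$block)
#' @export
build_trial_schedule <- function(group, seed = 1L) {
  group <- match_group(group)
  seed <- as.integer(seed)
  m <- group_noise_amplitude(group)

  rows <- withr_seed(seed, {
    list(
      baseline  = baseline_block(group, m),
      training  = training_block(m),
      retention = retention_block(m),
      decay     = decay_block()
    )
  })
  sched <- do.call(rbind, rows)
  sched$index <- seq_len(nrow(sched))
  rownames(sched) <- NULL
  sched <- sched[, c("index", "block", "trial_type", "ff_gain",
                     "noise_amplitude", "delay_after", "direction")]
  structure(sched, class = c("trial_schedule", "data.frame"),
            group = group, seed = seed)
}

# evaluate expr under a local RNG seed without disturbing the caller's RNG
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

trial_rows <- function(block, type, noise, delay = 0) {
  n <- length(type)
  data.frame(
    index = NA_integer_,
    block = rep(block, n),
    trial_type = type,
    ff_gain = as.integer(type == "FF"),
    noise_amplitude = ifelse(type %in% c("FF", "noise_only"), noise, 0),
    delay_after = if (length(delay) == 1L) rep(delay, n) else delay,
    direction = rep(270, n),
    stringsAsFactors = FALSE
  )
}

baseline_block <- function(group, m) {
  types <- if (group == "control") {
    c(rep("null", 100), rep("EC", 10))
  } else {
    c(rep("noise_only", 50), rep("null", 60), rep("EC", 10))
  }
  trial_rows("baseline", sample(types), m)
}

training_block <- function(m) {
  # 20 cells of 5 FF + 1 EC; EC slot uniform within each cell
  cells <- lapply(seq_len(20), function(i) {
    cell <- rep("FF", 6)
    cell[sample.int(6, 1)] <- "EC"
    cell
  })
  trial_rows("training", unlist(cells), m)
}

retention_block <- function(m) {
  reps <- lapply(seq_len(10), function(i) {
    n_ff <- sample(5:7, 1)
    type <- c(rep("FF", n_ff), "EC", "EC")
    delay <- c(rep(0, n_ff), 60, 0)  # 1 min hold after the pre-probe EC
    trial_rows("retention", type, m, delay)
  })
  do.call(rbind, reps)
}

decay_block <- function() trial_rows("decay", rep("EC", 80), 0)

#' Error-clamp trial mask
#'
#' Logical mask over the whole schedule that is `TRUE` exactly at the
#' error-clamp trials of the requested block.
#'
#' @param schedule A [build_trial_schedule()] result.
#' @param block One of `"baseline"`, `"training"`, `"retention"`, `"decay"`.
#' @return Logical vector of length `nrow(schedule)`.
#' @export
ec_trial_mask <- function(schedule, block) {
  stopifnot(inherits(schedule, "trial_schedule") || is.data.frame(schedule))
  if (length(block) != 1L || !block %in% block_levels()) {
    stop("unknown block label: ", block, call. = FALSE)
  }
  in_block <- schedule$block == block
  if (!any(in_block)) stop("block '", block, "' is empty", call. = FALSE)
  in_block & schedule$trial_type == "EC"
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat("<trial_schedule> group:", attr(x, "group"),
      " seed:", attr(x, "seed"), " trials:", nrow(x), "\n")
  tab <- table(factor(x$block, levels = block_levels()),
               factor(x$trial_type, levels = trial_types()))
  print(tab)
  invisible(x)
}

#' Write / read a trial schedule as CSV
#'
#' The CSV holds the seven schedule columns; group and seed travel in a
#' `# group=...,seed=...` comment on the first line.
#'
#' @param schedule A `trial_schedule`.
#' @param path File path.
#' @return `write_schedule_csv` returns `path` invisibly;
#'   `read_schedule_csv` returns the reconstructed `trial_schedule`.
#' @export
write_schedule_csv <- function(schedule, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# group=%s,seed=%d", attr(schedule, "group"),
                     attr(schedule, "seed")), con)
  utils::write.csv(as.data.frame(schedule), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- regmatches(header, regexec("group=([^,]+),seed=(-?[0-9]+)", header))[[1]]
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  df <- canonical_schedule_types(df)
  structure(df, class = c("trial_schedule", "data.frame"),
            group = if (length(meta)) meta[2] else NA_character_,
            seed = if (length(meta)) as.integer(meta[3]) else NA_integer_)
}

canonical_schedule_types <- function(df) {
  df$index <- as.integer(df$index)
  df$ff_gain <- as.integer(df$ff_gain)
  for (nm in c("noise_amplitude", "delay_after", "direction")) {
    df[[nm]] <- as.numeric(df[[nm]])
  }
  df
}

#' JSON round-trip for a trial schedule
#'
#' @param schedule A `trial_schedule`.
#' @return `schedule_to_json` returns a JSON string; `schedule_from_json`
#'   its inverse.
#' @export
schedule_to_json <- function(schedule) {
  jsonlite::toJSON(list(group = attr(schedule, "group"),
                        seed = attr(schedule, "seed"),
                        trials = as.data.frame(schedule)),
                   dataframe = "columns", auto_unbox = TRUE, digits = NA)
}

#' @rdname schedule_to_json
#' @param json JSON string produced by `schedule_to_json`.
#' @export
schedule_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  df <- canonical_schedule_types(as.data.frame(obj$trials,
                                               stringsAsFactors = FALSE))
  structure(df, class = c("trial_schedule", "data.frame"),
            group = obj$group, seed = as.integer(obj$seed))
}
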