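#' Construct a ProAL task schedule
#'
#' A schedule for the probabilistic associative learning (ProAL) task is an
#' ordered list of blocks. Within a block the cue--outcome contingency is
#' constant: `p_match` is the probability that the reference association
#' ("high tone is followed by a female face", equivalently "low tone by a
#' male face") holds on a trial.
#'
#' @param lengths Integer vector of block lengths (trials per block).
#' @param p_match Numeric vector, same length, of per-block probabilities
#'   that the reference association holds.
#' @param length_range Length-2 integer vector; every block length must lie
#'   inside this closed interval.
#' @param levels Admissible contingency levels; each `p_match` must equal a
#'   level or its complement (the task is symmetric in the two outcomes).
#'
#' @return An object of class `proal_schedule`: a list with elements
#'   `blocks` (data frame with columns `length`, `p_match`),
#'   `session_length`, `length_range` and `levels`.
#' @export
proal_schedule <- function(lengths, p_match,
                           length_range = c(11L, 17L),
                           levels = c(0.9, 0.7, 0.5)) {
  lengths <- as.integer(lengths)
  stopifnot(length(lengths) == length(p_match), length(lengths) >= 1)
  if (any(lengths < length_range[1]) || any(lengths > length_range[2])) {
    stop_proalhgf("block length outside the configured length range",
                  "proalhgf_invalid_schedule")
  }
  admissible <- sort(unique(c(levels, 1 - levels)))
  if (!all(vapply(p_match, function(p) any(abs(p - admissible) < 1e-12),
                  logical(1)))) {
    stop_proalhgf("p_match outside the configured contingency levels",
                  "proalhgf_invalid_schedule")
  }
  structure(
    list(blocks = data.frame(length = lengths, p_match = p_match),
         session_length = sum(lengths),
         length_range = as.integer(length_range),
         levels = levels),
    class = "proal_schedule")
}

#' The canonical 150-trial ProAL schedule
#'
#' The fixed default session: 150 trials in 10 blocks with lengths between
#' 11 and 17 trials and contingencies drawn from 90/10, 70/30 and 50/50.
#' The exact per-block sequence is a package default chosen to span both
#' extreme block lengths and all three contingency levels together with
#' their complements.
#'
#' @return A [proal_schedule()] with 10 blocks summing to 150 trials.
#' @export
#' @examples
#' sched <- canonical_schedule()
#' sched$session_length # 150
canonical_schedule <- function() {
  proal_schedule(
    lengths = c(15L, 16L, 11L, 17L, 14L, 16L, 15L, 13L, 17L, 16L),
    p_match = c(0.5, 0.9, 0.1, 0.7, 0.3, 0.9, 0.5, 0.1, 0.7, 0.5))
}

#' Sample a randomised ProAL schedule
#'
#' Draws a random composition of `session_length` trials into `n_blocks`
#' blocks whose lengths lie in `length_range`, and assigns each block a
#' contingency sampled uniformly from the levels and their complements.
#'
#' @param seed Integer seed; identical seeds give identical schedules.
#' @param n_blocks Number of blocks.
#' @param length_range Closed interval of admissible block lengths.
#' @param levels Contingency levels (complements are added automatically).
#' @param session_length Total number of trials.
#'
#' @return A [proal_schedule()].
#' @export
sample_schedule <- function(seed, n_blocks = 10L,
                            length_range = c(11L, 17L),
                            levels = c(0.9, 0.7, 0.5),
                            session_length = 150L) {
  lo <- length_range[1]; hi <- length_range[2]
  if (session_length < n_blocks * lo || session_length > n_blocks * hi) {
    stop_proalhgf(
      sprintf(paste0("no composition of %d trials into %d blocks with ",
                     "lengths in [%d, %d] exists"),
              session_length, n_blocks, lo, hi),
      "proalhgf_infeasible_schedule")
  }
  with_seed(seed, {
    lengths <- integer(n_blocks)
    remaining <- session_length
    for (i in seq_len(n_blocks)) {
      k <- n_blocks - i # blocks still to fill after this one
      l_min <- max(lo, remaining - k * hi)
      l_max <- min(hi, remaining - k * lo)
      lengths[i] <- if (l_min == l_max) l_min else
        sample(seq.int(l_min, l_max), 1L)
      remaining <- remaining - lengths[i]
    }
    p <- sample(sort(unique(c(levels, 1 - levels))), n_blocks,
                replace = TRUE)
    proal_schedule(lengths, p, length_range = length_range,
                   levels = levels)
  })
}

# Match indicator: 1 iff the (cue, outcome) pair realises the reference
# association high_tone -> female / low_tone -> male.
match_indicator <- function(cue, outcome) {
  as.integer((cue == "high_tone" & outcome == "female") |
               (cue == "low_tone" & outcome == "male"))
}

#' Generate the trial sequence of a ProAL session
#'
#' Cues are drawn as fair coins; the outcome is then drawn so that the
#' reference association holds with the block's `p_match`. The binary input
#' `u` fed to the learning models is the match indicator, which is a
#' deterministic function of cue and outcome.
#'
#' @param schedule A [proal_schedule()].
#' @param seed Integer seed.
#' @return A data frame with one row per trial and columns `trial`, `block`,
#'   `cue`, `outcome`, `u`, `response` (all `NA`: no responses yet) and
#'   `correct` (all `NA`).
#' @export
generate_trials <- function(schedule, seed = NULL) {
  stopifnot(inherits(schedule, "proal_schedule"))
  n <- schedule$session_length
  block <- rep(seq_len(nrow(schedule$blocks)), schedule$blocks$length)
  p_match <- schedule$blocks$p_match[block]
  with_seed(seed, {
    cue <- ifelse(runif(n) < 0.5, "high_tone", "low_tone")
    u <- rbinom(n, 1L, p_match)
    outcome <- ifelse(
      u == 1L,
      ifelse(cue == "high_tone", "female", "male"),
      ifelse(cue == "high_tone", "male", "female"))
    data.frame(trial = seq_len(n), block = block, cue = cue,
               outcome = outcome, u = match_indicator(cue, outcome),
               response = NA_character_, correct = NA,
               stringsAsFactors = FALSE)
  })
}

#' Score the responses of a ProAL session
#'
#' @param trials Trial data frame with a `response` column (`NA` marks a
#'   missing response).
#' @return A list with `accuracy` (percent correct among non-missing trials)
#'   and `n_missing`.
#' @export
score_responses <- function(trials) {
  missing <- is.na(trials$response)
  if (all(missing)) {
    stop_proalhgf("all responses missing; accuracy undefined",
                  "proalhgf_all_missing")
  }
  correct <- trials$response[!missing] == trials$outcome[!missing]
  list(accuracy = 100 * mean(correct), n_missing = sum(missing))
}

#' Read and write trial tables
#'
#' Trial tables are interchanged as comma-separated text with the header
#' `subject_id, trial, block, cue, outcome, u, response`; a missing response
#' is an empty field.
#'
#' @param trials Trial data frame (optionally with a `subject_id` column).
#' @param path File path.
#' @param subject_id Subject identifier used when `trials` lacks the column.
#' @return `write_trials()` returns `path` invisibly; `read_trials()`
#'   returns the trial data frame with a recomputed `correct` column.
#' @export
write_trials <- function(trials, path, subject_id = "S01") {
  if (is.null(trials$subject_id)) trials$subject_id <- subject_id
  out <- trials[, c("subject_id", "trial", "block", "cue", "outcome",
                    "u", "response")]
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(response = "character"))
  df$response[!is.na(df$response) & df$response == ""] <- NA_character_
  df$correct <- ifelse(is.na(df$response), NA, df$response == df$outcome)
  df
}

#' Read and write schedules
#'
#' Schedules are serialised as comma-separated length/p_match pairs.
#'
#' @param schedule A [proal_schedule()].
#' @param path File path.
#' @export
write_schedule <- function(schedule, path) {
  write.csv(schedule$blocks, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path, length_range = c(11L, 17L),
                          levels = c(0.9, 0.7, 0.5)) {
  df <- read.csv(path)
  proal_schedule(df$length, df$p_match, length_range = length_range,
                 levels = levels)
}

#' @export
print.proal_schedule <- function(x, ...) {
  cat(sprintf("ProAL schedule: %d trials in %d blocks\n",
              x$session_length, nrow(x$blocks)))
  print(x$blocks)
  invisible(x)
}
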