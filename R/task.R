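#' Task environment configuration
#'
#' Describes the iterated investment task: a participant repeatedly chooses
#' how much of $10 to invest with one of several stimuli (social partners or
#' slot-machine bandits).  The investment is multiplied (by 4) and the
#' stimulus returns a pre-scheduled fraction of the multiplied amount, so a
#' return rate above 0.25 yields a net gain and below 0.25 a net loss.
#'
#' Each stimulus is assigned one reward condition.  The default return-rate
#' table gives the `high` stimulus rates that always exceed 0.25 (always a
#' net gain), the `low` stimulus rates always below 0.25 (always a net
#' loss), a near-break-even `neutral` stimulus, and a high-variance `random`
#' stimulus spanning the full 0--0.5 range with mean 0.25.
#'
#' @param n_stimuli number of stimuli (partners/bandits) per task.
#' @param trials_per_stimulus trials played with each stimulus.
#' @param investment_options permitted investments in dollars, strictly
#'   increasing, starting at 0.
#' @param multiplier factor applied to the investment before the return
#'   fraction is taken.
#' @param conditions condition label assigned to each stimulus, in stimulus
#'   order; must name entries of `return_rate_table`.
#' @param return_rate_table named list of per-condition return-rate vectors,
#'   each of length `trials_per_stimulus`, all rates in `[0, 0.5]`.
#' @param max_gap largest allowed spacing (in trials) between consecutive
#'   presentations of the same stimulus.
#'
#' @return An object of class `ca_task_config`.
#' @examples
#' cfg <- task_config()
#' range(cfg$return_rate_table$high)
#' @export
task_config <- function(n_stimuli = 4,
                        trials_per_stimulus = 15,
                        investment_options = c(0, 2.5, 5, 7.5, 10),
                        multiplier = 4,
                        conditions = c("high", "low", "neutral", "random"),
                        return_rate_table = NULL,
                        max_gap = 15) {
  if (is.null(return_rate_table))
    return_rate_table <- default_return_rates(trials_per_stimulus)
  cfg <- structure(
    list(n_stimuli = as.integer(n_stimuli),
         trials_per_stimulus = as.integer(trials_per_stimulus),
         investment_options = as.numeric(investment_options),
         multiplier = multiplier,
         conditions = conditions,
         return_rate_table = return_rate_table,
         max_gap = as.integer(max_gap)),
    class = "ca_task_config")
  validate_task_config(cfg)
  cfg
}

#' @rdname task_config
#' @param n number of trials per stimulus for the default rate lists.
#' @export
default_return_rates <- function(n = 15) {
  list(high    = seq(0.30, 0.50, length.out = n),
       low     = seq(0.00, 0.20, length.out = n),
       neutral = seq(0.22, 0.28, length.out = n),
       random  = seq(0.00, 0.50, length.out = n))
}

validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "ca_task_config"))
  inv <- cfg$investment_options
  if (length(inv) < 2 || any(diff(inv) <= 0))
    stop("investment_options must be strictly increasing")
  if (inv[1] != 0) stop("investment_options must start at 0")
  if (cfg$n_stimuli < 1) stop("need at least one stimulus")
  if (length(cfg$conditions) != cfg$n_stimuli)
    stop("conditions must have one label per stimulus")
  missing_cond <- setdiff(cfg$conditions, names(cfg$return_rate_table))
  if (length(missing_cond))
    stop("no return rates for condition(s): ",
         paste(missing_cond, collapse = ", "))
  for (cond in names(cfg$return_rate_table)) {
    r <- cfg$return_rate_table[[cond]]
    if (length(r) != cfg$trials_per_stimulus)
      stop(sprintf("return rate list for '%s' has length %d, expected %d",
                   cond, length(r), cfg$trials_per_stimulus))
    if (any(r < 0 | r > 0.5))
      stop(sprintf("return rates for '%s' must lie in [0, 0.5]", cond))
  }
  if (cfg$max_gap < cfg$n_stimuli)
    stop("max_gap < n_stimuli makes interleaving infeasible")
  invisible(cfg)
}

#' Pre-scheduled return rates for every stimulus
#'
#' Every simulated participant experiences the same multiset of return rates
#' per stimulus (the condition's preselected list); only the within-stimulus
#' ordering is randomized by the seed.
#'
#' @param config a [task_config()].
#' @param seed integer seed; `NULL` draws from the ambient RNG stream.
#' @return A list with one element per stimulus: `stimulus_id`, `condition`,
#'   and the shuffled `rates` vector.
#' @export
make_reward_schedule <- function(config = task_config(), seed = NULL) {
  validate_task_config(config)
  with_seed(seed, {
    lapply(seq_len(config$n_stimuli), function(s) {
      cond <- config$conditions[s]
      rates <- config$return_rate_table[[cond]]
      list(stimulus_id = s, condition = cond,
           rates = sample(rates, length(rates)))
    })
  })
}

#' Interleaved stimulus ordering
#'
#' Randomly interleaves the stimuli so that consecutive presentations of the
#' same stimulus are 1 to `max_gap` trials apart.  Orderings are drawn as
#' unconstrained random shuffles and rejected until the gap bound holds,
#' which yields a right-skewed (truncated, geometric-like) gap distribution
#' with most gaps in the 1--5 range.
#'
#' @inheritParams make_reward_schedule
#' @param max_attempts rejection-sampling budget before giving up.
#' @return Integer vector of stimulus ids, length
#'   `n_stimuli * trials_per_stimulus`.
#' @export
interleave_trials <- function(config = task_config(), seed = NULL,
                              max_attempts = 10000) {
  validate_task_config(config)
  base <- rep(seq_len(config$n_stimuli), each = config$trials_per_stimulus)
  with_seed(seed, {
    for (i in seq_len(max_attempts)) {
      ord <- sample(base, length(base))
      ok <- TRUE
      for (s in seq_len(config$n_stimuli)) {
        gaps <- diff(which(ord == s))
        if (length(gaps) && max(gaps) > config$max_gap) { ok <- FALSE; break }
      }
      if (ok) return(ord)
    }
    stop("could not find an ordering satisfying max_gap = ", config$max_gap)
  })
}

#' Outcome valence of a trial
#'
#' Gain if more was returned than invested, loss if less, neutral if equal
#' (break-even trials are excluded from gain/loss splits downstream).
#'
#' @param investment,returned dollar amounts.
#' @return Character vector in `{"gain", "loss", "neutral"}`.
#' @export
trial_valence <- function(investment, returned) {
  out <- ifelse(returned > investment, "gain",
                ifelse(returned < investment, "loss", "neutral"))
  out
}

behavior_columns <- c("participant_id", "task", "trial_index", "stimulus_id",
                      "condition", "investment", "returned", "missed")

#' Validate a behavioral table
#'
#' Checks the column schema and per-row invariants (investments drawn from
#' the configured options, returns within `[0, multiplier/2 * investment]`,
#' missed trials with zero investment, contiguous trial indices per task).
#' Invalid rows are reported by row number.
#'
#' @param data behavioral data.frame (see [read_behavior()] for the schema).
#' @param config a [task_config()].
#' @return The data, invisibly, with a `valence` column added.
#' @export
validate_behavior <- function(data, config = task_config()) {
  missing_cols <- setdiff(behavior_columns, names(data))
  if (length(missing_cols))
    stop("missing behavioral columns: ", paste(missing_cols, collapse = ", "))
  bad_inv <- which(!vapply(data$investment, function(x)
    any(abs(x - config$investment_options) < 1e-8), logical(1)))
  if (length(bad_inv))
    stop("investment not in investment_options at row(s): ",
         paste(utils::head(bad_inv, 10), collapse = ", "))
  max_ret <- config$multiplier * 0.5 * data$investment
  bad_ret <- which(data$returned < -1e-8 | data$returned > max_ret + 1e-8)
  if (length(bad_ret))
    stop("returned amount outside [0, ", config$multiplier * 0.5,
         " x investment] at row(s): ",
         paste(utils::head(bad_ret, 10), collapse = ", "))
  bad_miss <- which(data$missed & data$investment != 0)
  if (length(bad_miss))
    stop("missed trials must have investment 0 at row(s): ",
         paste(utils::head(bad_miss, 10), collapse = ", "))
  for (pt in split(data, list(data$participant_id, data$task), drop = TRUE)) {
    idx <- sort(pt$trial_index)
    if (!identical(as.integer(idx), seq_along(idx)))
      stop("trial_index not contiguous from 1 for participant ",
           pt$participant_id[1], ", task ", pt$task[1])
  }
  data$valence <- trial_valence(data$investment, data$returned)
  invisible(data)
}

#' Read and write behavioral tables
#'
#' Plain CSV (or TSV for `.tsv` paths) with columns `participant_id, task,
#' trial_index, stimulus_id, condition, investment, returned, missed`.
#' Reading validates the table against the configuration and derives the
#' `valence` column; writing drops derived columns so that a write/read
#' cycle is an identity.
#'
#' @param path file path; a `.tsv` extension selects tab separation.
#' @param config a [task_config()] used for validation.
#' @return `read_behavior()` returns the validated data.frame.
#' @export
read_behavior <- function(path, config = task_config()) {
  tsv <- grepl("\\.tsv$", path, ignore.case = TRUE)
  data <- if (tsv) utils::read.delim(path, stringsAsFactors = FALSE)
          else utils::read.csv(path, stringsAsFactors = FALSE)
  data$missed <- as.logical(data$missed)
  validate_behavior(data, config)
  data$valence <- trial_valence(data$investment, data$returned)
  data
}

#' @rdname read_behavior
#' @param data behavioral data.frame.
#' @export
write_behavior <- function(data, path) {
  missing_cols <- setdiff(behavior_columns, names(data))
  if (length(missing_cols))
    stop("missing behavioral columns: ", paste(missing_cols, collapse = ", "))
  out <- data[, behavior_columns]
  tsv <- grepl("\\.tsv$", path, ignore.case = TRUE)
  if (tsv) utils::write.table(out, path, sep = "\t", row.names = FALSE,
                              quote = FALSE)
  else utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
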