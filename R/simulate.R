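#' Simulate an agent playing the investment task
#'
#' Draws a reward schedule and interleaved stimulus ordering (unless
#' supplied), then plays the task under the given model and parameters:
#' on each trial the investment is sampled from the Gaussian choice
#' probabilities around the sigmoid-predicted investment, the return is the
#' scheduled fraction of the multiplied investment (rounded to whole
#' cents), and values update per the model variant.
#'
#' @param model model name or [ca_model()] spec.
#' @param params named vector of the model's free parameters.
#' @param config a [task_config()].
#' @param seed integer seed (`NULL` = ambient RNG stream).
#' @param participant_id,task identifiers stored in the output table.
#' @param schedule optional [make_reward_schedule()] result.
#' @param ordering optional [interleave_trials()] result.
#' @param miss_rate probability a trial is missed (investment forced to 0,
#'   no return, no value update).
#' @return Behavioral data.frame (see [read_behavior()] for the schema, plus
#'   `valence`), with the generating parameters in `attr(, "true_params")`.
#' @examples
#' d <- simulate_agent("baseline",
#'                     c(lr = 0.4, prior = 5, m = 1, bias = 5), seed = 1)
#' head(d)
#' @export
simulate_agent <- function(model, params, config = task_config(),
                           seed = NULL, participant_id = "sim1",
                           task = "social", schedule = NULL, ordering = NULL,
                           miss_rate = 0) {
  spec <- if (inherits(model, "ca_model_spec")) model else ca_model(model)
  validate_task_config(config)
  full <- expand_params(spec, params)
  with_seed(seed, {
    if (is.null(schedule)) schedule <- make_reward_schedule(config)
    if (is.null(ordering)) ordering <- interleave_trials(config)
    n_trials <- length(ordering)
    opt <- config$investment_options
    max_inv <- max(opt)
    v <- rep(full[["prior"]], config$n_stimuli)
    occ <- integer(config$n_stimuli)
    investment <- returned <- numeric(n_trials)
    missed <- logical(n_trials)
    for (t in seq_len(n_trials)) {
      s <- ordering[t]
      occ[s] <- occ[s] + 1L
      rate <- schedule[[s]]$rates[occ[s]]
      if (miss_rate > 0 && runif(1) < miss_rate) {
        investment[t] <- 0; returned[t] <- 0; missed[t] <- TRUE
        next
      }
      pred <- predict_investment(v[s], full[["m"]], full[["bias"]], max_inv)
      p <- choice_probabilities(pred, opt)
      inv <- opt[sample.int(length(opt), 1, prob = p)]
      ret <- round(config$multiplier * inv * rate, 2)
      delta <- ret - v[s]
      lr <- if (delta >= 0) full[["lr_pos"]] else full[["lr_neg"]]
      if (spec$update == "ca_decay") {
        v <- update_values_decay(v, s, delta, lr, full[["decay"]],
                                 full[["prior"]])
      } else {
        ca <- if (delta >= 0) full[["ca_pos"]] else full[["ca_neg"]]
        v <- update_values_ca(v, s, delta, lr, ca)
      }
      investment[t] <- inv; returned[t] <- ret
    }
    out <- data.frame(
      participant_id = participant_id, task = task,
      trial_index = seq_len(n_trials), stimulus_id = ordering,
      condition = vapply(schedule, `[[`, "", "condition")[ordering],
      investment = investment, returned = returned, missed = missed,
      valence = trial_valence(investment, returned),
      stringsAsFactors = FALSE)
    attr(out, "true_params") <- params
    out
  })
}

#' Default parameter sampler for simulation studies
#'
#' Uniform draws over behaviorally meaningful ranges: learning rates in
#' `[0.05, 1]` (a rate of ~0 produces a non-learner with no identifiable
#' dynamics), credit-assignment and decay fractions over their full
#' `[0, 1]` range, `prior` and `bias` on the investable `[0, 10]` dollar
#' scale, and sigmoid slope `m` in `[0.2, 3]` (below ~0.2 the policy is
#' essentially flat on a $10 value scale).
#'
#' @param model model name or spec.
#' @return A function of no arguments returning one named parameter draw.
#' @export
default_param_sampler <- function(model) {
  spec <- if (inherits(model, "ca_model_spec")) model else ca_model(model)
  ranges <- list(lr = c(0.05, 1), lr_pos = c(0.05, 1), lr_neg = c(0.05, 1),
                 ca = c(0, 1), ca_pos = c(0, 1), ca_neg = c(0, 1),
                 decay = c(0, 1), prior = c(0, 10), m = c(0.2, 3),
                 bias = c(0, 10))
  function() {
    vapply(spec$free, function(nm) {
      r <- ranges[[nm]]
      runif(1, r[1], r[2])
    }, numeric(1))
  }
}

#' Simulate a cohort of agents
#'
#' Generates `n_participants` agents with parameters drawn from `sampler`,
#' each playing every task in `tasks` (fresh schedule ordering per task).
#' Fully reproducible from the seed; generating parameters are retained for
#' recovery studies.
#'
#' @param n_participants cohort size (the emulated study uses 28).
#' @param model model name or spec used to generate behavior.
#' @param config a [task_config()].
#' @param sampler function returning one named parameter draw; defaults to
#'   [default_param_sampler()].
#' @param tasks character vector of task labels.
#' @param seed integer seed.
#' @return An object of class `ca_cohort`: list with `behavior` (stacked
#'   behavioral table) and `true_params` (one row per participant).
#' @export
generate_cohort <- function(n_participants = 28, model = "vlr_vca",
                            config = task_config(), sampler = NULL,
                            tasks = c("social", "bandit"), seed = 1) {
  spec <- if (inherits(model, "ca_model_spec")) model else ca_model(model)
  if (is.null(sampler)) sampler <- default_param_sampler(spec)
  with_seed(seed, {
    params <- vector("list", n_participants)
    behav <- vector("list", n_participants * length(tasks))
    k <- 0
    for (i in seq_len(n_participants)) {
      params[[i]] <- sampler()
      for (tk in tasks) {
        k <- k + 1
        behav[[k]] <- simulate_agent(spec, params[[i]], config,
                                     participant_id = sprintf("p%02d", i),
                                     task = tk)
      }
    }
    true_params <- do.call(rbind, lapply(params, function(p)
      as.data.frame(as.list(p))))
    true_params$participant_id <- sprintf("p%02d", seq_len(n_participants))
    structure(list(behavior = do.call(rbind, behav),
                   true_params = true_params,
                   model = spec$name, tasks = tasks, seed = seed),
              class = "ca_cohort")
  })
}

#' @export
print.ca_cohort <- function(x, ...) {
  cat(sprintf("<ca_cohort> %d participants x %d task(s), model %s\n",
              nrow(x$true_params), length(x$tasks), x$model))
  invisible(x)
}
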