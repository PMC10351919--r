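#' The credit-assignment model family
#'
#' Four nested Rescorla-Wagner variants for continuous investment choices.
#' All share the sigmoid investment readout and Gaussian choice density
#' (see [predict_investment()] and [choice_probabilities()]); they differ in
#' how the prediction error updates the trial-by-stimulus value matrix V:
#'
#' * `baseline` -- single learning rate, full credit to the engaged
#'   stimulus (standard Rescorla-Wagner); free parameters `lr, prior, m,
#'   bias` (4).
#' * `vlr_ca` -- valenced learning rates (`lr_pos` on positive, `lr_neg` on
#'   negative prediction errors) plus one credit-assignment parameter `ca`
#'   governing how much of each update spreads to the other stimuli; free
#'   parameters `lr_pos, lr_neg, ca, prior, m, bias` (6).
#' * `vlr_vca` -- as `vlr_ca` with separate `ca_pos`/`ca_neg` for positive
#'   vs negative prediction errors (7 parameters).
#' * `vlr_decay` -- valenced learning rates with full credit to the engaged
#'   stimulus while unengaged stimulus values decay back toward the prior at
#'   rate `decay` (6 parameters).
#'
#' @param name one of `"baseline"`, `"vlr_ca"`, `"vlr_vca"`, `"vlr_decay"`.
#' @return `ca_model()` returns an object of class `ca_model_spec` with the
#'   model name, free-parameter names, parameter count `k`, and update type.
#' @examples
#' ca_model("vlr_vca")$k
#' @export
ca_model <- function(name = c("baseline", "vlr_ca", "vlr_vca", "vlr_decay")) {
  name <- match.arg(name)
  registry <- list(
    baseline  = list(free = c("lr", "prior", "m", "bias"), update = "ca"),
    vlr_ca    = list(free = c("lr_pos", "lr_neg", "ca", "prior", "m", "bias"),
                     update = "ca"),
    vlr_vca   = list(free = c("lr_pos", "lr_neg", "ca_pos", "ca_neg",
                              "prior", "m", "bias"), update = "ca"),
    vlr_decay = list(free = c("lr_pos", "lr_neg", "decay", "prior", "m",
                              "bias"), update = "ca_decay"))
  entry <- registry[[name]]
  structure(list(name = name, free = entry$free, k = length(entry$free),
                 update = entry$update),
            class = "ca_model_spec")
}

#' @rdname ca_model
#' @export
ca_model_names <- function() c("baseline", "vlr_ca", "vlr_vca", "vlr_decay")

#' @export
print.ca_model_spec <- function(x, ...) {
  cat(sprintf("<ca_model_spec> %s (%d free parameters)\n", x$name, x$k))
  cat("  free:", paste(x$free, collapse = ", "), "\n")
  invisible(x)
}

#' Parameter bounds for fitting and sampling
#'
#' Learning rates, credit-assignment fractions and decay rates are defined
#' on `[0, 1]`.  Dollar-scale quantities (`prior`, `bias`) are bounded by
#' the maximum possible return ($20 with the default task); the sigmoid
#' slope `m` is kept positive and below 5 (already a near-step policy on a
#' $10 scale).
#'
#' @return Named list with `lower` and `upper` named vectors covering every
#'   parameter name used by the model family.
#' @export
ca_bounds <- function() {
  lower <- c(lr = 0, lr_pos = 0, lr_neg = 0, ca = 0, ca_pos = 0, ca_neg = 0,
             decay = 0, prior = 0, m = 0.01, bias = 0)
  upper <- c(lr = 1, lr_pos = 1, lr_neg = 1, ca = 1, ca_pos = 1, ca_neg = 1,
             decay = 1, prior = 20, m = 5, bias = 20)
  list(lower = lower, upper = upper)
}

# Map a model's free parameters onto the full 8-slot vector used by the
# C++ likelihood: lr_pos, lr_neg, ca_pos, ca_neg, decay, prior, m, bias.
# The baseline uses a single lr and CA = 1; vlr_ca ties ca_pos = ca_neg;
# vlr_decay performs the full-credit update (CA = 1) plus decay-to-prior.
expand_params <- function(spec, params) {
  params <- unlist(params)
  missing_par <- setdiff(spec$free, names(params))
  if (length(missing_par))
    stop("missing parameter(s) for model '", spec$name, "': ",
         paste(missing_par, collapse = ", "))
  p <- params[spec$free]
  full <- c(lr_pos = NA_real_, lr_neg = NA_real_, ca_pos = 1, ca_neg = 1,
            decay = 0, prior = 0, m = NA_real_, bias = NA_real_)
  if (spec$name == "baseline") {
    full["lr_pos"] <- full["lr_neg"] <- p["lr"]
  } else {
    full["lr_pos"] <- p["lr_pos"]; full["lr_neg"] <- p["lr_neg"]
  }
  if (spec$name == "vlr_ca") full["ca_pos"] <- full["ca_neg"] <- p["ca"]
  if (spec$name == "vlr_vca") {
    full["ca_pos"] <- p["ca_pos"]; full["ca_neg"] <- p["ca_neg"]
  }
  if (spec$name == "vlr_decay") full["decay"] <- p["decay"]
  full["prior"] <- p["prior"]; full["m"] <- p["m"]; full["bias"] <- p["bias"]
  full
}

#' Sigmoid investment readout
#'
#' Maps an expected value onto a predicted investment:
#' `max_investment / (1 + exp(-m * (v - bias)))`.  Strictly increasing in
#' `v`, equal to half the maximum at `v = bias`, saturating at 0 and
#' `max_investment`.
#'
#' @param v expected value(s), dollar scale.
#' @param m positive slope.
#' @param bias value at which the predicted investment is half-maximal.
#' @param max_investment largest investable amount.
#' @return Predicted investment(s) in `(0, max_investment)`.
#' @export
predict_investment <- function(v, m, bias, max_investment = 10) {
  stopifnot(m > 0)
  max_investment / (1 + exp(-m * (v - bias)))
}

#' Gaussian choice probabilities over the discrete options
#'
#' Probability of each investment option given a predicted investment:
#' unnormalized Gaussian density `exp(-(option - pred)^2 / (2 sigma^2))`,
#' renormalized to sum to one across the options on every trial.
#'
#' @param pred predicted investment (scalar).
#' @param options investment options.
#' @param sigma density width, fixed to 1 in all fitted models.
#' @return Probability vector summing to 1.
#' @export
choice_probabilities <- function(pred, options, sigma = 1) {
  stopifnot(length(pred) == 1, length(options) >= 1, sigma > 0)
  w <- exp(-(options - pred)^2 / (2 * sigma^2))
  w / sum(w)
}

#' Reward prediction error
#'
#' @param reward received return, dollars.
#' @param v_prev expected value of the engaged stimulus before the outcome.
#' @return `reward - v_prev`.
#' @export
prediction_error <- function(reward, v_prev) reward - v_prev

#' Value updates: credit-assignment spreading and decay
#'
#' `update_values_ca()` applies the credit-assignment rule: the engaged
#' stimulus `j` receives `lr * delta * ca` while each of the `n - 1` other
#' stimuli receives `lr * delta * (1 - ca) / (n - 1)`.  At `ca = 1` this is
#' the standard Rescorla-Wagner update; at `ca = 0` the whole update spreads
#' to the irrelevant stimuli.  `update_values_decay()` gives the engaged
#' stimulus the full `lr * delta` and relaxes every other value toward the
#' prior by fraction `decay`.
#'
#' @param v current value vector (one entry per stimulus).
#' @param j index of the engaged stimulus.
#' @param delta prediction error.
#' @param lr learning rate.
#' @param ca credit-assignment fraction in `[0, 1]`.
#' @param decay decay rate in `[0, 1]`.
#' @param prior value toward which unengaged stimuli decay.
#' @return Updated value vector.
#' @export
update_values_ca <- function(v, j, delta, lr, ca) {
  n <- length(v)
  stopifnot(j >= 1, j <= n)
  if (n < 2) {
    if (ca < 1) stop("credit spreading needs at least 2 stimuli")
    v[j] <- v[j] + lr * delta
    return(v)
  }
  out <- v + lr * delta * (1 - ca) / (n - 1)
  out[j] <- v[j] + lr * delta * ca
  out
}

#' @rdname update_values_ca
#' @export
update_values_decay <- function(v, j, delta, lr, decay, prior) {
  out <- v + decay * (prior - v)
  out[j] <- v[j] + lr * delta
  out
}

# Order and validate one participant-task slice for the likelihood.
prep_trials <- function(data, config) {
  if (length(unique(data$participant_id)) != 1)
    stop("expected data from a single participant")
  if (length(unique(data$task)) != 1)
    stop("expected data from a single task")
  data <- data[order(data$trial_index), , drop = FALSE]
  opt <- config$investment_options
  idx <- vapply(data$investment, function(x) {
    m <- which(abs(x - opt) < 1e-8)
    if (!length(m)) NA_integer_ else m[1]
  }, integer(1))
  if (anyNA(idx))
    stop("investment not in investment_options at trial(s): ",
         paste(data$trial_index[is.na(idx)], collapse = ", "))
  list(stim = as.integer(data$stimulus_id), choice_idx = as.integer(idx),
       reward = as.numeric(data$returned), missed = as.logical(data$missed),
       data = data)
}

#' Negative log-likelihood of observed investments
#'
#' Runs the full trial loop for one participant-task: values start at the
#' prior, each non-missed trial contributes `-log p(observed investment)`
#' under the sigmoid + Gaussian choice rule, and the variant's update rule
#' is applied to the value vector.  Missed trials contribute no likelihood
#' and trigger no update.  Probabilities are floored at 1e-12 before the
#' log.
#'
#' @param data behavioral data for one participant and one task.
#' @param model model name or `ca_model_spec`.
#' @param params named vector/list of the model's free parameters.
#' @param config a [task_config()].
#' @return `negative_log_likelihood()` returns the scalar NLL;
#'   `ca_trajectory()` additionally returns the `(trials + 1) x n_stimuli`
#'   value matrix `V` (row 1 = prior), the per-trial prediction errors
#'   `delta`, predicted investments `pred`, and observed-choice
#'   probabilities `p_obs` (all `NA` on missed trials).
#' @export
negative_log_likelihood <- function(data, model, params,
                                    config = task_config()) {
  spec <- if (inherits(model, "ca_model_spec")) model else ca_model(model)
  pr <- prep_trials(data, config)
  full <- expand_params(spec, params)
  .ca_nll_cpp(pr$stim, pr$choice_idx, pr$reward, pr$missed,
              config$investment_options, config$n_stimuli, full,
              as.integer(spec$update == "ca_decay"),
              max(config$investment_options), 1.0)
}

#' @rdname negative_log_likelihood
#' @export
ca_trajectory <- function(data, model, params, config = task_config()) {
  spec <- if (inherits(model, "ca_model_spec")) model else ca_model(model)
  pr <- prep_trials(data, config)
  full <- expand_params(spec, params)
  out <- .ca_trace_cpp(pr$stim, pr$choice_idx, pr$reward, pr$missed,
                       config$investment_options, config$n_stimuli, full,
                       as.integer(spec$update == "ca_decay"),
                       max(config$investment_options), 1.0)
  colnames(out$V) <- paste0("stimulus_", seq_len(config$n_stimuli))
  out$trial_index <- pr$data$trial_index
  out
}
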