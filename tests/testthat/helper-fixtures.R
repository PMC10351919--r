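# Shared fixtures and independent reference implementations used as
# oracles.  Everything is generated in code; nothing is read from disk.

demo_params <- list(
  baseline  = c(lr = 0.4, prior = 5, m = 1, bias = 5),
  vlr_ca    = c(lr_pos = 0.6, lr_neg = 0.3, ca = 0.8, prior = 5, m = 1,
                bias = 5),
  vlr_vca   = c(lr_pos = 0.6, lr_neg = 0.3, ca_pos = 0.9, ca_neg = 0.5,
                prior = 5, m = 1, bias = 5),
  vlr_decay = c(lr_pos = 0.6, lr_neg = 0.3, decay = 0.2, prior = 5, m = 1,
                bias = 5))

# Straight-line R reference for the likelihood/trajectory, written from
# the exported building blocks; independent of the C++ trial loop.
ref_nll <- function(data, model, params, config = task_config()) {
  spec <- ca_model(model)
  full <- credassign:::expand_params(spec, params)
  data <- data[order(data$trial_index), ]
  opt <- config$investment_options
  v <- rep(full[["prior"]], config$n_stimuli)
  nll <- 0
  V <- matrix(NA_real_, nrow(data) + 1, config$n_stimuli)
  V[1, ] <- v
  for (t in seq_len(nrow(data))) {
    j <- data$stimulus_id[t]
    if (!data$missed[t]) {
      pred <- predict_investment(v[j], full[["m"]], full[["bias"]], max(opt))
      p <- choice_probabilities(pred, opt)[which(
        abs(opt - data$investment[t]) < 1e-8)]
      nll <- nll - log(max(p, 1e-12))
      delta <- prediction_error(data$returned[t], v[j])
      lr <- if (delta >= 0) full[["lr_pos"]] else full[["lr_neg"]]
      if (spec$update == "ca_decay") {
        v <- update_values_decay(v, j, delta, lr, full[["decay"]],
                                 full[["prior"]])
      } else {
        ca <- if (delta >= 0) full[["ca_pos"]] else full[["ca_neg"]]
        v <- update_values_ca(v, j, delta, lr, ca)
      }
    }
    V[t + 1, ] <- v
  }
  list(nll = nll, V = V)
}

# Two-task dataset from one simulated agent (shared across lagged tests).
two_task_agent <- function(model, params, seed, config = task_config(),
                           miss_rate = 0) {
  rbind(
    simulate_agent(model, params, config, seed = seed, task = "social",
                   miss_rate = miss_rate),
    simulate_agent(model, params, config, seed = seed + 5000L,
                   task = "bandit", miss_rate = miss_rate))
}

# Brute-force lag pairing: for one task's non-missed trials (in trial
# order), return the n-th most recent relevant/irrelevant return.
bf_lag <- function(d, i, n, relevant) {
  prev <- seq_len(i - 1)
  if (relevant) prev <- prev[d$stimulus_id[prev] == d$stimulus_id[i]]
  if (length(prev) < n) return(NA_real_)
  d$returned[rev(prev)[n]]
}

# Independent cross-timepoint score: straight-line recomputation from raw
# trial patterns with explicit loops.
bf_crosstime_score <- function(choice, feedback) {
  stims <- sort(unique(choice$meta$stimulus_id))
  mean_half <- function(ps, s, which_half) {
    ord <- order(ps$meta$trial_index)
    rows <- ord[ps$meta$stimulus_id[ord] == s]
    sel <- if (which_half == "odd") rows[seq(1, length(rows), by = 2)]
           else rows[seq(2, length(rows), by = 2)]
    colMeans(ps$patterns[sel, , drop = FALSE])
  }
  conds <- expand.grid(stimulus = stims, phase = c("choice", "feedback"),
                       stringsAsFactors = FALSE)
  conds <- conds[order(match(conds$phase, c("choice", "feedback"))), ]
  even <- odd <- list()
  for (r in seq_len(nrow(conds))) {
    ps <- if (conds$phase[r] == "choice") choice else feedback
    even[[r]] <- mean_half(ps, conds$stimulus[r], "even")
    odd[[r]] <- mean_half(ps, conds$stimulus[r], "odd")
  }
  sims <- model <- numeric(0)
  for (a in seq_len(nrow(conds))) {
    for (b in seq_len(nrow(conds))) {
      if (conds$phase[a] == conds$phase[b]) next
      sims <- c(sims, cor(even[[a]], odd[[b]]))
      model <- c(model, as.numeric(conds$stimulus[a] == conds$stimulus[b]))
    }
  }
  cor(sims, model)
}
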