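#' Fit a credit-assignment model by maximum likelihood
#'
#' Per-participant, per-task MLE via bounded quasi-Newton optimization
#' (`optim(method = "L-BFGS-B")` with numerical gradients) from `n_starts`
#' seeded uniform-random initializations within the bounds.  The best start
#' (lowest NLL) is returned together with its value trajectory, prediction
#' errors and per-start diagnostics.
#'
#' @param data behavioral data for one participant and one task (see
#'   [read_behavior()] for the schema).
#' @param model model name or [ca_model()] spec.
#' @param config a [task_config()].
#' @param n_starts number of random restarts.
#' @param bounds list with `lower`/`upper` named vectors, as [ca_bounds()].
#' @param seed integer seed for the restart draws (`NULL` = ambient RNG).
#' @return An object of class `ca_fit` with methods `print`, `summary`,
#'   `coef`, `logLik` (hence `AIC`), `fitted`, `residuals`, `predict`,
#'   `simulate` and `plot`.
#' @examples
#' d <- simulate_agent("baseline",
#'                     c(lr = 0.4, prior = 5, m = 1, bias = 5), seed = 1)
#' f <- fit_ca_model(d, "baseline", n_starts = 5, seed = 2)
#' coef(f); AIC(f)
#' @export
fit_ca_model <- function(data, model = "vlr_vca", config = task_config(),
                         n_starts = 20, bounds = ca_bounds(), seed = 1) {
  spec <- if (inherits(model, "ca_model_spec")) model else ca_model(model)
  pr <- prep_trials(data, config)
  if (!any(!pr$missed)) stop("no non-missed trials to fit")
  lower <- bounds$lower[spec$free]
  upper <- bounds$upper[spec$free]
  if (anyNA(lower) || anyNA(upper))
    stop("bounds missing for parameter(s): ",
         paste(spec$free[is.na(lower) | is.na(upper)], collapse = ", "))
  opt <- config$investment_options
  decay_flag <- as.integer(spec$update == "ca_decay")
  # Encode the variant's parameter tying as an affine map full = base + M p
  # so objective and gradient stay inside C++ during optimization.
  base <- expand_params(spec, stats::setNames(numeric(spec$k), spec$free))
  M <- vapply(seq_len(spec$k), function(j) {
    e <- stats::setNames(numeric(spec$k), spec$free)
    e[j] <- 1
    expand_params(spec, e) - base
  }, numeric(8))
  nll_fn <- function(p)
    .ca_nll_free_cpp(p, M, base, pr$stim, pr$choice_idx, pr$reward,
                     pr$missed, opt, config$n_stimuli, decay_flag,
                     max(opt), 1.0)
  grad_fn <- function(p)
    .ca_nll_grad_cpp(p, M, base, pr$stim, pr$choice_idx, pr$reward,
                     pr$missed, opt, config$n_stimuli, decay_flag,
                     max(opt), 1.0, 1e-6)
  starts <- with_seed(seed, {
    matrix(runif(n_starts * spec$k, rep(lower, each = n_starts),
                 rep(upper, each = n_starts)),
           nrow = n_starts, dimnames = list(NULL, spec$free))
  })
  runs <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    runs[[i]] <- tryCatch(
      stats::optim(starts[i, ], nll_fn, gr = grad_fn, method = "L-BFGS-B",
                   lower = lower, upper = upper),
      error = function(e) list(value = NA_real_, par = starts[i, ],
                               convergence = -1L, message = conditionMessage(e)))
  }
  nlls <- vapply(runs, function(r) r$value, numeric(1))
  if (all(is.na(nlls)))
    stop("all optimization starts failed; first error: ",
         runs[[1]]$message %||% "unknown")
  best <- which.min(nlls)
  par <- runs[[best]]$par
  names(par) <- spec$free
  trace <- ca_trajectory(pr$data, spec, par, config)
  n_obs <- sum(!pr$missed)
  structure(list(
    coefficients = par,
    model = spec,
    nll = nlls[best],
    aic = 2 * spec$k + 2 * nlls[best],
    n_obs = n_obs,
    n_starts = n_starts,
    starts = data.frame(starts, nll = nlls,
                        convergence = vapply(runs, function(r)
                          as.integer(r$convergence), integer(1))),
    trajectory = trace$V,
    delta = trace$delta,
    pred = trace$pred,
    p_obs = trace$p_obs,
    data = pr$data,
    participant_id = pr$data$participant_id[1],
    task = pr$data$task[1],
    config = config,
    seed = seed,
    call = match.call()),
    class = "ca_fit")
}

#' @export
print.ca_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<ca_fit> model %s | participant %s, task %s\n",
              x$model$name, x$participant_id, x$task))
  print(round(x$coefficients, digits))
  cat(sprintf("NLL %.3f on %d trials; AIC %.2f (%d starts)\n",
              x$nll, x$n_obs, x$aic, x$n_starts))
  invisible(x)
}

#' @export
summary.ca_fit <- function(object, ...) {
  conv <- object$starts$convergence
  structure(list(fit = object,
                 n_converged = sum(conv == 0, na.rm = TRUE),
                 nll_range = range(object$starts$nll, na.rm = TRUE),
                 mean_p_obs = mean(object$p_obs, na.rm = TRUE)),
            class = "summary.ca_fit")
}

#' @export
print.summary.ca_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("starts converged: %d/%d; NLL range across starts: %.3f..%.3f\n",
              x$n_converged, x$fit$n_starts, x$nll_range[1], x$nll_range[2]))
  cat(sprintf("mean p(observed investment): %.3f\n", x$mean_p_obs))
  invisible(x)
}

#' @export
coef.ca_fit <- function(object, ...) object$coefficients

#' @export
logLik.ca_fit <- function(object, ...) {
  structure(-object$nll, df = object$model$k, nobs = object$n_obs,
            class = "logLik")
}

#' @export
fitted.ca_fit <- function(object, ...) object$pred

#' @export
residuals.ca_fit <- function(object, ...) {
  object$data$investment - object$pred
}

#' @rdname fit_ca_model
#' @param object a `ca_fit`.
#' @param newdata optional behavioral table to evaluate under the fitted
#'   parameters (defaults to the fitted data).
#' @param type `"investment"` for per-trial predicted investments,
#'   `"probabilities"` for the trial x option choice-probability matrix.
#' @param ... unused.
#' @export
predict.ca_fit <- function(object, newdata = NULL,
                           type = c("investment", "probabilities"), ...) {
  type <- match.arg(type)
  data <- newdata %||% object$data
  tr <- ca_trajectory(data, object$model, object$coefficients, object$config)
  if (type == "investment") return(tr$pred)
  opt <- object$config$investment_options
  t(vapply(tr$pred, function(p) {
    if (is.na(p)) rep(NA_real_, length(opt))
    else choice_probabilities(p, opt)
  }, numeric(length(opt))))
}

#' @rdname fit_ca_model
#' @param nsim number of datasets to simulate from the fitted parameters.
#' @param schedule,ordering passed to [simulate_agent()]; freshly drawn when
#'   `NULL`.
#' @export
simulate.ca_fit <- function(object, nsim = 1, seed = NULL, schedule = NULL,
                            ordering = NULL, ...) {
  with_seed(seed, {
    out <- lapply(seq_len(nsim), function(i)
      simulate_agent(object$model, object$coefficients, object$config,
                     participant_id = paste0(object$participant_id, "_sim", i),
                     task = object$task, schedule = schedule,
                     ordering = ordering))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

#' @export
plot.ca_fit <- function(x, ...) {
  V <- x$trajectory
  n_stim <- ncol(V)
  cols <- grDevices::hcl.colors(n_stim, "Dark 3")
  graphics::matplot(seq_len(nrow(V)) - 1, V, type = "l", lty = 1,
                    col = cols, xlab = "trial", ylab = "expected value V ($)",
                    main = sprintf("%s: value trajectory (%s, %s)",
                                   x$model$name, x$participant_id, x$task),
                    ...)
  ok <- !x$data$missed
  graphics::points(x$data$trial_index[ok], x$data$investment[ok],
                   col = cols[x$data$stimulus_id[ok]], pch = 16, cex = 0.6)
  graphics::legend("topleft", legend = colnames(V), col = cols, lty = 1,
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' Compare fitted models with AIC
#'
#' Computes `AIC = 2k + 2 NLL` per fit and, within each participant-task,
#' the difference from that participant's best model (delta AIC = 0 for the
#' winner).  Ties are broken in favor of the model with fewer parameters.
#' Group-level winners (per task) are reported both by summed AIC and by
#' participant win counts.
#'
#' @param fits list of `ca_fit` objects covering the same data per
#'   participant-task across models.
#' @return An object of class `ca_model_comparison`: `table` (per fit),
#'   `group` (per task x model summary) and `winners` (per participant-task).
#' @export
compare_ca_models <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "ca_fit")))
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(participant_id = f$participant_id, task = f$task,
               model = f$model$name, k = f$model$k, nll = f$nll,
               aic = f$aic, stringsAsFactors = FALSE)))
  n_per <- table(tab$participant_id, tab$task, tab$model)
  if (any(n_per > 1))
    stop("duplicate fits for the same participant-task-model")
  key <- interaction(tab$participant_id, tab$task, drop = TRUE)
  nm <- tapply(tab$model, key, length)
  if (length(unique(nm)) > 1)
    stop("mismatched model sets across participant-tasks")
  tab$delta_aic <- tab$aic - stats::ave(tab$aic, key, FUN = min)
  winners <- do.call(rbind, lapply(split(tab, key), function(d) {
    d <- d[order(d$aic, d$k), , drop = FALSE]  # parsimony tie-break
    d[1, c("participant_id", "task", "model", "aic")]
  }))
  rownames(winners) <- NULL
  group <- do.call(rbind, lapply(split(tab, tab$task), function(d) {
    agg <- stats::aggregate(aic ~ model, d, sum)
    wins <- table(factor(winners$model[winners$task == d$task[1]],
                         levels = agg$model))
    data.frame(task = d$task[1], model = agg$model, summed_aic = agg$aic,
               wins = as.integer(wins[agg$model]), stringsAsFactors = FALSE)
  }))
  rownames(group) <- NULL
  group$group_winner <- stats::ave(group$summed_aic, group$task,
                                   FUN = function(a) a == min(a)) > 0
  structure(list(table = tab, winners = winners, group = group),
            class = "ca_model_comparison")
}

#' @export
print.ca_model_comparison <- function(x, ...) {
  cat("<ca_model_comparison>\n")
  print(x$group)
  invisible(x)
}
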