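#' Model confusability study
#'
#' For each generative model, simulates `n_sim` agents with parameters
#' drawn uniformly within the sampler's ranges, fits every candidate model
#' to each agent, and classifies the agent by the model with the lowest AIC
#' (highest negative AIC; ties go to the smaller model).  Reports the
#' forward confusion matrix (row-normalized classification rates per
#' generative model) and the inverse matrix (column-normalized: probability
#' that a given best-fitting model arose from each generative model).
#'
#' @param models candidate model names.
#' @param n_sim simulated agents per generative model (100 in the emulated
#'   validation protocol).
#' @param config a [task_config()].
#' @param sampler optional named list of samplers per model; defaults to
#'   [default_param_sampler()] for each.
#' @param n_starts restarts per fit.
#' @param seed integer seed.
#' @return An object of class `ca_confusion` with `counts`, `rates`,
#'   `inverse` matrices (generative model x fitted model).
#' @export
confusability_study <- function(models = ca_model_names(), n_sim = 100,
                                config = task_config(), sampler = NULL,
                                n_starts = 20, seed = 1) {
  specs <- lapply(models, ca_model)
  names(specs) <- models
  if (is.null(sampler))
    sampler <- lapply(specs, default_param_sampler)
  counts <- matrix(0L, length(models), length(models),
                   dimnames = list(generative = models, fitted = models))
  with_seed(seed, {
    for (g in models) {
      for (i in seq_len(n_sim)) {
        params <- sampler[[g]]()
        d <- simulate_agent(specs[[g]], params, config,
                            participant_id = sprintf("%s_%03d", g, i))
        aics <- vapply(models, function(m) {
          fit_ca_model(d, specs[[m]], config, n_starts = n_starts,
                       seed = NULL)$aic
        }, numeric(1))
        ks <- vapply(specs, `[[`, numeric(1), "k")
        best <- models[order(aics, ks)][1]
        counts[g, best] <- counts[g, best] + 1L
      }
    }
  })
  rates <- counts / rowSums(counts)
  inv <- sweep(counts, 2, pmax(colSums(counts), 1L), "/")
  structure(list(counts = counts, rates = rates, inverse = inv,
                 models = models, n_sim = n_sim),
            class = "ca_confusion")
}

#' @export
print.ca_confusion <- function(x, digits = 2, ...) {
  cat(sprintf("<ca_confusion> %d simulated agents per model\n", x$n_sim))
  cat("classification rates (rows = generative):\n")
  print(round(x$rates, digits))
  invisible(x)
}

#' Parameter recovery study
#'
#' Simulates `n_sim` agents from the model with sampled parameters, refits
#' the same model to each, and reports the generative-vs-recovered table
#' with a Spearman rank correlation per free parameter.
#'
#' @inheritParams confusability_study
#' @param model model name or spec.
#' @return An object of class `ca_recovery` with `generative`, `recovered`
#'   data.frames and the named `spearman` vector.
#' @export
parameter_recovery <- function(model = "vlr_vca", n_sim = 50,
                               config = task_config(), sampler = NULL,
                               n_starts = 20, seed = 1) {
  spec <- if (inherits(model, "ca_model_spec")) model else ca_model(model)
  if (is.null(sampler)) sampler <- default_param_sampler(spec)
  gen <- rec <- matrix(NA_real_, n_sim, spec$k,
                       dimnames = list(NULL, spec$free))
  with_seed(seed, {
    for (i in seq_len(n_sim)) {
      params <- sampler()
      d <- simulate_agent(spec, params, config,
                          participant_id = sprintf("rec_%03d", i))
      fit <- fit_ca_model(d, spec, config, n_starts = n_starts, seed = NULL)
      gen[i, ] <- params[spec$free]
      rec[i, ] <- coef(fit)[spec$free]
    }
  })
  rho <- vapply(spec$free, function(p)
    stats::cor(gen[, p], rec[, p], method = "spearman"), numeric(1))
  structure(list(generative = as.data.frame(gen),
                 recovered = as.data.frame(rec),
                 spearman = rho, model = spec$name, n_sim = n_sim),
            class = "ca_recovery")
}

#' @export
print.ca_recovery <- function(x, digits = 2, ...) {
  cat(sprintf("<ca_recovery> model %s, %d simulations\n", x$model, x$n_sim))
  cat("Spearman rho (generative vs recovered):\n")
  print(round(x$spearman, digits))
  invisible(x)
}

#' Posterior predictive check
#'
#' Simulates `n_rep` datasets under the fitted parameters (same schedule
#' and ordering options as [simulate_agent()]) and compares per-condition
#' mean-investment-by-occasion learning curves against the observed data,
#' with pointwise simulation quantile bands.
#'
#' @param fit a [fit_ca_model()] result.
#' @param schedule,ordering optional fixed environment; freshly drawn per
#'   replicate when `NULL`.
#' @param n_rep number of simulated datasets.
#' @param seed integer seed.
#' @param level band coverage level (default 95%).
#' @return An object of class `ca_ppc` with `observed` and `simulated`
#'   curve tables and the fraction of observed points inside the band.
#' @export
posterior_predictive <- function(fit, schedule = NULL, ordering = NULL,
                                 n_rep = 100, seed = 1, level = 0.95) {
  stopifnot(inherits(fit, "ca_fit"))
  curve_of <- function(d) {
    d <- d[!d$missed, , drop = FALSE]
    d <- d[order(d$trial_index), , drop = FALSE]
    occ <- stats::ave(seq_len(nrow(d)),
                      interaction(d$stimulus_id, drop = TRUE),
                      FUN = seq_along)
    stats::aggregate(investment ~ condition + occasion,
                     data.frame(condition = d$condition, occasion = occ,
                                investment = d$investment),
                     FUN = mean)
  }
  obs <- curve_of(fit$data)
  sims <- with_seed(seed, {
    lapply(seq_len(n_rep), function(i) {
      curve_of(simulate_agent(fit$model, coef(fit), fit$config,
                              schedule = schedule, ordering = ordering,
                              task = fit$task))
    })
  })
  all_sim <- do.call(rbind, sims)
  a <- (1 - level) / 2
  band <- do.call(rbind, lapply(
    split(all_sim, list(all_sim$condition, all_sim$occasion), drop = TRUE),
    function(d) data.frame(condition = d$condition[1],
                           occasion = d$occasion[1],
                           mean = mean(d$investment),
                           lo = stats::quantile(d$investment, a, names = FALSE),
                           hi = stats::quantile(d$investment, 1 - a,
                                                names = FALSE))))
  rownames(band) <- NULL
  m <- merge(obs, band, by = c("condition", "occasion"))
  coverage <- mean(m$investment >= m$lo - 1e-9 & m$investment <= m$hi + 1e-9)
  structure(list(observed = obs, simulated = band, coverage = coverage,
                 n_rep = n_rep, level = level),
            class = "ca_ppc")
}

#' @export
print.ca_ppc <- function(x, ...) {
  cat(sprintf(
    "<ca_ppc> %d replicates; %.0f%% of observed curve points in %.0f%% band\n",
    x$n_rep, 100 * x$coverage, 100 * x$level))
  invisible(x)
}

#' @export
plot.ca_ppc <- function(x, ...) {
  conds <- unique(x$simulated$condition)
  cols <- grDevices::hcl.colors(length(conds), "Dark 3")
  graphics::plot(NULL, xlim = range(x$simulated$occasion),
                 ylim = c(0, max(x$simulated$hi, x$observed$investment)),
                 xlab = "occasion (within-stimulus trial)",
                 ylab = "mean investment ($)",
                 main = "posterior predictive learning curves")
  for (i in seq_along(conds)) {
    b <- x$simulated[x$simulated$condition == conds[i], ]
    b <- b[order(b$occasion), ]
    graphics::polygon(c(b$occasion, rev(b$occasion)), c(b$lo, rev(b$hi)),
                      col = grDevices::adjustcolor(cols[i], 0.2), border = NA)
    graphics::lines(b$occasion, b$mean, col = cols[i], lwd = 2)
    o <- x$observed[x$observed$condition == conds[i], ]
    graphics::points(o$occasion, o$investment, col = cols[i], pch = 16,
                     cex = 0.6)
  }
  graphics::legend("bottomright", legend = conds, col = cols, lwd = 2,
                   bty = "n", cex = 0.8)
  invisible(x)
}
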