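#' Time-lagged regression design
#'
#' Builds, for one participant with both tasks, the design relating each
#' investment to previous returns: relevant lag *n* is the return from the
#' *n*-th most recent prior trial with the same stimulus, irrelevant lag
#' *n* is the return from the *n*-th most recent prior trial regardless of
#' stimulus.  Each lag is crossed with task (a trial contributes to its own
#' task's slope column; the other task's column is 0), yielding
#' `2 x 2 x n_lags` slope columns plus the intercept -- 13 coefficients at
#' the default 3 lags.  Missed trials are excluded both as responses and as
#' lag sources (the pairing skips over them).  Rows lacking any of their
#' own task's lags are dropped (listwise within model).
#'
#' @param data behavioral table for one participant containing both tasks.
#' @param n_lags number of lags per term (default 3).
#' @param tasks the two task labels expected in `data`.
#' @param irrelevant_excludes_relevant if `TRUE`, irrelevant lags skip
#'   trials of the same stimulus as the current trial; the default `FALSE`
#'   counts the immediately preceding trials irrespective of identity.
#' @return An object of class `ca_lagged_design`: list with `design`
#'   data.frame (response + 12 slope columns), `n_dropped`, `terms`.
#' @export
build_lagged_design <- function(data, n_lags = 3,
                                tasks = c("social", "bandit"),
                                irrelevant_excludes_relevant = FALSE) {
  if (length(unique(data$participant_id)) != 1)
    stop("expected data from a single participant")
  missing_task <- setdiff(tasks, unique(data$task))
  if (length(missing_task))
    stop("missing task(s): ", paste(missing_task, collapse = ", "))
  term_names <- as.vector(t(outer(
    c(outer(c("rel", "irrel"), seq_len(n_lags), paste0)),
    tasks, paste, sep = "_")))
  rows <- list()
  n_dropped <- 0L
  for (tk in tasks) {
    d <- data[data$task == tk & !data$missed, , drop = FALSE]
    d <- d[order(d$trial_index), , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      rel_hist <- rev(d$returned[seq_len(i - 1)][
        d$stimulus_id[seq_len(i - 1)] == d$stimulus_id[i]])
      irr_idx <- seq_len(i - 1)
      if (irrelevant_excludes_relevant)
        irr_idx <- irr_idx[d$stimulus_id[irr_idx] != d$stimulus_id[i]]
      irr_hist <- rev(d$returned[irr_idx])
      if (length(rel_hist) < n_lags || length(irr_hist) < n_lags) {
        n_dropped <- n_dropped + 1L
        next
      }
      row <- stats::setNames(numeric(length(term_names)), term_names)
      row[paste0("rel", seq_len(n_lags), "_", tk)] <- rel_hist[seq_len(n_lags)]
      row[paste0("irrel", seq_len(n_lags), "_", tk)] <-
        irr_hist[seq_len(n_lags)]
      rows[[length(rows) + 1L]] <- c(investment = d$investment[i], row)
    }
  }
  if (!length(rows)) stop("no usable rows after lag construction")
  design <- as.data.frame(do.call(rbind, rows))
  structure(list(design = design, terms = term_names, n_lags = n_lags,
                 tasks = tasks, n_dropped = n_dropped,
                 participant_id = data$participant_id[1]),
            class = "ca_lagged_design")
}

#' Fit the 13-coefficient lagged regression
#'
#' Ordinary least squares of investment on the pooled two-task lag design.
#' Rank deficiency (aliased coefficients) is reported with a warning.
#'
#' @param design a [build_lagged_design()] result.
#' @return An object of class `ca_lagged_fit`: `coefficients` data.frame
#'   (term, estimate, se, t, p) including the intercept, plus the
#'   underlying `lm` in `$model`.
#' @export
fit_lagged_model <- function(design) {
  stopifnot(inherits(design, "ca_lagged_design"))
  f <- stats::as.formula(paste("investment ~",
                               paste(design$terms, collapse = " + ")))
  fit <- stats::lm(f, data = design$design)
  if (any(is.na(coef(fit))))
    warning("rank-deficient lagged design; aliased: ",
            paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      t = sm[, 3], p = sm[, 4], row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, model = fit,
                 participant_id = design$participant_id),
            class = "ca_lagged_fit")
}

#' @export
print.ca_lagged_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<ca_lagged_fit> participant %s (%d coefficients)\n",
              x$participant_id, nrow(x$coefficients)))
  print(cbind(x$coefficients["term"],
              round(x$coefficients[c("estimate", "se", "t")], digits)))
  invisible(x)
}

#' Valence-split lag-1 regressions
#'
#' Four separate lag-1-only regressions per participant, one per cell of
#' relevant/irrelevant x gain/loss, with task-crossed slopes.  A trial
#' enters a cell when its lag-1 source trial (same-stimulus for relevant,
#' immediately preceding for irrelevant) produced a net gain
#' (return > investment) or net loss (return < investment); break-even
#' sources are excluded.  Cells with fewer than `min_trials` usable rows in
#' a task are flagged and their estimate withheld.
#'
#' @param data behavioral table for one participant with both tasks.
#' @param tasks task labels.
#' @param min_trials minimum usable rows per cell-task.
#' @return data.frame with columns `cell`, `task`, `estimate`, `se`, `n`,
#'   `flagged`.
#' @export
valence_split_lag1 <- function(data, tasks = c("social", "bandit"),
                               min_trials = 5) {
  if (length(unique(data$participant_id)) != 1)
    stop("expected data from a single participant")
  missing_task <- setdiff(tasks, unique(data$task))
  if (length(missing_task))
    stop("missing task(s): ", paste(missing_task, collapse = ", "))
  out <- list()
  for (relevance in c("relevant", "irrelevant")) {
    for (val in c("gain", "loss")) {
      for (tk in tasks) {
        d <- data[data$task == tk & !data$missed, , drop = FALSE]
        d <- d[order(d$trial_index), , drop = FALSE]
        lag_val <- rep(NA_real_, nrow(d))
        for (i in seq_len(nrow(d))) {
          src <- if (relevance == "relevant") {
            prev <- seq_len(i - 1)[d$stimulus_id[seq_len(i - 1)] ==
                                     d$stimulus_id[i]]
            if (length(prev)) max(prev) else NA_integer_
          } else if (i > 1) i - 1L else NA_integer_
          if (is.na(src)) next
          src_val <- trial_valence(d$investment[src], d$returned[src])
          if (src_val == val) lag_val[i] <- d$returned[src]
        }
        use <- !is.na(lag_val)
        n <- sum(use)
        if (n < min_trials || stats::sd(lag_val[use]) == 0) {
          out[[length(out) + 1L]] <- data.frame(
            cell = paste(relevance, val, sep = "_"), task = tk,
            estimate = NA_real_, se = NA_real_, n = n, flagged = TRUE,
            stringsAsFactors = FALSE)
          next
        }
        fit <- stats::lm(d$investment[use] ~ lag_val[use])
        sm <- summary(fit)$coefficients
        out[[length(out) + 1L]] <- data.frame(
          cell = paste(relevance, val, sep = "_"), task = tk,
          estimate = sm[2, 1], se = sm[2, 2], n = n, flagged = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
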