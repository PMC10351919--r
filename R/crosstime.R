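#' Even/odd split-half condition means across task phases
#'
#' Splits trials within each stimulus by occurrence parity (1st, 3rd, ... =
#' odd; 2nd, 4th, ... = even) and averages the voxel patterns per stimulus
#' and phase in each half.  Returns one voxel x (stimulus x phase) matrix
#' per half with columns ordered choice-stimuli first, then
#' feedback-stimuli (the concatenated choice + feedback layout).
#'
#' @param choice,feedback `ca_patterns` objects for the two phases, with
#'   aligned trial metadata.
#' @return An object of class `ca_split`: `even` and `odd` matrices and the
#'   `conditions` table (`phase`, `stimulus`).
#' @export
split_even_odd <- function(choice, feedback) {
  stopifnot(inherits(choice, "ca_patterns"), inherits(feedback, "ca_patterns"))
  stim_levels <- sort(unique(c(choice$meta$stimulus_id,
                               feedback$meta$stimulus_id)))
  half_means <- function(ps) {
    ord <- order(ps$meta$trial_index)
    X <- ps$patterns[ord, , drop = FALSE]
    stim <- ps$meta$stimulus_id[ord]
    even <- odd <- matrix(NA_real_, ncol(X), length(stim_levels))
    for (i in seq_along(stim_levels)) {
      rows <- which(stim == stim_levels[i])
      if (length(rows) < 2)
        stop("stimulus ", stim_levels[i],
             " has fewer than 2 trials; even/odd split impossible")
      parity <- seq_along(rows) %% 2  # 1 = odd occurrence, 0 = even
      odd[, i] <- colMeans(X[rows[parity == 1], , drop = FALSE])
      even[, i] <- colMeans(X[rows[parity == 0], , drop = FALSE])
    }
    list(even = even, odd = odd)
  }
  ch <- half_means(choice)
  fb <- half_means(feedback)
  conditions <- data.frame(
    phase = rep(c("choice", "feedback"), each = length(stim_levels)),
    stimulus = rep(stim_levels, 2))
  structure(list(even = cbind(ch$even, fb$even),
                 odd = cbind(ch$odd, fb$odd),
                 conditions = conditions),
            class = "ca_split")
}

#' Cross-timepoint distance matrix
#'
#' Correlation distance between every even-half condition mean and every
#' odd-half condition mean: entry `(a, b) = 1 - r(even[, a], odd[, b])`.
#' For 4 stimuli and 2 phases this is the 8 x 8 cross-timepoint matrix
#' whose off-diagonal phase quadrants (choiceEven vs feedbackOdd and
#' feedbackEven vs choiceOdd) carry the cross-phase structure.
#'
#' @param split a [split_even_odd()] result.
#' @return An object of class `ca_crosstime`: distance matrix `d` (rows =
#'   even conditions, columns = odd conditions) and the `conditions` table.
#' @export
cross_timepoint_matrix <- function(split) {
  stopifnot(inherits(split, "ca_split"))
  if (any(apply(split$even, 2, stats::sd) == 0) ||
      any(apply(split$odd, 2, stats::sd) == 0))
    stop("zero-variance condition mean; cannot correlate")
  d <- 1 - stats::cor(split$even, split$odd)
  structure(list(d = d, conditions = split$conditions),
            class = "ca_crosstime")
}

#' Cross-quadrant identity score
#'
#' Extracts the two cross-phase quadrants of the cross-timepoint matrix,
#' converts distances to similarities (1 - distance), and correlates them
#' with the cross-timepoint identity model (same stimulus across phases =
#' similar, different = dissimilar).  Both quadrants are concatenated into
#' one vector before the Pearson correlation, so a stronger shared identity
#' code across choice and feedback gives a larger positive score.
#'
#' @param ct a [cross_timepoint_matrix()] result.
#' @return Pearson correlation in `[-1, 1]`.
#' @export
cross_quadrant_identity_score <- function(ct) {
  stopifnot(inherits(ct, "ca_crosstime"))
  ph <- ct$conditions$phase
  st <- ct$conditions$stimulus
  ich <- which(ph == "choice")
  ifb <- which(ph == "feedback")
  q1 <- ct$d[ich, ifb, drop = FALSE]  # choiceEven vs feedbackOdd
  q2 <- ct$d[ifb, ich, drop = FALSE]  # feedbackEven vs choiceOdd
  model1 <- outer(st[ich], st[ifb], "==") * 1
  model2 <- outer(st[ifb], st[ich], "==") * 1
  sim <- 1 - c(q1, q2)
  model <- c(model1, model2)
  if (stats::sd(sim) == 0) stop("constant cross-quadrant cells")
  stats::cor(sim, model)
}

#' Cross-timepoint RSA in one call
#'
#' Convenience wrapper: even/odd split, cross-timepoint matrix, and the
#' cross-quadrant identity score.
#'
#' @inheritParams split_even_odd
#' @return List with the `ca_crosstime` `matrix` and the numeric `score`.
#' @export
cross_timepoint_rsa <- function(choice, feedback) {
  ct <- cross_timepoint_matrix(split_even_odd(choice, feedback))
  list(matrix = ct, score = cross_quadrant_identity_score(ct))
}
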