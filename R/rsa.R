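#' Neural representational dissimilarity matrix
#'
#' Pairwise correlation distance (1 - Pearson r across voxels) between
#' trial patterns, with rows and columns reordered so that trials are
#' nested within stimulus identity (the ordering assumed by the hypothesis
#' matrices).
#'
#' @param patterns trials x voxels matrix, or a `ca_patterns` object.
#' @param stimulus per-trial stimulus ids (taken from the object's `meta`
#'   when `patterns` is a `ca_patterns`).
#' @param trial_index per-trial indices (for the autocorrelation predictor
#'   and tie-stable ordering).
#' @param values optional per-trial expected values carried into the item
#'   table for the value predictor.
#' @return An object of class `ca_rdm`: symmetric distance matrix `d` with
#'   zero diagonal and entries in `[0, 2]`, plus the reordered `items`
#'   table.
#' @export
neural_rdm <- function(patterns, stimulus = NULL, trial_index = NULL,
                       values = NULL) {
  if (inherits(patterns, "ca_patterns")) {
    stimulus <- stimulus %||% patterns$meta$stimulus_id
    trial_index <- trial_index %||% patterns$meta$trial_index
    values <- values %||% patterns$meta$value
    patterns <- patterns$patterns
  }
  stopifnot(is.matrix(patterns), !is.null(stimulus),
            length(stimulus) == nrow(patterns))
  if (nrow(patterns) < 2 || ncol(patterns) < 2)
    stop("need at least 2 trials and 2 voxels")
  trial_index <- trial_index %||% seq_len(nrow(patterns))
  sds <- apply(patterns, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance pattern at trial(s): ",
         paste(trial_index[sds == 0], collapse = ", "))
  ord <- order(stimulus, trial_index)
  X <- patterns[ord, , drop = FALSE]
  d <- 1 - stats::cor(t(X))
  diag(d) <- 0
  items <- data.frame(stimulus = stimulus[ord], trial_index = trial_index[ord])
  if (!is.null(values)) items$value <- values[ord]
  structure(list(d = d, items = items), class = "ca_rdm")
}

#' @export
print.ca_rdm <- function(x, ...) {
  cat(sprintf("<ca_rdm> %d items (%d stimuli)\n", nrow(x$d),
              length(unique(x$items$stimulus))))
  invisible(x)
}

#' Hypothesis dissimilarity matrices
#'
#' `identity_rdm()`: 0 for same-stimulus pairs, 1 otherwise.
#' `value_rdm()`: absolute difference of trial-wise expected values.
#' `autocorr_rdm()`: absolute difference of trial indices, absorbing
#' temporal-proximity (scanner autocorrelation) structure.
#'
#' @param items item table of a [neural_rdm()] (columns `stimulus`,
#'   `trial_index`, optionally `value`).
#' @return A square numeric matrix matching the neural RDM's item order.
#' @export
identity_rdm <- function(items) {
  out <- 1 - outer(items$stimulus, items$stimulus, "==")
  mode(out) <- "numeric"
  out
}

#' @rdname identity_rdm
#' @export
value_rdm <- function(items) {
  if (is.null(items$value)) stop("items carry no values; supply `values`")
  abs(outer(items$value, items$value, "-"))
}

#' @rdname identity_rdm
#' @export
autocorr_rdm <- function(items) {
  abs(outer(items$trial_index, items$trial_index, "-"))
}

#' Univariate noise normalization
#'
#' Divides each voxel's coefficients by its residual standard deviation
#' (estimated from the coefficients themselves when no residual SDs are
#' supplied).  Voxels with zero SD are excluded with a warning.
#'
#' @param patterns trials x voxels matrix.
#' @param residual_sd optional per-voxel positive SDs.
#' @return Normalized matrix (possibly fewer columns); kept column indices
#'   in `attr(, "kept_voxels")`.
#' @export
noise_normalize <- function(patterns, residual_sd = NULL) {
  stopifnot(is.matrix(patterns))
  s <- residual_sd %||% apply(patterns, 2, stats::sd)
  stopifnot(length(s) == ncol(patterns), all(s >= 0))
  keep <- s > 0
  if (!all(keep))
    warning(sum(!keep), " zero-SD voxel(s) excluded from normalization")
  out <- sweep(patterns[, keep, drop = FALSE], 2, s[keep], "/")
  attr(out, "kept_voxels") <- which(keep)
  out
}

#' Regression RSA
#'
#' Vectorizes the strict lower triangles of the neural RDM and each
#' hypothesis RDM, z-scores response and predictors, and regresses the
#' neural distances on the included predictors by OLS.  Predictors that are
#' constant over the triangle are dropped with a warning.  In searchlight
#' mode the included set is identity + autocorrelation; ROI analyses add
#' the expected-value predictor.
#'
#' @param neural a `ca_rdm` (or square matrix).
#' @param predictors named list of hypothesis matrices; defaults to the
#'   identity and autocorrelation matrices of `neural$items` (plus value
#'   when the items carry values and `include` requests it).
#' @param include names of predictors to include.
#' @return data.frame with one row per included predictor: `term`, `beta`
#'   (on the z-scored scale), `se`, `t`, `p`; residual degrees of freedom
#'   and pair count in attributes.
#' @export
rdm_regression <- function(neural, predictors = NULL,
                           include = NULL) {
  if (inherits(neural, "ca_rdm")) {
    items <- neural$items
    if (is.null(predictors)) {
      predictors <- list(identity = identity_rdm(items),
                         autocorr = autocorr_rdm(items))
      if (!is.null(items$value)) predictors$value <- value_rdm(items)
    }
    d <- neural$d
  } else {
    d <- neural
    if (is.null(predictors)) stop("predictors required for a bare matrix")
  }
  include <- include %||% names(predictors)
  predictors <- predictors[include]
  lt <- lower.tri(d)
  y <- zscore(d[lt])
  if (anyNA(y)) stop("neural distances are constant over the triangle")
  Xs <- lapply(predictors, function(p) zscore(p[lt]))
  constant <- vapply(Xs, anyNA, logical(1))
  if (any(constant)) {
    warning("constant predictor(s) dropped: ",
            paste(names(Xs)[constant], collapse = ", "))
    Xs <- Xs[!constant]
  }
  if (!length(Xs)) stop("no usable predictors")
  X <- cbind(`(Intercept)` = 1, do.call(cbind, Xs))
  fit <- stats::lm.fit(X, y)
  p <- ncol(X)
  df <- length(y) - p
  rss <- sum(fit$residuals^2)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtXinv) * rss / df)
  beta <- fit$coefficients
  tval <- beta / se
  out <- data.frame(term = names(Xs), beta = unname(beta[-1]),
                    se = unname(se[-1]), t = unname(tval[-1]),
                    p = unname(2 * stats::pt(-abs(tval[-1]), df)),
                    stringsAsFactors = FALSE)
  attr(out, "df") <- df
  attr(out, "n_pairs") <- length(y)
  out
}

#' Spherical searchlight offsets
#'
#' All integer voxel offsets `(dx, dy, dz)` whose physical length
#' `||offset * voxel_size||` is at most `radius_mm`; always includes the
#' origin and is symmetric under sign flips.
#'
#' @param radius_mm sphere radius in mm (9 mm in the emulated analysis).
#' @param voxel_size_mm voxel edge length in mm (scalar or length 3).
#' @return Integer matrix with columns `dx`, `dy`, `dz`.
#' @export
sphere_offsets <- function(radius_mm, voxel_size_mm = 2) {
  stopifnot(radius_mm > 0, all(voxel_size_mm > 0))
  vs <- rep(voxel_size_mm, length.out = 3)
  k <- floor(radius_mm / vs)
  g <- as.matrix(expand.grid(dx = -k[1]:k[1], dy = -k[2]:k[2],
                             dz = -k[3]:k[3]))
  keep <- (g[, 1] * vs[1])^2 + (g[, 2] * vs[2])^2 + (g[, 3] * vs[3])^2 <=
    radius_mm^2 + 1e-9
  g[keep, , drop = FALSE]
}

#' Whole-volume searchlight RSA
#'
#' Places a sphere at every in-mask voxel, gathers the in-mask sphere
#' voxels, noise-normalizes their coefficients, computes the trial RDM and
#' regresses it on the identity and autocorrelation hypothesis matrices
#' (see [rdm_regression()]), storing the identity predictor's t-statistic
#' (and beta) at the center.  Spheres with fewer than 2 usable voxels give
#' `NaN`.  Edge spheres are truncated at the mask.
#'
#' @param volumes 4-D array (x, y, z, trial).
#' @param mask 3-D logical/0-1 array of analyzable voxels.
#' @param stimulus,trial_index per-trial metadata.
#' @param radius_mm,voxel_size_mm sphere geometry.
#' @param normalize apply univariate noise normalization within each sphere.
#' @return An object of class `ca_searchlight`: 3-D arrays `t` and `beta`
#'   (`NaN` outside the mask), the mask, and the sphere geometry.
#' @export
searchlight <- function(volumes, mask, stimulus, trial_index = NULL,
                        radius_mm = 9, voxel_size_mm = 2, normalize = TRUE) {
  dims <- dim(volumes)
  stopifnot(length(dims) == 4, all(dim(mask) == dims[1:3]))
  n_trials <- dims[4]
  stopifnot(length(stimulus) == n_trials)
  trial_index <- trial_index %||% seq_len(n_trials)
  vmat <- matrix(volumes, prod(dims[1:3]), n_trials)  # voxels x trials
  mask <- array(as.logical(mask != 0), dims[1:3])
  centers <- which(mask)
  cc <- arrayInd(centers, dims[1:3])
  off <- sphere_offsets(radius_mm, voxel_size_mm)

  # Predictors are shared across centers: build once from the nested order.
  ord <- order(stimulus, trial_index)
  items <- data.frame(stimulus = stimulus[ord], trial_index = trial_index[ord])
  lt <- lower.tri(matrix(0, n_trials, n_trials))
  X <- cbind(1, zscore(identity_rdm(items)[lt]),
             zscore(autocorr_rdm(items)[lt]))
  XtXinv <- chol2inv(chol(crossprod(X)))
  P <- XtXinv %*% t(X)
  df <- nrow(X) - ncol(X)

  tmap <- bmap <- array(NaN, dims[1:3])
  in_mask <- rep(FALSE, prod(dims[1:3]))
  in_mask[centers] <- TRUE
  for (i in seq_along(centers)) {
    nb <- sweep(off, 2, cc[i, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nb <- nb[ok, , drop = FALSE]
    lin <- nb[, 1] + (nb[, 2] - 1) * dims[1] +
      (nb[, 3] - 1) * dims[1] * dims[2]
    lin <- lin[in_mask[lin]]
    if (length(lin) < 2) next
    pat <- t(vmat[lin, , drop = FALSE])  # trials x voxels
    if (normalize) {
      s <- apply(pat, 2, stats::sd)
      keep <- s > 0
      if (sum(keep) < 2) next
      pat <- sweep(pat[, keep, drop = FALSE], 2, s[keep], "/")
    }
    pat <- pat[ord, , drop = FALSE]
    rowsd <- apply(pat, 1, stats::sd)
    if (any(rowsd == 0)) next
    y <- 1 - stats::cor(t(pat))
    yv <- zscore(y[lt])
    if (anyNA(yv)) next
    beta <- drop(P %*% yv)
    res <- yv - drop(X %*% beta)
    se <- sqrt(diag(XtXinv) * sum(res^2) / df)
    tmap[centers[i]] <- beta[2] / se[2]
    bmap[centers[i]] <- beta[2]
  }
  structure(list(t = tmap, beta = bmap, mask = mask, radius_mm = radius_mm,
                 voxel_size_mm = voxel_size_mm, n_offsets = nrow(off),
                 df = df),
            class = "ca_searchlight")
}

#' @export
print.ca_searchlight <- function(x, ...) {
  cat(sprintf(
    "<ca_searchlight> %s grid, %d in-mask centers, radius %.1f mm\n",
    paste(dim(x$t), collapse = "x"), sum(x$mask), x$radius_mm))
  invisible(x)
}

#' Valence-split RSA
#'
#' Z-scores the trial-wise prediction errors (within participant) and
#' splits trials at the z-scored sign into positive- and negative-PE
#' subsets, then runs the identity + autocorrelation RDM regression in
#' each subset.  Subsets in which some stimulus has fewer than 2 trials
#' are flagged; subsets too small to analyze get `NA` estimates.
#'
#' @param pattern_set a `ca_patterns` object or named list of them (e.g.
#'   the `choice`/`feedback` pair from [generate_patterns()]).
#' @param delta per-trial prediction errors; defaults to the object's meta.
#' @return data.frame with `phase`, `valence`, `beta_identity`, `se`, `t`,
#'   `p`, `n_trials`, `flagged`.
#' @export
valence_split_rsa <- function(pattern_set, delta = NULL) {
  if (inherits(pattern_set, "ca_patterns"))
    pattern_set <- stats::setNames(list(pattern_set), pattern_set$phase)
  out <- list()
  for (ps in pattern_set) {
    dl <- delta %||% ps$meta$delta
    stopifnot(length(dl) == nrow(ps$patterns))
    z <- zscore(dl)
    if (anyNA(z)) stop("prediction errors are constant; cannot split")
    for (val in c("positive", "negative")) {
      sel <- if (val == "positive") z >= 0 else z < 0
      n <- sum(sel)
      all_stim <- sort(unique(ps$meta$stimulus_id))
      counts <- table(factor(ps$meta$stimulus_id[sel], levels = all_stim))
      flagged <- n < 4 || length(unique(ps$meta$stimulus_id[sel])) < 2 ||
        any(counts < 2)
      row <- data.frame(phase = ps$phase, valence = val,
                        beta_identity = NA_real_, se = NA_real_,
                        t = NA_real_, p = NA_real_, n_trials = n,
                        flagged = flagged, stringsAsFactors = FALSE)
      if (n >= 4 && length(unique(ps$meta$stimulus_id[sel])) >= 2) {
        rdm <- neural_rdm(ps$patterns[sel, , drop = FALSE],
                          stimulus = ps$meta$stimulus_id[sel],
                          trial_index = ps$meta$trial_index[sel])
        reg <- rdm_regression(rdm, include = c("identity", "autocorr"))
        idr <- reg[reg$term == "identity", ]
        row$beta_identity <- idr$beta; row$se <- idr$se
        row$t <- idr$t; row$p <- idr$p
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}
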