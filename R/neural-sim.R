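#' Synthetic voxel-pattern configuration
#'
#' Controls the generative structure of simulated trial-wise multivoxel
#' patterns: a stimulus-identity code of configurable strength per task
#' phase, an optional expected-value code, cross-phase overlap `kappa`
#' between the choice and feedback identity prototypes (`kappa = 1`:
#' identical prototypes; `kappa = 0`: independent), and AR(1) trial-to-trial
#' noise emulating scanner autocorrelation.
#'
#' @param n_voxels voxels per pattern (flat mode).
#' @param identity_signal strength of the stimulus-identity component;
#'   scalar or named vector `c(choice=, feedback=)`.
#' @param value_signal strength of the expected-value component.
#' @param kappa cross-phase prototype overlap in `[0, 1]`.
#' @param noise_sd stationary standard deviation of the voxel noise.
#' @param rho AR(1) coefficient of the trial-to-trial noise, in `[0, 1)`.
#' @param grid optional 3-D grid dimensions for volume mode.
#' @param voxel_size voxel edge length in mm (volume mode).
#' @return An object of class `ca_neural_config`.
#' @export
neural_config <- function(n_voxels = 60, identity_signal = 1,
                          value_signal = 0, kappa = 1, noise_sd = 1,
                          rho = 0, grid = NULL, voxel_size = 2) {
  if (length(identity_signal) == 1)
    identity_signal <- c(choice = unname(identity_signal),
                         feedback = unname(identity_signal))
  stopifnot(all(identity_signal >= 0), value_signal >= 0,
            kappa >= 0, kappa <= 1, noise_sd > 0, rho >= 0, rho < 1,
            n_voxels >= 2)
  structure(list(n_voxels = as.integer(n_voxels),
                 identity_signal = identity_signal[c("choice", "feedback")],
                 value_signal = value_signal, kappa = kappa,
                 noise_sd = noise_sd, rho = rho, grid = grid,
                 voxel_size = voxel_size),
            class = "ca_neural_config")
}

#' Generate trial-wise voxel patterns for choice and feedback
#'
#' Each non-missed trial's pattern is
#' `identity_signal[phase] * prototype(stimulus, phase) +
#'  value_signal * value_direction * V(trial) + AR(1) noise`.
#' Stimulus prototypes are orthonormal random directions; feedback
#' prototypes mix the choice prototype with an independent orthonormal
#' component as `kappa * choice + sqrt(1 - kappa^2) * independent`, so
#' `kappa` is exactly the expected cross-phase prototype correlation.
#'
#' @param data behavioral table for one participant-task.
#' @param config a [neural_config()].
#' @param values,delta optional per-trial expected values and prediction
#'   errors aligned to `data` rows (e.g. from [ca_trajectory()]); default 0.
#' @param seed integer seed (`NULL` = ambient RNG).
#' @return Named list of two `ca_patterns` objects (`choice`, `feedback`),
#'   each with `patterns` (non-missed trials x voxels) and aligned `meta`
#'   (`trial_index`, `stimulus_id`, `value`, `delta`).
#' @export
generate_patterns <- function(data, config = neural_config(),
                              values = NULL, delta = NULL, seed = NULL) {
  stopifnot(inherits(config, "ca_neural_config"))
  n_stim <- length(unique(data$stimulus_id))
  stim_levels <- sort(unique(data$stimulus_id))
  if (config$n_voxels < 2 * n_stim + 1)
    stop("need n_voxels >= 2 * n_stimuli + 1 for orthonormal prototypes")
  keep <- !data$missed
  d <- data[keep, , drop = FALSE]
  d <- d[order(d$trial_index), , drop = FALSE]
  values <- (values %||% rep(0, nrow(data)))[keep]
  delta <- (delta %||% rep(0, nrow(data)))[keep]
  if (config$value_signal > 0 && all(values == 0))
    warning("value_signal > 0 but all supplied values are 0")
  n_trials <- nrow(d)
  with_seed(seed, {
    basis <- qr.Q(qr(matrix(rnorm(config$n_voxels * (2 * n_stim + 1)),
                            config$n_voxels)))
    proto_choice <- basis[, seq_len(n_stim), drop = FALSE]
    indep <- basis[, n_stim + seq_len(n_stim), drop = FALSE]
    v_dir <- basis[, 2 * n_stim + 1]
    proto_feedback <- config$kappa * proto_choice +
      sqrt(1 - config$kappa^2) * indep
    ar1_noise <- function() {
      e <- matrix(0, n_trials, config$n_voxels)
      e[1, ] <- rnorm(config$n_voxels, sd = config$noise_sd)
      if (n_trials > 1) {
        innov_sd <- config$noise_sd * sqrt(1 - config$rho^2)
        for (t in 2:n_trials)
          e[t, ] <- config$rho * e[t - 1, ] +
            rnorm(config$n_voxels, sd = innov_sd)
      }
      e
    }
    make_phase <- function(phase, proto) {
      sig <- config$identity_signal[[phase]]
      stim_col <- match(d$stimulus_id, stim_levels)
      X <- sig * t(proto[, stim_col, drop = FALSE]) +
        config$value_signal * outer(values, v_dir) + ar1_noise()
      structure(list(phase = phase, patterns = X,
                     meta = data.frame(trial_index = d$trial_index,
                                       stimulus_id = d$stimulus_id,
                                       value = values, delta = delta)),
                class = "ca_patterns")
    }
    list(choice = make_phase("choice", proto_choice),
         feedback = make_phase("feedback", proto_feedback))
  })
}

#' @export
print.ca_patterns <- function(x, ...) {
  cat(sprintf("<ca_patterns> phase %s: %d trials x %d voxels\n",
              x$phase, nrow(x$patterns), ncol(x$patterns)))
  invisible(x)
}

#' Write and read trial-pattern volumes as NIfTI
#'
#' Embeds a flat pattern set into a contiguous cuboid signal region of a
#' 3-D grid and writes one volume per trial as a 4-D NIfTI file (double
#' precision, so the coefficient matrix round-trips bit-identically),
#' together with a binary mask volume of the signal region.
#'
#' @param pattern_set a `ca_patterns` object.
#' @param grid 3-D grid dimensions.
#' @param corner lower corner (1-based voxel coordinates) of the signal
#'   region.
#' @param region_dim dimensions of the signal region cuboid; its volume
#'   must be at least `n_voxels` (the first `n_voxels` voxels in
#'   column-major order carry the pattern).
#' @param path output path for the 4-D volume; the mask is written next to
#'   it with suffix `_mask`.
#' @param voxel_size voxel edge length in mm, recorded in the header.
#' @return Invisibly, list with `volume`, `mask` paths and the linear
#'   `voxel_indices` of the pattern voxels.
#' @export
write_volumes <- function(pattern_set, grid = c(20, 20, 20),
                          corner = c(1, 1, 1), region_dim = NULL,
                          path, voxel_size = 2) {
  stopifnot(inherits(pattern_set, "ca_patterns"), length(grid) == 3)
  n_vox <- ncol(pattern_set$patterns)
  if (is.null(region_dim)) {
    edge <- ceiling(n_vox^(1 / 3))
    region_dim <- rep(edge, 3)
  }
  if (prod(region_dim) < n_vox)
    stop("signal region smaller than the pattern (", prod(region_dim),
         " < ", n_vox, " voxels)")
  if (any(corner + region_dim - 1 > grid))
    stop("signal region does not fit in the grid")
  region_coords <- as.matrix(expand.grid(
    x = corner[1]:(corner[1] + region_dim[1] - 1),
    y = corner[2]:(corner[2] + region_dim[2] - 1),
    z = corner[3]:(corner[3] + region_dim[3] - 1)))
  lin <- region_coords[, 1] +
    (region_coords[, 2] - 1) * grid[1] +
    (region_coords[, 3] - 1) * grid[1] * grid[2]
  lin <- sort(lin)[seq_len(n_vox)]
  n_trials <- nrow(pattern_set$patterns)
  vol <- array(0, c(grid, n_trials))
  flat <- matrix(vol, prod(grid), n_trials)
  flat[lin, ] <- t(pattern_set$patterns)
  vol <- array(flat, c(grid, n_trials))
  mask <- array(0L, grid)
  mask[lin] <- 1L
  mask_path <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
  if (identical(mask_path, path)) mask_path <- paste0(path, "_mask.nii")
  RNifti::writeNifti(RNifti::asNifti(vol, pixdim = rep(voxel_size, 3)),
                     path, datatype = "double")
  RNifti::writeNifti(RNifti::asNifti(mask, pixdim = rep(voxel_size, 3)),
                     mask_path, datatype = "int16")
  invisible(list(volume = path, mask = mask_path, voxel_indices = lin))
}

#' @rdname write_volumes
#' @param volume_path,mask_path files written by `write_volumes()`.
#' @return `read_volumes()` returns a list with the trials x voxels
#'   `patterns` matrix (mask voxels in linear order), the `mask` array and
#'   the 4-D `volumes` array.
#' @export
read_volumes <- function(volume_path, mask_path) {
  vol <- as.array(RNifti::readNifti(volume_path))
  mask <- as.array(RNifti::readNifti(mask_path))
  dims <- dim(vol)
  stopifnot(length(dims) == 4, all(dim(mask) == dims[1:3]))
  flat <- matrix(vol, prod(dims[1:3]), dims[4])
  idx <- which(mask != 0)
  list(patterns = t(flat[idx, , drop = FALSE]), mask = mask != 0,
       volumes = vol, voxel_indices = idx)
}
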