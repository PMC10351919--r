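test_that("RDM entries have the correlation-distance landmarks", {
  X <- rbind(c(1, -1, 1, -1),       # r1
             c(1, -1, 1, -1),       # identical -> 0
             c(-1, 1, -1, 1),       # negation -> 2
             c(1, 1, -1, -1))       # zero-mean orthogonal -> 1
  rdm <- neural_rdm(X, stimulus = c(1, 1, 2, 2))
  expect_true(isSymmetric(rdm$d))
  expect_equal(diag(rdm$d), rep(0, 4))
  expect_equal(rdm$d[1, 2], 0)
  expect_equal(rdm$d[1, 3], 2)
  expect_equal(rdm$d[1, 4], 1)
  expect_true(all(rdm$d >= 0 & rdm$d <= 2))
})

test_that("RDMs are invariant to per-trial linear rescaling", {
  set.seed(91)
  X <- matrix(rnorm(10 * 8), 10)
  a <- runif(10, 0.5, 3)
  b <- rnorm(10)
  Y <- X * a + b
  r1 <- neural_rdm(X, stimulus = rep(1:2, 5))
  r2 <- neural_rdm(Y, stimulus = rep(1:2, 5))
  expect_equal(r1$d, r2$d, tolerance = 1e-12)
})

test_that("items are nested within stimulus and zero-variance rows are named", {
  set.seed(92)
  X <- matrix(rnorm(6 * 5), 6)
  rdm <- neural_rdm(X, stimulus = c(2, 1, 2, 1, 3, 1), trial_index = 1:6)
  expect_equal(rdm$items$stimulus, c(1, 1, 1, 2, 2, 3))
  expect_equal(rdm$items$trial_index, c(2, 4, 6, 1, 3, 5))
  X[3, ] <- 7
  expect_error(neural_rdm(X, stimulus = c(2, 1, 2, 1, 3, 1)), "trial\\(s\\): 3")
})

test_that("noise normalization rescales voxels and drops degenerate ones", {
  set.seed(93)
  X <- matrix(rnorm(8 * 4), 8)
  expect_equal(noise_normalize(X, residual_sd = rep(1, 4)), X,
               ignore_attr = TRUE)
  halved <- noise_normalize(X, residual_sd = c(2, 1, 1, 1))
  expect_equal(halved[, 1], X[, 1] / 2)
  Xz <- cbind(X, 0)
  expect_warning(out <- noise_normalize(Xz), "zero-SD")
  expect_equal(ncol(out), 4)
})

test_that("self-regression of the identity structure returns beta 1", {
  # patterns built so the neural RDM *is* the identity RDM
  proto <- rbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  X <- proto[rep(1:2, each = 3), ]
  rdm <- neural_rdm(X + 0, stimulus = rep(1:2, each = 3))
  expect_equal(unname(rdm$d[1, 4]), 1)
  reg <- rdm_regression(rdm, include = c("identity", "autocorr"))
  expect_equal(reg$beta[reg$term == "identity"], 1, tolerance = 1e-10)
  expect_equal(reg$beta[reg$term == "autocorr"], 0, tolerance = 1e-10)
})

test_that("a sole predictor's beta equals the z-scored correlation", {
  d <- simulate_agent("baseline", demo_params$baseline, seed = 94)
  p <- generate_patterns(d, neural_config(n_voxels = 30), seed = 4)$choice
  rdm <- neural_rdm(p)
  reg <- rdm_regression(rdm, include = "identity")
  lt <- lower.tri(rdm$d)
  expect_equal(reg$beta,
               cor(rdm$d[lt], identity_rdm(rdm$items)[lt]),
               tolerance = 1e-10)
})

test_that("constant predictors are dropped with a warning", {
  set.seed(95)
  X <- matrix(rnorm(8 * 6), 8)
  rdm <- neural_rdm(X, stimulus = rep(1:2, 4))
  expect_warning(
    reg <- rdm_regression(rdm, predictors = list(
      identity = identity_rdm(rdm$items),
      flat = matrix(1, 8, 8))),
    "flat")
  expect_equal(reg$term, "identity")
})

test_that("omitting a real value predictor inflates the identity beta", {
  d <- simulate_agent("vlr_ca", demo_params$vlr_ca, seed = 96)
  tr <- ca_trajectory(d, "vlr_ca", demo_params$vlr_ca)
  v <- tr$V[cbind(seq_len(60), d$stimulus_id)]
  cfg <- neural_config(n_voxels = 40, identity_signal = 1.2,
                       value_signal = 0.5, noise_sd = 1)
  betas <- t(vapply(1:25, function(k) {
    p <- generate_patterns(d, cfg, values = v, seed = 200 + k)$choice
    rdm <- neural_rdm(p)
    full <- rdm_regression(rdm, include = c("identity", "value", "autocorr"))
    no_v <- rdm_regression(rdm, include = c("identity", "autocorr"))
    c(full = full$beta[full$term == "identity"],
      value = full$beta[full$term == "value"],
      no_v = no_v$beta[no_v$term == "identity"])
  }, c(full = 0, value = 0, no_v = 0)))
  expect_gt(mean(betas[, "full"]), 0)
  expect_gt(mean(betas[, "value"]), 0)
  expect_gt(mean(betas[, "no_v"]), mean(betas[, "full"]))
})

test_that("sphere offsets match a brute-force lattice enumeration", {
  o1 <- sphere_offsets(2, 2)
  expect_equal(nrow(o1), 7)  # center + 6 face neighbors
  # independent triple loop over the bounding cube
  count <- 0
  for (dx in -5:5) for (dy in -5:5) for (dz in -5:5)
    if ((2 * dx)^2 + (2 * dy)^2 + (2 * dz)^2 <= 81) count <- count + 1
  o9 <- sphere_offsets(9, 2)
  expect_equal(nrow(o9), count)
  expect_true(all(rowSums(abs(o9) > 4.5) == 0))
  # symmetric under sign flips
  expect_setequal(apply(o9, 1, paste, collapse = ","),
                  apply(-o9, 1, paste, collapse = ","))
  # anisotropic voxels
  oa <- sphere_offsets(4, c(1, 2, 4))
  expect_true(all(oa[, 3] %in% -1:1))
})

test_that("valence-split RSA flags one-sided splits and detects planted asymmetry", {
  d <- simulate_agent("baseline", demo_params$baseline, seed = 97)
  cfg <- neural_config(n_voxels = 30, identity_signal = 1.5, noise_sd = 1)
  p <- generate_patterns(d, cfg, seed = 7)$choice
  # the split is on *z-scored* deltas, so an all-positive delta series is
  # still re-centred at its mean and both subsets stay populated
  p_all <- p
  set.seed(101)
  p_all$meta$delta <- abs(rnorm(nrow(p$patterns))) + 0.1
  res <- valence_split_rsa(p_all)
  expect_true(all(res$n_trials > 0))
  expect_equal(sum(res$n_trials), nrow(p$patterns))
  # a stimulus with < 2 trials in a subset flags that subset
  p_skew <- p
  p_skew$meta$delta <- ifelse(p_skew$meta$stimulus_id == 1, 5,
                              rnorm(nrow(p$patterns)))
  res_skew <- valence_split_rsa(p_skew)
  expect_true(res_skew$flagged[res_skew$valence == "negative"])
  # constant deltas cannot be split at all
  p_const <- p
  p_const$meta$delta <- rep(1, nrow(p$patterns))
  expect_error(valence_split_rsa(p_const), "constant")

  # identity structure carried only by positive-delta trials
  set.seed(98)
  delta <- rnorm(60)
  noise_only <- matrix(rnorm(60 * 30), 60)
  planted <- p$patterns
  planted[delta < 0, ] <- noise_only[delta < 0, ]
  ps <- structure(list(phase = "choice", patterns = planted,
                       meta = data.frame(trial_index = p$meta$trial_index,
                                         stimulus_id = p$meta$stimulus_id,
                                         delta = delta, value = 0)),
                  class = "ca_patterns")
  res2 <- valence_split_rsa(ps)
  pos_b <- res2$beta_identity[res2$valence == "positive"]
  neg_b <- res2$beta_identity[res2$valence == "negative"]
  expect_gt(pos_b, neg_b)
  # z-scored split of a roughly symmetric delta keeps subsets comparable
  expect_lt(abs(res2$n_trials[1] - res2$n_trials[2]), 0.25 * 60)
})

test_that("searchlight equals the standalone ROI analysis at each center", {
  d <- simulate_agent("baseline", demo_params$baseline, seed = 99)
  p <- generate_patterns(d, neural_config(n_voxels = 27,
                                          identity_signal = 1), seed = 8)
  grid <- c(7, 7, 7)
  path <- file.path(tempdir(), "sl.nii")
  info <- write_volumes(p$choice, grid = grid, corner = c(3, 3, 3),
                        region_dim = c(3, 3, 3), path = path)
  vols <- read_volumes(info$volume, info$mask)
  mask <- array(TRUE, grid)
  sl <- searchlight(vols$volumes, mask, stimulus = p$choice$meta$stimulus_id,
                    trial_index = p$choice$meta$trial_index,
                    radius_mm = 4, voxel_size_mm = 2)
  expect_equal(dim(sl$t), grid)
  # a sphere with no informative voxels is NaN
  expect_true(is.nan(sl$t[1, 1, 1]))
  # oracle: standalone pipeline on the same sphere voxels
  for (center in list(c(4, 4, 4), c(3, 4, 5))) {
    roi <- roi_extract(sl$t, center, radius_mm = 4, voxel_size_mm = 2)
    flat <- matrix(vols$volumes, prod(grid), dim(vols$volumes)[4])
    pat <- t(flat[roi$indices, , drop = FALSE])
    keep <- apply(pat, 2, sd) > 0
    pat <- noise_normalize(pat[, keep, drop = FALSE])
    rdm <- neural_rdm(pat, stimulus = p$choice$meta$stimulus_id,
                      trial_index = p$choice$meta$trial_index)
    reg <- rdm_regression(rdm, include = c("identity", "autocorr"))
    expect_equal(sl$t[center[1], center[2], center[3]],
                 reg$t[reg$term == "identity"], tolerance = 1e-8)
  }
})
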