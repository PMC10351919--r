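test_that("pattern generation is a pure function of config and seed", {
  d <- simulate_agent("baseline", demo_params$baseline, seed = 81)
  cfg <- neural_config(n_voxels = 30, identity_signal = 1, kappa = 0.5,
                       rho = 0.3)
  p1 <- generate_patterns(d, cfg, seed = 5)
  p2 <- generate_patterns(d, cfg, seed = 5)
  expect_identical(p1$choice$patterns, p2$choice$patterns)
  expect_identical(p1$feedback$patterns, p2$feedback$patterns)
  expect_false(identical(p1$choice$patterns,
                         generate_patterns(d, cfg, seed = 6)$choice$patterns))
  # rows = non-missed trials, metadata aligned
  dm <- simulate_agent("baseline", demo_params$baseline, seed = 82,
                       miss_rate = 0.2)
  pm <- generate_patterns(dm, cfg, seed = 1)
  expect_equal(nrow(pm$choice$patterns), sum(!dm$missed))
  expect_equal(pm$choice$meta$trial_index, dm$trial_index[!dm$missed])
})

test_that("kappa controls cross-phase prototype overlap", {
  d <- simulate_agent("baseline", demo_params$baseline, seed = 83)
  near0 <- neural_config(n_voxels = 40, identity_signal = 1,
                         noise_sd = 1e-8, kappa = 1)
  p <- generate_patterns(d, near0, seed = 2)
  expect_equal(p$choice$patterns, p$feedback$patterns, tolerance = 1e-5)
  # kappa = 0: independent prototypes, cross-phase correlation ~ 0
  p0 <- generate_patterns(d, neural_config(n_voxels = 40,
                                           identity_signal = 1,
                                           noise_sd = 1e-8, kappa = 0),
                          seed = 2)
  cors <- vapply(seq_len(nrow(p0$choice$patterns)), function(t)
    cor(p0$choice$patterns[t, ], p0$feedback$patterns[t, ]), numeric(1))
  expect_lt(max(abs(cors)), 0.05)
})

test_that("same-stimulus pattern correlations match the analytic value", {
  # x = s*u + e with unit-norm prototypes: E r ~ s^2 / (s^2 + n*sigma^2)
  d <- simulate_agent("baseline", demo_params$baseline, seed = 84)
  s <- 2; n_vox <- 50; sigma <- 0.3
  cfg <- neural_config(n_voxels = n_vox, identity_signal = s,
                       noise_sd = sigma, rho = 0)
  rs <- unlist(lapply(1:20, function(k) {
    p <- generate_patterns(d, cfg, seed = 100 + k)$choice
    out <- c()
    for (st in unique(p$meta$stimulus_id)) {
      rows <- which(p$meta$stimulus_id == st)
      pairs <- cbind(rows[-length(rows)], rows[-1])
      out <- c(out, vapply(seq_len(nrow(pairs)), function(i)
        cor(p$patterns[pairs[i, 1], ], p$patterns[pairs[i, 2], ]),
        numeric(1)))
    }
    out
  }))
  expect_equal(mean(rs), s^2 / (s^2 + n_vox * sigma^2), tolerance = 0.05)
})

test_that("volumes round-trip bit-identically through NIfTI", {
  d <- simulate_agent("baseline", demo_params$baseline, seed = 85)
  p <- generate_patterns(d, neural_config(n_voxels = 60), seed = 3)$choice
  path <- file.path(tempdir(), "trials.nii")
  info <- write_volumes(p, grid = c(12, 12, 12), corner = c(3, 3, 3),
                        region_dim = c(4, 4, 4), path = path)
  expect_equal(length(info$voxel_indices), 60)
  back <- read_volumes(info$volume, info$mask)
  expect_identical(back$patterns, unname(p$patterns))
  expect_equal(sum(back$mask), 60)
  # pattern larger than the region is an error
  expect_error(write_volumes(p, grid = c(12, 12, 12),
                             region_dim = c(3, 3, 3), path = path),
               "smaller")
  expect_error(write_volumes(p, grid = c(3, 3, 3), path = path), "fit")
})

test_that("cohort generation stores true parameters within bounds", {
  ch <- generate_cohort(n_participants = 3, model = "vlr_vca", seed = 9)
  expect_identical(ch$behavior,
                   generate_cohort(n_participants = 3, model = "vlr_vca",
                                   seed = 9)$behavior)
  expect_equal(nrow(ch$true_params), 3)
  expect_equal(sort(unique(ch$behavior$task)), c("bandit", "social"))
  b <- ca_bounds()
  for (nm in setdiff(names(ch$true_params), "participant_id")) {
    expect_true(all(ch$true_params[[nm]] >= b$lower[[nm]] &
                      ch$true_params[[nm]] <= b$upper[[nm]]))
  }
})
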