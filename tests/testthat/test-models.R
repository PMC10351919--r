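test_that("sigmoid readout has the right midpoint, saturation and closed form", {
  expect_equal(predict_investment(5, m = 1, bias = 5), 5)
  expect_equal(predict_investment(1e6, m = 1, bias = 5), 10)
  expect_equal(predict_investment(-1e6, m = 1, bias = 5), 0)
  expect_equal(predict_investment(4, m = 0.5, bias = 2, max_investment = 10),
               10 / (1 + exp(-1)), tolerance = 1e-10)
  v <- seq(-5, 25, by = 0.5)
  expect_true(all(diff(predict_investment(v, 0.7, 5)) > 0))
})

test_that("Gaussian choice probabilities normalize, are symmetric, and match direct density evaluation", {
  opt <- c(0, 2.5, 5, 7.5, 10)
  p <- choice_probabilities(5, opt)
  expect_equal(sum(p), 1)
  expect_true(all(p > 0))
  expect_equal(p[2], p[4])
  expect_equal(p[1], p[5])
  expect_equal(p[3], 1 / (1 + 2 * exp(-3.125) + 2 * exp(-12.5)),
               tolerance = 1e-12)
  expect_equal(round(p[3], 4), 0.9192)
  # oracle: explicit normal density on a grid of predictions
  for (pred in seq(0, 10, by = 1.25)) {
    dens <- stats::dnorm(opt, mean = pred, sd = 1)
    expect_equal(choice_probabilities(pred, opt), dens / sum(dens),
                 tolerance = 1e-12)
  }
})

test_that("prediction error is reward minus expectation", {
  expect_equal(prediction_error(6, 4), 2)
  expect_equal(prediction_error(3, 3), 0)
  expect_equal(prediction_error(0, 7.5), -7.5)
})

test_that("credit-assignment update splits credit as specified and conserves it", {
  v <- rep(0, 4)
  out <- update_values_ca(v, j = 2, delta = 2, lr = 0.5, ca = 0.7)
  expect_equal(out[2], 0.70)
  expect_equal(out[-2], rep(0.10, 3))
  # ca = 1 reduces to Rescorla-Wagner; ca = 0 spreads everything
  expect_equal(update_values_ca(v, 1, 2, 0.5, 1), c(1, 0, 0, 0))
  expect_equal(update_values_ca(v, 1, 2, 0.5, 0), c(0, 1, 1, 1) / 3)
  # credit conservation across the whole ca range
  for (ca in seq(0, 1, by = 0.1)) {
    for (delta in c(-3.3, 0.7, 9)) {
      out <- update_values_ca(c(1, 2, 3, 4), 3, delta, 0.4, ca)
      expect_equal(sum(out - c(1, 2, 3, 4)) / (0.4 * delta), 1,
                   tolerance = 1e-12)
    }
  }
  expect_error(update_values_ca(0.5, 1, 1, 0.5, 0.5), "2 stimuli")
})

test_that("decay update has the stated limits and arithmetic", {
  v <- c(9, 9, 9)
  expect_equal(update_values_decay(v, 1, 1, 0.5, decay = 0, prior = 5),
               c(9.5, 9, 9))
  expect_equal(update_values_decay(v, 1, 1, 0.5, decay = 1, prior = 5),
               c(9.5, 5, 5))
  expect_equal(update_values_decay(v, 1, 0, 0.5, decay = 0.5, prior = 5)[2],
               7)
})

test_that("C++ likelihood and trajectory match a straight-line R reference", {
  cfg <- task_config()
  for (m in ca_model_names()) {
    d <- simulate_agent(m, demo_params[[m]], cfg, seed = 31,
                        miss_rate = 0.1)
    ref <- ref_nll(d, m, demo_params[[m]], cfg)
    expect_equal(negative_log_likelihood(d, m, demo_params[[m]], cfg),
                 ref$nll, tolerance = 1e-12)
    tr <- ca_trajectory(d, m, demo_params[[m]], cfg)
    expect_equal(unname(tr$V), unname(ref$V), tolerance = 1e-12)
    expect_equal(tr$nll, ref$nll, tolerance = 1e-12)
  }
})

test_that("likelihood under frozen values has its closed form", {
  # lr = 0 and prior = bias freeze every prediction at half-maximum ($5)
  d <- simulate_agent("baseline", c(lr = 0.5, prior = 5, m = 1, bias = 5),
                      seed = 32)
  params <- c(lr = 0, prior = 4, m = 1, bias = 4)
  opt <- task_config()$investment_options
  p5 <- choice_probabilities(5, opt)
  idx <- match(d$investment, opt)
  expect_equal(negative_log_likelihood(d, "baseline", params),
               -sum(log(p5[idx])), tolerance = 1e-10)
  # additivity: duplicating the data doubles the frozen-value NLL
  d2 <- rbind(d, transform(d, trial_index = trial_index + 60))
  expect_equal(negative_log_likelihood(d2, "baseline", params),
               2 * negative_log_likelihood(d, "baseline", params),
               tolerance = 1e-10)
})

test_that("missed trials contribute no likelihood and freeze values", {
  d <- simulate_agent("vlr_ca", demo_params$vlr_ca, seed = 33)
  dm <- d
  dm$missed[10] <- TRUE
  dm$investment[10] <- 0
  dm$returned[10] <- 0
  tr <- ca_trajectory(dm, "vlr_ca", demo_params$vlr_ca)
  expect_equal(tr$V[11, ], tr$V[10, ])
  expect_true(is.na(tr$p_obs[10]))
})

test_that("model variants reduce to each other with tied parameters", {
  d <- simulate_agent("vlr_vca", demo_params$vlr_vca, seed = 34)
  # vlr_vca with ca_pos = ca_neg is vlr_ca, bit-identically
  p_vca <- c(lr_pos = 0.6, lr_neg = 0.3, ca_pos = 0.8, ca_neg = 0.8,
             prior = 5, m = 1, bias = 5)
  p_ca <- c(lr_pos = 0.6, lr_neg = 0.3, ca = 0.8, prior = 5, m = 1, bias = 5)
  t1 <- ca_trajectory(d, "vlr_vca", p_vca)
  t2 <- ca_trajectory(d, "vlr_ca", p_ca)
  expect_identical(t1$V, t2$V)
  expect_identical(t1$nll, t2$nll)
  # vlr_ca with ca = 1 and tied learning rates is the baseline
  p_ca1 <- c(lr_pos = 0.4, lr_neg = 0.4, ca = 1, prior = 5, m = 1, bias = 5)
  p_base <- c(lr = 0.4, prior = 5, m = 1, bias = 5)
  t3 <- ca_trajectory(d, "vlr_ca", p_ca1)
  t4 <- ca_trajectory(d, "baseline", p_base)
  expect_identical(t3$V, t4$V)
  expect_identical(t3$nll, t4$nll)
})

test_that("likelihood is invariant to relabeling the irrelevant stimuli", {
  d <- simulate_agent("vlr_ca", demo_params$vlr_ca, seed = 35)
  perm <- c(3L, 1L, 4L, 2L)
  dp <- d
  dp$stimulus_id <- perm[d$stimulus_id]
  expect_equal(negative_log_likelihood(dp, "vlr_ca", demo_params$vlr_ca),
               negative_log_likelihood(d, "vlr_ca", demo_params$vlr_ca),
               tolerance = 1e-12)
})

test_that("simulated agents are reproducible and learn the reward structure", {
  p <- demo_params$vlr_ca
  expect_identical(simulate_agent("vlr_ca", p, seed = 36),
                   simulate_agent("vlr_ca", p, seed = 36))
  means <- t(vapply(1:60, function(s) {
    d <- simulate_agent("vlr_ca", p, seed = 400 + s)
    c(high = mean(d$investment[d$condition == "high"]),
      low = mean(d$investment[d$condition == "low"]))
  }, c(high = 0, low = 0)))
  expect_gt(mean(means[, "high"]), mean(means[, "low"]))
})

test_that("credit spreading abolishes (and inverts) stimulus discrimination", {
  # high-minus-low mean investment as a function of the ca parameter:
  # ca = 1 discriminates; ca = 1/n gives every stimulus an equal share of
  # each update (identical value trajectories, the single-state learner);
  # ca = 0 credits only the unengaged stimuli, reversing discrimination.
  diff_at <- function(ca, seeds) {
    p <- c(lr_pos = 0.6, lr_neg = 0.6, ca = ca, prior = 5, m = 1, bias = 5)
    mean(vapply(seeds, function(s) {
      d <- simulate_agent("vlr_ca", p, seed = 600 + s)
      m <- vapply(split(d$investment, d$condition), mean, numeric(1))
      m[["high"]] - m[["low"]]
    }, numeric(1)))
  }
  expect_gt(diff_at(1, 1:60), 2)
  expect_lt(abs(diff_at(0.25, 1:60)), 1)
  expect_lt(diff_at(0, 1:60), 0)
  # equal-share updates keep the value columns identical
  p <- c(lr_pos = 0.6, lr_neg = 0.6, ca = 0.25, prior = 5, m = 1, bias = 5)
  d <- simulate_agent("vlr_ca", p, seed = 601)
  V <- ca_trajectory(d, "vlr_ca", p)$V
  expect_lt(max(apply(V, 1, function(r) diff(range(r)))), 1e-12)
})
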