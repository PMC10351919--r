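test_that("a hand-enumerated toy sequence pairs lags correctly", {
  # stimuli 1,2,1,1,2,1,2,2 with returns 1..8; relevant lag-1 partners
  # derived by hand: t3->t1, t4->t3, t5->t2, t6->t4, t7->t5, t8->t7
  toy_task <- function(task) data.frame(
    participant_id = "p1", task = task, trial_index = 1:8,
    stimulus_id = c(1, 2, 1, 1, 2, 1, 2, 2), condition = "high",
    investment = c(5, 5, 2.5, 7.5, 5, 10, 0, 2.5),
    returned = 1:8, missed = FALSE, stringsAsFactors = FALSE)
  d <- rbind(toy_task("social"), toy_task("bandit"))
  des <- build_lagged_design(d, n_lags = 1)
  soc <- des$design[des$design$rel1_social != 0 |
                      des$design$irrel1_social != 0, ]
  expect_equal(soc$rel1_social, c(1, 3, 2, 4, 5, 7))
  expect_equal(soc$irrel1_social, c(2, 3, 4, 5, 6, 7))
  # trial 1 of each stimulus is excluded (no relevant history)
  expect_equal(des$n_dropped, 4L)
})

test_that("the design has 13 coefficients and matches brute-force pairing", {
  d <- two_task_agent("vlr_ca", demo_params$vlr_ca, seed = 71,
                      miss_rate = 0.1)
  des <- build_lagged_design(d)
  expect_length(des$terms, 12)
  fit <- fit_lagged_model(des)
  expect_equal(nrow(fit$coefficients), 13)
  # brute-force oracle for every row of every task
  for (tk in c("social", "bandit")) {
    dd <- d[d$task == tk & !d$missed, ]
    dd <- dd[order(dd$trial_index), ]
    expected <- list()
    for (i in seq_len(nrow(dd))) {
      lags <- c(vapply(1:3, function(n) bf_lag(dd, i, n, TRUE), 0),
                vapply(1:3, function(n) bf_lag(dd, i, n, FALSE), 0))
      if (anyNA(lags)) next
      expected[[length(expected) + 1]] <- c(dd$investment[i], lags)
    }
    expected <- do.call(rbind, expected)
    got <- des$design[
      rowSums(des$design[, paste0(c("rel", "irrel"),
                                  rep(1:3, each = 2), "_", tk)] != 0) > 0 |
        apply(des$design[, grep(paste0("_", tk, "$"), names(des$design))],
              1, function(r) any(r != 0)),
      c("investment", paste0("rel", 1:3, "_", tk),
        paste0("irrel", 1:3, "_", tk))]
    expect_equal(unname(as.matrix(got)), unname(expected))
  }
})

test_that("missing a task is a named error", {
  d <- simulate_agent("baseline", demo_params$baseline, seed = 72)
  expect_error(build_lagged_design(d), "bandit")
})

test_that("planted lag-1 dependence is recovered exactly", {
  d <- two_task_agent("baseline", demo_params$baseline, seed = 73)
  des <- build_lagged_design(d)
  # overwrite the response with a pure relevant-lag1 signal per task
  des$design$investment <- 0.5 * des$design$rel1_social +
    0.25 * des$design$rel1_bandit
  fit <- suppressWarnings(fit_lagged_model(des))  # noiseless, perfect fit
  co <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(co[["rel1_social"]], 0.5, tolerance = 1e-8)
  expect_equal(co[["rel1_bandit"]], 0.25, tolerance = 1e-8)
  others <- setdiff(names(co), c("rel1_social", "rel1_bandit"))
  expect_lt(max(abs(co[others])), 1e-8)
})

test_that("coefficients are invariant to stimulus relabeling", {
  d <- two_task_agent("vlr_ca", demo_params$vlr_ca, seed = 74)
  perm <- c(4L, 3L, 1L, 2L)
  dp <- d
  dp$stimulus_id <- perm[d$stimulus_id]
  f1 <- fit_lagged_model(build_lagged_design(d))
  f2 <- fit_lagged_model(build_lagged_design(dp))
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-10)
})

test_that("valence-split cells flag missing valences and recover planted slopes", {
  # all-gain data: every loss cell must be flagged empty
  all_gain <- function(task) {
    d <- simulate_agent("baseline", demo_params$baseline, seed = 75,
                        task = task)
    d$returned <- d$investment + 1
    d$valence <- trial_valence(d$investment, d$returned)
    d
  }
  vs <- valence_split_lag1(rbind(all_gain("social"), all_gain("bandit")))
  expect_true(all(vs$flagged[grepl("loss", vs$cell)]))
  expect_false(any(vs$flagged[grepl("gain", vs$cell)]))

  # planted gain-only dependence: gain slope ~ planted, loss slope ~ 0
  plant <- function(task, seed) {
    d <- simulate_agent("baseline", demo_params$baseline, seed = seed,
                        task = task)
    d <- d[order(d$trial_index), ]
    for (i in 2:nrow(d)) {
      prev <- max(which(d$stimulus_id[seq_len(i - 1)] == d$stimulus_id[i]),
                  -Inf)
      if (is.finite(prev) && d$returned[prev] > d$investment[prev])
        d$investment[i] <- 0.8 * d$returned[prev]
      else if (is.finite(prev)) d$investment[i] <- 2
    }
    d
  }
  vsp <- suppressWarnings(  # noiseless construction, perfect fit
    valence_split_lag1(rbind(plant("social", 76), plant("bandit", 77))))
  g <- vsp[vsp$cell == "relevant_gain" & !vsp$flagged, ]
  l <- vsp[vsp$cell == "relevant_loss" & !vsp$flagged, ]
  expect_true(all(abs(g$estimate - 0.8) < 1e-6))
  if (nrow(l)) expect_true(all(abs(l$estimate) < 1e-6))
})

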