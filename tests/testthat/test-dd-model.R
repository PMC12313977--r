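test_that("subjective value matches the hyperbolic closed form", {
  expect_equal(subjective_value(10000, 0, 0.017), 10000)
  # indifference with the 10,000 immediate: 45000/(1+kD) = 10000 at k = 3.5/62
  expect_equal(subjective_value(45000, 62, 3.5 / 62), 10000)
  expect_equal(subjective_value(48000, 180, 0.017), 48000 / (1 + 0.017 * 180))
  expect_equal(subjective_value(5000, 10, 0), 5000)
  expect_error(subjective_value(-1, 0, 0.01), "domain error")
  expect_error(subjective_value(100, -2, 0.01), "domain error")
  expect_error(subjective_value(100, 2, -0.01), "domain error")
})

test_that("discounting is strictly monotone in delay and rate", {
  set.seed(4)
  for (i in 1:25) {
    a <- runif(1, 11000, 48000)
    k <- runif(1, 1e-4, 0.5)
    d <- sort(sample(0:180, 10))
    sv <- subjective_value(a, d, k)
    expect_true(all(diff(sv) < 0))
    ks <- sort(runif(5, 1e-4, 0.5))
    expect_true(all(diff(subjective_value(a, 30, ks)) < 0))
  }
})

test_that("choice probability is a proper logistic rule", {
  expect_equal(choice_probability(8000, 8000, 0.3), 0.5)
  expect_equal(choice_probability(12000, 9000, 0), 0.5)
  expect_equal(choice_probability(1000, 0, 0.001), 1 / (1 + exp(-1)))
  p1 <- choice_probability(c(9000, 11000), 10000, 2e-3)
  expect_equal(p1 + choice_probability(10000, c(9000, 11000), 2e-3), c(1, 1))
  diffs <- seq(-5000, 5000, by = 500)
  expect_true(all(diff(choice_probability(10000 + diffs, 10000, 1e-3)) > 0))
  expect_error(choice_probability(1, 2, -0.1), "domain error")
})

test_that("flat choice rule gives exactly n*log(2) and saturation gives ~0", {
  ts <- generate_trial_set()
  choices <- rep(c(0L, 1L), 60)
  expect_identical(dd_negloglik(0.02, 0, choices, ts), 120 * log(2))
  # an always-delayed chooser under tiny k and large beta is modeled almost
  # surely correctly
  expect_lt(dd_negloglik(1e-5, 1, rep(1L, 120), ts), 1e-6)
})

test_that("vectorized likelihood equals the naive loop oracle", {
  ts <- generate_trial_set()
  set.seed(7)
  for (i in 1:200) {
    k <- 10^runif(1, -5, 0)
    beta <- 10^runif(1, -6, 0)
    choices <- rbinom(120, 1, runif(1, 0.1, 0.9))
    expect_equal(dd_negloglik(k, beta, choices, ts),
                 nll_loop_oracle(k, beta, choices, ts),
                 tolerance = 1e-10)
  }
  expect_error(dd_negloglik(0.01, 0.001, rep(1L, 100), ts), "misaligned")
})

test_that("a noiseless responder is recovered with beta at its bound", {
  ts <- generate_trial_set()
  fit <- fit_dd_subject(noiseless_choices(0.01, ts), ts)
  expect_lt(abs(fit$k - 0.01) / 0.01, 0.10)
  expect_identical(fit$boundary_flag, "beta_high")
  expect_equal(fit$log10_k, log10(fit$k))
})

test_that("degenerate choosers return bound values with flags, never raise", {
  ts <- generate_trial_set()
  all_imm <- fit_dd_subject(rep(0L, 120), ts)
  expect_identical(all_imm$boundary_flag, "k_high")
  all_del <- fit_dd_subject(rep(1L, 120), ts)
  expect_identical(all_del$boundary_flag, "k_low")
  expect_true(all_imm$nll >= 0 && all_del$nll >= 0)
})

test_that("refitting the same data is bit-identical", {
  ts <- generate_trial_set()
  set.seed(21)
  choices <- sample_choices(0.015, 1e-3, ts)
  expect_identical(fit_dd_subject(choices, ts), fit_dd_subject(choices, ts))
})

test_that("log10 k is recovered across a small stochastic cohort", {
  ts <- generate_trial_set()
  set.seed(33)
  log10k <- rnorm(30, -2.002, 0.456)
  err <- vapply(log10k, function(lk) {
    choices <- sample_choices(10^lk, 1e-3, ts)
    abs(fit_dd_subject(choices, ts)$log10_k - lk)
  }, numeric(1))
  expect_lt(median(err), 0.15)
})

test_that("recovery error does not worsen as beta grows", {
  ts <- generate_trial_set()
  log10k <- seq(-3, -1, length.out = 21)
  median_err <- vapply(c(2e-4, 2e-3), function(beta) {
    set.seed(55)
    median(vapply(log10k, function(lk) {
      abs(fit_dd_subject(sample_choices(10^lk, beta, ts), ts)$log10_k - lk)
    }, numeric(1)))
  }, numeric(1))
  expect_lte(median_err[2], median_err[1] + 0.02)  # Monte-Carlo slack
})

test_that("cohort fitting preserves subject alignment", {
  ts <- generate_trial_set()
  set.seed(8)
  ks <- c(0.002, 0.02, 0.2)
  choices <- do.call(rbind, lapply(seq_along(ks), function(i) {
    data.frame(subject_id = paste0("P", i), trial_id = ts$trial_id,
               choice = sample_choices(ks[i], 2e-3, ts))
  }))
  fits <- fit_dd_cohort(choices, ts)
  expect_equal(fits$subject_id, c("P1", "P2", "P3"))
  expect_true(all(diff(fits$k) > 0))  # ordering of true rates preserved
  expect_error(fit_dd_cohort(choices[-5, ], ts), "does not cover")
})
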