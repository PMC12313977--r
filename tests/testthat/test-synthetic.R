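test_that("the generator is byte-for-byte reproducible under a fixed seed", {
  cfg <- sim_config(n_subjects = 40)
  expect_identical(simulate_cohort(cfg, seed = 9), simulate_cohort(cfg, seed = 9))
  expect_false(identical(simulate_cohort(cfg, seed = 9)$cohort,
                         simulate_cohort(cfg, seed = 10)$cohort))
})

test_that("a fully null configuration generates no X-M-Y association", {
  cfg <- sim_config(n_subjects = 20000, a_true = 0, b_true = 0,
                    c_prime_true = 0)
  sim <- simulate_cohort(cfg, seed = 77)
  co <- sim$cohort
  expect_lt(abs(cor(co$reappraisal, co$vs_gmv)), 0.02)
  expect_lt(abs(cor(co$reappraisal, co$log10_k)), 0.02)
  expect_lt(abs(cor(co$vs_gmv, co$log10_k)), 0.02)
})

test_that("the default cohort mean log10 k sits within its sampling bound", {
  sim <- simulate_cohort(sim_config(), seed = 1)
  expect_lt(abs(mean(sim$cohort$log10_k) - (-2.002)), 3 * 0.456 / sqrt(155))
})

test_that("generator moments converge to every configured target", {
  cfg <- sim_config(n_subjects = 50000)
  sim <- simulate_cohort(cfg, seed = 123)
  co <- sim$cohort
  n <- nrow(co)
  # tolerance: 1% of the target, widened to 4 standard errors where the
  # target's own sampling noise at this n is the larger of the two
  check <- function(observed, target, se) {
    expect_lt(abs(observed - target), max(0.01 * abs(target), 4 * se))
  }
  check(mean(co$log10_k), cfg$log10k_mean, cfg$log10k_sd / sqrt(n))
  check(sd(co$log10_k), cfg$log10k_sd, cfg$log10k_sd / sqrt(2 * n))
  check(mean(co$reappraisal), cfg$reappraisal_mean, cfg$reappraisal_sd / sqrt(n))
  check(sd(co$reappraisal), cfg$reappraisal_sd, cfg$reappraisal_sd / sqrt(2 * n))
  check(mean(co$suppression), cfg$suppression_mean, cfg$suppression_sd / sqrt(n))
  check(sd(co$suppression), cfg$suppression_sd, cfg$suppression_sd / sqrt(2 * n))
  check(mean(co$vs_gmv), cfg$m_mean, cfg$m_sd / sqrt(n))
  check(sd(co$vs_gmv), cfg$m_sd, cfg$m_sd / sqrt(2 * n))
  check(mean(co$age), cfg$age_mean, cfg$age_sd / sqrt(n))
  check(sd(co$age), cfg$age_sd, cfg$age_sd / sqrt(2 * n))
  check(mean(co$education_years), cfg$education_mean, cfg$education_sd / sqrt(n))
  check(mean(co$tiv), cfg$tiv_mean, cfg$tiv_sd / sqrt(n))
  check(mean(co$sex), cfg$p_female, sqrt(cfg$p_female * (1 - cfg$p_female) / n))
  check(mean(co$handedness), cfg$p_right, sqrt(cfg$p_right * (1 - cfg$p_right) / n))
  # item reliability lands on the calibrated targets
  imap <- erq_item_map()
  items <- as.matrix(sim$erq_items[paste0("item_", 1:10)])
  expect_lt(abs(cronbach_alpha(items[, imap$reappraisal]) - cfg$reappraisal_alpha), 0.01)
  expect_lt(abs(cronbach_alpha(items[, imap$suppression]) - cfg$suppression_alpha), 0.01)
})

test_that("noiseless choices recover every subject's rate within menu resolution", {
  ts <- generate_trial_set()
  set.seed(44)
  log10k <- rnorm(20, -2.002, 0.456)
  for (lk in log10k) {
    fit <- fit_dd_subject(noiseless_choices(10^lk, ts), ts)
    # deterministic choices identify k only up to the cell of the menu's
    # indifference-rate partition; the fit must land inside that cell
    cell <- identified_interval(10^lk, ts)
    expect_gte(fit$k, cell[1] * (1 - 1e-6))
    expect_lte(fit$k, cell[2] * (1 + 1e-6))
  }
})

test_that("configurations implying degenerate rates or variances are flagged", {
  # paths too strong for the requested marginal variance of the mediator
  expect_error(sim_config(a_true = -0.01, m_sd = 0.05),
               "exceed the marginal variance")
  expect_error(sim_config(b_true = 50),
               "exceed the marginal variance of log10 k")
  expect_error(sim_config(n_subjects = 5), "at least 10")
  expect_warning(simulate_cohort(sim_config(log10k_mean = 0.4, b_true = 0.5),
                                 seed = 2),
                 "outside")
})

test_that("a minimal cohort passes end-to-end and reports every stage", {
  cfg <- sim_config(n_subjects = 12, p_right = 0.5, p_female = 0.5, seed = 6)
  rep <- suppressWarnings(end_to_end_check(cfg, n_boot = 1000))  # tiny-n
  # bootstrap legitimately warns about redraw frequency
  expect_s3_class(rep, "end_to_end_report")
  expect_true(is.finite(rep$recovery$median_abs_err_log10k))
  expect_true(is.finite(rep$mediation$ab))
  expect_identical(rep$classification$label %in% c("none", "partial", "full-pattern"),
                   TRUE)
  expect_true(all(c("reappraisal", "suppression") %in%
                  names(rep$correlations)))
})

test_that("stage failures are labelled with the failing stage", {
  cfg <- sim_config(n_subjects = 12, seed = 3)  # tiny n, default handedness:
  # the mediation stage can fail on a constant covariate; whatever stage
  # fails must be named in the error
  err <- suppressWarnings(tryCatch(end_to_end_check(cfg, n_boot = 1000),
                                   error = identity))
  if (inherits(err, "error")) expect_match(conditionMessage(err), "\\[stage ")
  else succeed("pipeline completed on this draw")
})

test_that("the planted-effect pipeline recovers rates and mediation sign", {
  rep <- suppressWarnings(end_to_end_check(sim_config(), n_boot = 1000, seed = 4))
  expect_lt(rep$recovery$median_abs_err_log10k, 0.15)
  expect_true(rep$sign_recovered)
  expect_gt(rep$recovery$cor_fitted_true, 0.8)
})
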