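test_that("total effect decomposes exactly on arbitrary data", {
  for (seed in 1:10) {
    rd <- rand_mediation_data(n = 80, q = seed %% 4, seed = seed)
    mp <- fit_mediation_paths(rd$data, rd$design)
    expect_lt(abs(mp$c - (mp$c_prime + mp$ab)), 1e-10)
  }
})

test_that("a null b path gives an indirect effect within noise of zero", {
  set.seed(42)
  n <- 20000
  dat <- data.frame(x = rnorm(n, 25, 6), z1 = rnorm(n))
  dat$m <- 0.3 - 0.01 * dat$x + 0.2 * dat$z1 + rnorm(n)
  dat$y <- -2 + 0.05 * dat$x + 0.1 * dat$z1 + rnorm(n)  # Y independent of M given X, C
  mp <- fit_mediation_paths(dat, mediation_design(x = "x", m = "m", y = "y",
                                                  covariates = "z1"))
  expect_lt(abs(mp$ab), 3 * mp$se_ab)
})

test_that("indirect effect is invariant to mediator and covariate rescaling", {
  rd <- rand_mediation_data(n = 150, q = 3, seed = 99)
  base <- fit_mediation_paths(rd$data, rd$design)

  scaled <- rd$data
  s <- 0.037
  scaled$m <- scaled$m * s
  mp_s <- fit_mediation_paths(scaled, rd$design)
  expect_equal(mp_s$a, base$a * s, tolerance = 1e-10)
  expect_equal(mp_s$b, base$b / s, tolerance = 1e-10)
  expect_equal(mp_s$ab, base$ab, tolerance = 1e-10)

  affine <- rd$data
  affine$z1 <- 100 + 1e4 * affine$z1
  affine$z2 <- -5 - 0.001 * affine$z2
  mp_a <- fit_mediation_paths(affine, rd$design)
  for (fld in c("a", "b", "c", "c_prime", "ab")) {
    expect_equal(mp_a[[fld]], base[[fld]], tolerance = 1e-9)
  }
})

test_that("bootstrap is reproducible bit-for-bit under a fixed seed", {
  rd <- rand_mediation_data(n = 100, q = 2, seed = 17)
  r1 <- bootstrap_mediation(rd$data, rd$design, n_boot = 1000, seed = 5)
  r2 <- bootstrap_mediation(rd$data, rd$design, n_boot = 1000, seed = 5)
  expect_identical(r1, r2)
  r3 <- bootstrap_mediation(rd$data, rd$design, n_boot = 1000, seed = 6)
  expect_false(identical(r1$ci_ab, r3$ci_ab))
})

test_that("duplicating every row leaves estimates unchanged and narrows the CI", {
  rd <- rand_mediation_data(n = 120, q = 2, seed = 23)
  single <- bootstrap_mediation(rd$data, rd$design, n_boot = 2000, seed = 3)
  doubled <- bootstrap_mediation(rbind(rd$data, rd$data), rd$design,
                                 n_boot = 2000, seed = 3)
  for (fld in c("a", "b", "c", "c_prime", "ab")) {
    expect_equal(doubled[[fld]], single[[fld]], tolerance = 1e-10)
  }
  expect_lt(diff(doubled$ci_ab), diff(single$ci_ab))
})

test_that("percentile CI brackets the point estimate on planted-effect data", {
  cfg <- sim_config()
  sim <- simulate_cohort(cfg, seed = 2)
  res <- bootstrap_mediation(sim$cohort, mediation_design(), n_boot = 2000,
                             seed = 8)
  expect_true(res$ci_ab[1] <= res$ab && res$ab <= res$ci_ab[2])
  bca <- bootstrap_mediation(sim$cohort, mediation_design(), n_boot = 2000,
                             seed = 8, ci_type = "bca")
  expect_true(bca$ci_ab[1] < bca$ci_ab[2])
  expect_identical(bca$ci_type, "bca")
})

test_that("planted negative mediation is recovered in sign across replicates", {
  cfg <- sim_config()
  signs <- rep(NA, 500)
  for (r in 1:500) {
    sim <- simulate_cohort(cfg, seed = 30000 + r)
    mp <- tryCatch(fit_mediation_paths(sim$cohort, mediation_design()),
                   error = function(e) NULL)  # rare all-right-handed draws
    if (!is.null(mp)) signs[r] <- mp$ab < 0
  }
  expect_gt(sum(!is.na(signs)) / 500, 0.98)
  expect_gt(mean(signs, na.rm = TRUE), 0.90)
})

test_that("mediation pattern classification follows the alpha rules", {
  lab <- function(p_ab, p_cp, p_c) {
    classify_mediation(list(p_ab = p_ab, p_c_prime = p_cp, p_c = p_c))$label
  }
  # significant indirect, non-significant direct, significant total
  expect_identical(lab(0.041, 0.161, 0.042), "full-pattern")
  expect_identical(lab(0.5, 0.01, 0.01), "none")
  expect_identical(lab(0.01, 0.01, 0.001), "partial")
  cls <- classify_mediation(list(p_ab = 0.01, p_c_prime = 0.5, p_c = 0.01))
  expect_match(cls$note, "cross-sectional")
})

test_that("design validation rejects overlapping roles and tiny samples", {
  expect_error(mediation_design(x = "a", m = "a", y = "y"), "distinct")
  expect_error(mediation_design(covariates = c("age", "reappraisal")),
               "exclude")
  rd <- rand_mediation_data(n = 6, q = 3, seed = 1)
  expect_error(fit_mediation_paths(rd$data, rd$design), "too few complete cases")
})
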