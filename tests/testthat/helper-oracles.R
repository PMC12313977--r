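# independent oracles and fixture builders shared across test files

# naive per-trial likelihood summation, deliberately unvectorized
nll_loop_oracle <- function(k, beta, choices, trials, eps = 1e-12) {
  total <- 0
  for (t in seq_len(nrow(trials))) {
    sv1 <- trials$delayed_amount[t] / (1 + k * trials$delay_days[t])
    sv2 <- trials$immediate_amount[t]
    p1 <- 1 / (1 + exp(-beta * (sv1 - sv2)))
    p1 <- min(max(p1, eps), 1 - eps)
    total <- total - (choices[t] * log(p1) + (1 - choices[t]) * log(1 - p1))
  }
  total
}

# random mediation dataset with q covariates and arbitrary linear structure
rand_mediation_data <- function(n, q, seed) {
  set.seed(seed)
  cov_names <- if (q > 0) paste0("z", seq_len(q)) else character(0)
  dat <- data.frame(x = rnorm(n, 25, 6))
  for (nm in cov_names) dat[[nm]] <- rnorm(n, runif(1, -2, 2), runif(1, 0.5, 3))
  coefs <- rnorm(q + 1, 0, 0.3)
  dat$m <- 0.5 + coefs[1] * dat$x +
    (if (q > 0) as.matrix(dat[cov_names]) %*% coefs[-1] else 0) + rnorm(n)
  dat$y <- rnorm(1) + rnorm(1, 0, 0.2) * dat$x + rnorm(1) * dat$m + rnorm(n)
  list(data = dat,
       design = mediation_design(x = "x", m = "m", y = "y",
                                 covariates = cov_names))
}

# deterministic (argmax subjective value) choices for a given k
noiseless_choices <- function(k, trials) {
  sv1 <- trials$delayed_amount / (1 + k * trials$delay_days)
  as.integer(sv1 > trials$immediate_amount)
}

# the interval of rates a noiseless responder identifies: the cell of the
# partition induced by the trial menu's indifference rates k* = (A/A0 - 1)/D
# that contains the true rate. Any k in the cell reproduces the choices
# exactly, so recovery "within grid resolution" means landing in this cell.
identified_interval <- function(k_true, trials) {
  k_star <- (trials$delayed_amount / trials$immediate_amount - 1) /
    trials$delay_days
  lower <- suppressWarnings(max(k_star[k_star <= k_true]))
  upper <- suppressWarnings(min(k_star[k_star > k_true]))
  c(max(lower, 0), upper)
}

# binary choices sampled from the model
sample_choices <- function(k, beta, trials) {
  sv1 <- trials$delayed_amount / (1 + k * trials$delay_days)
  p1 <- plogis(beta * (sv1 - trials$immediate_amount))
  as.integer(runif(nrow(trials)) < p1)
}
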