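test_that("ratio arithmetic reproduces the published change-coefficient quotients", {
  # published change coefficients -> printed ratios (2 d.p.)
  expect_equal(round(icefalcon_ratio(-2.215, -0.986), 2), 2.25)
  expect_equal(round(icefalcon_ratio(1.628, 0.629), 2), 2.59)
  expect_equal(round(icefalcon_ratio(-0.210, -0.059), 2), 3.56)
  expect_true(is.na(icefalcon_ratio(0.5, 0)))
  # equal deltas -> ratio 1, not causal
  fit <- list(beta_self = 1.0, beta_cotwin = 0.8, beta_self_prime = 0.6,
              beta_cotwin_prime = 0.4, estimable = TRUE)
  ch <- icefalcon_changes(fit)
  expect_equal(ch$ratio, 1.0)
  expect_false(ch$causal_flag)
})

test_that("identical self and co-twin exposures are flagged unestimable", {
  d <- toy_pairs(30, seed = 5)
  x <- rnorm(60)
  fit <- icefalcon_fit(d$y, x, x, NULL, d$cluster)
  expect_false(fit$estimable)
  expect_error(icefalcon_changes(fit), "estimable")
})

test_that("the ratio is invariant to rescaling the exposure", {
  set.seed(19)
  n_pairs <- 150
  pairf <- rep(rnorm(n_pairs), each = 2)
  xs <- pairf + rnorm(2 * n_pairs)
  xc <- xs[rep(seq(1, 2 * n_pairs, 2), each = 2) + rep(c(1, 0), n_pairs)]
  y <- 0.5 * xs + pairf + rnorm(2 * n_pairs)
  cl <- rep(seq_len(n_pairs), each = 2)
  r1 <- icefalcon_changes(icefalcon_fit(y, xs, xc, NULL, cl))
  r2 <- icefalcon_changes(icefalcon_fit(y, 3 * xs, 3 * xc, NULL, cl))
  expect_equal(r2$ratio, r1$ratio, tolerance = 1e-5)
  expect_equal(r2$delta_self, r1$delta_self / 3, tolerance = 1e-5)
})

test_that("swapping twin labels within every pair leaves the four slopes unchanged", {
  set.seed(20)
  n_pairs <- 100
  pairf <- rep(rnorm(n_pairs), each = 2)
  xs <- pairf + rnorm(2 * n_pairs)
  swap <- seq_len(2 * n_pairs) + rep(c(1, -1), n_pairs)
  xc <- xs[swap]
  y <- 0.4 * xs + pairf + rnorm(2 * n_pairs)
  cl <- rep(seq_len(n_pairs), each = 2)
  f1 <- icefalcon_fit(y, xs, xc, NULL, cl)
  f2 <- icefalcon_fit(y[swap], xs[swap], xc[swap], NULL, cl)
  expect_equal(f2$beta_self, f1$beta_self, tolerance = 1e-10)
  expect_equal(f2$beta_cotwin, f1$beta_cotwin, tolerance = 1e-10)
  expect_equal(f2$beta_self_prime, f1$beta_self_prime, tolerance = 1e-10)
  expect_equal(f2$beta_cotwin_prime, f1$beta_cotwin_prime, tolerance = 1e-10)
})

test_that("bootstrap change p-values are seed-reproducible and stable in B", {
  set.seed(23)
  n_pairs <- 60
  pairf <- rep(rnorm(n_pairs), each = 2)
  xs <- pairf + rnorm(2 * n_pairs)
  swap <- seq_len(2 * n_pairs) + rep(c(1, -1), n_pairs)
  xc <- xs[swap]
  y <- 0.6 * xs + pairf + rnorm(2 * n_pairs)
  cl <- rep(seq_len(n_pairs), each = 2)
  b1 <- bootstrap_change_pvalues(y, xs, xc, NULL, cl, B = 150, seed = 77)
  b2 <- bootstrap_change_pvalues(y, xs, xc, NULL, cl, B = 150, seed = 77)
  expect_identical(b1, b2)
  b3 <- bootstrap_change_pvalues(y, xs, xc, NULL, cl, B = 300, seed = 78)
  # doubling B moves the p-value by no more than a few MC standard errors
  expect_lt(abs(b3$p_delta_cotwin - b1$p_delta_cotwin),
            0.2 + 4 * b1$se_delta_cotwin)
  expect_error(bootstrap_change_pvalues(y, xs, xc, NULL, cl, B = 50), "B")
})

test_that("bidirectional analysis discriminates forward from reverse causation", {
  run_dir <- function(scenario, effect, seed) {
    cfg <- sim_config(n_pairs = 400, n_sites = 6, seed = seed,
                      coverage_mean = 60,
                      effect_scenarios = data.frame(site_index = 3,
                                                    scenario = scenario,
                                                    effect_size = effect))
    sim <- simulate_cohort(cfg)
    m <- beta_to_m(compute_beta(sim$counts))
    key <- rownames(m$values)[3]
    run_bidirectional(m, sim$cohort, key, B = 0)
  }
  fwd <- run_dir("forward_causal", 6, 41)
  expect_true(fwd[direction == "methylation_to_trait"]$causal_flag)
  rev <- run_dir("reverse_causal", 0.12, 43)
  expect_true(rev[direction == "trait_to_methylation"]$causal_flag)
})
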