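test_that("coverage capping truncates to the empirical quantile and rescales counts", {
  # 9 coverages of 10 plus one of 100: the 0.9 type-7 quantile is 19
  cov <- matrix(c(rep(10, 9), 100), ncol = 1)
  meth <- matrix(c(rep(4, 9), 50), ncol = 1)
  cc <- cap_coverage(toy_counts(meth, cov), 0.9)
  q <- round(quantile(cov, 0.9, type = 7, names = FALSE))   # oracle: 19
  expect_equal(q, 19)
  expect_equal(unname(cc$cov[10, 1]), q)
  expect_equal(unname(cc$meth[10, 1]), min(round(50 * q / 100), q))
  expect_identical(unname(cc$cov[1:9, 1]), cov[1:9, 1])

  # no value above the quantile, and quantile 1.0, are identities
  flat <- toy_counts(matrix(3, 5, 2), matrix(12, 5, 2))
  expect_identical(cap_coverage(flat, 0.9)$cov, flat$cov)
  big <- toy_counts(meth, cov)
  expect_identical(cap_coverage(big, 1.0)$cov, big$cov)
  expect_error(cap_coverage(toy_counts(matrix(NA_integer_, 1, 1),
                                       matrix(NA_integer_, 1, 1))), "empty")
})

test_that("capping never increases coverage and preserves meth <= cov", {
  set.seed(4)
  cov <- matrix(rnbinom(200, mu = 30, size = 2), 20)
  meth <- matrix(rbinom(200, as.vector(cov), 0.4), 20)
  cc <- cap_coverage(toy_counts(meth, cov), 0.8)
  expect_true(all(cc$cov <= cov))
  expect_true(all(cc$meth <= cc$cov))
})

test_that("beta computation matches elementwise counts and maps 0-coverage to NA", {
  cov <- matrix(c(10, 20, 20, 0), 2)
  meth <- matrix(c(5, 0, 20, 0), 2)
  b <- compute_beta(toy_counts(meth, cov))
  expect_equal(unname(b$values[1, 1]), 0.5)
  expect_equal(unname(b$values[2, 1]), 0.0)
  expect_equal(unname(b$values[1, 2]), 1.0)
  expect_true(is.na(b$values[2, 2]))
  set.seed(8)
  cov <- matrix(rpois(60, 15), 10)
  meth <- matrix(rbinom(60, as.vector(cov), 0.3), 10)
  b2 <- compute_beta(toy_counts(meth, cov))
  expect_equal(unname(b2$values), unname(meth / ifelse(cov == 0, NA, cov)))
})

test_that("site filters use strict 'below' / 'more than' boundaries", {
  # 12 individuals; rows: mean exactly 0.01 (kept), 0.005 (dropped),
  # 11 missing (dropped), 10 missing (kept), ordinary rows
  v <- rbind(rep(0.01, 12),
             rep(0.005, 12),
             c(0.5, rep(NA, 11)),
             c(0.5, 0.5, rep(NA, 10)),
             rep(0.3, 12),
             rep(0.7, 12))
  b <- beta_matrix(data.frame(chrom = "chr1", pos = 1:6 * 100), v)
  suppressMessages(out <- filter_sites(b))
  expect_equal(out$sites$pos, c(1, 4, 5, 6) * 100)
  # two planted violations out of six -> four survivors
  expect_equal(nrow(out$sites), 4)
})

test_that("filtering order does not matter", {
  set.seed(10)
  v <- matrix(runif(30 * 15), 30)
  v[sample(length(v), 80)] <- NA
  v[1:5, ] <- v[1:5, ] / 100
  b <- beta_matrix(data.frame(chrom = "chr1", pos = 1:30 * 50), v)
  # applying mean-beta then missing filters, in either order, equals the
  # combined filter
  suppressMessages({
    both <- filter_sites(b, 0.01, 3)
    a1 <- filter_sites(filter_sites(b, 0.01, .Machine$integer.max), 0, 3)
    a2 <- filter_sites(filter_sites(b, 0, 3), 0.01, .Machine$integer.max)
  })
  expect_identical(a1$sites, a2$sites)
  expect_identical(a1$sites, both$sites)
})

test_that("M-value transform hits the closed-form anchors and is antisymmetric", {
  b <- beta_matrix(data.frame(chrom = "chr1", pos = c(100, 200, 300)),
                   matrix(c(0.5, 0.8, 0), ncol = 1))
  m <- beta_to_m(b)
  expect_equal(unname(m$values[1, 1]), 0)
  expect_equal(unname(m$values[2, 1]), 2)
  expect_equal(unname(m$values[3, 1]), log2(1e-6 / (1 - 1e-6)))
  expect_lt(abs(m$values[3, 1] + 19.93), 0.01)
  # strictly increasing + antisymmetric about 0.5
  x <- seq(0.05, 0.45, by = 0.05)
  up <- beta_to_m(beta_matrix(data.frame(chrom = "chr1", pos = seq_along(x) * 10),
                              matrix(0.5 + x, ncol = 1)))$values
  dn <- beta_to_m(beta_matrix(data.frame(chrom = "chr1", pos = seq_along(x) * 10),
                              matrix(0.5 - x, ncol = 1)))$values
  expect_true(all(diff(up[, 1]) > 0))
  expect_equal(unname(up[, 1]), unname(-dn[, 1]))
  expect_error(beta_to_m(b, eps = 0.7), "eps")
})

test_that("kernel smoothing reduces to the raw beta at isolated sites and conserves constants", {
  # isolated site (neighbours beyond bandwidth)
  cnt <- toy_counts(matrix(c(3, 5, 7), 3), matrix(c(10, 10, 10), 3),
                    pos = c(1000, 5000, 9000))
  sm <- smooth_beta(cnt, bandwidth_bp = 80)
  expect_equal(unname(sm$values), unname(compute_beta(cnt)$values))
  # constant beta across a tight cluster stays constant
  cnt2 <- toy_counts(matrix(c(4, 8, 2), 3), matrix(c(10, 20, 5), 3),
                     pos = c(1000, 1020, 1040))
  sm2 <- smooth_beta(cnt2, bandwidth_bp = 80)
  expect_equal(unname(sm2$values[, 1]), rep(0.4, 3))
  # 3-site cluster against hand-computed triangular weights
  meth <- matrix(c(2, 5, 9), 3); cov <- matrix(c(10, 10, 10), 3)
  cnt3 <- toy_counts(meth, cov, pos = c(1000, 1040, 1060))
  sm3 <- smooth_beta(cnt3, bandwidth_bp = 80)
  w <- c(1, 1 - 40 / 80, 1 - 60 / 80)          # site 1 vs sites 1..3
  expect_equal(unname(sm3$values[1, 1]), sum(w * meth) / sum(w * cov))
})
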