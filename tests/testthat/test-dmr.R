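make_track <- function(pos, p, coef = 0.1, chrom = "chr1") {
  p_track(data.frame(chrom = chrom, pos = pos, p = p, coefficient = coef))
}

test_that("Stouffer-Liptak hits the closed form and reduces to Stouffer under independence", {
  expect_equal(stouffer_liptak(0.3), 0.3)                      # single p
  # two independent p = 0.05: z = 2 * 1.6449 / sqrt(2) = 2.3262
  got <- stouffer_liptak(c(0.05, 0.05))
  zc <- 2 * qnorm(0.95) / sqrt(2)
  expect_equal(zc, 2.3262, tolerance = 1e-4)
  expect_equal(got, pnorm(zc, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(got, 4), 0.0100)
  # identity correlation over k equal p's equals plain Stouffer
  set.seed(26)
  for (k in c(2, 5, 9)) {
    p <- runif(k)
    plain <- pnorm(sum(qnorm(1 - p)) / sqrt(k), lower.tail = FALSE)
    expect_equal(stouffer_liptak(p, diag(k)), plain, tolerance = 1e-12)
  }
})

test_that("stronger positive correlation never decreases the combined p", {
  p <- c(0.01, 0.02, 0.05, 0.03)
  vals <- sapply(seq(0, 0.9, by = 0.1), function(r) {
    C <- matrix(r, 4, 4); diag(C) <- 1
    stouffer_liptak(p, C)
  })
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("non-PSD correlation matrices are repaired with a message", {
  C <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)  # not PSD
  expect_message(out <- stouffer_liptak(c(0.05, 0.1, 0.2), C), "repaired")
  expect_true(out > 0 && out < 1)
  expect_message(stouffer_liptak(c(0, 0.5)), "clamped")
})

test_that("autocorrelation estimation recovers known structure", {
  # duplicated track: every site repeated at +1 bp with the same p
  set.seed(27)
  base_p <- runif(50)
  pos <- sort(sample(1e6, 50)) * 10L
  tr <- make_track(c(rbind(pos, pos + 1L)), c(rbind(base_p, base_p)))
  acf <- estimate_acf(tr, max_lag_bp = 100, bin_bp = 50)
  expect_equal(acf$corr[1], 1)                       # lag-0 by definition
  expect_gt(acf$corr[2], 0.99)                       # first bin: duplicates
  # independent p's: all bin correlations near 0
  set.seed(28)
  tr0 <- make_track(cumsum(rpois(4000, 50) + 1L), runif(4000))
  acf0 <- estimate_acf(tr0, max_lag_bp = 500, bin_bp = 50)
  np <- acf0$n_pairs[-1]
  expect_true(all(abs(acf0$corr[-1]) <= 3 / sqrt(pmax(np, 9)) + 0.02))
  # AR(1) z-track on a regular 50 bp grid: first-bin estimate near rho
  set.seed(29)
  n <- 10000; rho <- 0.5
  z <- numeric(n); z[1] <- rnorm(1)
  for (i in 2:n) z[i] <- rho * z[i - 1] + sqrt(1 - rho^2) * rnorm(1)
  tr1 <- make_track(seq(1, by = 50, length.out = n), pnorm(z, lower.tail = FALSE))
  acf1 <- estimate_acf(tr1, max_lag_bp = 200, bin_bp = 50)
  expect_lt(abs(acf1$corr[2] - rho), 0.05)
  expect_error(estimate_acf(make_track(100, 0.5)), "2 sites")
})

test_that("p-value smoothing leaves isolated sites alone and reinforces runs", {
  acf <- estimate_acf(make_track(c(100, 150, 200, 250), runif(4)),
                      max_lag_bp = 200, bin_bp = 50)
  tr <- make_track(c(1000, 50000, 50060, 50120), c(0.4, 1e-5, 1e-5, 1e-5))
  sm <- smooth_pvalues(tr, acf, window_bp = 500)
  expect_equal(sm$p[1], 0.4)                          # isolated
  expect_lte(sm$p[3], tr$p[3])                        # centre of a tiny-p run
  sm0 <- smooth_pvalues(tr, acf, window_bp = 0)
  expect_equal(sm0$p, tr$p)                           # window 0: identity
})

test_that("region seeding and merging behave on constructed tracks", {
  # no site below threshold -> empty
  none <- find_regions(make_track(1:5 * 1000, rep(0.5, 5)))
  expect_equal(nrow(none), 0)
  # 13 consecutive sub-threshold sites spanning 321 bp -> one region of 13
  pos <- 45948412L + round(seq(0, 321, length.out = 13))
  reg <- find_regions(make_track(pos, rep(0.001, 13)), seed_p = 0.05,
                      dist_bp = 500)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$n_sites, 13L)
  expect_equal(reg$end - reg$start, 321L)
  # two clusters 10 kb apart -> two regions
  two <- find_regions(make_track(c(1000, 1100, 11000, 11100), rep(0.01, 4)))
  expect_equal(nrow(two), 2)
  # single sub-threshold site dropped by min_sites
  one <- find_regions(make_track(c(1000, 9000), c(0.01, 0.9)))
  expect_equal(nrow(one), 0)
})

test_that("region scoring reports symmetric nulls, directions and Sidak correction", {
  acf_ind <- structure(
    data.table::data.table(lag_lo = c(0, 0), lag_hi = c(0, 50),
                           corr = c(1, 0), n_pairs = 0L),
    class = c("acf_estimate", "data.table", "data.frame"))
  tr <- make_track(c(1000, 1050, 1100), rep(0.5, 3), coef = c(1, 1, 1))
  reg <- find_regions(tr, seed_p = 0.6)
  sc <- score_regions(reg, tr, acf_ind, genome_bp = 10000)
  expect_equal(sc$slk_p, 0.5, tolerance = 1e-12)      # all-0.5 independent null
  expect_equal(sc$direction, "positive")
  expect_equal(sc$sidak_p, 1 - (1 - 0.5)^(10000 / (sc$end - sc$start + 1)))
  # direction partition on a constructed 21-region layout: 11 pos, 5 neg, 5 mixed
  dirs <- c(rep("positive", 11), rep("negative", 5), rep("mixed", 5))
  res <- character(21)
  for (i in 1:21) {
    co <- switch(dirs[i], positive = c(0.2, 0.1), negative = c(-0.2, -0.1),
                 mixed = c(0.2, -0.1))
    tri <- make_track(c(1000, 1050), c(0.01, 0.01), coef = co)
    ri <- find_regions(tri)
    res[i] <- score_regions(ri, tri, acf_ind, genome_bp = 1e4)$direction
  }
  expect_identical(res, dirs)
})

test_that("region calling is translation-invariant in genomic coordinates", {
  set.seed(33)
  pos <- cumsum(rpois(200, 80) + 1L)
  p <- runif(200); p[80:86] <- 1e-4
  tr1 <- make_track(pos, p)
  tr2 <- make_track(pos + 100000L, p)
  acf <- estimate_acf(tr1, 500, 50)
  r1 <- score_regions(find_regions(smooth_pvalues(tr1, acf)), tr1, acf,
                      genome_bp = 1e6)
  r2 <- score_regions(find_regions(smooth_pvalues(tr2, acf)), tr2, acf,
                      genome_bp = 1e6)
  expect_equal(r2$start - 100000L, r1$start)
  expect_equal(r2$slk_p, r1$slk_p, tolerance = 1e-12)
})
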