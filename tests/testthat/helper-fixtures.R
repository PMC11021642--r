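# Small programmatic fixtures shared across tests.

# hand-sized count container: `cov` and `meth` given as site x individual
# matrices; positions default to 100 bp spacing on one chromosome
toy_counts <- function(meth, cov, chrom = NULL, pos = NULL) {
  meth <- as.matrix(meth); cov <- as.matrix(cov)
  if (is.null(colnames(meth)))
    colnames(meth) <- colnames(cov) <- paste0("ind", seq_len(ncol(meth)))
  if (is.null(chrom)) chrom <- rep("chr1", nrow(meth))
  if (is.null(pos)) pos <- seq(1000, by = 100, length.out = nrow(meth))
  methylation_counts(data.frame(chrom = chrom, pos = pos), meth, cov)
}

# clustered Gaussian data for GEE tests: y = intercept + slope*trait +
# pair random effect + noise
toy_pairs <- function(n_pairs, slope = 0, sd_pair = 0.7, sd_noise = 0.5,
                      seed = 1) {
  set.seed(seed)
  n <- 2 * n_pairs
  trait <- rep(rnorm(n_pairs, 30, 8), each = 2) + rnorm(n, 0, 4)
  y <- 1 + slope * trait + rep(rnorm(n_pairs, 0, sd_pair), each = 2) +
    rnorm(n, 0, sd_noise)
  list(y = y, trait = trait, cluster = rep(paste0("p", seq_len(n_pairs)), each = 2),
       X = cbind(`(Intercept)` = 1, trait = trait))
}

# independent step-up BH oracle: direct double-loop over ranks
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    r <- which(o == i)         # rank of p[i]
    cand <- vapply(r:n, function(j) p[o[j]] * n / j, 0)
    q[i] <- min(1, min(cand))
  }
  q
}
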