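# RRBS quality control and the beta -> M-value transform.
#
# Missingness convention: a site x individual cell is missing iff its
# coverage is 0 (or NA).  All filters operate on the beta matrix; site order
# is never changed by any preprocessing step.

#' Cap read coverage at an empirical quantile
#'
#' Coverage values above the chosen quantile (computed over all non-missing
#' site-by-individual coverages, type-7 interpolation, rounded half-to-even to
#' an integer cap) are truncated to the cap, and methylated counts at capped
#' cells are rescaled proportionally (rounded half-to-even), preserving
#' `count_methylated <= coverage`.  This mirrors the usual RRBS practice of
#' limiting overdispersed coverage before smoothing/modelling.
#'
#' @param counts a [methylation_counts()] object.
#' @param quantile coverage quantile in (0, 1]; 1 is the identity.
#' @return A capped [methylation_counts()] object.
#' @export
cap_coverage <- function(counts, quantile = 0.90) {
  if (quantile <= 0 || quantile > 1) stop("quantile must be in (0, 1]")
  cov <- counts$cov
  obs <- cov[!is.na(cov)]
  if (!length(obs)) stop("empty coverage matrix")
  cap <- round(stats::quantile(obs, quantile, type = 7, names = FALSE))
  over <- which(!is.na(cov) & cov > cap)
  if (length(over)) {
    meth <- counts$meth
    meth[over] <- pmin(round(meth[over] * cap / cov[over]), cap)
    cov[over] <- cap
    counts$meth <- meth
    counts$cov <- cov
  }
  counts
}

#' Compute beta-values from counts
#'
#' beta = methylated / coverage; cells with zero or missing coverage become
#' missing (NA).
#'
#' @param counts a [methylation_counts()] object.
#' @return A [beta_matrix()].
#' @export
compute_beta <- function(counts) {
  cov <- counts$cov
  cov[!is.na(cov) & cov == 0] <- NA
  beta_matrix(counts$sites, counts$meth / cov)
}

#' Filter low-signal and poorly observed sites
#'
#' Drops sites whose mean beta over non-missing individuals is below
#' `mean_beta_min`, and sites with more than `max_missing` missing
#' observations (individuals).  Both thresholds follow the usual RRBS EWAS QC:
#' a site with mean beta exactly at the threshold, or exactly `max_missing`
#' missing values, is kept.  Surviving sites keep their original order; the
#' number dropped by each rule is reported via `message()` and attached as
#' attribute `"qc"`.
#'
#' @param beta a [beta_matrix()].
#' @param mean_beta_min minimum mean beta (default 0.01).
#' @param max_missing maximum allowed missing observations per site
#'   (default 10).
#' @return Filtered [beta_matrix()] (possibly empty, with a warning).
#' @export
filter_sites <- function(beta, mean_beta_min = 0.01, max_missing = 10) {
  if (mean_beta_min < 0 || max_missing < 0) stop("thresholds must be >= 0")
  v <- beta$values
  mb <- rowMeans(v, na.rm = TRUE)
  nmiss <- rowSums(is.na(v))
  low <- !is.na(mb) & mb < mean_beta_min
  low[is.nan(mb)] <- TRUE                      # all-missing site: no signal
  manymiss <- nmiss > max_missing
  keep <- !(low | manymiss)
  message(sprintf("filter_sites: dropped %d (mean beta < %g), %d (> %d missing); %d kept",
                  sum(low), mean_beta_min, sum(manymiss), max_missing, sum(keep)))
  if (!any(keep)) warning("all sites removed by QC filters")
  out <- beta_matrix(beta$sites[keep, , drop = FALSE], v[keep, , drop = FALSE])
  attr(out, "qc") <- data.frame(rule = c("mean_beta", "missing"),
                                dropped = c(sum(low), sum(manymiss)))
  out
}

#' Transform beta-values to M-values
#'
#' M = log2(beta / (1 - beta)) after clamping beta to \[eps, 1 - eps\];
#' missing values propagate.  M-values are the variance-stabilised scale used
#' for regression.
#'
#' @param beta a [beta_matrix()].
#' @param eps clamp width in (0, 0.5).
#' @return An [m_matrix()].
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (eps <= 0 || eps >= 0.5) stop("eps must be in (0, 0.5)")
  b <- pmin(pmax(beta$values, eps), 1 - eps)
  m_matrix(beta$sites, log2(b / (1 - b)))
}

#' Kernel-smoothed beta-values
#'
#' A light-weight local smoother for RRBS data: per individual, the beta at
#' each site is the triangular-kernel-weighted ratio of methylated to total
#' counts over all sites of the same chromosome within `bandwidth_bp`
#' (weight 1 - d/bandwidth at distance d).  An isolated site therefore equals
#' its raw beta.  Cells where the weighted coverage is zero are missing.
#'
#' @param counts a [methylation_counts()] object.
#' @param bandwidth_bp kernel half-width in bp (> 0).
#' @return A [beta_matrix()] of smoothed values.
#' @export
smooth_beta <- function(counts, bandwidth_bp = 80) {
  if (bandwidth_bp <= 0) stop("bandwidth_bp must be positive")
  meth <- counts$meth; cov <- counts$cov
  meth[is.na(cov)] <- 0
  cov[is.na(cov)] <- 0
  n <- nrow(meth)
  num <- matrix(0, n, ncol(meth))
  den <- matrix(0, n, ncol(meth))
  pos <- counts$sites$pos; chrom <- counts$sites$chrom
  for (i in seq_len(n)) {
    j <- which(chrom == chrom[i] & abs(pos - pos[i]) < bandwidth_bp)
    w <- 1 - abs(pos[j] - pos[i]) / bandwidth_bp
    num[i, ] <- as.vector(w %*% meth[j, , drop = FALSE])
    den[i, ] <- as.vector(w %*% cov[j, , drop = FALSE])
  }
  sm <- num / den
  sm[den == 0] <- NA
  beta_matrix(counts$sites, sm)
}
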