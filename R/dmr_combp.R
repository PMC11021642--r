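# Autocorrelation-adjusted region calling on an EWAS p-value track:
# (1) estimate the genomic autocorrelation of the z-transformed p-values in
# distance bins; (2) replace each site's p by a Stouffer-Liptak combination
# over its window (correlation-aware smoothing); (3) seed and merge candidate
# regions from sub-threshold smoothed p's; (4) score each region by the
# Stouffer-Liptak-Kechris combined p of its member raw p-values, with a
# Sidak correction for the effective number of regions of that width.

#' Build a p-value track from EWAS results
#'
#' @param results data.table/data.frame with chrom, pos, p and coefficient
#'   columns (e.g. from [ewas_scan()]); untested sites (NA p) are dropped.
#' @return data.table sorted by (chrom, pos) with class attribute preserved
#'   columns chrom, pos, p, coefficient.
#' @export
p_track <- function(results) {
  dt <- as.data.table(results)[!is.na(p), .(chrom, pos, p, coefficient)]
  if (any(dt$p <= 0 | dt$p > 1)) {
    dt[p <= 0, p := .Machine$double.xmin]
    message("p_track: clamped non-positive p-value(s) to the smallest representable")
  }
  setorder(dt, chrom, pos)
  dt
}

#' Estimate the distance-binned autocorrelation of a p-value track
#'
#' P-values are transformed to z = qnorm(1 - p); for each distance bin
#' ((0, bin_bp], (bin_bp, 2 bin_bp], ...) the Pearson correlation over all
#' same-chromosome site pairs whose separation falls in the bin is computed.
#' Bins with fewer than 3 pairs are interpolated from neighbouring bins.
#'
#' @param track a [p_track()].
#' @param max_lag_bp largest separation considered (default 500).
#' @param bin_bp bin width (default 50).
#' @return Object of class `acf_estimate`: data.table with lag_lo, lag_hi,
#'   corr, n_pairs; the first row is the lag-0 bin with correlation 1.
#' @export
estimate_acf <- function(track, max_lag_bp = 500, bin_bp = 50) {
  if (nrow(track) < 2) stop("need at least 2 sites to estimate autocorrelation")
  z <- qnorm(pmin(pmax(track$p, 1e-300), 1 - 1e-16), lower.tail = FALSE)
  nbin <- ceiling(max_lag_bp / bin_bp)
  za <- zb <- vector("list", 64); dd <- vector("list", 64); nacc <- 0
  for (ch in unique(track$chrom)) {
    ii <- which(track$chrom == ch)
    pos <- track$pos[ii]; zz <- z[ii]
    k <- 1
    repeat {
      if (k >= length(pos)) break
      d <- pos[-seq_len(k)] - pos[seq_len(length(pos) - k)]
      keep <- which(d <= max_lag_bp)
      if (!length(keep)) break
      nacc <- nacc + 1
      za[[nacc]] <- zz[keep]; zb[[nacc]] <- zz[keep + k]; dd[[nacc]] <- d[keep]
      k <- k + 1
    }
  }
  if (nacc == 0) {
    warning("no site pairs within max_lag_bp; assuming independence")
    acf <- data.table(lag_lo = c(0, (seq_len(nbin) - 1) * bin_bp),
                      lag_hi = c(0, seq_len(nbin) * bin_bp),
                      corr = c(1, rep(0, nbin)), n_pairs = 0L)
    return(structure(acf, class = c("acf_estimate", class(acf))))
  }
  za <- unlist(za[seq_len(nacc)]); zb <- unlist(zb[seq_len(nacc)])
  dd <- unlist(dd[seq_len(nacc)])
  bin <- pmin(ceiling(dd / bin_bp), nbin)
  corr <- rep(NA_real_, nbin); npr <- integer(nbin)
  for (bidx in unique(bin)) {
    sel <- bin == bidx
    npr[bidx] <- sum(sel)
    if (npr[bidx] >= 3) {
      # symmetrised Pearson correlation (pairs counted in both orders)
      x <- c(za[sel], zb[sel]); y <- c(zb[sel], za[sel])
      if (sd(x) > 0 && sd(y) > 0) corr[bidx] <- cor(x, y)
    }
  }
  if (all(is.na(corr))) corr[] <- 0
  if (anyNA(corr)) {
    known <- !is.na(corr)
    if (sum(known) == 1) corr[] <- corr[known]
    else {
      mid <- (seq_len(nbin) - 0.5) * bin_bp
      corr <- approx(mid[known], corr[known], xout = mid, rule = 2)$y
    }
  }
  corr <- pmin(pmax(corr, -1), 1)
  acf <- data.table(lag_lo = c(0, (seq_len(nbin) - 1) * bin_bp),
                    lag_hi = c(0, seq_len(nbin) * bin_bp),
                    corr = c(1, corr), n_pairs = c(0L, npr))
  structure(acf, class = c("acf_estimate", class(acf)))
}

# correlation for a vector of pairwise distances; distances beyond the last
# bin carry the last bin's value forward
acf_lookup <- function(acf, dist) {
  bin_bp <- acf$lag_hi[2]
  nbin <- nrow(acf) - 1L
  idx <- pmin(pmax(ceiling(dist / bin_bp), 0L) + 1L, nbin + 1L)
  idx[dist == 0] <- 1L
  acf$corr[idx]
}

# correlation matrix for a set of positions on one chromosome
acf_corr_matrix <- function(acf, pos) {
  d <- abs(outer(pos, pos, "-"))
  C <- matrix(acf_lookup(acf, as.vector(d)), length(pos))
  diag(C) <- 1
  C
}

#' Stouffer-Liptak combination of correlated p-values
#'
#' Transforms p-values to z = qnorm(1 - p) and combines them as
#' sum(z) / sqrt(1' C 1) where C is the correlation matrix, returning
#' 1 - Phi of the combined z.  With the identity correlation this is the
#' classical Stouffer combination.  A non-positive-semi-definite C is
#' repaired by eigenvalue clipping at 1e-8 (then rescaled to unit diagonal),
#' with a message.  Zero p-values are clamped to the smallest positive
#' representable value, with a message.
#'
#' @param pvals numeric p-values in (0, 1].
#' @param corr correlation matrix (default identity).
#' @return combined p-value in (0, 1).
#' @export
stouffer_liptak <- function(pvals, corr = NULL) {
  k <- length(pvals)
  if (k == 0) stop("no p-values")
  if (any(pvals == 0)) {
    message("stouffer_liptak: clamped zero p-value(s)")
    pvals[pvals == 0] <- .Machine$double.xmin
  }
  if (k == 1) return(pvals)
  if (is.null(corr)) corr <- diag(k)
  if (!isTRUE(all.equal(corr, t(corr)))) stop("correlation matrix not symmetric")
  ev <- eigen(corr, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    message("stouffer_liptak: correlation matrix repaired to nearest PSD")
    vals <- pmax(ev$values, 1e-8)
    corr <- ev$vectors %*% (vals * t(ev$vectors))
    s <- sqrt(diag(corr))
    corr <- corr / tcrossprod(s)
  }
  z <- qnorm(pmin(pmax(pvals, 1e-300), 1 - 1e-16), lower.tail = FALSE)
  zc <- sum(z) / sqrt(sum(corr))
  pnorm(zc, lower.tail = FALSE)
}

#' Correlation-aware smoothing of a p-value track
#'
#' Each site's p-value is replaced by the Stouffer-Liptak combination over
#' all same-chromosome sites within `window_bp`, with pairwise correlations
#' looked up from the autocorrelation estimate by genomic distance.  A
#' window of 0 (or an isolated site) leaves p unchanged.
#'
#' @param track a [p_track()].
#' @param acf an [estimate_acf()] result.
#' @param window_bp half-window in bp (default 500).
#' @return a new track with smoothed p (column `p`); raw p kept as `p_raw`.
#' @export
smooth_pvalues <- function(track, acf, window_bp = 500) {
  out <- copy(as.data.table(track))
  out[, p_raw := p]
  if (window_bp <= 0) return(out)
  newp <- out$p
  for (ch in unique(out$chrom)) {
    ii <- which(out$chrom == ch)
    pos <- out$pos[ii]; pp <- out$p_raw[ii]
    for (a in seq_along(ii)) {
      j <- which(abs(pos - pos[a]) <= window_bp)
      if (length(j) == 1) next
      C <- acf_corr_matrix(acf, pos[j])
      newp[ii[a]] <- suppressMessages(stouffer_liptak(pp[j], C))
    }
  }
  out[, p := newp]
  out
}

#' Seed and merge candidate regions
#'
#' Sites with (smoothed) p below `seed_p` are seeds; seeds on the same
#' chromosome within `dist_bp` of each other merge into one region.  Regions
#' with fewer than `min_sites` member seeds are dropped.
#'
#' @param smoothed track from [smooth_pvalues()] (or any [p_track()]).
#' @param seed_p seeding threshold (default 0.05).
#' @param dist_bp merge distance in bp (default 500).
#' @param min_sites minimum member sites per region (default 2).
#' @return data.table with chrom, start, end, n_sites and a list column
#'   `member_pos` of member positions.
#' @export
find_regions <- function(smoothed, seed_p = 0.05, dist_bp = 500, min_sites = 2) {
  dt <- as.data.table(smoothed)
  seeds <- dt[p < seed_p]
  if (!nrow(seeds)) return(data.table(chrom = character(), start = integer(),
                                      end = integer(), n_sites = integer(),
                                      member_pos = list()))
  setorder(seeds, chrom, pos)
  seeds[, grp := cumsum(c(1, diff(pos) > dist_bp | chrom[-1] != chrom[-.N]))]
  regions <- seeds[, .(chrom = chrom[1], start = min(pos), end = max(pos),
                       n_sites = .N, member_pos = list(pos)), by = grp][, grp := NULL]
  regions[n_sites >= min_sites]
}

#' Score candidate regions
#'
#' Each region's p-value is the Stouffer-Liptak-Kechris combination of its
#' member sites' *raw* p-values under the ACF-derived correlation (bins
#' beyond the estimated range carry the last bin forward).  A Sidak
#' correction for the effective number of regions of the same width,
#' `1 - (1 - slk_p)^(genome_bp / width)`, is also reported.  The direction of
#' effect is "positive" when all member coefficients are >= 0, "negative"
#' when all are <= 0, and "mixed" otherwise.
#'
#' @param regions output of [find_regions()].
#' @param track the raw [p_track()] (with coefficients).
#' @param acf an [estimate_acf()] result.
#' @param genome_bp total track extent in bp; defaults to the summed
#'   per-chromosome span of the track.
#' @param alpha significance threshold on the SLK p (default 0.05).
#' @return data.table: chrom, start, end, n_sites, slk_p, sidak_p,
#'   direction, significant.
#' @export
score_regions <- function(regions, track, acf, genome_bp = NULL, alpha = 0.05) {
  tr <- as.data.table(track)
  if (is.null(genome_bp))
    genome_bp <- sum(tr[, .(w = max(pos) - min(pos) + 1), by = chrom]$w)
  n <- nrow(regions)
  slk <- sidak <- rep(NA_real_, n)
  dirn <- character(n)
  for (i in seq_len(n)) {
    mp <- regions$member_pos[[i]]
    sub <- tr[chrom == regions$chrom[i] & pos %in% mp]
    C <- acf_corr_matrix(acf, sub$pos)
    slk[i] <- suppressMessages(stouffer_liptak(sub$p, C))
    width <- regions$end[i] - regions$start[i] + 1
    sidak[i] <- 1 - (1 - slk[i])^(genome_bp / width)
    co <- sub$coefficient
    dirn[i] <- if (all(co >= 0)) "positive" else if (all(co <= 0)) "negative" else "mixed"
  }
  out <- data.table(chrom = regions$chrom, start = regions$start,
                    end = regions$end, n_sites = regions$n_sites,
                    slk_p = slk, sidak_p = sidak, direction = dirn,
                    significant = slk < alpha)
  setorder(out, slk_p)
  out
}

#' Full DMR-calling chain on EWAS results
#'
#' Convenience wrapper: [p_track()] -> [estimate_acf()] ->
#' [smooth_pvalues()] -> [find_regions()] -> [score_regions()].
#'
#' @param results [ewas_scan()] output.
#' @param seed_p,dist_bp,window_bp,bin_bp,max_lag_bp,min_sites,alpha tuning
#'   parameters; see the stage functions.
#' @return scored region table (see [score_regions()]).
#' @export
call_dmrs <- function(results, seed_p = 0.05, dist_bp = 500, window_bp = 500,
                      bin_bp = 50, max_lag_bp = 500, min_sites = 2,
                      alpha = 0.05) {
  track <- p_track(results)
  acf <- estimate_acf(track, max_lag_bp = max_lag_bp, bin_bp = bin_bp)
  sm <- smooth_pvalues(track, acf, window_bp = window_bp)
  regions <- find_regions(sm, seed_p = seed_p, dist_bp = dist_bp,
                          min_sites = min_sites)
  score_regions(regions, track, acf, alpha = alpha)
}
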