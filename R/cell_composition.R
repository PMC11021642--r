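# Reference-free cell-composition surrogates.
#
# Whole-blood methylation mixes cell types with distinct methylomes; without
# reference profiles, the mixture structure is recovered from the data itself:
# sites best captured by a low-rank reconstruction of the standardized beta
# matrix are the most "composition-like", and principal components of the
# individuals over those sites serve as surrogate cell-proportion covariates.

#' Impute missing beta-values by the site mean
#'
#' Missing cells are replaced by the site's mean over non-missing
#' individuals; sites missing in every individual are dropped (message).
#'
#' @param beta a [beta_matrix()].
#' @return A complete [beta_matrix()].
#' @export
impute_missing <- function(beta) {
  v <- beta$values
  allmiss <- rowSums(!is.na(v)) == 0
  if (any(allmiss)) {
    message("impute_missing: dropping ", sum(allmiss), " all-missing site(s)")
    v <- v[!allmiss, , drop = FALSE]
    beta$sites <- beta$sites[!allmiss, , drop = FALSE]
  }
  na <- which(is.na(v), arr.ind = TRUE)
  if (nrow(na)) {
    rm <- rowMeans(v, na.rm = TRUE)
    v[na] <- rm[na[, 1]]
  }
  beta_matrix(beta$sites, v)
}

#' Reference-free cell-composition components
#'
#' The feature-selected PCA procedure for cell-mixture adjustment:
#' (1) standardize each site row to mean 0 / variance 1 (zero-variance sites
#' dropped with a warning); (2) form the rank-`k` truncated-SVD
#' reconstruction; (3) score each site by the Euclidean distance between its
#' standardized row and the reconstruction; (4) keep the `t` lowest-distance
#' sites (ties broken by site order); (5) return the first `d` principal
#' component scores of the individuals over those sites.  Component signs are
#' fixed by forcing the largest-absolute-loading entry of each component
#' positive, so results are reproducible across runs and platforms.
#'
#' @param beta a complete [beta_matrix()] (run [impute_missing()] first).
#' @param k rank of the reconstruction (default 5).
#' @param t number of low-distance sites retained (default 500).
#' @param d number of component scores returned (default 5).
#' @return An object of class `cell_components`: list with `scores`
#'   (individuals x d matrix, columns PC1..PCd ordered by decreasing explained
#'   variance), `selected_sites` (site keys, length t) and `sdev`.
#' @export
refactor_components <- function(beta, k = 5, t = 500, d = 5) {
  v <- beta$values
  if (anyNA(v)) stop("beta contains missing values; impute or drop first")
  if (k < 1 || d < 1 || t < 1) stop("k, t, d must be >= 1")
  if (t > nrow(v)) stop("t exceeds the number of sites")
  mu <- rowMeans(v)
  s <- apply(v, 1, sd)
  zero <- s == 0
  if (all(zero)) stop("constant beta matrix: no variation to decompose")
  if (any(zero)) {
    warning("dropping ", sum(zero), " zero-variance site(s)")
    v <- v[!zero, , drop = FALSE]
    mu <- mu[!zero]; s <- s[!zero]
    if (t > nrow(v)) t <- nrow(v)
  }
  if (nrow(v) < k) stop("fewer sites than rank k")
  xs <- (v - mu) / s
  sv <- svd(xs, nu = k, nv = k)
  recon <- sv$u %*% (sv$d[seq_len(k)] * t(sv$v))
  dist <- sqrt(rowSums((xs - recon)^2))
  sel <- order(dist)[seq_len(t)]            # order() is stable: ties by site order
  sel <- sort(sel)                          # keep genomic order of the panel
  pr <- prcomp(t(xs[sel, , drop = FALSE]), center = TRUE, scale. = FALSE)
  if (d > ncol(pr$x)) stop("d exceeds the number of available components")
  scores <- pr$x[, seq_len(d), drop = FALSE]
  rot <- pr$rotation[, seq_len(d), drop = FALSE]
  for (j in seq_len(d)) {                   # deterministic sign convention
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      scores[, j] <- -scores[, j]
      rot[, j] <- -rot[, j]
    }
  }
  colnames(scores) <- paste0("PC", seq_len(d))
  rownames(scores) <- colnames(v)
  structure(list(scores = scores,
                 selected_sites = rownames(v)[sel],
                 sdev = pr$sdev[seq_len(d)], d = d),
            class = "cell_components")
}

#' @export
print.cell_components <- function(x, ...) {
  cat(sprintf("cell_components: %d individuals x %d components (%d panel sites)\n",
              nrow(x$scores), x$d, length(x$selected_sites)))
  invisible(x)
}
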