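# Generalized estimating equations for twin-pair clustered data.
#
# Gaussian family, identity link, exchangeable working correlation.  The
# exchangeable structure admits closed-form cluster algebra: with
# V_i = phi * [(1-rho) I + rho J] the inverse is
#   V_i^{-1} = 1/(phi(1-rho)) [I - c_i J],  c_i = rho / (1 + (n_i-1) rho),
# so every GLS quantity reduces to per-cluster row sums and the whole update
# is vectorised over clusters (no per-cluster loop).  Inference uses the
# robust (sandwich) covariance over clusters with Wald z and two-sided
# normal p-values, the GEE standard.

#' Fit a Gaussian GEE with exchangeable working correlation
#'
#' Iterates (a) a GLS coefficient update under the current working
#' correlation and (b) a moment estimate of the exchangeable correlation
#' `rho` from standardized residuals, until the largest coefficient change
#' falls below `tol` (default 1e-8) or `max_iter` iterations; non-convergence
#' is flagged, not raised.  Robust (sandwich) standard errors are computed
#' over clusters.
#'
#' @param y numeric outcome vector.
#' @param X design matrix (including intercept), full column rank; columns
#'   must be named.
#' @param cluster_ids cluster (twin-pair) labels, one per observation.
#' @param max_iter,tol iteration controls.
#' @return Object of class `gee_fit`: list with `coefficients`, `robust_se`,
#'   `z`, `p`, `rho`, `phi`, `n_clusters`, `n_obs`, `converged`.
#' @export
fit_gee_exchangeable <- function(y, X, cluster_ids, max_iter = 100, tol = 1e-8) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  if (nrow(X) != n || length(cluster_ids) != n)
    stop("y, X and cluster_ids lengths disagree")
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  f <- factor(cluster_ids, levels = unique(cluster_ids))
  n_clusters <- nlevels(f)
  if (n_clusters < 2) stop("need at least 2 clusters")
  ni <- as.vector(table(f))
  npairs_within <- sum(ni * (ni - 1) / 2)

  beta <- qr.coef(qrX, y)
  rho <- 0
  converged <- FALSE
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  for (it in seq_len(max_iter)) {
    r <- y - as.vector(X %*% beta)
    phi <- sum(r^2) / (n - p)
    if (npairs_within > p) {
      rs <- r / sqrt(phi)
      Sr <- as.vector(rowsum(rs, f))
      Sr2 <- as.vector(rowsum(rs^2, f))
      rho <- sum((Sr^2 - Sr2) / 2) / (npairs_within - p)
    } else rho <- 0
    lo <- if (max(ni) > 1) -1 / (max(ni) - 1) + 1e-6 else -0.999
    rho <- min(max(rho, lo), 0.999)
    ci <- rho / (1 + (ni - 1) * rho)
    SX <- rowsum(X, f)
    Sy <- as.vector(rowsum(y, f))
    A <- XtX - crossprod(SX, ci * SX)
    bvec <- Xty - crossprod(SX, ci * Sy)
    beta_new <- solve(A, bvec)
    delta <- max(abs(beta_new - beta))
    beta <- as.vector(beta_new)
    if (delta < tol) { converged <- TRUE; break }
  }
  names(beta) <- colnames(X)

  # sandwich covariance: bread^-1 meat bread^-1, all in closed cluster form
  r <- y - as.vector(X %*% beta)
  phi <- sum(r^2) / (n - p)
  ci <- rho / (1 + (ni - 1) * rho)
  scale <- 1 / (phi * (1 - rho))
  SX <- rowsum(X, f)
  bread <- scale * (XtX - crossprod(SX, ci * SX))
  Srw <- as.vector(rowsum(r, f))
  Mrow <- scale * (rowsum(X * r, f) - (ci * Srw) * SX)
  meat <- crossprod(Mrow)
  bi <- solve(bread)
  vc <- bi %*% meat %*% bi
  se <- sqrt(diag(vc))
  z <- beta / se
  structure(list(coefficients = beta, robust_se = setNames(se, colnames(X)),
                 z = setNames(z, colnames(X)),
                 p = setNames(2 * pnorm(-abs(z)), colnames(X)),
                 vcov = vc, rho = rho, phi = phi,
                 n_clusters = n_clusters, n_obs = n, converged = converged),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  tab <- data.frame(estimate = x$coefficients, robust_se = x$robust_se,
                    z = x$z, p = x$p)
  print(tab)
  cat(sprintf("exchangeable rho = %.4f over %d clusters%s\n", x$rho,
              x$n_clusters, if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH q-values, `q_(i) = min_{j >= i} p_(j) * n / j` capped at 1,
#' returned in input order.
#'
#' @param pvals numeric p-values in \[0, 1\]; NA/NaN raise an error.
#' @return numeric q-values.
#' @export
bh_fdr <- function(pvals) {
  if (anyNA(pvals)) stop("NA/NaN p-values")
  if (any(pvals < 0 | pvals > 1)) stop("p-values outside [0, 1]")
  p.adjust(pvals, method = "BH")
}

# assemble the per-individual covariate matrix used by the EWAS scan and
# ICE FALCON: sex, age, plus cell-composition scores when supplied
covariate_matrix <- function(cohort, components = NULL,
                             covariates = c("sex", "age")) {
  Z <- NULL
  if (length(covariates)) {
    miss <- setdiff(covariates, names(cohort))
    if (length(miss)) stop("unknown covariate(s): ", paste(miss, collapse = ", "))
    Z <- as.matrix(cohort[, covariates, drop = FALSE])
    rownames(Z) <- cohort$individual_id
  }
  if (!is.null(components)) {
    sc <- components$scores[match(cohort$individual_id, rownames(components$scores)), ,
                            drop = FALSE]
    if (anyNA(sc)) stop("cell components missing for some individuals")
    rownames(sc) <- cohort$individual_id
    Z <- if (is.null(Z)) sc else cbind(Z, sc)
  }
  Z
}

#' Per-CpG GEE association scan
#'
#' For every site, fits M-value ~ trait + covariates (+ cell components)
#' with exchangeable within-pair correlation and collects the trait
#' coefficient, robust SE, Wald z and two-sided p; BH q-values are computed
#' over all successfully tested sites.  Sites with fewer than `min_n`
#' non-missing individuals, fewer than 2 pairs represented, or a collinear
#' site-level design are reported with a `reason` instead of being dropped.
#'
#' @param m an [m_matrix()].
#' @param cohort a [twin_cohort()] covering the matrix columns.
#' @param components optional `cell_components` (see
#'   [refactor_components()]).
#' @param covariates cohort columns to adjust for (default sex and age).
#' @param min_n minimum non-missing individuals per site (default 4).
#' @return data.table with columns chrom, pos, coefficient, robust_se, z, p,
#'   q, n_used, rho, reason (NA when tested).
#' @export
ewas_scan <- function(m, cohort, components = NULL,
                      covariates = c("sex", "age"), min_n = 4) {
  ids <- colnames(m$values)
  if (!setequal(ids, cohort$individual_id))
    stop("individual ids of M matrix and cohort do not match")
  cohort <- cohort[match(ids, cohort$individual_id), ]
  Z <- covariate_matrix(cohort, components, covariates)
  ns <- nrow(m$sites)
  coefficient <- robust_se <- z <- p <- rho <- rep(NA_real_, ns)
  n_used <- integer(ns)
  reason <- rep(NA_character_, ns)
  for (i in seq_len(ns)) {
    yy <- m$values[i, ]
    ok <- !is.na(yy)
    n_used[i] <- sum(ok)
    if (n_used[i] < min_n || length(unique(cohort$pair_id[ok])) < 2) {
      reason[i] <- "insufficient_observations"
      next
    }
    X <- cbind(`(Intercept)` = 1, trait = cohort$trait[ok],
               if (!is.null(Z)) Z[ok, , drop = FALSE])
    fit <- tryCatch(
      fit_gee_exchangeable(yy[ok], X, cohort$pair_id[ok]),
      error = function(e) conditionMessage(e))
    if (is.character(fit)) { reason[i] <- fit; next }
    coefficient[i] <- fit$coefficients["trait"]
    robust_se[i] <- fit$robust_se["trait"]
    z[i] <- fit$z["trait"]
    p[i] <- fit$p["trait"]
    rho[i] <- fit$rho
    if (!fit$converged) reason[i] <- "not_converged"
  }
  q <- rep(NA_real_, ns)
  tested <- !is.na(p)
  if (any(tested)) q[tested] <- bh_fdr(p[tested])
  data.table(chrom = m$sites$chrom, pos = m$sites$pos,
             coefficient = coefficient, robust_se = robust_se, z = z,
             p = p, q = q, n_used = n_used, rho = rho, reason = reason)
}

#' Basic Manhattan plot of EWAS results
#'
#' @param results data.table from [ewas_scan()].
#' @param alpha FDR threshold used to highlight significant sites.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the plotted data.
#' @export
plot_manhattan <- function(results, alpha = 0.05, ...) {
  res <- results[!is.na(results$p), ]
  chr <- factor(res$chrom, levels = unique(res$chrom))
  offs <- c(0, cumsum(tapply(res$pos, chr, max) + 1e4))
  x <- res$pos + offs[as.integer(chr)]
  graphics::plot(x, -log10(res$p), pch = 20, cex = 0.5,
                 col = c("grey40", "steelblue")[1 + as.integer(chr) %% 2],
                 xlab = "genomic position", ylab = "-log10 p", ...)
  sig <- !is.na(res$q) & res$q < alpha
  if (any(sig)) graphics::points(x[sig], -log10(res$p[sig]), col = "firebrick", pch = 20)
  invisible(data.frame(x = x, p = res$p))
}
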