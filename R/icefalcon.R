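# ICE FALCON: Inference about Causation through Examination of FAmiliaL
# CONfounding.  Within MZ pairs, a twin's outcome is regressed on (1) their
# own exposure, (2) their co-twin's exposure, and (3) both jointly, all by
# exchangeable GEE clustered on pair.  If the exposure causes the outcome,
# conditioning on the self exposure in the joint model strips most of the
# co-twin coefficient (large |delta_cotwin|) while the self coefficient
# barely moves (small |delta_self|); under pure familial confounding both
# attenuate similarly.  The decision statistic is
# ratio = |delta_cotwin| / |delta_self|, called causal when it exceeds a
# threshold (default 1.5).

#' Fit the three ICE FALCON regression models
#'
#' Model 1: outcome ~ self exposure (+ covariates); Model 2: outcome ~
#' co-twin exposure (+ covariates); Model 3: outcome ~ both (+ covariates).
#' All fits are exchangeable GEEs clustered on twin pair.
#'
#' @param outcome_self numeric outcome, one value per individual.
#' @param exposure_self individual's own exposure.
#' @param exposure_cotwin the pair partner's exposure, aligned to the same
#'   rows.
#' @param covariates optional numeric matrix of adjustment covariates.
#' @param cluster_ids twin-pair labels.
#' @return list with `beta_self`, `beta_cotwin`, `beta_self_prime`,
#'   `beta_cotwin_prime`, `estimable` (FALSE when the self/co-twin exposures
#'   are collinear so Model 3 is rank-deficient), and the three `gee_fit`s.
#' @export
icefalcon_fit <- function(outcome_self, exposure_self, exposure_cotwin,
                          covariates = NULL, cluster_ids) {
  n <- length(outcome_self)
  stopifnot(length(exposure_self) == n, length(exposure_cotwin) == n,
            length(cluster_ids) == n)
  Z <- if (!is.null(covariates)) as.matrix(covariates)
  base <- cbind(`(Intercept)` = rep(1, n), Z)
  fit1 <- fit_gee_exchangeable(outcome_self,
                               cbind(base[, 1, drop = FALSE],
                                     exposure_self = exposure_self,
                                     base[, -1, drop = FALSE]),
                               cluster_ids)
  fit2 <- fit_gee_exchangeable(outcome_self,
                               cbind(base[, 1, drop = FALSE],
                                     exposure_cotwin = exposure_cotwin,
                                     base[, -1, drop = FALSE]),
                               cluster_ids)
  fit3 <- tryCatch(
    fit_gee_exchangeable(outcome_self,
                         cbind(base[, 1, drop = FALSE],
                               exposure_self = exposure_self,
                               exposure_cotwin = exposure_cotwin,
                               base[, -1, drop = FALSE]),
                         cluster_ids),
    error = function(e) conditionMessage(e))
  if (is.character(fit3))
    return(list(beta_self = fit1$coefficients["exposure_self"],
                beta_cotwin = fit2$coefficients["exposure_cotwin"],
                beta_self_prime = NA_real_, beta_cotwin_prime = NA_real_,
                estimable = FALSE, reason = fit3,
                fits = list(fit1, fit2, NULL)))
  list(beta_self = unname(fit1$coefficients["exposure_self"]),
       beta_cotwin = unname(fit2$coefficients["exposure_cotwin"]),
       beta_self_prime = unname(fit3$coefficients["exposure_self"]),
       beta_cotwin_prime = unname(fit3$coefficients["exposure_cotwin"]),
       estimable = TRUE, fits = list(fit1, fit2, fit3))
}

#' ICE FALCON ratio from change coefficients
#'
#' `abs(delta_cotwin) / abs(delta_self)`, with a zero self-change yielding
#' NA (undefined).  Vectorised; used both on fitted models and on published
#' change-coefficient tables.
#'
#' @param delta_cotwin,delta_self marginal-minus-joint coefficient changes.
#' @return numeric ratio(s), NA where `delta_self` is 0.
#' @export
icefalcon_ratio <- function(delta_cotwin, delta_self) {
  out <- abs(delta_cotwin) / abs(delta_self)
  out[delta_self == 0] <- NA_real_
  out
}

#' Turn the four ICE FALCON slopes into a decision record
#'
#' Computes the change coefficients (marginal minus joint), the ratio
#' `|delta_cotwin| / |delta_self|`, and the causal flag (ratio strictly above
#' `threshold`; an undefined ratio is never flagged).
#'
#' @param fit list with `beta_self`, `beta_cotwin`, `beta_self_prime`,
#'   `beta_cotwin_prime` (e.g. from [icefalcon_fit()]).
#' @param threshold decision threshold (default 1.5).
#' @return one-row data.frame with the four slopes, both deltas, `ratio` and
#'   `causal_flag`.
#' @export
icefalcon_changes <- function(fit, threshold = 1.5) {
  if (!is.null(fit$estimable) && !fit$estimable)
    stop("fit is not estimable (collinear exposures)")
  delta_self <- fit$beta_self - fit$beta_self_prime
  delta_cotwin <- fit$beta_cotwin - fit$beta_cotwin_prime
  ratio <- icefalcon_ratio(delta_cotwin, delta_self)
  data.frame(beta_self = fit$beta_self, beta_cotwin = fit$beta_cotwin,
             beta_self_prime = fit$beta_self_prime,
             beta_cotwin_prime = fit$beta_cotwin_prime,
             delta_self = delta_self, delta_cotwin = delta_cotwin,
             ratio = ratio,
             causal_flag = !is.na(ratio) & ratio > threshold)
}

#' Bootstrap p-values for the ICE FALCON change coefficients
#'
#' Twin pairs are resampled with replacement `B` times; the three models are
#' refit per replicate and the change coefficients recomputed.  Two-sided
#' p-values use the normal approximation p = 2 Phi(-|delta| / SE_boot) with
#' the bootstrap standard error.  More than 20% replicate failures is an
#' error.
#'
#' @inheritParams icefalcon_fit
#' @param B number of bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @return list with `p_delta_self`, `p_delta_cotwin`, `se_delta_self`,
#'   `se_delta_cotwin`, `B_ok`.
#' @export
bootstrap_change_pvalues <- function(outcome_self, exposure_self,
                                     exposure_cotwin, covariates = NULL,
                                     cluster_ids, B = 1000, seed = 1L) {
  if (B < 100) stop("B must be >= 100")
  point <- icefalcon_fit(outcome_self, exposure_self, exposure_cotwin,
                         covariates, cluster_ids)
  if (!point$estimable) stop("point fit not estimable")
  d_self <- point$beta_self - point$beta_self_prime
  d_cot <- point$beta_cotwin - point$beta_cotwin_prime
  f <- factor(cluster_ids, levels = unique(cluster_ids))
  rows_by_pair <- split(seq_along(cluster_ids), f)
  np <- length(rows_by_pair)
  set.seed(seed)
  bs <- bc <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    pick <- sample.int(np, np, replace = TRUE)
    idx <- unlist(rows_by_pair[pick], use.names = FALSE)
    newcl <- rep(seq_len(np), lengths(rows_by_pair)[pick])
    fb <- tryCatch(
      icefalcon_fit(outcome_self[idx], exposure_self[idx],
                    exposure_cotwin[idx],
                    if (!is.null(covariates)) covariates[idx, , drop = FALSE],
                    newcl),
      error = function(e) NULL)
    if (is.null(fb) || !fb$estimable) next
    bs[b] <- fb$beta_self - fb$beta_self_prime
    bc[b] <- fb$beta_cotwin - fb$beta_cotwin_prime
  }
  ok <- !is.na(bs)
  if (mean(ok) < 0.8) stop("more than 20% of bootstrap replicates failed")
  se_s <- sd(bs[ok]); se_c <- sd(bc[ok])
  list(p_delta_self = 2 * pnorm(-abs(d_self) / se_s),
       p_delta_cotwin = 2 * pnorm(-abs(d_cot) / se_c),
       se_delta_self = se_s, se_delta_cotwin = se_c, B_ok = sum(ok))
}

#' Bidirectional ICE FALCON over a set of CpGs
#'
#' For each requested site, runs ICE FALCON in both directions:
#' (i) methylation-to-trait — outcome is the twin's trait, exposures are the
#' own and co-twin M-values; (ii) trait-to-methylation — outcome is the
#' twin's M-value, exposures are the own and co-twin trait.  Covariates
#' (sex, age and cell components by default) enter all three models.  Pairs
#' with a missing M-value in either member are dropped for that site.
#'
#' @param m an [m_matrix()].
#' @param cohort a [twin_cohort()].
#' @param sites character site keys ("chrom:pos") to analyse.
#' @param components optional `cell_components`.
#' @param covariates cohort covariate columns (default sex, age).
#' @param threshold causal ratio threshold (default 1.5).
#' @param B bootstrap replicates for change p-values; 0 disables the
#'   bootstrap (p columns NA).
#' @param seed integer seed for the bootstrap.
#' @return data.table with one row per site x direction: the four slopes,
#'   deltas, bootstrap p-values, ratio, causal flag, n pairs used.
#' @export
run_bidirectional <- function(m, cohort, sites, components = NULL,
                              covariates = c("sex", "age"), threshold = 1.5,
                              B = 1000, seed = 1L) {
  keys <- rownames(m$values)
  missing_sites <- setdiff(sites, keys)
  if (length(missing_sites))
    stop("site(s) not in M matrix: ", paste(head(missing_sites, 3), collapse = ", "))
  cohort <- cohort[order(cohort$pair_id, cohort$individual_id), ]
  Z <- covariate_matrix(cohort, components, covariates)
  cot <- cotwin_ids(cohort)
  out <- vector("list", 2L * length(sites))
  k <- 0L
  set.seed(seed)
  site_seeds <- sample.int(.Machine$integer.max - 1L, length(sites))
  for (si in seq_along(sites)) {
    key <- sites[si]
    mv <- m$values[key, cohort$individual_id]
    mv_cot <- m$values[key, cot]
    ok <- !is.na(mv) & !is.na(mv_cot)      # complete pairs only
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    for (dir in c("methylation_to_trait", "trait_to_methylation")) {
      k <- k + 1L
      if (sum(ok) < 8 || length(unique(cohort$pair_id[ok])) < 4) {
        out[[k]] <- data.table(site = key, chrom = parts[1],
                               pos = as.integer(parts[2]), direction = dir,
                               beta_self = NA_real_, beta_cotwin = NA_real_,
                               beta_self_prime = NA_real_,
                               beta_cotwin_prime = NA_real_,
                               delta_self = NA_real_, delta_cotwin = NA_real_,
                               p_delta_self = NA_real_,
                               p_delta_cotwin = NA_real_, ratio = NA_real_,
                               causal_flag = NA, n_pairs = sum(ok) %/% 2L,
                               estimable = FALSE)
        next
      }
      if (dir == "methylation_to_trait") {
        yy <- cohort$trait[ok]; es <- mv[ok]; ec <- mv_cot[ok]
      } else {
        yy <- mv[ok]; es <- cohort$trait[ok]; ec <- cohort$trait[match(cot, cohort$individual_id)][ok]
      }
      Zok <- if (!is.null(Z)) Z[ok, , drop = FALSE]
      cl <- cohort$pair_id[ok]
      fit <- icefalcon_fit(yy, es, ec, Zok, cl)
      if (!fit$estimable) {
        out[[k]] <- data.table(site = key, chrom = parts[1],
                               pos = as.integer(parts[2]), direction = dir,
                               beta_self = unname(fit$beta_self),
                               beta_cotwin = unname(fit$beta_cotwin),
                               beta_self_prime = NA_real_,
                               beta_cotwin_prime = NA_real_,
                               delta_self = NA_real_, delta_cotwin = NA_real_,
                               p_delta_self = NA_real_,
                               p_delta_cotwin = NA_real_, ratio = NA_real_,
                               causal_flag = NA, n_pairs = sum(ok) %/% 2L,
                               estimable = FALSE)
        next
      }
      ch <- icefalcon_changes(fit, threshold)
      ps <- pc <- NA_real_
      if (B > 0) {
        bp <- bootstrap_change_pvalues(yy, es, ec, Zok, cl, B = B,
                                       seed = site_seeds[si] + (dir == "trait_to_methylation"))
        ps <- bp$p_delta_self; pc <- bp$p_delta_cotwin
      }
      out[[k]] <- data.table(site = key, chrom = parts[1],
                             pos = as.integer(parts[2]), direction = dir,
                             beta_self = ch$beta_self,
                             beta_cotwin = ch$beta_cotwin,
                             beta_self_prime = ch$beta_self_prime,
                             beta_cotwin_prime = ch$beta_cotwin_prime,
                             delta_self = ch$delta_self,
                             delta_cotwin = ch$delta_cotwin,
                             p_delta_self = ps, p_delta_cotwin = pc,
                             ratio = ch$ratio, causal_flag = ch$causal_flag,
                             n_pairs = sum(ok) %/% 2L, estimable = TRUE)
    }
  }
  rbindlist(out)
}
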