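# Monozygotic twin cohort simulator with RRBS-like count data.
#
# Generative model, per individual i (member of pair p) and site s:
#   logit beta_is = sum_c w_ic * L_sc            (cell-mixture baseline)
#                 + g_ps                          (pair-shared epigenetic term)
#                 + e_is                          (individual logit noise)
#                 [+ reverse / confounded scenario terms]
#   trait_i = trait_mean + sqrt(rho) sd u_p + sqrt(1-rho) sd r_i
#                 [+ forward / confounded scenario terms]
# where w_i ~ Dirichlet(alpha) are latent cell proportions, L_sc are per-site
# per-cell-type baseline logits, u_p and r_i are standard normal, and
# rho = pair_trait_corr so that corr(trait_1, trait_2 | pair) = rho.
# Counts: coverage ~ NegBin(mu, size); methylated ~ Binomial(coverage, beta).

#' Simulation configuration for a monozygotic twin cohort
#'
#' Defaults emulate the motivating handgrip-strength twin design: 66
#' trait-discordant MZ pairs, trait centred at 32 kg with sd 10.3 kg, a
#' within-pair trait correlation of 0.85, a minimum intra-pair discordance of
#' 0.1 kg, whole-blood-like five-cell-type composition, and overdispersed
#' RRBS coverage (negative binomial, mean 30, size 3).  The site count
#' defaults to 2000 — a deliberately scaled-down methylome; all downstream
#' operations are linear in sites so genome-scale runs only change `n_sites`.
#'
#' @param n_pairs number of twin pairs (>= 2).
#' @param n_sites number of CpG sites.
#' @param n_chroms number of chromosomes sites are spread over.
#' @param site_spacing_bp mean gap between adjacent sites (bp, exponential).
#' @param n_cell_types number of latent cell types.
#' @param dirichlet_alpha Dirichlet concentration for cell proportions;
#'   length `n_cell_types`.
#' @param trait_mean,trait_sd trait location/scale (kg).
#' @param pair_trait_corr within-pair trait correlation in \[0, 1).
#' @param discordance_min minimum intra-pair absolute trait difference (kg);
#'   pairs below it have their individual trait residuals redrawn.
#' @param effect_scenarios data.frame with columns `site_index`,
#'   `scenario` (one of "forward_causal", "reverse_causal", "confounded",
#'   "null") and `effect_size`, or NULL for a fully null cohort.
#' @param coverage_mean,coverage_dispersion negative-binomial coverage mean
#'   (`mu`) and dispersion (`size`); smaller size = more overdispersion.
#' @param noise_sd_logit sd of individual site-level logit noise.
#' @param pair_sd_logit sd of the pair-shared epigenetic term (logit scale).
#' @param baseline_sd_logit sd of per-site baseline logits across sites.
#' @param celltype_sd_logit sd of cell-type-specific deviations around a
#'   site's baseline; controls how informative sites are about composition.
#' @param seed integer seed; all randomness in [simulate_cohort()] derives
#'   from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 66L, n_sites = 2000L, n_chroms = 5L,
                       site_spacing_bp = 150, n_cell_types = 5L,
                       dirichlet_alpha = c(10, 5, 2.5, 1.5, 1),
                       trait_mean = 32, trait_sd = 10.3,
                       pair_trait_corr = 0.85, discordance_min = 0.1,
                       effect_scenarios = NULL,
                       coverage_mean = 30, coverage_dispersion = 3,
                       noise_sd_logit = 0.3, pair_sd_logit = 0.5,
                       baseline_sd_logit = 1.5, celltype_sd_logit = 1,
                       seed = 1L) {
  cfg <- list(n_pairs = as.integer(n_pairs), n_sites = as.integer(n_sites),
              n_chroms = as.integer(n_chroms),
              site_spacing_bp = site_spacing_bp,
              n_cell_types = as.integer(n_cell_types),
              dirichlet_alpha = dirichlet_alpha,
              trait_mean = trait_mean, trait_sd = trait_sd,
              pair_trait_corr = pair_trait_corr,
              discordance_min = discordance_min,
              effect_scenarios = effect_scenarios,
              coverage_mean = coverage_mean,
              coverage_dispersion = coverage_dispersion,
              noise_sd_logit = noise_sd_logit,
              pair_sd_logit = pair_sd_logit,
              baseline_sd_logit = baseline_sd_logit,
              celltype_sd_logit = celltype_sd_logit,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_pairs < 2L) stop("n_pairs must be >= 2")
  if (cfg$n_sites < 1L || cfg$n_chroms < 1L) stop("n_sites/n_chroms must be positive")
  if (length(cfg$dirichlet_alpha) != cfg$n_cell_types)
    stop("dirichlet_alpha length must equal n_cell_types")
  if (any(cfg$dirichlet_alpha <= 0)) stop("dirichlet_alpha must be positive")
  if (cfg$trait_sd < 0 || cfg$noise_sd_logit < 0 || cfg$pair_sd_logit < 0 ||
      cfg$baseline_sd_logit < 0 || cfg$celltype_sd_logit < 0)
    stop("all standard deviations must be >= 0")
  if (cfg$pair_trait_corr < 0 || cfg$pair_trait_corr >= 1)
    stop("pair_trait_corr must lie in [0, 1)")
  if (cfg$discordance_min < 0) stop("discordance_min must be >= 0")
  if (cfg$coverage_mean <= 0 || cfg$coverage_dispersion <= 0)
    stop("coverage parameters must be positive")
  if (cfg$site_spacing_bp <= 0) stop("site_spacing_bp must be positive")
  es <- cfg$effect_scenarios
  if (!is.null(es)) {
    es <- as.data.frame(es)
    if (!all(c("site_index", "scenario", "effect_size") %in% names(es)))
      stop("effect_scenarios needs site_index, scenario, effect_size")
    if (!all(es$scenario %in% c("forward_causal", "reverse_causal",
                                "confounded", "null")))
      stop("unknown scenario label")
    if (anyDuplicated(es$site_index))
      stop("scenario site indices must be unique")
    if (any(es$site_index < 1L | es$site_index > cfg$n_sites))
      stop("scenario site_index out of range")
  }
  invisible(cfg)
}

rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Simulate a trait-discordant MZ twin cohort with RRBS counts
#'
#' Generates the full study object: a [twin_cohort()] phenotype table, a
#' [methylation_counts()] container, and a ground-truth list for
#' parameter-recovery testing.  Effect scenarios plant structure at chosen
#' sites: `forward_causal` adds `effect_size * M` (latent M-value) to the
#' trait; `reverse_causal` adds `effect_size * (trait - trait_mean)` to the
#' site's logit; `confounded` adds `effect_size` times a pair-level standard
#' normal confounder to both the trait and the site's logit, with no direct
#' path between them.  Pairs whose intra-pair trait difference falls below
#' `discordance_min` have their individual residuals redrawn (up to 100
#' attempts each, then an error), preserving `n_pairs`.
#'
#' @param config a [sim_config()].
#' @return list with elements `cohort` (twin_cohort), `counts`
#'   (methylation_counts) and `truth` (list: `sites` data.frame with scenario
#'   labels and effect sizes, `profiles` site x cell-type baseline logit
#'   matrix, `individuals` data.frame with pair factor, confounder and true
#'   cell proportions).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_ind <- 2L * config$n_pairs
  ids <- sprintf("tw%03d_%d", rep(seq_len(config$n_pairs), each = 2), rep(1:2, config$n_pairs))
  pair_ids <- sprintf("pair%03d", rep(seq_len(config$n_pairs), each = 2))
  pair_of <- rep(seq_len(config$n_pairs), each = 2)

  # site map: sites split across chromosomes, exponential gaps (>= 2 bp)
  per_chrom <- diff(round(seq(0, config$n_sites, length.out = config$n_chroms + 1)))
  chrom <- rep(paste0("chr", seq_len(config$n_chroms)), per_chrom)
  gaps <- pmax(2, round(rexp(config$n_sites, rate = 1 / config$site_spacing_bp)))
  pos <- unlist(lapply(split(gaps, chrom)[unique(chrom)],
                       function(g) 1000L + cumsum(as.integer(g))), use.names = FALSE)
  sites <- data.frame(chrom = chrom, pos = pos)

  # latent structure (fixed draw order => seed-reproducible)
  mu_site <- rnorm(config$n_sites, 0, config$baseline_sd_logit)
  L <- mu_site + matrix(rnorm(config$n_sites * config$n_cell_types,
                              0, config$celltype_sd_logit),
                        config$n_sites, config$n_cell_types)
  u_pair <- rnorm(config$n_pairs)           # shared trait factor
  c_pair <- rnorm(config$n_pairs)           # pair-level confounder
  W <- rdirichlet(n_ind, config$dirichlet_alpha)
  G <- matrix(rnorm(config$n_sites * config$n_pairs, 0, config$pair_sd_logit),
              config$n_sites, config$n_pairs)
  E <- matrix(rnorm(config$n_sites * n_ind, 0, config$noise_sd_logit),
              config$n_sites, n_ind)
  r_ind <- rnorm(n_ind)                     # individual trait residuals

  logit <- L %*% t(W) + G[, pair_of, drop = FALSE] + E

  es <- config$effect_scenarios
  fwd <- rvs <- cfd <- NULL
  if (!is.null(es)) {
    es <- as.data.frame(es)
    fwd <- es[es$scenario == "forward_causal", , drop = FALSE]
    rvs <- es[es$scenario == "reverse_causal", , drop = FALSE]
    cfd <- es[es$scenario == "confounded", , drop = FALSE]
  }

  a <- config$trait_sd * sqrt(config$pair_trait_corr)
  b <- config$trait_sd * sqrt(1 - config$pair_trait_corr)
  trait_fixed <- config$trait_mean + a * u_pair[pair_of]
  if (!is.null(fwd) && nrow(fwd)) {
    M_fwd <- logit[fwd$site_index, , drop = FALSE] / log(2)
    trait_fixed <- trait_fixed + as.vector(fwd$effect_size %*% M_fwd)
  }
  if (!is.null(cfd) && nrow(cfd)) {
    trait_fixed <- trait_fixed + sum(cfd$effect_size) * c_pair[pair_of]
  }
  trait <- trait_fixed + b * r_ind

  # enforce minimum discordance by redrawing individual residuals
  if (config$discordance_min > 0 && b > 0) {
    t1 <- seq(1, n_ind, by = 2); t2 <- t1 + 1
    for (p in seq_len(config$n_pairs)) {
      att <- 0
      while (abs(trait[t1[p]] - trait[t2[p]]) < config$discordance_min) {
        att <- att + 1
        if (att > 100) stop("could not satisfy discordance_min for pair ", p)
        e2 <- rnorm(2)
        trait[c(t1[p], t2[p])] <- trait_fixed[c(t1[p], t2[p])] + b * e2
      }
    }
  } else if (config$discordance_min > 0 && b == 0) {
    d <- abs(trait[seq(1, n_ind, 2)] - trait[seq(2, n_ind, 2)])
    if (any(d < config$discordance_min))
      stop("discordance_min unattainable with zero residual variance")
  }

  if (!is.null(rvs) && nrow(rvs)) {
    logit[rvs$site_index, ] <- logit[rvs$site_index, , drop = FALSE] +
      outer(rvs$effect_size, trait - config$trait_mean)
  }
  if (!is.null(cfd) && nrow(cfd)) {
    logit[cfd$site_index, ] <- logit[cfd$site_index, , drop = FALSE] +
      outer(cfd$effect_size, c_pair[pair_of])
  }

  beta_latent <- plogis(logit)
  coverage <- matrix(rnbinom(config$n_sites * n_ind, mu = config$coverage_mean,
                             size = config$coverage_dispersion),
                     config$n_sites, n_ind)
  meth <- matrix(rbinom(config$n_sites * n_ind, coverage, beta_latent),
                 config$n_sites, n_ind)
  colnames(meth) <- colnames(coverage) <- ids

  sex <- rep(rbinom(config$n_pairs, 1, 0.5), each = 2)       # MZ: shared
  age <- rep(round(runif(config$n_pairs, 35, 65)), each = 2)

  cohort <- twin_cohort(ids, pair_ids, trait, sex, age)
  counts <- methylation_counts(sites, meth, coverage)

  scen <- rep("null", config$n_sites); eff <- rep(0, config$n_sites)
  if (!is.null(es) && nrow(es)) {
    scen[es$site_index] <- es$scenario
    eff[es$site_index] <- es$effect_size
  }
  truth <- list(
    sites = data.frame(chrom = sites$chrom, pos = sites$pos,
                       scenario = scen, effect_size = eff,
                       stringsAsFactors = FALSE),
    profiles = L,
    individuals = data.frame(individual_id = ids, pair_id = pair_ids,
                             pair_factor = u_pair[pair_of],
                             confounder = c_pair[pair_of],
                             W, stringsAsFactors = FALSE),
    beta_latent = beta_latent)
  names(truth$individuals)[-(1:4)] <- paste0("cell", seq_len(config$n_cell_types))
  list(cohort = cohort, counts = counts, truth = truth)
}

#' Twin-design EWAS power by simulation
#'
#' Monte-Carlo power for detecting a single planted forward-causal CpG with
#' the exchangeable-GEE scan at significance level `alpha`: for each
#' replicate a cohort of `n_pairs` discordant MZ pairs is simulated with the
#' effect planted at one site, the site is tested (M-value ~ trait + sex +
#' age, clustered on pair, robust Wald p), and power is the fraction of
#' replicates with p < alpha.
#'
#' @param n_pairs pairs per replicate.
#' @param effect_size forward-causal effect (kg of trait per latent M unit).
#' @param reps number of replicates (>= 1).
#' @param alpha test level.
#' @param seed integer seed.
#' @param config optional baseline [sim_config()] whose nuisance parameters
#'   (noise, coverage, cell mixture) are reused; `n_pairs`, the scenario and
#'   the seed are overridden per replicate.
#' @return scalar power estimate in \[0, 1\].
#' @export
estimate_power <- function(n_pairs, effect_size, reps = 200, alpha = 0.05,
                           seed = 1L, config = NULL) {
  if (reps < 1) stop("reps must be >= 1")
  if (is.null(config)) config <- sim_config()
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  hits <- logical(reps)
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$n_pairs <- as.integer(n_pairs)
    cfg$n_sites <- 1L; cfg$n_chroms <- 1L
    cfg$effect_scenarios <- data.frame(site_index = 1L,
                                       scenario = "forward_causal",
                                       effect_size = effect_size)
    cfg$seed <- rep_seeds[r]
    sim <- simulate_cohort(cfg)
    m <- beta_to_m(compute_beta(sim$counts))
    ok <- !is.na(m$values[1, ])
    ch <- sim$cohort[match(colnames(m$values)[ok], sim$cohort$individual_id), ]
    X <- cbind(`(Intercept)` = 1, trait = ch$trait, sex = ch$sex, age = ch$age)
    fit <- fit_gee_exchangeable(m$values[1, ok], X, ch$pair_id)
    hits[r] <- is.finite(fit$p["trait"]) && fit$p["trait"] < alpha
  }
  mean(hits)
}
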