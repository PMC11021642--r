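# Pipeline configuration and orchestration.  Stages communicate through
# files in `out_dir`, so the `run` subcommand and a sequence of individual
# stage invocations produce identical artifacts.

default_config <- function() {
  list(
    paths = list(counts = NULL, phenotype = NULL, genes = NULL,
                 expression = NULL),
    qc = list(coverage_quantile = 0.9, mean_beta_min = 0.01, max_missing = 10,
              eps = 1e-6),
    refactor = list(k = 5, t = 500, d = 5),
    ewas = list(covariates = c("sex", "age"), fdr_alpha = 0.05),
    icefalcon = list(threshold = 1.5, B = 1000, seed = 1L),
    dmr = list(seed_p = 0.05, dist_bp = 500, window_bp = 500, bin_bp = 50,
               max_lag_bp = 500, min_sites = 2),
    simulation = NULL)
}

merge_config <- function(base, user, path = "") {
  for (k in names(user)) {
    if (!k %in% names(base))
      stop("unknown config key: ", sub("^\\.", "", paste0(path, ".", k)))
    if (is.list(base[[k]]) && !is.null(names(base[[k]])) && is.list(user[[k]]))
      base[[k]] <- merge_config(base[[k]], user[[k]], paste0(path, ".", k))
    else base[[k]] <- user[[k]]
  }
  base
}

#' Assemble a pipeline configuration
#'
#' Starts from the package defaults (QC: coverage capped at the 0.9
#' quantile, mean-beta minimum 0.01, at most 10 missing observations;
#' cell components k = t(500)-selected rank-5 with 5 scores; EWAS adjusted
#' for sex, age and the components with FDR alpha 0.05; ICE FALCON
#' threshold 1.5 with B = 1000 bootstrap replicates; DMR seeding/merging at
#' 0.05 within 500 bp) and overrides them with the supplied nested list.
#' Unknown keys are rejected.
#'
#' @param ... named top-level sections (`paths`, `qc`, `refactor`, `ewas`,
#'   `icefalcon`, `dmr`, `simulation`) given as lists; `simulation` may be a
#'   [sim_config()] or a list of its arguments.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  cfg <- merge_config(default_config(), user)
  if (!is.null(cfg$simulation) && !inherits(cfg$simulation, "sim_config"))
    cfg$simulation <- do.call(sim_config, cfg$simulation)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with the nested sections of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  do.call(pipeline_config, user)
}

# ---- file-based stages -----------------------------------------------------
# Each stage reads its inputs from cfg$paths or from out_dir artifacts of the
# previous stages and writes its outputs into out_dir.

artifact <- function(out_dir, name) file.path(out_dir, name)

stage_simulate <- function(cfg, out_dir, seed = NULL) {
  sc <- cfg$simulation
  if (is.null(sc)) stop("no simulation block in config")
  if (!is.null(seed)) sc$seed <- as.integer(seed)
  sim <- simulate_cohort(sc)
  prm <- list(n_pairs = sc$n_pairs, n_sites = sc$n_sites)
  write_methylation_counts(sim$counts, artifact(out_dir, "counts.tsv"),
                           "simulate", prm, sc$seed)
  write_phenotype(sim$cohort, artifact(out_dir, "phenotype.tsv"), "simulate",
                  prm, sc$seed)
  truth <- cbind(sim$truth$sites,
                 setNames(as.data.frame(sim$truth$profiles),
                          paste0("profile_cell", seq_len(ncol(sim$truth$profiles)))))
  write_tsv_stage(truth, artifact(out_dir, "truth_sites.tsv"), "simulate", prm, sc$seed)
  write_tsv_stage(sim$truth$individuals, artifact(out_dir, "truth_individuals.tsv"),
                  "simulate", prm, sc$seed)
  invisible(sim)
}

stage_preprocess <- function(cfg, out_dir, seed = NULL) {
  cpath <- cfg$paths$counts %||% artifact(out_dir, "counts.tsv")
  counts <- read_methylation_counts(cpath)
  qc <- cfg$qc
  counts <- cap_coverage(counts, qc$coverage_quantile)
  beta <- compute_beta(counts)
  beta <- filter_sites(beta, qc$mean_beta_min, qc$max_missing)
  m <- beta_to_m(beta, qc$eps)
  write_site_matrix(beta, artifact(out_dir, "beta_filtered.tsv"), "preprocess",
                    qc, seed)
  write_site_matrix(m, artifact(out_dir, "mvalues.tsv"), "preprocess", qc, seed)
  write_tsv_stage(attr(beta, "qc"), artifact(out_dir, "qc_report.tsv"),
                  "preprocess", qc, seed)
  invisible(list(beta = beta, m = m))
}

stage_refactor <- function(cfg, out_dir, seed = NULL) {
  beta <- read_site_matrix(artifact(out_dir, "beta_filtered.tsv"), "beta")
  rf <- cfg$refactor
  t_eff <- min(rf$t, nrow(beta$sites))
  comp <- refactor_components(impute_missing(beta), k = rf$k, t = t_eff,
                              d = rf$d)
  dt <- data.table(individual_id = rownames(comp$scores))
  dt <- cbind(dt, as.data.table(comp$scores))
  write_tsv_stage(dt, artifact(out_dir, "cell_components.tsv"), "refactor",
                  rf, seed)
  invisible(comp)
}

read_components_file <- function(path) {
  dt <- read_tsv_skip(path)
  sc <- as.matrix(dt[, -1])
  rownames(sc) <- dt[[1]]
  structure(list(scores = sc, selected_sites = character(), d = ncol(sc)),
            class = "cell_components")
}

stage_ewas <- function(cfg, out_dir, seed = NULL) {
  m <- read_site_matrix(artifact(out_dir, "mvalues.tsv"), "m")
  cohort <- read_phenotype(cfg$paths$phenotype %||% artifact(out_dir, "phenotype.tsv"))
  comp <- read_components_file(artifact(out_dir, "cell_components.tsv"))
  res <- ewas_scan(m, cohort, comp, covariates = cfg$ewas$covariates)
  write_tsv_stage(res, artifact(out_dir, "ewas_results.tsv"), "ewas",
                  list(covariates = cfg$ewas$covariates,
                       fdr_alpha = cfg$ewas$fdr_alpha), seed)
  invisible(res)
}

stage_icefalcon <- function(cfg, out_dir, seed = NULL) {
  res <- read_tsv_skip(artifact(out_dir, "ewas_results.tsv"))
  m <- read_site_matrix(artifact(out_dir, "mvalues.tsv"), "m")
  cohort <- read_phenotype(cfg$paths$phenotype %||% artifact(out_dir, "phenotype.tsv"))
  comp <- read_components_file(artifact(out_dir, "cell_components.tsv"))
  sig <- res[!is.na(res$q) & res$q < cfg$ewas$fdr_alpha, ]
  sites <- site_key(sig$chrom, sig$pos)
  icf <- cfg$icefalcon
  sd <- if (!is.null(seed)) as.integer(seed) else icf$seed
  out <- if (length(sites))
    run_bidirectional(m, cohort, sites, comp,
                      covariates = cfg$ewas$covariates,
                      threshold = icf$threshold, B = icf$B, seed = sd)
  else data.table(site = character(), chrom = character(), pos = integer(),
                  direction = character(), beta_self = numeric(),
                  beta_cotwin = numeric(), beta_self_prime = numeric(),
                  beta_cotwin_prime = numeric(), delta_self = numeric(),
                  delta_cotwin = numeric(), p_delta_self = numeric(),
                  p_delta_cotwin = numeric(), ratio = numeric(),
                  causal_flag = logical(), n_pairs = integer(),
                  estimable = logical())
  write_tsv_stage(out, artifact(out_dir, "icefalcon_results.tsv"), "icefalcon",
                  icf[c("threshold", "B")], sd)
  invisible(out)
}

stage_dmr <- function(cfg, out_dir, seed = NULL) {
  res <- read_tsv_skip(artifact(out_dir, "ewas_results.tsv"))
  d <- cfg$dmr
  regions <- call_dmrs(res, seed_p = d$seed_p, dist_bp = d$dist_bp,
                       window_bp = d$window_bp, bin_bp = d$bin_bp,
                       max_lag_bp = d$max_lag_bp, min_sites = d$min_sites)
  write_tsv_stage(regions, artifact(out_dir, "dmr_regions.tsv"), "dmr", d, seed)
  write_regions_bed(regions, artifact(out_dir, "dmr_regions.bed"), "dmr", d, seed)
  invisible(regions)
}

stage_annotate <- function(cfg, out_dir, seed = NULL) {
  if (is.null(cfg$paths$genes)) return(invisible(NULL))
  res <- read_tsv_skip(artifact(out_dir, "ewas_results.tsv"))
  genes <- read_gene_models(cfg$paths$genes)
  sig <- res[!is.na(res$q) & res$q < cfg$ewas$fdr_alpha, ]
  ann <- nearest_gene(sig[, c("chrom", "pos")], genes)
  ann <- cbind(ann, sig[, c("coefficient", "p", "q")])
  write_tsv_stage(ann, artifact(out_dir, "annotation.tsv"), "annotate",
                  list(), seed)
  out <- list(annotation = ann)
  if (!is.null(cfg$paths$expression)) {
    expr <- read_expression(cfg$paths$expression)
    m <- read_site_matrix(artifact(out_dir, "mvalues.tsv"), "m")
    keys <- site_key(ann$chrom, ann$pos)
    prs <- data.frame(site = keys, gene = ann$gene_id)
    prs <- prs[!is.na(prs$gene) & prs$gene %in% rownames(expr), , drop = FALSE]
    if (nrow(prs)) {
      sp <- spearman_methylation_expression(m, expr, prs)
      write_tsv_stage(sp, artifact(out_dir, "methylation_expression.tsv"),
                      "annotate", list(), seed)
      out$expression <- sp
    }
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the complete twin-EWAS pipeline
#'
#' Executes simulate (when a `simulation` block is present) -> preprocess ->
#' cell components -> GEE EWAS -> ICE FALCON on FDR-significant CpGs + DMR
#' calling -> annotation, writing every artifact into `out_dir` together
#' with a run log recording versions, parameters and seeds.  A failing stage
#' renames the artifacts it had already written with a `.partial` suffix and
#' re-raises the error.  Reruns with the same configuration and seed are
#' byte-identical.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if needed).
#' @param seed optional integer overriding the simulation and bootstrap
#'   seeds.
#' @return invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (!inherits(config, "pipeline_config")) stop("config must be a pipeline_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list(
    simulate = if (!is.null(config$simulation)) stage_simulate,
    preprocess = stage_preprocess, refactor = stage_refactor,
    ewas = stage_ewas, icefalcon = stage_icefalcon, dmr = stage_dmr,
    annotate = stage_annotate)
  stages <- Filter(Negate(is.null), stages)
  stage_files <- list(
    simulate = c("counts.tsv", "phenotype.tsv", "truth_sites.tsv",
                 "truth_individuals.tsv"),
    preprocess = c("beta_filtered.tsv", "mvalues.tsv", "qc_report.tsv"),
    refactor = "cell_components.tsv", ewas = "ewas_results.tsv",
    icefalcon = "icefalcon_results.tsv",
    dmr = c("dmr_regions.tsv", "dmr_regions.bed"),
    annotate = c("annotation.tsv", "methylation_expression.tsv"))
  for (nm in names(stages)) {
    before <- file.path(out_dir, stage_files[[nm]])
    ok <- tryCatch({ stages[[nm]](config, out_dir, seed); TRUE },
                   error = function(e) e)
    if (!isTRUE(ok)) {
      part <- before[file.exists(before)]
      file.rename(part, paste0(part, ".partial"))
      stop("stage '", nm, "' failed: ", conditionMessage(ok))
    }
  }
  log <- c(sprintf("mzewas %s on R %s", as.character(packageVersion("mzewas")),
                   paste(R.version$major, R.version$minor, sep = ".")),
           sprintf("seed: %s", if (is.null(seed)) "config default" else seed),
           "config:", yaml::as.yaml(unclass_config(config)))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  paths <- file.path(out_dir, unlist(stage_files[names(stages)], use.names = FALSE))
  invisible(paths[file.exists(paths)])
}

unclass_config <- function(cfg) {
  cfg <- unclass(cfg)
  if (!is.null(cfg$simulation)) {
    sim <- unclass(cfg$simulation)
    sim$effect_scenarios <- if (!is.null(sim$effect_scenarios))
      lapply(seq_len(nrow(sim$effect_scenarios)),
             function(i) as.list(sim$effect_scenarios[i, ]))
    cfg$simulation <- sim
  }
  cfg
}
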