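# Lightweight S3 containers shared across the pipeline.  Methylation data are
# stored as site-by-individual matrices with a parallel site table; sites are
# keyed as "chrom:pos" (1-based positions, strand-combined CpGs).

site_key <- function(chrom, pos) {
  if (!length(chrom)) return(character(0))
  paste0(chrom, ":", pos)
}

#' Construct a methylation count container
#'
#' Per-CpG methylated read counts and total coverage for a set of individuals,
#' the unit of exchange for bismark-coverage-style RRBS data.  Cells with zero
#' or missing coverage are treated as missing observations downstream.
#'
#' @param sites data.frame with columns `chrom` and `pos` (1-based bp),
#'   sorted by (chrom, pos) with strictly increasing positions per chromosome.
#' @param meth integer matrix (sites x individuals) of methylated read counts.
#' @param cov integer matrix of total read coverage, same shape as `meth`.
#' @return An object of class `methylation_counts`: a list with elements
#'   `sites`, `meth`, `cov`.  Row names are "chrom:pos" keys, column names are
#'   individual ids.
#' @export
methylation_counts <- function(sites, meth, cov) {
  sites <- as.data.frame(sites)
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  meth <- as.matrix(meth)
  cov <- as.matrix(cov)
  if (nrow(sites) != nrow(meth) || !identical(dim(meth), dim(cov)))
    stop("sites, meth and cov dimensions disagree")
  if (is.null(colnames(meth)))
    stop("meth/cov must carry individual ids as column names")
  bad <- which(meth > cov)
  if (length(bad))
    stop("count_methylated exceeds coverage in ", length(bad), " cell(s)")
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on ", ch)
  }
  keys <- site_key(sites$chrom, sites$pos)
  rownames(meth) <- rownames(cov) <- keys
  structure(list(sites = sites, meth = meth, cov = cov),
            class = "methylation_counts")
}

#' @export
print.methylation_counts <- function(x, ...) {
  cat(sprintf("methylation_counts: %d sites x %d individuals (%d chrom)\n",
              nrow(x$sites), ncol(x$meth), length(unique(x$sites$chrom))))
  invisible(x)
}

# beta / M-value matrices share a representation: site table + value matrix.
new_site_matrix <- function(sites, values, class) {
  sites <- as.data.frame(sites)
  values <- as.matrix(values)
  if (nrow(sites) != nrow(values)) stop("sites/values dimension mismatch")
  rownames(values) <- site_key(sites$chrom, sites$pos)
  structure(list(sites = sites, values = values), class = class)
}

#' Construct a beta-value matrix
#'
#' @param sites site table as in [methylation_counts()].
#' @param beta numeric matrix of methylation fractions in \[0, 1\] (NA for
#'   missing), sites x individuals.
#' @return Object of class `beta_matrix` with elements `sites` and `values`.
#' @export
beta_matrix <- function(sites, beta) {
  rng <- range(beta, na.rm = TRUE)
  if (any(is.finite(rng)) && (rng[1] < 0 || rng[2] > 1))
    stop("beta values outside [0, 1]")
  new_site_matrix(sites, beta, c("beta_matrix", "site_matrix"))
}

#' Construct an M-value matrix
#'
#' @param sites site table as in [methylation_counts()].
#' @param m numeric matrix of M-values (log2 beta/(1-beta)), NA for missing.
#' @return Object of class `m_matrix` with elements `sites` and `values`.
#' @export
m_matrix <- function(sites, m) {
  new_site_matrix(sites, m, c("m_matrix", "site_matrix"))
}

#' @export
print.site_matrix <- function(x, ...) {
  cat(sprintf("%s: %d sites x %d individuals\n", class(x)[1],
              nrow(x$sites), ncol(x$values)))
  invisible(x)
}

#' Construct a twin cohort table
#'
#' One row per individual; every `pair_id` must occur exactly twice (complete
#' monozygotic pairs).  `sex` is coded 0/1 and shared within a pair, as is
#' `age` (in years); `trait` is the continuous phenotype (handgrip strength,
#' kg, in the motivating design).
#'
#' @param individual_id character vector of unique individual ids.
#' @param pair_id character vector of twin-pair labels.
#' @param trait numeric trait values.
#' @param sex integer 0/1.
#' @param age numeric, years.
#' @return A `twin_cohort` data.frame.
#' @export
twin_cohort <- function(individual_id, pair_id, trait, sex, age) {
  df <- data.frame(individual_id = as.character(individual_id),
                   pair_id = as.character(pair_id),
                   trait = as.numeric(trait),
                   sex = as.integer(sex), age = as.numeric(age),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$individual_id)) stop("duplicate individual ids")
  sz <- table(df$pair_id)
  if (any(sz != 2)) stop("every pair_id must occur exactly twice")
  if (!all(df$sex %in% c(0L, 1L))) stop("sex must be coded 0/1")
  class(df) <- c("twin_cohort", "data.frame")
  df
}

# id of each individual's co-twin, in cohort row order
cotwin_ids <- function(cohort) {
  idx <- stats::ave(seq_len(nrow(cohort)), cohort$pair_id,
                    FUN = function(i) rev(i))
  cohort$individual_id[idx]
}
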