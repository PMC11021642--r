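# File formats.  All internal coordinates are 1-based inclusive (bismark
# coverage convention); BED output converts to 0-based half-open at the
# writer boundary.  Every file written by the pipeline starts with '#'
# comment lines naming the producing stage, its parameters and the seed;
# readers skip such lines.

count_comment_lines <- function(path, comment = "#") {
  con <- file(path, "r"); on.exit(close(con))
  k <- 0L
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || !startsWith(ln, comment)) break
    k <- k + 1L
  }
  k
}

stage_header <- function(stage, params = list(), seed = NULL) {
  ps <- if (length(params))
    paste(names(params), vapply(params, function(x) paste(format(x), collapse = "|"),
                                ""), sep = "=", collapse = " ") else ""
  c(sprintf("# mzewas %s stage=%s", as.character(packageVersion("mzewas")), stage),
    sprintf("# params: %s", ps),
    sprintf("# seed: %s", if (is.null(seed)) "NA" else format(seed)))
}

write_tsv_stage <- function(dt, path, stage, params = list(), seed = NULL,
                            col.names = TRUE) {
  writeLines(stage_header(stage, params, seed), path)
  fwrite(as.data.table(dt), path, sep = "\t", append = TRUE,
         col.names = col.names)
  invisible(path)
}

read_tsv_skip <- function(path, header = TRUE, ...) {
  fread(path, sep = "\t", skip = count_comment_lines(path), header = header,
        ...)
}

#' Read bismark-coverage-style methylation counts
#'
#' Accepts either one long-format file with an `individual_id` column
#' (columns: chrom, start, end, methylation_percentage, count_methylated,
#' count_unmethylated, individual_id) or a vector of per-individual 6-column
#' files (ids taken from `names(paths)`, else file basenames).  Files are
#' headerless apart from optional leading '#' comment lines.  Lines with
#' `count_methylated` implying methylation inconsistent with coverage raise
#' an error naming the line; duplicate (chrom, pos, individual) entries are
#' an error; unsorted input is sorted with a warning.
#'
#' @param paths one or more file paths.
#' @return A [methylation_counts()] object; cells absent from a file are
#'   missing (NA).
#' @export
read_methylation_counts <- function(paths) {
  read_one <- function(path, id = NULL) {
    nskip <- count_comment_lines(path)
    dt <- fread(path, sep = "\t", skip = nskip, header = FALSE)
    if (ncol(dt) == 6) {
      if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
      setnames(dt, c("chrom", "start", "end", "meth_pct", "n_meth", "n_unmeth"))
      dt[, individual_id := id]
    } else if (ncol(dt) == 7) {
      setnames(dt, c("chrom", "start", "end", "meth_pct", "n_meth", "n_unmeth",
                     "individual_id"))
    } else stop(path, ": expected 6 or 7 tab-separated columns, found ", ncol(dt))
    bad <- which(dt$n_meth < 0 | dt$n_unmeth < 0)
    if (length(bad))
      stop(path, ": negative count at line ", bad[1] + nskip)
    dt
  }
  dts <- if (length(paths) == 1 && is.null(names(paths)))
    list(read_one(paths)) else
    lapply(seq_along(paths), function(i)
      read_one(paths[i], if (!is.null(names(paths))) names(paths)[i]))
  dt <- rbindlist(dts)
  dt[, `:=`(pos = start, coverage = n_meth + n_unmeth)]
  if (anyDuplicated(dt[, .(chrom, pos, individual_id)]))
    stop("duplicate (chrom, pos, individual) entries")
  sorted_within <- dt[, .(ok = identical(order(chrom, pos), seq_len(.N))),
                      by = individual_id]
  if (!all(sorted_within$ok))
    warning("input not sorted by (chrom, pos); sorting")
  sites <- unique(dt[, .(chrom, pos)])
  setorder(sites, chrom, pos)
  ids <- unique(dt$individual_id)
  keys <- site_key(sites$chrom, sites$pos)
  meth <- cov <- matrix(NA_integer_, nrow(sites), length(ids),
                        dimnames = list(keys, ids))
  ri <- match(site_key(dt$chrom, dt$pos), keys)
  ci <- match(dt$individual_id, ids)
  meth[cbind(ri, ci)] <- dt$n_meth
  cov[cbind(ri, ci)] <- dt$coverage
  methylation_counts(as.data.frame(sites), meth, cov)
}

#' Write methylation counts as long-format bismark-style TSV
#'
#' @param counts a [methylation_counts()] object.
#' @param path output file.
#' @param stage,params,seed provenance recorded in the '#' header.
#' @return the path, invisibly.
#' @export
write_methylation_counts <- function(counts, path, stage = "simulate",
                                     params = list(), seed = NULL) {
  keys <- rownames(counts$meth)
  long <- data.table(
    chrom = rep(counts$sites$chrom, ncol(counts$meth)),
    start = rep(counts$sites$pos, ncol(counts$meth)),
    end = rep(counts$sites$pos, ncol(counts$meth)),
    n_meth = as.vector(counts$meth),
    coverage = as.vector(counts$cov),
    individual_id = rep(colnames(counts$meth), each = nrow(counts$meth)))
  long <- long[!is.na(coverage)]
  long[, `:=`(meth_pct = round(100 * n_meth / pmax(coverage, 1), 4),
              n_unmeth = coverage - n_meth)]
  out <- long[, .(chrom, start, end, meth_pct, n_meth, n_unmeth, individual_id)]
  writeLines(stage_header(stage, params, seed), path)
  fwrite(out, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}

#' Read / write the phenotype table
#'
#' TSV with header columns individual_id, pair_id, trait_kg, sex, age.
#'
#' @param path file path.
#' @return a [twin_cohort()].
#' @export
read_phenotype <- function(path) {
  dt <- read_tsv_skip(path)
  twin_cohort(dt$individual_id, dt$pair_id, dt$trait_kg, dt$sex, dt$age)
}

#' @rdname read_phenotype
#' @param cohort a [twin_cohort()].
#' @param stage,params,seed provenance header fields.
#' @export
write_phenotype <- function(cohort, path, stage = "simulate", params = list(),
                            seed = NULL) {
  dt <- data.table(individual_id = cohort$individual_id,
                   pair_id = cohort$pair_id, trait_kg = cohort$trait,
                   sex = cohort$sex, age = cohort$age)
  write_tsv_stage(dt, path, stage, params, seed)
}

#' Read / write wide site-by-individual matrices
#'
#' TSV with key columns chrom, pos followed by one column per individual.
#'
#' @param path file path.
#' @param what "beta" or "m": the container class to construct.
#' @return a [beta_matrix()] or [m_matrix()].
#' @export
read_site_matrix <- function(path, what = c("beta", "m")) {
  what <- match.arg(what)
  dt <- read_tsv_skip(path)
  sites <- data.frame(chrom = dt$chrom, pos = dt$pos)
  v <- as.matrix(dt[, -c("chrom", "pos")])
  if (what == "beta") beta_matrix(sites, v) else m_matrix(sites, v)
}

#' @rdname read_site_matrix
#' @param x a `beta_matrix` or `m_matrix`.
#' @param stage,params,seed provenance header fields.
#' @export
write_site_matrix <- function(x, path, stage, params = list(), seed = NULL) {
  dt <- data.table(chrom = x$sites$chrom, pos = x$sites$pos)
  dt <- cbind(dt, as.data.table(x$values))
  write_tsv_stage(dt, path, stage, params, seed)
}

#' Read gene models from BED6 or TSV
#'
#' `.bed` files are parsed as BED (0-based half-open; converted to 1-based
#' inclusive, name used as both gene_id and symbol).  Anything else is a
#' header TSV with columns gene_id, symbol, chrom, start, end (1-based
#' inclusive) and optional strand.
#'
#' @param path file path.
#' @return data.frame of gene models.
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    dt <- fread(path, sep = "\t", header = FALSE,
                skip = count_comment_lines(path))
    if (ncol(dt) < 4) stop("BED file needs at least 4 columns (name required)")
    setnames(dt, seq_len(4), c("chrom", "start0", "end", "name"))
    out <- data.frame(gene_id = dt$name, symbol = dt$name, chrom = dt$chrom,
                      start = dt$start0 + 1L, end = dt$end,
                      strand = if (ncol(dt) >= 6) dt[[6]] else "*",
                      stringsAsFactors = FALSE)
  } else {
    dt <- read_tsv_skip(path)
    need <- c("gene_id", "symbol", "chrom", "start", "end")
    if (!all(need %in% names(dt))) stop("gene TSV needs columns: ",
                                        paste(need, collapse = ", "))
    out <- as.data.frame(dt)
    if (!"strand" %in% names(out)) out$strand <- "*"
  }
  if (any(out$start > out$end)) stop("gene start > end")
  out
}

#' Read a gene-by-individual expression matrix (e.g. FPKM)
#'
#' TSV with header: gene_id column then one column per individual.
#'
#' @param path file path.
#' @return numeric matrix with gene ids as rownames.
#' @export
read_expression <- function(path) {
  dt <- read_tsv_skip(path)
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  if (any(m < 0, na.rm = TRUE)) stop("negative expression values")
  m
}

#' Write DMR regions as a BED file
#'
#' Converts 1-based inclusive region coordinates to BED 0-based half-open;
#' the name field is chrom:start-end and the score field carries the SLK p.
#'
#' @param regions scored region table from [score_regions()].
#' @param path output path.
#' @param stage,params,seed provenance header fields.
#' @return the path, invisibly.
#' @export
write_regions_bed <- function(regions, path, stage = "dmr", params = list(),
                              seed = NULL) {
  bed <- data.table(chrom = regions$chrom, start = regions$start - 1L,
                    end = regions$end,
                    name = sprintf("%s:%d-%d", regions$chrom, regions$start,
                                   regions$end),
                    score = signif(regions$slk_p, 6))
  writeLines(stage_header(stage, params, seed), path)
  fwrite(bed, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}
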