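# Nearest-gene annotation and methylation-expression correlation.

#' Annotate sites with their nearest gene
#'
#' A site inside a gene (start <= pos <= end, 1-based inclusive) gets
#' distance 0 and relation "inside"; otherwise the distance to the nearest
#' gene boundary is used, with relation "upstream" (site before the gene
#' start) or "downstream" (site past the gene end).  Strand is ignored.
#' Ties in distance are broken by the smaller gene start (a message is
#' emitted).  Sites on chromosomes without genes are annotated NA.
#'
#' @param sites data.frame with columns chrom, pos.
#' @param genes data.frame with columns gene_id, symbol, chrom, start, end
#'   (1-based inclusive), e.g. from [read_gene_models()].
#' @return data.table: chrom, pos, gene_id, symbol, distance, relation.
#' @export
nearest_gene <- function(sites, genes) {
  genes <- as.data.frame(genes)
  if (any(genes$start > genes$end)) stop("gene start > end")
  sites <- as.data.frame(sites)
  n <- nrow(sites)
  gene_id <- symbol <- rep(NA_character_, n)
  distance <- rep(NA_real_, n)
  relation <- rep(NA_character_, n)
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(g)) next
    for (i in si) {
      pos <- sites$pos[i]
      d <- ifelse(pos < g$start, g$start - pos,
                  ifelse(pos > g$end, pos - g$end, 0))
      best <- min(d)
      cand <- which(d == best)
      if (length(cand) > 1) {
        cand <- cand[order(g$start[cand])]
        message(sprintf("nearest_gene: tie at %s:%d resolved by smaller start (%s)",
                        ch, pos, g$gene_id[cand[1]]))
      }
      j <- cand[1]
      gene_id[i] <- g$gene_id[j]
      symbol[i] <- g$symbol[j]
      distance[i] <- best
      relation[i] <- if (best == 0) "inside" else if (pos < g$start[j]) "upstream" else "downstream"
    }
  }
  data.table(chrom = sites$chrom, pos = sites$pos, gene_id = gene_id,
             symbol = symbol, distance = distance, relation = relation)
}

#' Spearman correlation of CpG methylation with gene expression
#'
#' For each requested (site, gene) pair, Spearman's rho is computed from
#' average-ranked values over the individuals shared between the two
#' matrices (pairwise complete), with a two-sided p-value from the t
#' approximation t = rho sqrt((n-2)/(1-rho^2)).  Zero variance in either
#' vector yields NA.
#'
#' @param m an [m_matrix()] (or [beta_matrix()]); rows are sites.
#' @param expr numeric gene x individual matrix (e.g. FPKM), rownames are
#'   gene ids.
#' @param pairs data.frame with columns `site` (site key "chrom:pos") and
#'   `gene`.
#' @return data.table: site, gene, rho, p, n.
#' @export
spearman_methylation_expression <- function(m, expr, pairs) {
  shared <- intersect(colnames(m$values), colnames(expr))
  if (length(shared) < 4) stop("fewer than 4 shared individuals")
  pairs <- as.data.frame(pairs)
  nr <- nrow(pairs)
  rho <- p <- rep(NA_real_, nr)
  n <- integer(nr)
  for (i in seq_len(nr)) {
    if (!pairs$site[i] %in% rownames(m$values) ||
        !pairs$gene[i] %in% rownames(expr)) next
    x <- m$values[pairs$site[i], shared]
    y <- expr[pairs$gene[i], shared]
    ok <- !is.na(x) & !is.na(y)
    n[i] <- sum(ok)
    if (n[i] < 4) next
    x <- x[ok]; y <- y[ok]
    if (sd(x) == 0 || sd(y) == 0) next
    r <- cor(rank(x), rank(y))
    rho[i] <- r
    if (abs(r) >= 1) { p[i] <- 0; next }
    tt <- r * sqrt((n[i] - 2) / (1 - r^2))
    p[i] <- 2 * pt(-abs(tt), df = n[i] - 2)
  }
  data.table(site = pairs$site, gene = pairs$gene, rho = rho, p = p, n = n)
}
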