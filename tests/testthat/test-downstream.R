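genes_fixture <- function() {
  data.frame(gene_id = c("g1", "g2", "g3"), symbol = c("A", "B", "C"),
             chrom = c("chr1", "chr1", "chr2"),
             start = c(1000L, 5000L, 2000L), end = c(2000L, 6000L, 2500L),
             strand = "*", stringsAsFactors = FALSE)
}

test_that("nearest-gene annotation handles inside, flanks, ties and empty chromosomes", {
  g <- genes_fixture()
  inside <- nearest_gene(data.frame(chrom = "chr1", pos = 1500), g)
  expect_equal(inside$gene_id, "g1")
  expect_equal(inside$distance, 0)
  expect_equal(inside$relation, "inside")
  up <- nearest_gene(data.frame(chrom = "chr1", pos = 4000), g)
  expect_equal(up$gene_id, "g2")             # 1000 bp to g2 start vs 2000 to g1 end
  expect_equal(up$distance, 1000)
  expect_equal(up$relation, "upstream")
  # equidistant between g1 end (2000) and g2 start (5000): midpoint 3500
  expect_message(tie <- nearest_gene(data.frame(chrom = "chr1", pos = 3500), g),
                 "tie")
  expect_equal(tie$gene_id, "g1")            # smaller start wins
  none <- nearest_gene(data.frame(chrom = "chrX", pos = 100), g)
  expect_true(is.na(none$gene_id))
})

test_that("nearest-gene matches an exhaustive brute-force search", {
  set.seed(35)
  genes <- data.frame(gene_id = paste0("g", 1:20), symbol = paste0("s", 1:20),
                      chrom = sample(c("chr1", "chr2"), 20, TRUE),
                      start = sample(1e5, 20))
  genes$end <- genes$start + sample(500:5000, 20)
  sites <- data.frame(chrom = sample(c("chr1", "chr2"), 100, TRUE),
                      pos = sample(110000, 100))
  got <- suppressMessages(nearest_gene(sites, genes))
  for (i in seq_len(nrow(sites))) {          # O(n*m) oracle
    best_d <- Inf; best_j <- NA
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != sites$chrom[i]) next
      d <- if (sites$pos[i] < genes$start[j]) genes$start[j] - sites$pos[i]
      else if (sites$pos[i] > genes$end[j]) sites$pos[i] - genes$end[j] else 0
      if (d < best_d || (d == best_d && genes$start[j] < genes$start[best_j])) {
        best_d <- d; best_j <- j
      }
    }
    expect_equal(got$distance[i], best_d)
    expect_equal(got$gene_id[i], genes$gene_id[best_j])
  }
})

test_that("nearest-gene is invariant to gene list order", {
  set.seed(36)
  genes <- genes_fixture()
  sites <- data.frame(chrom = "chr1", pos = sample(8000, 30))
  a <- suppressMessages(nearest_gene(sites, genes))
  b <- suppressMessages(nearest_gene(sites, genes[sample(3), ]))
  expect_identical(a, b)
})

make_m <- function(v, ids) {
  colnames(v) <- ids
  m_matrix(data.frame(chrom = "chr1", pos = seq_len(nrow(v)) * 100), v)
}

test_that("Spearman correlation hits the monotone anchors and the rank oracle", {
  ids <- paste0("i", 1:24)
  set.seed(37)
  mv <- matrix(rnorm(24), 1)
  m <- make_m(mv, ids)
  expr_up <- matrix(exp(mv), 1, dimnames = list("gA", ids))
  res <- spearman_methylation_expression(m, expr_up,
                                         data.frame(site = "chr1:100", gene = "gA"))
  expect_equal(res$rho, 1)
  expect_equal(res$p, 0)
  expr_dn <- matrix(-mv, 1, dimnames = list("gA", ids))
  res2 <- spearman_methylation_expression(m, expr_dn,
                                          data.frame(site = "chr1:100", gene = "gA"))
  expect_equal(res2$rho, -1)
  # random vectors: rank-then-Pearson + t-approximation oracle
  x <- rnorm(24); y <- rnorm(24)
  m2 <- make_m(matrix(x, 1), ids)
  e2 <- matrix(y, 1, dimnames = list("gB", ids))
  r3 <- spearman_methylation_expression(m2, e2,
                                        data.frame(site = "chr1:100", gene = "gB"))
  rho_o <- cor(rank(x), rank(y))
  t_o <- rho_o * sqrt(22 / (1 - rho_o^2))
  expect_equal(r3$rho, rho_o, tolerance = 1e-12)
  expect_equal(r3$p, 2 * pt(-abs(t_o), 22), tolerance = 1e-12)
  expect_equal(r3$rho, unname(cor.test(x, y, method = "spearman")$estimate),
               tolerance = 1e-12)
  # invariance under strictly monotone transforms
  r4 <- spearman_methylation_expression(make_m(matrix(exp(x), 1), ids), e2,
                                        data.frame(site = "chr1:100", gene = "gB"))
  expect_equal(r4$rho, r3$rho)
})

test_that("degenerate expression vectors give NA and few individuals error", {
  ids <- paste0("i", 1:10)
  m <- make_m(matrix(rnorm(10), 1), ids)
  econst <- matrix(5, 1, 10, dimnames = list("gC", ids))
  res <- spearman_methylation_expression(m, econst,
                                         data.frame(site = "chr1:100", gene = "gC"))
  expect_true(is.na(res$rho))
  e2 <- matrix(1:3, 1, 3, dimnames = list("gC", ids[1:3]))
  expect_error(spearman_methylation_expression(m, e2,
                                               data.frame(site = "chr1:100", gene = "gC")),
               "shared")
})
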