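test_that("QC metrics follow their definitions", {
  m <- tiny_counts(matrix(c(2L, 0L, 3L,
                            0L, 0L, 0L), 2, 3, byrow = TRUE),
                   genes = c("g1", "g2", "mt-1"))
  qc <- compute_qc_metrics(m)
  expect_equal(qc$nGene, c(2L, 0L))
  expect_equal(qc$nUMI, c(5L, 0L))
  expect_equal(qc$percent.mito, c(60, 0))
  # no mito genes: warning, zeros
  m2 <- tiny_counts(matrix(1L, 2, 2))
  expect_warning(qc2 <- compute_qc_metrics(m2), "mito")
  expect_equal(qc2$percent.mito, c(0, 0))
})

test_that("simulated mito fraction is recovered by the metrics", {
  d <- simulation_design(n_cells_per_condition = 300, n_genes = 600,
                         marker_genes_per_cluster = 20, marker_log2fc = 0,
                         cycling_fraction = 0, mito_gene_fraction = 0.05,
                         seed = 11)
  sim <- simulate_counts(d)
  qc <- compute_qc_metrics(sim$matrix)
  expect_lt(abs(median(qc$percent.mito) - 5), 0.5)
})

test_that("loess residual filter retains exact relationships and flags planted outliers", {
  set.seed(20)
  nUMI <- sort(round(runif(200, 1000, 9000)))
  qc <- data.frame(cell_id = sprintf("c%d", 1:200),
                   nGene = round(0.1 * nUMI + 50), nUMI = nUMI,
                   percent.mito = 0)
  out <- filter_cells_loess_residual(qc)
  expect_length(out$removed, 0)

  # displace one cell far below the curve
  qc2 <- qc
  qc2$nGene <- qc2$nGene + round(rnorm(200, 0, 10))
  fit_sd <- sd(filter_cells_loess_residual(qc2)$residuals)
  qc2$nGene[100] <- qc2$nGene[100] - round(10 * fit_sd)
  out2 <- filter_cells_loess_residual(qc2)
  expect_identical(out2$removed, "c100")
})

test_that("degenerate loess inputs error informatively", {
  qc <- data.frame(cell_id = sprintf("c%d", 1:60), nGene = 1:60,
                   nUMI = rep(100L, 60), percent.mito = 0)
  expect_error(filter_cells_loess_residual(qc), "constant|degenerate")
  expect_error(filter_cells_loess_residual(qc[1:10, ]), "50")
})

test_that("gaussian residual noise is removed at the 2*pnorm(-3) rate", {
  set.seed(21)
  n <- 10000
  nUMI <- round(runif(n, 1000, 9000))
  qc <- data.frame(cell_id = sprintf("c%d", 1:n),
                   nGene = round(0.1 * nUMI + rnorm(n, 0, 25)),
                   nUMI = nUMI, percent.mito = 0)
  out <- filter_cells_loess_residual(qc)
  rate <- length(out$removed) / n
  expected <- 2 * pnorm(-3)  # 0.0027
  ci <- 2.576 * sqrt(expected * (1 - expected) / n)
  expect_lt(abs(rate - expected), ci)
})

test_that("threshold boundaries are inclusive on the stated values", {
  qc <- data.frame(cell_id = c("a", "b", "c", "d", "e"),
                   nGene = c(199L, 200L, 500L, 500L, 500L),
                   nUMI = c(1000L, 1000L, 2000L, 2000L, 2000L),
                   percent.mito = c(0, 0, 10.0, 10.1, 5))
  out <- filter_cells_thresholds(qc, high_quantile = 1)
  expect_identical(out$retained, c("b", "c", "e"))
  expect_equal(out$qc$removal_reason[out$qc$cell_id == "a"], "low_nGene")
  expect_equal(out$qc$removal_reason[out$qc$cell_id == "d"], "high_mito")
  # all passing: identity
  ok <- qc[qc$cell_id %in% c("b", "c", "e"), ]
  expect_identical(filter_cells_thresholds(ok, high_quantile = 1)$retained,
                   ok$cell_id)
})

test_that("joint upper-quantile rule removes only jointly extreme cells", {
  set.seed(4)
  n <- 1000
  qc <- data.frame(cell_id = sprintf("c%d", 1:n),
                   nGene = rpois(n, 800), nUMI = rpois(n, 4000),
                   percent.mito = 0)
  qc$nGene[1] <- 5000; qc$nUMI[1] <- 50000       # joint outlier
  qc$nGene[2] <- 5000                            # nGene only
  out <- filter_cells_thresholds(qc, min_nGene = 0,
                                 max_percent_mito = 100,
                                 high_quantile = 0.999)
  expect_true("c1" %in% out$removed)
  expect_false("c2" %in% out$removed)
})

test_that("gene prevalence filter matches a brute-force scan", {
  m <- random_counts(60, 40, density = 0.15, seed = 6)
  filtered <- filter_genes_min_cells(m, min_cells = 10)
  dense <- as.matrix(m$counts)
  keep_oracle <- colSums(dense > 0) >= 10
  expect_identical(filtered$gene_ids, m$gene_ids[keep_oracle])
  # boundary: exactly 10 cells kept, 9 dropped
  mm <- matrix(0L, 20, 2)
  mm[1:9, 1] <- 1L; mm[1:10, 2] <- 1L
  tc <- tiny_counts(mm)
  expect_identical(filter_genes_min_cells(tc, 10)$gene_ids, "g2")
  # min_cells 0: identity
  expect_identical(filter_genes_min_cells(m, 0)$gene_ids, m$gene_ids)
})

test_that("normalisation is depth-invariant and scaling standardises genes", {
  base <- c(2L, 4L, 6L, 0L)
  m <- tiny_counts(rbind(base, base * 3L, c(1L, 1L, 1L, 1L)))
  norm <- normalize_scale(m)
  expect_equal(as.numeric(norm$lognorm[1, ]), as.numeric(norm$lognorm[2, ]))
  r <- random_counts(80, 50, density = 0.5, seed = 8)
  nr <- normalize_scale(r)
  expect_lt(max(abs(colMeans(nr$scaled))), 1e-8)
  sds <- apply(nr$scaled, 2, sd)
  expect_lt(max(abs(sds[sds > 0] - 1)), 1e-8)
  # gene constant after depth normalisation scales to zeros
  me <- tiny_counts(cbind(c(5L, 5L, 5L), c(1L, 1L, 1L)))
  expect_true(all(normalize_scale(me)$scaled[, 1] == 0))
  # zero-depth cell errors
  mz <- tiny_counts(rbind(c(1L, 2L), c(0L, 0L)))
  expect_error(normalize_scale(mz), "zero-depth")
})

test_that("variable-gene selection finds planted outliers and respects symmetry", {
  set.seed(9)
  n <- 200; g <- 600
  lambda <- runif(g, 2, 20)  # a genuine mean-variance trend
  base <- matrix(rpois(n * g, rep(lambda, each = n)), n, g)
  # 20 planted across the mean range: same mean, strongly inflated variance
  hot <- sample(g, 20)
  lambda[hot] <- runif(20, 6, 18)
  for (j in hot) {
    lo <- max(1, round(0.1 * lambda[j])); hi <- round(1.9 * lambda[j])
    base[, j] <- ifelse(rbinom(n, 1, 0.5) == 1, hi, lo)
  }
  m <- tiny_counts(base)
  sel <- select_variable_genes(normalize_scale(m))
  expect_setequal(sel, m$gene_ids[hot])
  # permutation of gene order does not change the selected set
  perm <- sample(g)
  m2 <- tiny_counts(base[, perm], genes = m$gene_ids[perm])
  sel2 <- select_variable_genes(normalize_scale(m2))
  expect_setequal(sel2, sel)
})

test_that("genes with identical profiles yield an empty variable-gene set", {
  set.seed(10)
  col <- rpois(150, 5L) + 1L
  m <- tiny_counts(matrix(rep(col, 300), 150, 300))
  sel <- select_variable_genes(normalize_scale(m))
  expect_length(sel, 0)
})

test_that("component selection keeps planted signal and drops pure noise", {
  set.seed(12)
  n <- 150; g <- 120
  noise <- matrix(rnorm(n * g), n, g)
  u <- rnorm(n); v <- rnorm(g)
  signal <- noise + 3 * u %*% t(v) / sqrt(g)
  m <- tiny_counts(matrix(rpois(n * g, 10L), n, g))
  norm <- normalize_scale(m)
  norm$scaled <- signal  # inject a controlled scaled matrix
  cs <- select_significant_components(norm, n_components = 20,
                                      n_perm = 60, seed = 3)
  expect_true(cs$retained[1])
  expect_lt(sum(cs$retained[-1]), 3)
  # var_frac_min = 1 retains nothing
  cs2 <- select_significant_components(norm, n_components = 20,
                                       var_frac_min = 1, n_perm = 20,
                                       seed = 3)
  expect_false(any(cs2$retained))
  expect_true(all(diff(cs$var_frac) <= 1e-12))
})

test_that("jackstraw false-retention on pure noise is near the nominal level", {
  set.seed(13)
  rates <- replicate(6, {
    n <- 120; g <- 100
    m <- tiny_counts(matrix(rpois(n * g, 10L), n, g))
    norm <- normalize_scale(m)
    norm$scaled <- matrix(rnorm(n * g), n, g)
    cs <- select_significant_components(norm, n_components = 15,
                                        var_frac_min = 0, n_perm = 60,
                                        seed = sample.int(1e6, 1))
    mean(cs$signif)
  })
  rate <- mean(rates)  # 90 component tests in total
  ci <- 2.576 * sqrt(0.05 * 0.95 / 90)
  expect_lt(rate, 0.05 + ci)
  expect_gt(rate, 0.05 - ci)
})

test_that("cell filters are order-independent", {
  set.seed(14)
  n <- 300
  qc <- data.frame(cell_id = sprintf("c%d", 1:n),
                   nGene = round(runif(n, 100, 1200)),
                   nUMI = round(runif(n, 500, 9000)),
                   percent.mito = runif(n, 0, 20))
  keep1 <- sort(filter_cells_thresholds(qc)$retained)
  perm <- sample(n)
  keep2 <- sort(filter_cells_thresholds(qc[perm, ])$retained)
  expect_identical(keep1, keep2)
})

test_that("repeating the loess filter changes under 0.3% of cells", {
  set.seed(15)
  n <- 5000
  nUMI <- round(runif(n, 1000, 9000))
  qc <- data.frame(cell_id = sprintf("c%d", 1:n),
                   nGene = round(0.1 * nUMI + rnorm(n, 0, 25)),
                   nUMI = nUMI, percent.mito = 0)
  out1 <- filter_cells_loess_residual(qc)
  qc2 <- qc[qc$cell_id %in% out1$retained, ]
  out2 <- filter_cells_loess_residual(qc2)
  expect_lt(length(out2$removed) / n, 0.003)
})

test_that("planted low-quality cells are caught at default thresholds", {
  d_good <- simulation_design(n_cells_per_condition = 300, n_genes = 600,
                              marker_genes_per_cluster = 20, seed = 16)
  good <- simulate_counts(d_good)
  # low-quality planting: shallow libraries and high mito load
  d_bad <- simulation_design(n_cells_per_condition = 30, n_genes = 600,
                             marker_genes_per_cluster = 20,
                             libsize_logmean = log(300),
                             mito_gene_fraction = 0.30, seed = 17)
  bad <- simulate_counts(d_bad)
  bad_ids <- paste0("bad_", bad$matrix$cell_ids)
  comb <- sc_counts(rbind(good$matrix$counts,
                          `rownames<-`(as.matrix(bad$matrix$counts),
                                       bad_ids)))
  qc <- compute_qc_metrics(comb)
  out <- filter_cells_thresholds(qc)
  recall <- mean(bad_ids %in% out$removed)
  expect_gte(recall, 0.95)
})
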