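# Shared small fixtures and oracles, built in code at test time.

# small dense integer matrix wrapped as sc_counts
tiny_counts <- function(m, cells = sprintf("c%d", seq_len(nrow(m))),
                        genes = sprintf("g%d", seq_len(ncol(m)))) {
  sc_counts(m, cell_ids = cells, gene_ids = genes)
}

# random sparse non-negative integer matrix
random_counts <- function(n_cells, n_genes, density = 0.2, max_count = 20,
                          seed = 1) {
  set.seed(seed)
  m <- matrix(0L, n_cells, n_genes)
  nz <- round(density * n_cells * n_genes)
  idx <- sample.int(n_cells * n_genes, nz)
  m[idx] <- sample.int(max_count, nz, replace = TRUE)
  tiny_counts(m, cells = sprintf("cell%04d", seq_len(n_cells)),
              genes = sprintf("gene%04d", seq_len(n_genes)))
}

# brute-force CSPA tally: O(R * n^2) loop, the independent oracle
brute_force_cspa <- function(partitions) {
  n <- length(partitions[[1]])
  R <- length(partitions)
  cm <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    cnt <- 0
    for (p in partitions) if (p[i] == p[j]) cnt <- cnt + 1
    cm[i, j] <- cnt / R
  }
  cm
}

# two-condition cluster-count table under a planted multiplier
simulate_proportion_table <- function(props, n_per_cond, multipliers = NULL,
                                      seed = 1) {
  set.seed(seed)
  k <- length(props)
  ctrl <- as.vector(stats::rmultinom(1, n_per_cond, props))
  pt <- if (is.null(multipliers)) props else {
    q <- props * multipliers; q / sum(q)
  }
  trt <- as.vector(stats::rmultinom(1, n_per_cond, pt))
  cluster <- c(rep(seq_len(k), ctrl), rep(seq_len(k), trt))
  condition <- c(rep("control", sum(ctrl)), rep("treated", sum(trt)))
  proportion_table(cluster, condition, levels = c("control", "treated"))
}

# well-separated Gaussian blobs in d dimensions
gaussian_blobs <- function(n_per, centers, sd = 0.5, seed = 1) {
  set.seed(seed)
  d <- ncol(centers)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(stats::rnorm(n_per * d, mean = rep(centers[i, ], each = n_per),
                        sd = sd), n_per, d)))
  labels <- rep(seq_len(nrow(centers)), each = n_per)
  list(coords = x, labels = labels)
}
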