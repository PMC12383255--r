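#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs the expression, and restores the caller's RNG state,
#' so that every stochastic operation draws from a stream governed solely by
#' its own seed argument.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Design of a two-condition synthetic droplet scRNA-seq experiment
#'
#' Describes the planted structure the generator emulates: negative-binomial
#' counts with log-normal library sizes, a small set of clusters of unequal
#' sizes distinguished by marker programs, mitochondrial genes carrying a
#' fixed fraction of the transcriptome, condition-dependent abundance shifts
#' and marker shifts, cycling-gene programs in a subset of cells, and a
#' regulon of transcription factors driving target genes.
#'
#' Defaults describe the study conditions used throughout the test surface:
#' five clusters of unequal size, 1,000 cells per condition, 1,000 genes
#' with 40 markers per cluster at log2FC 2, NB size 2, library sizes
#' log-normal around 5,000 UMIs, 5% mitochondrial transcriptome share.
#' The default population emulates the non-proliferating stem cells the
#' study subclustered (cycling cells were isolated out beforehand), so
#' `cycling_fraction` defaults to 0; cycle-scoring fixtures plant their
#' stated cycling fraction explicitly.
#'
#' @param n_clusters number of planted clusters.
#' @param n_cells_per_condition total cells per condition (split across
#'   clusters by `cluster_props`, or give `cells_per_cluster_per_condition`
#'   directly).
#' @param cluster_props control-condition cluster proportions (length
#'   `n_clusters`, sums to 1).
#' @param cells_per_cluster_per_condition optional integer matrix
#'   (`n_clusters` x 2, columns control/treated) overriding the proportional
#'   split.
#' @param n_genes total genes, including mitochondrial and cycling genes.
#' @param marker_genes_per_cluster markers elevated in each cluster.
#' @param marker_log2fc log2 fold elevation of a cluster's markers.
#' @param dispersion negative-binomial size parameter.
#' @param libsize_logmean,libsize_logsd log-normal library-size parameters.
#' @param mito_gene_fraction expected fraction of each cell's transcriptome
#'   carried by the mitochondrial genes (named with prefix `mt-`).
#' @param n_mito_genes number of mitochondrial genes.
#' @param doublet_rate planted doublet fraction used by [run_pipeline()]
#'   when it calls [inject_doublets()].
#' @param treated_abundance_multipliers per-cluster multiplicative shifts of
#'   treated-condition cluster proportions (renormalised so the treated
#'   total is unchanged).
#' @param treated_marker_shift_log2fc per-cluster additional log2 shift of
#'   marker expression in treated cells.
#' @param n_cycle_genes genes per cell-cycle phase program (G1/S and G2/M).
#' @param cycling_fraction fraction of cells assigned a cycling phase
#'   (split evenly between G1/S and G2/M).
#' @param cycle_log2fc log2 elevation of a phase program in cells of that
#'   phase.
#' @param n_tfs,n_targets,tfs_per_target,tf_effect,n_cells_regulon regulon
#'   simulation parameters, see [simulate_regulon()].
#' @param shared_driver if `TRUE`, the first transcription factor drives
#'   every target (the coregulation structure the consensus step detects).
#' @param seed integer seed.
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(n_clusters = 5L,
                              n_cells_per_condition = 1000L,
                              cluster_props = NULL,
                              cells_per_cluster_per_condition = NULL,
                              n_genes = 1000L,
                              marker_genes_per_cluster = 40L,
                              marker_log2fc = 2,
                              dispersion = 2,
                              libsize_logmean = log(5000),
                              libsize_logsd = 0.3,
                              mito_gene_fraction = 0.05,
                              n_mito_genes = 13L,
                              doublet_rate = 0.1,
                              treated_abundance_multipliers = rep(1, n_clusters),
                              treated_marker_shift_log2fc = rep(0, n_clusters),
                              n_cycle_genes = 50L,
                              cycling_fraction = 0,
                              cycle_log2fc = 2,
                              n_tfs = 43L,
                              n_targets = 4L,
                              tfs_per_target = 3L,
                              tf_effect = 1,
                              n_cells_regulon = 1000L,
                              shared_driver = TRUE,
                              seed = 1L) {
  if (is.null(cluster_props)) {
    cluster_props <- rev(seq_len(n_clusters)) + n_clusters / 2
    cluster_props <- cluster_props / sum(cluster_props)
  }
  stopifnot(length(cluster_props) == n_clusters,
            abs(sum(cluster_props) - 1) < 1e-8)
  if (is.null(cells_per_cluster_per_condition)) {
    treated_props <- cluster_props * treated_abundance_multipliers
    treated_props <- treated_props / sum(treated_props)
    cells_per_cluster_per_condition <- cbind(
      control = round(cluster_props * n_cells_per_condition),
      treated = round(treated_props * n_cells_per_condition))
  }
  design <- structure(as.list(environment()), class = "simulation_design")
  validate_design(design)
  design
}

validate_design <- function(d) {
  stopifnot(d$n_clusters >= 1, d$n_genes >= 1,
            d$marker_log2fc >= 0, d$dispersion > 0,
            all(d$treated_abundance_multipliers > 0))
  frac <- c(d$mito_gene_fraction, d$cycling_fraction)
  if (any(frac < 0 | frac > 1)) stop("fractions must lie in [0, 1]")
  if (d$doublet_rate < 0 || d$doublet_rate > 0.25)
    stop("doublet_rate must lie in [0, 0.25]")
  if (any(d$cells_per_cluster_per_condition < 0))
    stop("cell counts must be non-negative")
  if (sum(d$cells_per_cluster_per_condition) == 0)
    stop("design implies 0 total cells")
  invisible(d)
}

# Gene identity layout shared by simulate_counts and the QC/scoring stages:
# mt-* mitochondrial, g1s.* / g2m.* cycling programs, gene* background
# (markers are drawn from the background genes).
design_gene_ids <- function(d) {
  n_bg <- d$n_genes - d$n_mito_genes - 2L * d$n_cycle_genes
  if (n_bg < d$n_clusters * d$marker_genes_per_cluster)
    stop("n_genes too small for the requested marker/mito/cycle layout")
  c(paste0("mt-", seq_len(d$n_mito_genes)),
    paste0("g1s.", seq_len(d$n_cycle_genes)),
    paste0("g2m.", seq_len(d$n_cycle_genes)),
    paste0("gene", seq_len(n_bg)))
}

#' Simulate a two-condition droplet scRNA-seq count matrix
#'
#' Counts for cell i, gene g are NB(mu = libsize_i * p\[g | cluster,
#' condition, phase\], size = dispersion), where the gene-probability vector
#' p is a base log-normal expression program with the cluster's markers
#' elevated by `marker_log2fc` (plus the treated marker shift in treated
#' cells) and the cell's cycle-phase program elevated by `cycle_log2fc`,
#' renormalised to sum to one. Mitochondrial genes (prefix `mt-`) carry
#' `mito_gene_fraction` of the program mass in expectation.
#'
#' @param design a [simulation_design()].
#' @return A list with elements `matrix` ([sc_counts]), `cells` (the cell
#'   table: cell_id, condition, replicate, cluster, qc_pass), and `truth`
#'   (list: true_cluster, is_doublet, true_phase, planted_enriched,
#'   planted_depleted, marker_genes).
#' @export
simulate_counts <- function(design) {
  d <- validate_design(design)
  gene_ids <- design_gene_ids(d)
  with_seed(d$seed, {
    base <- stats::rlnorm(d$n_genes, meanlog = 0, sdlog = 1)
    names(base) <- gene_ids
    is_mito <- startsWith(gene_ids, "mt-")
    if (d$mito_gene_fraction > 0 && d$mito_gene_fraction < 1) {
      target <- d$mito_gene_fraction / (1 - d$mito_gene_fraction) *
        sum(base[!is_mito])
      base[is_mito] <- base[is_mito] * target / sum(base[is_mito])
    }
    bg <- gene_ids[startsWith(gene_ids, "gene")]
    marker_genes <- split(
      sample(bg, d$n_clusters * d$marker_genes_per_cluster),
      rep(seq_len(d$n_clusters), each = d$marker_genes_per_cluster))
    names(marker_genes) <- paste0("clust", seq_len(d$n_clusters))

    counts_cc <- d$cells_per_cluster_per_condition
    conds <- c("control", "treated")
    blocks <- list(); labels <- list()
    for (ci in 1:2) {
      for (k in seq_len(d$n_clusters)) {
        n_k <- counts_cc[k, ci]
        if (n_k == 0) next
        prog <- base
        fc <- d$marker_log2fc +
          if (ci == 2) d$treated_marker_shift_log2fc[k] else 0
        prog[marker_genes[[k]]] <- prog[marker_genes[[k]]] * 2^fc
        # phase assignment within the block
        n_cyc <- round(d$cycling_fraction * n_k)
        phase <- rep("none", n_k)
        if (n_cyc > 0)
          phase[sample.int(n_k, n_cyc)] <-
            sample(c("G1S", "G2M"), n_cyc, replace = TRUE)
        lib <- stats::rlnorm(n_k, d$libsize_logmean, d$libsize_logsd)
        block <- matrix(0L, n_k, d$n_genes)
        for (ph in unique(phase)) {
          idx <- which(phase == ph)
          p <- prog
          if (ph != "none") {
            pg <- gene_ids[startsWith(gene_ids,
                                      if (ph == "G1S") "g1s." else "g2m.")]
            p[pg] <- p[pg] * 2^d$cycle_log2fc
          }
          p <- p / sum(p)
          mu <- outer(lib[idx], p)
          block[idx, ] <- stats::rnbinom(length(mu), mu = mu,
                                         size = d$dispersion)
        }
        blocks[[length(blocks) + 1L]] <- block
        labels[[length(labels) + 1L]] <-
          data.frame(condition = conds[ci], cluster = k, phase = phase,
                     stringsAsFactors = FALSE)
      }
    }
    counts <- do.call(rbind, blocks)
    lab <- do.call(rbind, labels)
    cell_ids <- sprintf("cell%05d", seq_len(nrow(counts)))
    mat <- sc_counts(counts, cell_ids = cell_ids, gene_ids = gene_ids)
    cells <- data.frame(
      cell_id = cell_ids,
      condition = factor(lab$condition, levels = conds),
      replicate = "r1",
      cluster = NA_integer_,
      qc_pass = NA,
      stringsAsFactors = FALSE)
    mult <- d$treated_abundance_multipliers
    truth <- list(
      true_cluster = stats::setNames(lab$cluster, cell_ids),
      is_doublet = stats::setNames(rep(FALSE, length(cell_ids)), cell_ids),
      true_phase = stats::setNames(lab$phase, cell_ids),
      planted_enriched = which(mult > 1),
      planted_depleted = which(mult < 1),
      marker_genes = marker_genes)
    list(matrix = mat, cells = cells, truth = truth)
  })
}

#' Append artificial doublet cells to a simulated matrix
#'
#' Each doublet is the entrywise sum of the counts of two distinct randomly
#' chosen cells (droplet capture is additive in molecules). `floor(rate * n)`
#' doublets are appended and flagged in the ground truth.
#'
#' @param matrix an [sc_counts] object.
#' @param truth a ground-truth list as returned by [simulate_counts()], or
#'   `NULL`.
#' @param rate doublet fraction in `[0, 0.25]`, relative to the current cell
#'   count.
#' @param seed integer seed.
#' @return A list `matrix`, `truth` (with `is_doublet` extended and
#'   `doublet_parents` recorded).
#' @export
inject_doublets <- function(matrix, truth = NULL, rate, seed = 1L) {
  stopifnot(inherits(matrix, "sc_counts"))
  if (rate < 0 || rate > 0.25) stop("rate must lie in [0, 0.25]")
  n <- nrow(matrix$counts)
  n_db <- floor(rate * n)
  if (n_db == 0) return(list(matrix = matrix, truth = truth))
  with_seed(seed, {
    parents <- t(replicate(n_db, sample.int(n, 2L)))
    db <- matrix$counts[parents[, 1], , drop = FALSE] +
      matrix$counts[parents[, 2], , drop = FALSE]
    ids <- sprintf("doublet%04d", seq_len(n_db))
    rownames(db) <- ids
    out <- sc_counts(rbind(matrix$counts, db))
    if (!is.null(truth)) {
      truth$is_doublet <- c(truth$is_doublet,
                            stats::setNames(rep(TRUE, n_db), ids))
      truth$true_cluster <- c(truth$true_cluster,
                              stats::setNames(rep(NA_integer_, n_db), ids))
      truth$true_phase <- c(truth$true_phase,
                            stats::setNames(rep("none", n_db), ids))
      truth$doublet_parents <- cbind(matrix$cell_ids[parents[, 1]],
                                     matrix$cell_ids[parents[, 2]])
    }
    list(matrix = out, truth = truth)
  })
}

#' Simulate activated-cell counts for the response-rate statistic
#'
#' Draws binomial activated-cell counts for two populations (e.g. marker-pos
#' and marker-neg) under two conditions, mirroring in-situ quantification of
#' proliferating (Pcna-positive) cells.
#'
#' @param p_control_pos,p_treated_pos,p_control_neg,p_treated_neg activation
#'   probabilities per population x condition, in `[0, 1]`.
#' @param n total cells per group: a scalar or a length-4 vector in the
#'   order (pos control, pos treated, neg control, neg treated).
#' @param seed integer seed.
#' @return A `response_rate_input` data frame with columns population,
#'   condition, activated, total.
#' @export
simulate_cell_counts <- function(p_control_pos, p_treated_pos,
                                 p_control_neg, p_treated_neg,
                                 n, seed = 1L) {
  p <- c(p_control_pos, p_treated_pos, p_control_neg, p_treated_neg)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  n <- rep_len(as.integer(n), 4L)
  if (any(n < 1)) stop("group sizes must be >= 1")
  with_seed(seed, {
    act <- stats::rbinom(4L, size = n, prob = p)
    response_rate_input(
      population = c("pos", "pos", "neg", "neg"),
      condition = c("control", "treated", "control", "treated"),
      activated = act[c(1, 2, 3, 4)],
      total = n)
  })
}

#' Simulate a regulon: transcription factors driving target genes
#'
#' Each target gene's log-mean is a monotone (linear in standardised
#' log-expression) function of its true transcription factors with planted
#' signs, plus negative-binomial noise; decoy factors are independent. If
#' `shared_driver` is set in the design, the first factor drives every
#' target, emulating coregulation of multiple Notch effectors.
#'
#' @param design a [simulation_design()]; fields `n_tfs`, `n_targets`,
#'   `tfs_per_target`, `tf_effect`, `n_cells_regulon`, `dispersion`,
#'   `shared_driver` and `seed` are used.
#' @param seed optional seed overriding `design$seed`.
#' @param truth optional regulator truth (named list per target of signed
#'   vectors) to reuse, e.g. to draw a second condition with the same
#'   planted regulators.
#' @return A list: `expression` (cells x genes numeric matrix covering all
#'   factors and targets), `tf_ids`, `target_ids`, and `truth` — a named
#'   list per target of signed integer vectors (+1/-1) named by the true
#'   regulators.
#' @export
simulate_regulon <- function(design, seed = design$seed, truth = NULL) {
  d <- design
  stopifnot(d$n_tfs >= d$tfs_per_target)
  with_seed(seed, {
    n <- d$n_cells_regulon
    tf_ids <- paste0("tf", seq_len(d$n_tfs))
    target_ids <- paste0("target", seq_len(d$n_targets))
    tf_mu <- stats::rlnorm(d$n_tfs, meanlog = log(5), sdlog = 0.5)
    tfs <- sapply(seq_len(d$n_tfs), function(j)
      stats::rnbinom(n, mu = tf_mu[j], size = d$dispersion))
    colnames(tfs) <- tf_ids
    z <- scale(log1p(tfs))
    z[, apply(tfs, 2, stats::sd) == 0] <- 0
    given <- truth
    truth <- list()
    targets <- matrix(0, n, d$n_targets, dimnames = list(NULL, target_ids))
    for (t in seq_len(d$n_targets)) {
      if (!is.null(given)) {
        regs <- match(names(given[[target_ids[t]]]), tf_ids)
        signs <- as.integer(given[[target_ids[t]]])
      } else if (isTRUE(d$shared_driver)) {
        regs <- c(1L, sample(2:d$n_tfs, d$tfs_per_target - 1L))
        signs <- sample(c(-1L, 1L), length(regs), replace = TRUE)
      } else {
        regs <- sample.int(d$n_tfs, d$tfs_per_target)
        signs <- sample(c(-1L, 1L), length(regs), replace = TRUE)
      }
      eta <- as.vector(z[, regs, drop = FALSE] %*% signs)
      mu <- exp(log(10) + d$tf_effect * eta / sqrt(length(regs)))
      targets[, t] <- stats::rnbinom(n, mu = mu, size = d$dispersion)
      truth[[target_ids[t]]] <- stats::setNames(signs, tf_ids[regs])
    }
    expr <- cbind(tfs, targets)
    rownames(expr) <- sprintf("rcell%05d", seq_len(n))
    list(expression = expr, tf_ids = tf_ids, target_ids = target_ids,
         truth = truth)
  })
}
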