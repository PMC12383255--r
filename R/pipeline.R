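#' Run the full analysis pipeline on simulated data
#'
#' Orchestrates simulate -> qc -> cluster -> abundance -> cellcycle ->
#' regulators as configured, writing every intermediate table under
#' `out_dir` and recording a manifest of stage parameters and output file
#' digests. Two runs with the same configuration and design produce
#' identical manifests.
#'
#' @param config an `analysis_config` (see [default_config()]).
#' @param design a [simulation_design()]; defaults to the standard design
#'   seeded from the configuration.
#' @param out_dir output directory (created); `NULL` for a temporary one.
#' @param stages stages to run, in order; later stages require the outputs
#'   of earlier ones.
#' @return An object of class `sc_pipeline`: list of per-stage result
#'   bundles plus `manifest`.
#' @export
run_pipeline <- function(config = default_config(),
                         design = NULL,
                         out_dir = NULL,
                         stages = c("simulate", "qc", "cluster",
                                    "abundance", "cellcycle",
                                    "regulators")) {
  validate_config(config)
  if (is.null(design))
    design <- simulation_design(seed = stage_seed(config$seed, "simulate"),
                                doublet_rate = config$cluster$doublet_rate)
  if (is.null(out_dir)) out_dir <- tempfile("scq_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  order_all <- c("simulate", "qc", "cluster", "abundance", "cellcycle",
                 "regulators")
  stages <- order_all[order_all %in% stages]
  needs <- list(qc = "simulate", cluster = "qc", abundance = "cluster",
                cellcycle = "cluster", regulators = "cluster")
  for (s in stages) {
    miss <- setdiff(needs[[s]], stages)
    if (length(miss))
      stop("stage '", s, "' requires stage '", miss[1],
           "' which is not configured")
  }
  results <- list(); manifest <- list()
  record <- function(stage, params, files) {
    manifest[[stage]] <<- list(
      stage = stage, params = params,
      files = files,
      digests = as.vector(tools::md5sum(files)))
  }
  run_stage <- function(stage, code) {
    tryCatch(code, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           " (partial outputs preserved in ", out_dir, ")", call. = FALSE))
  }

  if ("simulate" %in% stages) run_stage("simulate", {
    sim <- simulate_counts(design)
    if (design$doublet_rate > 0) {
      db <- inject_doublets(sim$matrix, sim$truth, design$doublet_rate,
                            seed = stage_seed(config$seed, "doublets"))
      extra <- setdiff(db$matrix$cell_ids, sim$matrix$cell_ids)
      sim$matrix <- db$matrix; sim$truth <- db$truth
      parent1 <- db$truth$doublet_parents[, 1]
      sim$cells <- rbind(sim$cells, data.frame(
        cell_id = extra,
        condition = sim$cells$condition[match(parent1, sim$cells$cell_id)],
        replicate = "r1", cluster = NA_integer_, qc_pass = NA))
    }
    files <- write_counts(sim$matrix, file.path(out_dir, "counts"))
    f_cells <- write_tsv(sim$cells, file.path(out_dir, "cells.tsv"))
    f_truth <- write_tsv(
      data.frame(cell_id = names(sim$truth$true_cluster),
                 true_cluster = sim$truth$true_cluster,
                 is_doublet = sim$truth$is_doublet,
                 true_phase = sim$truth$true_phase),
      file.path(out_dir, "truth.tsv"))
    results$simulate <- sim
    record("simulate", design[c("n_clusters", "n_genes", "doublet_rate",
                                "seed")], c(files, f_cells, f_truth))
  })

  if ("qc" %in% stages) run_stage("qc", {
    sim <- results$simulate
    qc <- compute_qc_metrics(sim$matrix, config$qc$mito_prefix)
    lo <- filter_cells_loess_residual(qc, span = config$qc$loess_span,
                                      sd_mult = config$qc$sd_mult)
    th <- filter_cells_thresholds(
      lo$qc[lo$qc$cell_id %in% lo$retained, ],
      min_nGene = config$qc$min_nGene,
      max_percent_mito = config$qc$max_percent_mito,
      high_quantile = config$qc$high_quantile)
    retained <- th$retained
    mat <- sim$matrix[match(retained, sim$matrix$cell_ids), ]
    mat <- filter_genes_min_cells(mat, config$qc$min_cells_per_gene)
    qc_all <- lo$qc
    qc_all$removal_reason[match(th$qc$cell_id, qc_all$cell_id)] <-
      th$qc$removal_reason
    f <- write_tsv(qc_all, file.path(out_dir, "qc_metrics.tsv"))
    results$qc <- list(matrix = mat, qc = qc_all, retained = retained)
    record("qc", config$qc, f)
  })

  if ("cluster" %in% stages) run_stage("cluster", {
    mat <- results$qc$matrix
    ds <- score_artificial_doublets(
      mat, rate = config$cluster$doublet_rate,
      art_frac = config$cluster$doublet_art_frac,
      k = config$cluster$k, n_seeds = config$cluster$doublet_seeds,
      seed = stage_seed(config$seed, "doublet_screen"))
    keep <- ds$cell_id[!ds$flagged]
    mat2 <- mat[match(keep, mat$cell_ids), ]
    norm <- normalize_scale(mat2, config$normalize$scale_factor)
    genes <- select_variable_genes(norm)
    if (length(genes) < 30) {
      v <- apply(as.matrix(norm$lognorm), 2, stats::var)
      genes <- names(sort(v, decreasing = TRUE))[seq_len(
        min(200, length(v)))]
    }
    comps <- select_significant_components(
      norm, genes = genes,
      n_components = config$components$n_components,
      var_frac_min = config$components$var_frac_min,
      n_perm = config$components$n_perm,
      alpha = config$components$alpha,
      seed = stage_seed(config$seed, "jackstraw"))
    if (!any(comps$retained)) comps$retained[1:min(5, length(
      comps$retained))] <- TRUE
    cons <- consensus_cluster(
      comps, norm, genes = genes, k = config$cluster$k,
      cut_height = config$cluster$cut_height,
      min_markers = config$cluster$min_markers,
      lfc_min = config$cluster$lfc_min, alpha = config$cluster$alpha,
      seed = stage_seed(config$seed, "cluster"))
    dc <- if (length(unique(cons$labels)) >= 3)
      flag_doublet_clusters(cons$labels, norm, genes = genes) else NULL
    f_lab <- write_tsv(
      data.frame(cell_id = mat2$cell_ids, cluster = cons$labels),
      file.path(out_dir, "clusters.tsv"))
    f_ds <- write_tsv(ds, file.path(out_dir, "doublet_scores.tsv"))
    results$cluster <- list(labels = cons$labels, consensus = cons,
                             norm = norm, genes = genes, comps = comps,
                             doublet_scores = ds, doublet_clusters = dc,
                             cell_ids = mat2$cell_ids)
    record("cluster", config$cluster, c(f_lab, f_ds))
  })

  if ("abundance" %in% stages) run_stage("abundance", {
    cl <- results$cluster
    cells <- results$simulate$cells
    cond <- cells$condition[match(cl$cell_ids, cells$cell_id)]
    tab <- proportion_table(cl$labels, cond,
                            levels = c("control", "treated"))
    ab <- bootstrap_diff_abundance(tab, B = config$abundance$B,
                                   seed = stage_seed(config$seed,
                                                     "abundance"),
                                   alpha = config$abundance$alpha)
    f <- write_tsv(as.data.frame(ab), file.path(out_dir, "abundance.tsv"))
    results$abundance <- ab
    record("abundance", config$abundance, f)
  })

  if ("cellcycle" %in% stages) run_stage("cellcycle", {
    cl <- results$cluster
    sets <- list(
      G1S = grep("^g1s\\.", colnames(cl$norm$lognorm), value = TRUE),
      G2M = grep("^g2m\\.", colnames(cl$norm$lognorm), value = TRUE))
    sets <- sets[lengths(sets) > 0]
    if (!length(sets)) stop("no cycle-phase genes present")
    scores <- compute_cycle_scores(
      cl$norm, sets, n_bins = config$cellcycle$n_bins,
      per_gene = config$cellcycle$ctrl_per_gene,
      seed = stage_seed(config$seed, "cellcycle"))
    f <- write_tsv(as.data.frame(scores),
                   file.path(out_dir, "cycle_scores.tsv"))
    results$cellcycle <- scores
    record("cellcycle", config$cellcycle, f)
  })

  if ("regulators" %in% stages) run_stage("regulators", {
    reg_c <- simulate_regulon(design,
                              seed = stage_seed(config$seed, "reg_control"))
    reg_t <- simulate_regulon(design,
                              seed = stage_seed(config$seed, "reg_treated"),
                              truth = reg_c$truth)
    regulons <- lapply(list(control = reg_c, treated = reg_t), function(rg) {
      w <- fallback_weights(rg$expression, rg$tf_ids, rg$target_ids)
      refine_regulators(w, rg$expression,
                        elbow_tol = config$regulators$elbow_tol)
    })
    cons <- consensus_regulators(regulons,
                                 min_targets = config$regulators$min_targets)
    f <- write_tsv(as.data.frame(cons),
                   file.path(out_dir, "consensus_regulators.tsv"))
    results$regulators <- list(regulons = regulons, consensus = cons,
                                truth = reg_c$truth)
    record("regulators", config$regulators, f)
  })

  structure(list(results = results, manifest = manifest,
                 out_dir = out_dir, config = config, design = design),
            class = "sc_pipeline")
}

#' @export
print.sc_pipeline <- function(x, ...) {
  cat("sc_pipeline run:", length(x$manifest), "stage(s) in", x$out_dir,
      "\n")
  for (s in names(x$manifest))
    cat("  ", s, ": ", length(x$manifest[[s]]$files), " file(s)\n",
        sep = "")
  invisible(x)
}

#' Human-readable markdown report of a pipeline run
#'
#' @param x an `sc_pipeline` object.
#' @param path optional file to write the report to.
#' @return The report, a character vector of markdown lines (invisibly if
#'   written to file).
#' @export
report <- function(x, path = NULL) {
  stopifnot(inherits(x, "sc_pipeline"))
  r <- x$results
  lines <- c("# Pipeline report", "")
  if (!is.null(r$cluster)) {
    sizes <- table(r$cluster$labels)
    lines <- c(lines, "## Clusters", "",
               paste0("- cluster ", names(sizes), ": ",
                      as.integer(sizes), " cells"), "")
  } else lines <- c(lines, "## Clusters", "", "not run", "")
  if (!is.null(r$abundance)) {
    ab <- as.data.frame(r$abundance)
    lines <- c(lines, "## Differential abundance", "",
               "| cluster | diff | p_adj | direction |",
               "|---|---|---|---|",
               sprintf("| %s | %.4f | %.3g | %s |", ab$cluster, ab$diff,
                       ab$p_adj, ifelse(
                         ab$p_adj < attr(r$abundance, "alpha"),
                         ab$direction, "ns")), "")
  } else lines <- c(lines, "## Differential abundance", "", "not run", "")
  if (!is.null(r$cellcycle)) {
    sets <- setdiff(names(r$cellcycle), "cell_id")
    lines <- c(lines, "## Cell-cycle scores", "",
               sprintf("- %s: mean %.3f, sd %.3f", sets,
                       vapply(sets, function(s) mean(r$cellcycle[[s]]),
                              numeric(1)),
                       vapply(sets, function(s) stats::sd(r$cellcycle[[s]]),
                              numeric(1))), "")
  } else lines <- c(lines, "## Cell-cycle scores", "", "not run", "")
  if (!is.null(r$regulators)) {
    cr <- r$regulators$consensus
    lines <- c(lines, "## Consensus regulators", "",
               if (nrow(cr)) sprintf("- %s (support %d)", cr$tf,
                                     cr$support) else "none retained", "")
  } else lines <- c(lines, "## Consensus regulators", "", "not run", "")
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}
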