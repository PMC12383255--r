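#' Elbow (knee) point of a descending weight curve
#'
#' Locates the break in a descending-sorted curve of non-negative values as
#' the last index before the point of maximum perpendicular distance below
#' the chord joining the first and last points (both axes normalised to
#' `[0, 1]`, so the result is invariant to positive rescaling of the
#' weights). Flat curves, and curves whose maximum distance is below
#' `tol`, carry no break: the full length is returned (keep all).
#'
#' Used to threshold ranked regulator weights, ranked variable-gene
#' residuals, density-peak scores, and intensity profiles alike.
#'
#' @param weights numeric vector sorted in descending order, non-negative.
#' @param tol flat-curve tolerance on the normalised distance scale.
#' @return Integer index in `[1, length(weights)]`; the retained prefix is
#'   `weights[1:index]`.
#' @export
elbow_index <- function(weights, tol = 0.05) {
  n <- length(weights)
  if (n == 0) stop("empty weight vector")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (is.unsorted(rev(weights))) stop("weights must be sorted descending")
  if (n <= 2) return(n)
  span <- weights[1] - weights[n]
  if (span <= 0) return(n)  # flat: no break, keep all
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (weights - weights[n]) / span
  # distance to the chord from (0,1) to (1,0): |x + y - 1| / sqrt(2);
  # ranked weight curves bow below the chord, so signed distance suffices
  dist <- (1 - x - y) / sqrt(2)
  dist[dist < 0] <- 0
  if (max(dist) < tol) return(n)
  brk <- which.max(dist)  # first point after the break (ties: smallest)
  max(1L, brk - 1L)
}

#' Elbow point iterated to a fixpoint
#'
#' Repeatedly applies [elbow_index()] to the retained prefix until the cut
#' stabilises. On curves with a long, slowly declining tail the single-pass
#' chord distance can overshoot the corner; iterating re-normalises the
#' chord to the retained range and converges onto the sharp break, while
#' leaving single-pass results (including the keep-all verdict on flat
#' curves) unchanged.
#'
#' @inheritParams elbow_index
#' @return Integer index in `[1, length(weights)]`.
#' @export
elbow_index_fixpoint <- function(weights, tol = 0.05) {
  cur <- length(weights)
  repeat {
    idx <- elbow_index(weights[seq_len(cur)], tol = tol)
    if (idx >= cur) return(cur)
    cur <- idx
  }
}

#' Bin genes by average expression
#'
#' Assigns every gene to one of `n_bins` quantile bins of near-equal gene
#' count (sizes differ by at most one) on the per-gene mean log-normalised
#' expression over the stated cell population. Ties are broken
#' deterministically by gene order.
#'
#' @param norm an `sc_norm` object.
#' @param cells optional cell ids / indices defining the scored population
#'   (default: all cells).
#' @param n_bins number of bins.
#' @return Named integer vector: bin index in `1..n_bins` per gene.
#' @export
bin_genes_by_mean <- function(norm, cells = NULL, n_bins = 24) {
  stopifnot(inherits(norm, "sc_norm"))
  m <- norm$lognorm
  if (!is.null(cells)) m <- m[cells, , drop = FALSE]
  if (ncol(m) < n_bins)
    stop("fewer genes (", ncol(m), ") than bins (", n_bins, ")")
  mu <- Matrix::colMeans(m)
  ord <- order(mu, seq_along(mu))  # ties by gene order
  sizes <- tabulate(cut(seq_along(mu), n_bins, labels = FALSE), n_bins)
  bins <- integer(length(mu))
  bins[ord] <- rep.int(seq_len(n_bins), sizes)
  stats::setNames(bins, colnames(m))
}

#' Sample expression-matched control genes for a gene set
#'
#' For each set gene, draws `per_gene` genes (with replacement) from the
#' gene's own average-expression bin, excluding the gene itself, so the
#' control pool matches the set's expression-level distribution.
#'
#' @param bins gene bin assignment from [bin_genes_by_mean()].
#' @param gene_set character vector of set gene symbols.
#' @param per_gene control genes drawn per set gene.
#' @param seed integer seed.
#' @return A list: `pool` (character vector with multiplicity),
#'   `per_gene_pools` (list per set gene), `set` (the set genes found).
#' @export
sample_control_genes <- function(bins, gene_set, per_gene = 100, seed = 1L) {
  missing <- setdiff(gene_set, names(bins))
  if (length(missing)) {
    warning("set gene(s) absent from matrix, dropped: ",
            paste(missing, collapse = ", "))
    gene_set <- setdiff(gene_set, missing)
  }
  if (!length(gene_set)) stop("no set genes present in the matrix")
  with_seed(seed, {
    per_pools <- lapply(gene_set, function(g) {
      candidates <- names(bins)[bins == bins[[g]]]
      candidates <- setdiff(candidates, g)
      if (!length(candidates)) {
        warning("bin of gene ", g, " holds no other gene; empty pool")
        return(character(0))
      }
      if (per_gene == 0) return(character(0))
      sample(candidates, per_gene, replace = TRUE)
    })
    names(per_pools) <- gene_set
    list(pool = unlist(per_pools, use.names = FALSE),
         per_gene_pools = per_pools, set = gene_set)
  })
}

#' Cell-cycle (or arbitrary gene-set) scores with matched controls
#'
#' Scores each cell for each phase gene set as the difference between the
#' mean log-normalised expression of the set genes and the mean over the
#' set's expression-matched control pool.
#'
#' @param norm an `sc_norm` object.
#' @param sets named list of gene sets (e.g. `G1S`, `G2M`).
#' @param bins gene bins from [bin_genes_by_mean()]; computed over all cells
#'   if `NULL`.
#' @param per_gene control genes per set gene.
#' @param n_bins bins used when `bins` is `NULL`.
#' @param seed integer seed.
#' @return An object of class `cycle_scores`: data frame with `cell_id` and
#'   one score column per set; control pools attached as attribute
#'   `controls`.
#' @export
compute_cycle_scores <- function(norm, sets, bins = NULL, per_gene = 100,
                                 n_bins = 24, seed = 1L) {
  stopifnot(inherits(norm, "sc_norm"), is.list(sets), length(sets) > 0)
  if (is.null(bins)) bins <- bin_genes_by_mean(norm, n_bins = n_bins)
  m <- norm$lognorm
  out <- data.frame(cell_id = rownames(m), stringsAsFactors = FALSE)
  controls <- list()
  for (s in names(sets)) {
    ctrl <- sample_control_genes(bins, sets[[s]], per_gene = per_gene,
                                 seed = stage_seed(seed, s))
    set_mean <- Matrix::rowMeans(m[, ctrl$set, drop = FALSE])
    ctrl_mean <- if (length(ctrl$pool))
      Matrix::rowMeans(m[, ctrl$pool, drop = FALSE]) else 0
    out[[s]] <- as.numeric(set_mean - ctrl_mean)
    controls[[s]] <- ctrl
  }
  attr(out, "controls") <- controls
  class(out) <- c("cycle_scores", "data.frame")
  out
}

#' @export
print.cycle_scores <- function(x, ...) {
  sets <- setdiff(names(x), "cell_id")
  cat("cycle_scores: ", nrow(x), " cells, sets: ",
      paste(sets, collapse = ", "), "\n", sep = "")
  for (s in sets)
    cat(sprintf("  %s: mean %.3f, sd %.3f\n", s, mean(x[[s]]),
                stats::sd(x[[s]])))
  invisible(x)
}

#' Prevalence filter for regulator-network inference
#'
#' Keeps genes expressed (count > 0) in at least `min_global` of all cells,
#' or in at least `min_cluster` of the cells of at least one cluster.
#'
#' @param matrix an [sc_counts] object.
#' @param labels cluster labels, one per cell.
#' @param min_global global prevalence floor (fraction of all cells).
#' @param min_cluster per-cluster prevalence floor.
#' @return Character vector of retained gene ids.
#' @export
filter_genes_for_grn <- function(matrix, labels, min_global = 0.01,
                                 min_cluster = 0.10) {
  stopifnot(inherits(matrix, "sc_counts"),
            length(labels) == nrow(matrix$counts))
  det <- matrix$counts > 0
  global <- Matrix::colMeans(det)
  keep <- global >= min_global
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    keep <- keep |
      (Matrix::colMeans(det[idx, , drop = FALSE]) >= min_cluster)
  }
  matrix$gene_ids[keep]
}

#' Fallback regulator-weight matrix from rank correlation
#'
#' Builds a transcription-factor x target importance matrix as the absolute
#' Spearman correlation between each factor's and each target's expression
#' across cells. Serves as the self-contained default where an externally
#' inferred weight matrix (e.g. from gradient-boosted regression) is not
#' supplied; constant genes receive weight 0 with a note.
#'
#' @param expression cells x genes numeric matrix covering all listed genes.
#' @param tf_list,target_list character vectors of factor and target gene
#'   ids.
#' @return A matrix (factors x targets) of weights in `[0, 1]`, with
#'   attribute `provenance = "fallback"`.
#' @export
fallback_weights <- function(expression, tf_list, target_list) {
  miss <- setdiff(c(tf_list, target_list), colnames(expression))
  if (length(miss)) stop("genes absent from expression: ",
                         paste(miss, collapse = ", "))
  tfs <- expression[, tf_list, drop = FALSE]
  tgs <- expression[, target_list, drop = FALSE]
  const <- c(colnames(tfs)[apply(tfs, 2, stats::sd) == 0],
             colnames(tgs)[apply(tgs, 2, stats::sd) == 0])
  if (length(const))
    message("constant gene(s) assigned weight 0: ",
            paste(const, collapse = ", "))
  w <- abs(suppressWarnings(stats::cor(tfs, tgs, method = "spearman")))
  w[is.na(w)] <- 0
  dimnames(w) <- list(tf_list, target_list)
  attr(w, "provenance") <- "fallback"
  w
}

#' Refine regulator lists by elbow thresholding and sign assignment
#'
#' For each target, factors are sorted by importance weight; the descending
#' curve is cut at its elbow ([elbow_index()]) and the retained prefix is
#' signed by the Spearman correlation between factor and target expression
#' (negative when anticorrelated), computed over cells where either gene is
#' detected (minimum 30 cells, otherwise the sign is flagged undetermined
#' and reported as +1).
#'
#' @param weights factors x targets weight matrix (non-negative).
#' @param expression cells x genes matrix used for sign assignment.
#' @param targets targets to refine (default: all columns of `weights`).
#' @param elbow_tol tolerance passed to [elbow_index()].
#' @param min_sign_cells minimum informative cells for a determined sign.
#' @return An object of class `regulon_set`: named list per target of data
#'   frames (tf, rank, weight, sign, sign_determined).
#' @export
refine_regulators <- function(weights, expression,
                              targets = colnames(weights),
                              elbow_tol = 0.05, min_sign_cells = 30) {
  miss <- setdiff(targets, colnames(weights))
  if (length(miss)) stop("no weight column for target(s): ",
                         paste(miss, collapse = ", "))
  out <- lapply(targets, function(t) {
    w <- weights[, t]
    if (all(w == 0)) {
      message("target ", t, " has all-zero weights; empty regulon")
      return(data.frame(tf = character(0), rank = integer(0),
                        weight = numeric(0), sign = integer(0),
                        sign_determined = logical(0)))
    }
    ord <- order(-w, seq_along(w))
    ws <- w[ord]
    keep <- seq_len(elbow_index(as.numeric(ws), tol = elbow_tol))
    tf <- names(ws)[keep]
    sign <- rep(1L, length(tf)); determined <- rep(FALSE, length(tf))
    for (i in seq_along(tf)) {
      x <- expression[, tf[i]]; y <- expression[, t]
      use <- x > 0 | y > 0
      if (sum(use) >= min_sign_cells &&
          stats::sd(x[use]) > 0 && stats::sd(y[use]) > 0) {
        rho <- stats::cor(x[use], y[use], method = "spearman")
        if (!is.na(rho)) { sign[i] <- ifelse(rho < 0, -1L, 1L)
                           determined[i] <- TRUE }
      }
    }
    data.frame(tf = tf, rank = seq_along(tf), weight = as.numeric(ws[keep]),
               sign = sign, sign_determined = determined,
               stringsAsFactors = FALSE)
  })
  names(out) <- targets
  structure(out, class = "regulon_set")
}

#' @export
print.regulon_set <- function(x, ...) {
  cat("regulon_set:", length(x), "target(s)\n")
  for (t in names(x)) {
    r <- x[[t]]
    cat("  ", t, ": ",
        if (nrow(r)) paste0(ifelse(r$sign < 0, "-", "+"), r$tf,
                            collapse = ", ") else "(empty)", "\n", sep = "")
  }
  invisible(x)
}

#' Cross-condition consensus of refined regulators
#'
#' Retains factors that appear in the refined regulons of at least
#' `min_targets` targets in every condition, ranked by total support.
#'
#' @param regulons_by_condition named list (one entry per condition) of
#'   `regulon_set` objects.
#' @param targets targets to count over (default: union).
#' @param min_targets minimum targets per condition.
#' @return A data frame (tf, support, per-condition counts) of class
#'   `consensus_regulators`, ordered by decreasing support.
#' @export
consensus_regulators <- function(regulons_by_condition, targets = NULL,
                                 min_targets = 2) {
  stopifnot(length(regulons_by_condition) >= 2)
  conds <- names(regulons_by_condition)
  if (is.null(conds)) conds <- paste0("condition", seq_along(regulons_by_condition))
  counts <- lapply(regulons_by_condition, function(rs) {
    use <- if (is.null(targets)) names(rs) else intersect(targets, names(rs))
    tfs <- unlist(lapply(rs[use], function(r) unique(r$tf)))
    table(tfs)
  })
  all_tfs <- sort(unique(unlist(lapply(counts, names))))
  tab <- sapply(counts, function(ct) {
    v <- as.integer(ct[all_tfs]); v[is.na(v)] <- 0L; v
  })
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = length(all_tfs))
  colnames(tab) <- conds; rownames(tab) <- all_tfs
  keep <- rowSums(tab >= min_targets) == length(conds)
  out <- data.frame(tf = all_tfs[keep],
                    support = rowSums(tab)[keep],
                    tab[keep, , drop = FALSE],
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$support, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("consensus_regulators", "data.frame")
  out
}
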