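#' Build a shared-nearest-neighbour graph
#'
#' Finds each cell's k nearest neighbours by Euclidean distance in
#' component space (the neighbour set includes the cell itself; distance
#' ties are broken by cell index for determinism) and connects cells that
#' share neighbours. Edge weights follow either the rank scheme
#' (`rank_shared`, as in SNN-Cliq: `w = max over shared neighbours v of
#' (k - (rank_i(v) + rank_j(v)) / 2) / k`) or the Jaccard overlap of the
#' two neighbour sets (`jaccard`, as in Phenograph). Zero-weight edges are
#' dropped.
#'
#' @param coords cells x components numeric matrix (or a `component_space`).
#' @param k neighbours per cell.
#' @param scheme `"rank_shared"` or `"jaccard"`.
#' @return An igraph undirected weighted graph with vertex name attribute
#'   set to cell ids and graph attributes `scheme` and `k`.
#' @export
build_snn_graph <- function(coords, k = 20, scheme = c("jaccard",
                                                       "rank_shared")) {
  if (inherits(coords, "component_space"))
    coords <- coords$coords[, coords$retained, drop = FALSE]
  scheme <- match.arg(scheme)
  n <- nrow(coords)
  if (k >= n) stop("k (", k, ") must be smaller than the number of cells (",
                   n, ")")
  nn <- knn_index(coords, k)
  # long table: (cell i, neighbour v, rank of v in i's list)
  dt <- data.table::data.table(
    i = rep(seq_len(n), each = k),
    v = as.vector(t(nn)),
    r = rep(seq_len(k), times = n))
  pairs <- merge(dt, dt, by = "v", allow.cartesian = TRUE,
                 suffixes = c("_a", "_b"))
  pairs <- pairs[pairs$i_a < pairs$i_b, ]
  if (scheme == "rank_shared") {
    # SNN-Cliq: best shared neighbour, ranks averaged
    pairs$w <- (k - (pairs$r_a + pairs$r_b) / 2) / k
    agg <- pairs[, list(w = max(w)), by = c("i_a", "i_b")]
  } else {
    # Jaccard: |shared| / |union|; each row of `pairs` is one shared member
    agg <- pairs[, list(s = .N), by = c("i_a", "i_b")]
    agg$w <- agg$s / (2 * k - agg$s)
  }
  agg <- agg[agg$w > 0, ]
  g <- igraph::graph_from_data_frame(
    data.frame(from = agg$i_a, to = agg$i_b, weight = agg$w),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  ids <- rownames(coords)
  if (!is.null(ids)) igraph::V(g)$cell_id <- ids
  g$scheme <- scheme
  g$k <- k
  g
}

# k nearest neighbours (self included, rank 1) with index tie-breaking.
knn_index <- function(coords, k) {
  d <- as.matrix(stats::dist(coords))
  n <- nrow(d)
  t(vapply(seq_len(n), function(i)
    order(d[i, ], seq_len(n))[seq_len(k)], integer(k)))
}

#' Run an ensemble of base clusterings
#'
#' Executes every clusterer in the roster and collects one partition per
#' roster entry. The default roster pairs two graph community methods
#' (multilevel/Louvain and walktrap) with each SNN weighting scheme, a
#' Gaussian mixture on the component coordinates, and a density-peaks
#' clusterer — the pluggable stand-in for the published six-algorithm pool.
#' A clusterer failure is recorded and tolerated as long as at least three
#' partitions succeed.
#'
#' @param coords cells x components matrix (or `component_space`).
#' @param k SNN neighbours.
#' @param roster named list of functions `function(coords, graphs, seed)`
#'   returning an integer label vector; `NULL` for the default roster.
#' @param seed integer seed; each roster entry receives a name-salted
#'   substream.
#' @param max_g maximum mixture components for the Gaussian-mixture member.
#' @return An object of class `partition_ensemble`: list of integer label
#'   vectors (one per successful clusterer), with attributes `failures`
#'   and `n_cells`.
#' @export
run_base_clusterings <- function(coords, k = 20, roster = NULL, seed = 1L,
                                 max_g = 9) {
  if (inherits(coords, "component_space"))
    coords <- coords$coords[, coords$retained, drop = FALSE]
  graphs <- list(jaccard = build_snn_graph(coords, k, "jaccard"),
                 rank_shared = build_snn_graph(coords, k, "rank_shared"))
  if (is.null(roster)) roster <- default_roster(max_g = max_g)
  partitions <- list(); failures <- character(0)
  for (nm in names(roster)) {
    lab <- tryCatch(
      with_seed(stage_seed(seed, nm), roster[[nm]](coords, graphs)),
      error = function(e) e)
    if (inherits(lab, "error")) {
      warning("clusterer ", nm, " failed: ", conditionMessage(lab))
      failures <- c(failures, nm)
    } else {
      partitions[[nm]] <- as.integer(lab)
    }
  }
  if (length(partitions) < 3)
    stop("fewer than 3 base partitions succeeded (",
         length(partitions), ")")
  structure(partitions, class = "partition_ensemble",
            failures = failures, n_cells = nrow(coords))
}

default_roster <- function(max_g = 9) {
  list(
    louvain_jaccard = function(coords, graphs)
      igraph::membership(igraph::cluster_louvain(graphs$jaccard)),
    walktrap_jaccard = function(coords, graphs)
      igraph::membership(igraph::cluster_walktrap(graphs$jaccard)),
    louvain_rank = function(coords, graphs)
      igraph::membership(igraph::cluster_louvain(graphs$rank_shared)),
    walktrap_rank = function(coords, graphs)
      igraph::membership(igraph::cluster_walktrap(graphs$rank_shared)),
    gaussian_mixture = function(coords, graphs) {
      mclustBIC <- mclust::mclustBIC  # Mclust resolves this by name
      d <- coords[, seq_len(min(10, ncol(coords))), drop = FALSE]
      fit <- mclust::Mclust(d, G = 1:max_g, modelNames = "VVI",
                            verbose = FALSE)
      fit$classification
    },
    density_peaks = function(coords, graphs)
      density_peaks_cluster(coords[, seq_len(min(10, ncol(coords))),
                                   drop = FALSE])
  )
}

#' @export
print.partition_ensemble <- function(x, ...) {
  cat("partition_ensemble: ", length(x), " partitions over ",
      attr(x, "n_cells"), " cells\n", sep = "")
  for (nm in names(x))
    cat("  ", nm, ": ", length(unique(x[[nm]])), " clusters\n", sep = "")
  invisible(x)
}

#' Density-peaks clustering
#'
#' Local density from a Gaussian kernel at bandwidth `dc` (a low quantile
#' of pairwise distances); each point's `delta` is its distance to the
#' nearest point of higher density. Cluster centres are the points before
#' the elbow of the sorted `rho * delta` curve; remaining points are
#' assigned to the cluster of their nearest higher-density neighbour.
#'
#' @param coords cells x components matrix.
#' @param dc_quantile distance quantile for the kernel bandwidth.
#' @param max_centers cap on the number of centres considered.
#' @return Integer label vector.
#' @export
density_peaks_cluster <- function(coords, dc_quantile = 0.02,
                                  max_centers = 12) {
  d <- as.matrix(stats::dist(coords))
  n <- nrow(d)
  dc <- stats::quantile(d[upper.tri(d)], dc_quantile, names = FALSE)
  if (dc == 0) dc <- mean(d) * 0.01 + .Machine$double.eps
  rho <- rowSums(exp(-(d / dc)^2)) - 1
  ord <- order(-rho, seq_len(n))
  delta <- numeric(n); nn_higher <- integer(n)
  delta[ord[1]] <- max(d[ord[1], ]); nn_higher[ord[1]] <- ord[1]
  for (idx in 2:n) {
    i <- ord[idx]
    higher <- ord[seq_len(idx - 1)]
    j <- higher[which.min(d[i, higher])]
    delta[i] <- d[i, j]; nn_higher[i] <- j
  }
  gamma <- sort(rho * delta, decreasing = TRUE)
  n_centers <- min(elbow_index(gamma[seq_len(min(max_centers * 4, n))]),
                   max_centers)
  centers <- order(-(rho * delta), seq_len(n))[seq_len(n_centers)]
  labels <- integer(n)
  labels[centers] <- seq_len(n_centers)
  for (idx in seq_len(n)) {
    i <- ord[idx]
    if (labels[i] == 0) labels[i] <- labels[nn_higher[i]]
  }
  labels
}

#' CSPA consensus matrix of an ensemble of partitions
#'
#' Entry (i, j) is the fraction of partitions in which cells i and j share
#' a cluster label — the cluster-based similarity partitioning statistic.
#'
#' @param ensemble a `partition_ensemble` (or plain list of equal-length
#'   integer label vectors).
#' @return An object of class `consensus_matrix`: symmetric n x n matrix
#'   with unit diagonal and attribute `R` (number of partitions).
#' @export
cspa_consensus <- function(ensemble) {
  parts <- unclass(ensemble)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  R <- length(parts)
  if (R < 2) stop("need at least 2 partitions")
  n <- length(parts[[1]])
  stopifnot(all(vapply(parts, length, integer(1)) == n))
  cm <- matrix(0, n, n)
  for (p in parts) {
    cm <- cm + outer(p, p, "==")
  }
  cm <- cm / R
  structure(cm, class = c("consensus_matrix", "matrix"), R = R)
}

#' @export
print.consensus_matrix <- function(x, ...) {
  cat("consensus_matrix: ", nrow(x), " cells, ", attr(x, "R"),
      " partitions\n", sep = "")
  invisible(x)
}

#' Hierarchical tree over the consensus matrix and its conservative cut
#'
#' Builds an average-linkage tree on the consensus distance
#' `1 - co-clustering frequency` and cuts it at `cut_height` (default 0.2:
#' clusters co-cluster in at least 80% of partitions — the conservative
#' cutoff).
#'
#' @param cm a `consensus_matrix`.
#' @param linkage hclust agglomeration method.
#' @param cut_height tree cut height in `[0, 1]`.
#' @return An object of class `cluster_tree`: list with `tree` (hclust),
#'   `labels` (integer), `cut_height`.
#' @export
cut_consensus_tree <- function(cm, linkage = "average", cut_height = 0.2) {
  stopifnot(inherits(cm, "consensus_matrix"))
  tree <- stats::hclust(stats::as.dist(1 - unclass(cm)), method = linkage)
  labels <- stats::cutree(tree, h = cut_height)
  structure(list(tree = tree, labels = as.integer(labels),
                 cut_height = cut_height),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("cluster_tree: cut at ", x$cut_height, " -> ",
      length(unique(x$labels)), " clusters\n", sep = "")
  print(table(cluster = x$labels))
  invisible(x)
}

# Vectorised two-sample Wilcoxon rank-sum tests, one per gene (normal
# approximation with tie correction), plus log2 fold changes of the mean
# log-normalised expression.
pairwise_de_stats <- function(X1, X2) {
  n1 <- nrow(X1); n2 <- nrow(X2); n <- n1 + n2
  X <- rbind(as.matrix(X1), as.matrix(X2))
  ranks <- apply(X, 2, rank)
  R1 <- colSums(ranks[seq_len(n1), , drop = FALSE])
  U <- R1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tie_term <- apply(X, 2, function(col) {
    t <- table(col); sum(t^3 - t)
  })
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- (U - mu) / sqrt(pmax(sigma2, .Machine$double.eps))
  p <- 2 * stats::pnorm(-abs(z))
  p[sigma2 == 0] <- 1
  lfc <- (colMeans(as.matrix(X1)) - colMeans(as.matrix(X2))) / log(2)
  data.frame(p = p, log2fc = lfc)
}

#' Merge dendrogram-adjacent clusters lacking discriminating genes
#'
#' Each pair of neighbouring clusters (siblings in an average-linkage
#' dendrogram over cluster centroids in consensus-distance space) is
#' subjected to per-gene rank-sum tests on log-normalised expression with
#' Benjamini-Hochberg correction. A pair is merged when fewer than
#' `min_markers` genes discriminate it (adjusted p < `alpha` and
#' |log2FC| >= `lfc_min`); merging iterates until no adjacent pair merges.
#' Clusters of fewer than 3 cells are absorbed into their nearest
#' neighbour with a warning.
#'
#' @param labels integer cluster labels per cell.
#' @param norm an `sc_norm` object (log-normalised slot is used).
#' @param cm optional `consensus_matrix` defining between-cluster distance;
#'   centroid Euclidean distance on log-normalised expression is used when
#'   absent.
#' @param genes genes to test (default: all).
#' @param min_markers merge when fewer than this many discriminating genes.
#' @param lfc_min minimum |log2FC| for a discriminating gene.
#' @param alpha BH-adjusted significance level.
#' @return A list: `labels` (merged, renumbered consecutively), `report`
#'   (`merge_report` data frame: pair, n cells, discriminating genes,
#'   decision), `rounds`.
#' @export
merge_by_pairwise_de <- function(labels, norm, cm = NULL, genes = NULL,
                                 min_markers = 5, lfc_min = 0.5,
                                 alpha = 0.05) {
  stopifnot(inherits(norm, "sc_norm"),
            length(labels) == nrow(norm$lognorm))
  X <- norm$lognorm
  if (!is.null(genes)) X <- X[, genes, drop = FALSE]
  labels <- as.integer(labels)

  # absorb tiny clusters first
  repeat {
    sizes <- table(labels)
    tiny <- as.integer(names(sizes)[sizes < 3])
    if (!length(tiny) || length(sizes) <= 1) break
    cl <- tiny[1]
    cen <- cluster_centroids(X, labels)
    others <- setdiff(rownames(cen), as.character(cl))
    dists <- sqrt(colSums((t(cen[others, , drop = FALSE]) -
                             cen[as.character(cl), ])^2))
    nearest <- as.integer(others[which.min(dists)])
    warning("cluster ", cl, " has fewer than 3 cells; merged into ",
            nearest)
    labels[labels == cl] <- nearest
  }

  report <- list(); rounds <- 0L
  repeat {
    k <- length(unique(labels))
    if (k < 2) break
    rounds <- rounds + 1L
    pairs <- adjacent_cluster_pairs(labels, X, cm)
    merged_this_round <- FALSE
    best <- NULL
    for (pi in seq_len(nrow(pairs))) {
      a <- pairs[pi, 1]; b <- pairs[pi, 2]
      ia <- which(labels == a); ib <- which(labels == b)
      de <- pairwise_de_stats(X[ia, , drop = FALSE], X[ib, , drop = FALSE])
      adj <- stats::p.adjust(de$p, "BH")
      n_disc <- sum(adj < alpha & abs(de$log2fc) >= lfc_min, na.rm = TRUE)
      merge <- n_disc < min_markers
      report[[length(report) + 1L]] <-
        data.frame(cluster_a = a, cluster_b = b, n_a = length(ia),
                   n_b = length(ib), n_discriminating = n_disc,
                   merged = merge)
      if (merge && (is.null(best) || n_disc < best$n_disc))
        best <- list(a = a, b = b, n_disc = n_disc)
    }
    if (!is.null(best)) {
      labels[labels == best$b] <- best$a
      merged_this_round <- TRUE
    }
    if (!merged_this_round) break
  }
  labels <- as.integer(factor(labels, levels = sort(unique(labels))))
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(cluster_a = integer(0), cluster_b = integer(0),
               n_a = integer(0), n_b = integer(0),
               n_discriminating = integer(0), merged = logical(0))
  class(report) <- c("merge_report", "data.frame")
  list(labels = labels, report = report, rounds = rounds)
}

cluster_centroids <- function(X, labels) {
  cls <- sort(unique(labels))
  cen <- t(vapply(cls, function(cl)
    Matrix::colMeans(X[labels == cl, , drop = FALSE]), numeric(ncol(X))))
  rownames(cen) <- as.character(cls)
  cen
}

# dendrogram-adjacent cluster pairs: siblings whose merge joins two leaves
# in an average-linkage tree over cluster centroids (consensus distance if
# available, else centroid Euclidean distance)
adjacent_cluster_pairs <- function(labels, X, cm = NULL) {
  cls <- sort(unique(labels))
  k <- length(cls)
  if (k == 2) return(matrix(cls, nrow = 1))
  if (!is.null(cm)) {
    d <- matrix(0, k, k)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      d[i, j] <- d[j, i] <-
        1 - mean(unclass(cm)[labels == cls[i], labels == cls[j]])
    }
  } else {
    cen <- cluster_centroids(X, labels)
    d <- as.matrix(stats::dist(cen))
  }
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  sib <- tree$merge[tree$merge[, 1] < 0 & tree$merge[, 2] < 0, ,
                    drop = FALSE]
  pairs <- cbind(cls[-sib[, 1]], cls[-sib[, 2]])
  t(apply(pairs, 1, sort))
}

#' Artificial-doublet screen
#'
#' Generates artificial doublets by summing the counts of random cell
#' pairs, co-embeds them with the real cells (depth normalisation, log1p,
#' PCA on the most variable genes), and scores every real cell by the
#' fraction of its k nearest neighbours that are artificial (pANN-style),
#' averaged over `n_seeds` repetitions. Cells whose score exceeds the
#' `1 - rate` quantile of the score distribution are flagged.
#'
#' @param matrix an [sc_counts] object (QC-filtered).
#' @param rate expected doublet fraction in `(0, 0.25]`; drives the flagging
#'   threshold.
#' @param art_frac artificial doublets generated per real cell (DoubletFinder
#'   convention ~0.25).
#' @param k neighbours used for the score.
#' @param n_seeds repetitions averaged over.
#' @param n_pcs components of the co-embedding.
#' @param n_var_genes genes (by variance of log-normalised expression) used
#'   for the co-embedding.
#' @param seed integer seed.
#' @return An object of class `doublet_scores`: data frame (cell_id, score,
#'   flagged) with attribute `threshold`.
#' @export
score_artificial_doublets <- function(matrix, rate = 0.1, art_frac = 0.25,
                                      k = 20, n_seeds = 3, n_pcs = 10,
                                      n_var_genes = 500, seed = 1L) {
  stopifnot(inherits(matrix, "sc_counts"))
  if (rate <= 0) stop("rate must be positive: artificial doublets are ",
                      "required for scoring")
  if (rate > 0.25) stop("rate must lie in (0, 0.25]")
  n <- nrow(matrix$counts)
  n_art <- max(2L, ceiling(art_frac * n))
  scores <- matrix(0, n, n_seeds)
  for (s in seq_len(n_seeds)) {
    scores[, s] <- with_seed(stage_seed(seed, paste0("doublet", s)), {
      p1 <- sample.int(n, n_art, replace = TRUE)
      shift <- sample.int(n - 1L, n_art, replace = TRUE)
      p2 <- ((p1 + shift - 1L) %% n) + 1L  # distinct partner
      art <- matrix$counts[p1, , drop = FALSE] +
        matrix$counts[p2, , drop = FALSE]
      rownames(art) <- sprintf("art%05d", seq_len(n_art))
      comb <- sc_counts(rbind(matrix$counts, art))
      norm <- normalize_scale(comb)
      v <- apply(as.matrix(norm$lognorm), 2, stats::var)
      genes <- names(sort(v, decreasing = TRUE))[
        seq_len(min(n_var_genes, length(v)))]
      pc <- stats::prcomp(norm$scaled[, genes, drop = FALSE],
                          rank. = min(n_pcs, length(genes) - 1))
      nn <- knn_index(pc$x, k + 1L)[seq_len(n), -1, drop = FALSE]
      rowMeans(nn > n)  # fraction of neighbours that are artificial
    })
  }
  score <- rowMeans(scores)
  threshold <- stats::quantile(score, 1 - rate, names = FALSE)
  out <- data.frame(cell_id = matrix$cell_ids, score = score,
                    flagged = score > threshold, stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("doublet_scores", "data.frame")
  out
}

#' Flag clusters that look like mixtures of two other clusters
#'
#' Fits each cluster's centroid as a convex combination of every other
#' pair of centroids by constrained least squares; the mixture-fit score
#' is the best R-squared. Centroids are means of depth-normalised counts
#' (`expm1` of the log-normalised values), the scale on which droplet
#' capture is additive and a genuine doublet cluster is a linear mixture
#' of its parents. Clusters scoring above `r2_min` with an interior
#' mixing weight in `[0.25, 0.75]` are flagged as putative doublet
#' clusters.
#'
#' @param labels integer cluster labels per cell.
#' @param norm an `sc_norm` object.
#' @param genes genes used for the centroids (default all).
#' @param r2_min R-squared threshold for flagging.
#' @return A data frame of class `doublet_cluster_report`: cluster,
#'   best parent pair, mixing weight, r2, flagged.
#' @export
flag_doublet_clusters <- function(labels, norm, genes = NULL,
                                  r2_min = 0.95) {
  stopifnot(inherits(norm, "sc_norm"))
  cls <- sort(unique(labels))
  if (length(cls) < 3) stop("need at least 3 clusters")
  X <- norm$lognorm
  if (!is.null(genes)) X <- X[, genes, drop = FALSE]
  X <- expm1(X)  # depth-normalised counts: the additive scale
  cen <- cluster_centroids(X, labels)
  out <- lapply(seq_along(cls), function(ci) {
    target <- cen[ci, ]
    best <- list(r2 = -Inf)
    for (ai in seq_along(cls)) for (bi in seq_along(cls)) {
      if (ai >= bi || ai == ci || bi == ci) next
      a <- cen[ai, ]; b <- cen[bi, ]
      denom <- sum((a - b)^2)
      w <- if (denom == 0) 0.5 else sum((target - b) * (a - b)) / denom
      w <- min(max(w, 0), 1)
      fit <- w * a + (1 - w) * b
      tss <- sum((target - mean(target))^2)
      r2 <- if (tss == 0) 0 else 1 - sum((target - fit)^2) / tss
      if (r2 > best$r2)
        best <- list(r2 = r2, w = w, a = cls[ai], b = cls[bi])
    }
    data.frame(cluster = cls[ci], parent_a = best$a, parent_b = best$b,
               weight = best$w, r2 = best$r2,
               flagged = best$r2 > r2_min &&
                 best$w >= 0.25 && best$w <= 0.75)
  })
  out <- do.call(rbind, out)
  class(out) <- c("doublet_cluster_report", "data.frame")
  out
}

#' End-to-end consensus clustering
#'
#' Convenience wrapper chaining [run_base_clusterings()],
#' [cspa_consensus()], [cut_consensus_tree()] and [merge_by_pairwise_de()].
#'
#' @param coords component coordinates (or `component_space`).
#' @param norm `sc_norm` used for the merge step.
#' @param genes genes for the merge tests.
#' @param k,cut_height,min_markers,lfc_min,alpha,seed stage parameters.
#' @return An object of class `sc_consensus`: list with `labels`,
#'   `ensemble`, `consensus` matrix, `tree`, `merge`.
#' @export
consensus_cluster <- function(coords, norm, genes = NULL, k = 20,
                              cut_height = 0.2, min_markers = 5,
                              lfc_min = 0.5, alpha = 0.05, seed = 1L) {
  ensemble <- run_base_clusterings(coords, k = k, seed = seed)
  cm <- cspa_consensus(ensemble)
  tree <- cut_consensus_tree(cm, cut_height = cut_height)
  merged <- merge_by_pairwise_de(tree$labels, norm, cm = cm, genes = genes,
                                 min_markers = min_markers,
                                 lfc_min = lfc_min, alpha = alpha)
  structure(list(labels = merged$labels, ensemble = ensemble,
                 consensus = cm, tree = tree, merge = merged$report),
            class = "sc_consensus")
}

#' @export
print.sc_consensus <- function(x, ...) {
  cat("sc_consensus: ", length(x$labels), " cells -> ",
      length(unique(x$labels)), " clusters (", attr(x$consensus, "R"),
      " base partitions, cut ", x$tree$cut_height, ")\n", sep = "")
  print(table(cluster = x$labels))
  invisible(x)
}

#' @export
summary.sc_consensus <- function(object, ...) {
  sizes <- table(object$labels)
  cat("Consensus clustering of", length(object$labels), "cells\n")
  cat("  base partitions:", attr(object$consensus, "R"), "\n")
  cat("  clusters:", length(sizes), "\n")
  cat("  sizes:", paste(as.integer(sizes), collapse = ", "), "\n")
  cat("  merge rounds:", nrow(object$merge), "pairs tested,",
      sum(object$merge$merged), "merged\n")
  invisible(object)
}
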