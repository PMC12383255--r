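#' Per-cell quality-control metrics
#'
#' Computes the standard droplet QC covariates: detected genes (`nGene`,
#' genes with count > 0), total molecules (`nUMI`), and the percentage of
#' the transcriptome from mitochondrial genes (`percent.mito`, 0 for empty
#' cells).
#'
#' @param matrix an [sc_counts] object.
#' @param mito_prefix gene-symbol prefix identifying mitochondrial genes
#'   (zebrafish nomenclature: `"mt-"`).
#' @return A data frame with columns `cell_id`, `nGene`, `nUMI`,
#'   `percent.mito`.
#' @export
compute_qc_metrics <- function(matrix, mito_prefix = "mt-") {
  stopifnot(inherits(matrix, "sc_counts"))
  m <- matrix$counts
  nUMI <- Matrix::rowSums(m)
  nGene <- Matrix::rowSums(m > 0)
  mito <- startsWith(matrix$gene_ids, mito_prefix)
  if (!any(mito)) {
    warning("no genes match mito prefix '", mito_prefix,
            "'; percent.mito set to 0")
    pm <- rep(0, nrow(m))
  } else {
    pm <- ifelse(nUMI > 0, 100 * Matrix::rowSums(m[, mito, drop = FALSE]) /
                   nUMI, 0)
  }
  data.frame(cell_id = matrix$cell_ids, nGene = as.integer(nGene),
             nUMI = as.integer(nUMI), percent.mito = as.numeric(pm),
             stringsAsFactors = FALSE)
}

#' Library-complexity filter on the nGene ~ nUMI relationship
#'
#' Fits a loess curve (gaussian family) of detected genes against total
#' molecules and removes cells whose residual lies beyond `sd_mult`
#' standard deviations of the mean residual: low residuals indicate poor
#' library complexity, high residuals excessive complexity (likely
#' doublets).
#'
#' @param qc QC metrics table from [compute_qc_metrics()].
#' @param span loess span.
#' @param sd_mult residual SD multiplier beyond which cells are removed.
#' @return A list: `retained` (cell ids), `removed` (cell ids),
#'   `residuals` (named, all cells), and an augmented `qc` table with
#'   `loess_residual` and `removal_reason` columns.
#' @export
filter_cells_loess_residual <- function(qc, span = 0.5, sd_mult = 3) {
  if (nrow(qc) < 50)
    stop("need at least 50 cells for a stable loess fit")
  if (stats::sd(qc$nUMI) == 0)
    stop("nUMI is constant; loess fit is degenerate - use threshold ",
         "filtering only")
  fit <- stats::loess(nGene ~ nUMI, data = qc, span = span,
                      family = "gaussian", degree = 2,
                      control = stats::loess.control(surface = "direct"))
  r <- stats::residuals(fit)
  s <- stats::sd(r)
  # exact (noise-free) relationships leave only numerical dust: retain all
  tol <- 1e-8 * max(stats::sd(qc$nGene), 1)
  bad <- if (s <= tol) rep(FALSE, nrow(qc)) else abs(r - mean(r)) > sd_mult * s
  qc$loess_residual <- as.numeric(r)
  qc$removal_reason <- ifelse(bad, "complexity", NA_character_)
  list(retained = qc$cell_id[!bad], removed = qc$cell_id[bad],
       residuals = stats::setNames(as.numeric(r), qc$cell_id), qc = qc)
}

#' Threshold filters on detected genes and mitochondrial fraction
#'
#' Removes cells below the detected-gene floor, above the mitochondrial
#' percentage ceiling, or jointly above a high upper quantile of both nGene
#' and nUMI (the operationalisation of "abnormally high" complexity).
#' Boundaries are inclusive on the retained side: `nGene = 200` and
#' `percent.mito = 10` are retained at the defaults.
#'
#' @param qc QC metrics table.
#' @param min_nGene minimum detected genes (retained if `nGene >= min_nGene`).
#' @param max_percent_mito maximum mitochondrial percentage (retained if
#'   `percent.mito <= max_percent_mito`).
#' @param high_quantile joint upper quantile of nGene and nUMI above which
#'   (strictly, on both covariates) cells are removed; `1` disables the rule.
#' @return A list `retained`, `removed`, and `qc` with `removal_reason`.
#' @export
filter_cells_thresholds <- function(qc, min_nGene = 200,
                                    max_percent_mito = 10,
                                    high_quantile = 0.999) {
  reason <- rep(NA_character_, nrow(qc))
  reason[qc$percent.mito > max_percent_mito] <- "high_mito"
  reason[qc$nGene < min_nGene] <- "low_nGene"
  if (high_quantile < 1) {
    qg <- stats::quantile(qc$nGene, high_quantile, names = FALSE)
    qu <- stats::quantile(qc$nUMI, high_quantile, names = FALSE)
    reason[qc$nGene >= qg & qc$nUMI >= qu] <- "high_outlier"
  }
  qc$removal_reason <- reason
  bad <- !is.na(reason)
  list(retained = qc$cell_id[!bad], removed = qc$cell_id[bad], qc = qc)
}

#' Remove genes detected in too few cells
#'
#' @param matrix an [sc_counts] object.
#' @param min_cells genes detected (count > 0) in fewer than `min_cells`
#'   cells are dropped.
#' @return A gene-filtered [sc_counts] object.
#' @export
filter_genes_min_cells <- function(matrix, min_cells = 10) {
  stopifnot(inherits(matrix, "sc_counts"))
  keep <- Matrix::colSums(matrix$counts > 0) >= min_cells
  matrix[, which(keep)]
}

#' Depth-normalise, log-transform and scale a count matrix
#'
#' The conventional recipe: counts are scaled to a fixed per-cell total
#' (`scale_factor`), log1p-transformed (kept for scoring and differential
#' expression), then per-gene centred and unit-variance scaled (used only
#' for the component step). Optionally, replicate indicators are regressed
#' out of the scaled values (off by default).
#'
#' @param matrix a QC-filtered [sc_counts] object.
#' @param scale_factor fixed per-cell total after depth normalisation.
#' @param batch optional factor (one level per replicate) to regress out of
#'   the scaled values.
#' @return An object of class `sc_norm`: list with `lognorm` (sparse cells x
#'   genes), `scaled` (dense cells x genes, zero-variance genes all-zero),
#'   `depth` (per-cell totals), `recipe` tag.
#' @export
normalize_scale <- function(matrix, scale_factor = 1e4, batch = NULL) {
  stopifnot(inherits(matrix, "sc_counts"))
  depth <- Matrix::rowSums(matrix$counts)
  if (any(depth == 0))
    stop("zero-depth cell(s) present; QC filtering should remove them: ",
         paste(utils::head(matrix$cell_ids[depth == 0], 3), collapse = ", "))
  lognorm <- matrix$counts
  d <- Matrix::Diagonal(x = scale_factor / depth)
  lognorm <- d %*% lognorm
  lognorm@x <- log1p(lognorm@x)
  dimnames(lognorm) <- dimnames(matrix$counts)
  dense <- as.matrix(lognorm)
  mu <- colMeans(dense)
  sdv <- apply(dense, 2, stats::sd)
  scaled <- sweep(dense, 2, mu, "-")
  nz <- sdv > 0
  scaled[, nz] <- sweep(scaled[, nz, drop = FALSE], 2, sdv[nz], "/")
  scaled[, !nz] <- 0
  recipe <- sprintf("total=%g,log1p,zscale", scale_factor)
  if (!is.null(batch)) {
    batch <- as.factor(batch)
    if (nlevels(batch) > 1) {
      X <- stats::model.matrix(~batch)
      scaled <- stats::lm.fit(X, scaled)$residuals
      recipe <- paste0(recipe, ",batch_regressed")
    }
  }
  structure(list(lognorm = methods::as(lognorm, "CsparseMatrix"),
                 scaled = scaled, depth = depth, recipe = recipe),
            class = "sc_norm")
}

#' @export
print.sc_norm <- function(x, ...) {
  cat("sc_norm: ", nrow(x$scaled), " cells x ", ncol(x$scaled),
      " genes (", x$recipe, ")\n", sep = "")
  invisible(x)
}

#' Select highly variable genes from the mean-variance trend
#'
#' Fits a loess trend of log variance on log mean over the log-normalised
#' values, standardises the residuals, and cuts the descending curve of
#' positive residuals with the shared elbow detector iterated to its
#' fixpoint ([elbow_index_fixpoint()]): the
#' genes before the break are selected. When the residual curve carries no
#' break (e.g. all genes sit on the trend) no gene is selected.
#'
#' @param norm an `sc_norm` object.
#' @param span loess span for the trend fit.
#' @param elbow_tol flat-curve tolerance passed to [elbow_index()].
#' @return Character vector of selected gene ids, with the standardised
#'   residuals of all genes attached as attribute `residuals`.
#' @export
select_variable_genes <- function(norm, span = 0.5, elbow_tol = 0.05) {
  stopifnot(inherits(norm, "sc_norm"))
  dense <- as.matrix(norm$lognorm)
  if (ncol(dense) < 100) stop("need at least 100 genes")
  mu <- colMeans(dense)
  v <- apply(dense, 2, stats::var)
  ok <- mu > 0 & v > 0
  lm_ <- log(mu[ok]); lv <- log(v[ok])
  r <- if (diff(range(lm_)) < 1e-10) {
    lv - mean(lv)  # degenerate predictor: trend is a point
  } else {
    fit <- stats::loess(lv ~ lm_, span = span, degree = 2,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    stats::residuals(fit)
  }
  s <- stats::sd(r)
  sr <- if (s > 0) r / s else r * 0
  std_resid <- stats::setNames(rep(NA_real_, ncol(dense)), colnames(dense))
  std_resid[ok] <- sr
  pos <- sort(sr[sr > 0], decreasing = TRUE)
  selected <- character(0)
  if (length(pos) >= 2) {
    idx <- elbow_index_fixpoint(as.numeric(pos), tol = elbow_tol)
    # a flat curve (keep-all verdict) means no gene stands off the trend
    if (idx < length(pos)) selected <- names(pos)[seq_len(idx)]
  }
  attr(selected, "residuals") <- std_resid
  selected
}

#' Select significant principal components
#'
#' Components are retained iff they explain more than `var_frac_min` of the
#' variance across the first `n_components` components AND are flagged as
#' significant by a permutation test (parallel analysis): in each
#' repetition every gene's values are independently permuted across cells,
#' destroying all between-gene structure while preserving marginals, and
#' the per-component variances of the permuted matrices form the null
#' spectrum; component k is significant when its observed variance exceeds
#' the permutation null of component k at level `alpha`. For a
#' structureless matrix the leading-component comparison is exact, so
#' false retention runs at the nominal level.
#'
#' @param norm an `sc_norm` object.
#' @param genes genes to use (typically from [select_variable_genes()]);
#'   default all.
#' @param n_components maximum number of components examined.
#' @param var_frac_min minimum variance fraction (of the examined
#'   components' total) for retention.
#' @param n_perm permutation repetitions.
#' @param alpha significance level.
#' @param seed integer seed.
#' @return An object of class `component_space`: list with `coords` (cells x
#'   K), `loadings`, `var_frac` (non-increasing), `signif` (logical),
#'   `retained` (logical: both rules), `p_component`.
#' @export
select_significant_components <- function(norm, genes = NULL,
                                          n_components = 100,
                                          var_frac_min = 0.01,
                                          n_perm = 100,
                                          alpha = 0.05, seed = 1L) {
  stopifnot(inherits(norm, "sc_norm"))
  X <- norm$scaled
  if (!is.null(genes)) X <- X[, genes, drop = FALSE]
  n <- nrow(X); G <- ncol(X)
  K <- min(n_components, n - 1L, G)
  if (K < n_components)
    warning("only ", K, " components available; truncating from ",
            n_components)
  sv <- svd(X, nu = 0, nv = K)
  d2 <- sv$d^2
  var_frac <- d2[seq_len(K)] / sum(d2[seq_len(K)])
  null_d2 <- with_seed(seed, {
    out <- matrix(0, n_perm, K)
    for (r in seq_len(n_perm)) {
      Xp <- apply(X, 2, function(col) col[sample.int(n)])
      out[r, ] <- svd(Xp, nu = 0, nv = 0)$d[seq_len(K)]^2
    }
    out
  })
  p_component <- vapply(seq_len(K), function(k)
    (1 + sum(null_d2[, k] >= d2[k])) / (n_perm + 1), numeric(1))
  signif <- p_component < alpha
  retained <- var_frac > var_frac_min & signif
  coords <- X %*% sv$v[, seq_len(K), drop = FALSE]
  colnames(coords) <- paste0("PC", seq_len(K))
  rownames(coords) <- rownames(X)
  structure(list(coords = coords, loadings = sv$v, var_frac = var_frac,
                 signif = signif, retained = retained,
                 p_component = p_component),
            class = "component_space")
}

#' @export
print.component_space <- function(x, ...) {
  cat("component_space: ", nrow(x$coords), " cells, ",
      length(x$var_frac), " components examined, ",
      sum(x$retained), " retained\n", sep = "")
  invisible(x)
}
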