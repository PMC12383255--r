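#' Default analysis configuration
#'
#' Returns the full set of pipeline parameters with their documented
#' defaults. Every stage of [run_pipeline()] reads its parameters from this
#' structure; [load_config()] overlays a user file on top of it.
#'
#' @param seed integer master seed; every stochastic stage derives its own
#'   substream from it via [stage_seed()].
#' @return A named nested list of class `analysis_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    qc = list(
      mito_prefix = "mt-",
      loess_span = 0.5,
      sd_mult = 3,
      min_nGene = 200L,
      max_percent_mito = 10,
      high_quantile = 0.999,
      min_cells_per_gene = 10L
    ),
    normalize = list(scale_factor = 1e4),
    components = list(n_components = 100L, var_frac_min = 0.01,
                      n_perm = 100L, alpha = 0.05),
    cluster = list(k = 20L, cut_height = 0.2, min_markers = 5L,
                   lfc_min = 0.5, alpha = 0.05, doublet_rate = 0.1,
                   doublet_art_frac = 0.25, doublet_seeds = 3L),
    abundance = list(B = 10000L, alpha = 0.05),
    cellcycle = list(n_bins = 24L, ctrl_per_gene = 100L),
    regulators = list(min_global = 0.01, min_cluster = 0.10,
                      elbow_tol = 0.05, min_targets = 2L),
    respond = list(n_repeats = 50L, n_samples = 1000L)
  ), class = "analysis_config")
}

config_ranges <- list(
  "qc.loess_span" = c(0.1, 1),
  "qc.sd_mult" = c(0.5, Inf),
  "qc.min_nGene" = c(0, Inf),
  "qc.max_percent_mito" = c(0, 100),
  "qc.high_quantile" = c(0.5, 1),
  "qc.min_cells_per_gene" = c(0, Inf),
  "normalize.scale_factor" = c(1, Inf),
  "components.n_components" = c(1, Inf),
  "components.var_frac_min" = c(0, 1),
  "components.n_perm" = c(10, Inf),
  "components.alpha" = c(0, 1),
  "cluster.k" = c(2, Inf),
  "cluster.cut_height" = c(0, 1),
  "cluster.min_markers" = c(0, Inf),
  "cluster.lfc_min" = c(0, Inf),
  "cluster.alpha" = c(0, 1),
  "cluster.doublet_rate" = c(0, 0.25),
  "cluster.doublet_art_frac" = c(0, 1),
  "abundance.B" = c(100, Inf),
  "abundance.alpha" = c(0, 1),
  "cellcycle.n_bins" = c(2, Inf),
  "cellcycle.ctrl_per_gene" = c(0, Inf),
  "regulators.min_global" = c(0, 1),
  "regulators.min_cluster" = c(0, 1),
  "regulators.elbow_tol" = c(0, 1),
  "regulators.min_targets" = c(1, Inf),
  "respond.n_repeats" = c(1, Inf),
  "respond.n_samples" = c(100, Inf)
)

validate_config <- function(config) {
  for (key in names(config_ranges)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    val <- config[[parts[1]]][[parts[2]]]
    if (is.null(val)) next
    rng <- config_ranges[[key]]
    if (!is.numeric(val) || length(val) != 1 || is.na(val) ||
        val < rng[1] || val > rng[2])
      stop("config parameter ", key, " = ", val,
           " outside allowed range [", rng[1], ", ", rng[2], "]")
  }
  invisible(config)
}

#' Load an analysis configuration from a YAML or JSON file
#'
#' Absent keys take their documented defaults; all parameters are validated
#' against their allowed ranges at load time.
#'
#' @param path path to a YAML (or JSON, which YAML subsumes) file. An empty
#'   file yields the full default configuration.
#' @param seed optional master seed overriding both the default and the file.
#' @return An `analysis_config` list.
#' @export
load_config <- function(path, seed = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  config <- default_config()
  for (section in names(user)) {
    if (section == "seed") { config$seed <- as.integer(user$seed); next }
    if (!section %in% names(config))
      stop("unknown config section: ", section)
    for (key in names(user[[section]])) {
      if (!key %in% names(config[[section]]))
        stop("unknown config key: ", section, ".", key)
      config[[section]][[key]] <- user[[section]][[key]]
    }
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_config(config)
  config
}

#' Derive a stage-specific seed from the master seed
#'
#' Each stochastic stage seeds its own generator from the master seed salted
#' with the stage name, so that adding or reordering stages does not perturb
#' the draws of the others.
#'
#' @param seed integer master seed.
#' @param stage character stage name.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.double(seed) %% m
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% m
  as.integer(h)
}
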