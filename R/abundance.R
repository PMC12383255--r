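#' Cluster x condition proportion table
#'
#' Tabulates cell counts per cluster and condition, the input of the
#' bootstrapped difference-of-proportion test.
#'
#' @param cluster cluster label per cell.
#' @param condition condition per cell, a factor or character with the
#'   control level first.
#' @param levels optional explicit condition level order
#'   (control, treated).
#' @return An object of class `proportion_table`: integer matrix clusters x
#'   conditions with attribute `totals`.
#' @export
proportion_table <- function(cluster, condition, levels = NULL) {
  stopifnot(length(cluster) == length(condition))
  condition <- if (is.null(levels)) as.factor(condition)
    else factor(condition, levels = levels)
  if (nlevels(condition) != 2)
    stop("exactly two conditions are required, got: ",
         paste(levels(condition), collapse = ", "))
  tab <- table(cluster = cluster, condition = condition)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  structure(m, class = c("proportion_table", "matrix"),
            totals = colSums(m))
}

#' Bootstrapped difference-of-proportion test for cluster abundance
#'
#' For each cluster, the observed proportion difference (treated - control)
#' is compared against `B` simulated differences: per condition, a
#' Binomial(n_condition, observed proportion) draw divided by n, mimicking
#' a resampling of cluster membership at the observed rate. Under no
#' abundance change the simulated differences centre on the observed
#' difference and the doubled tail fraction at zero gives a two-sided
#' p-value (continuity-floored at 1/(B+1)), Bonferroni-corrected across
#' the clusters tested.
#'
#' @param table a `proportion_table` (clusters x 2, control column first
#'   unless `treated`/`control` are named).
#' @param B simulations per cluster (>= 100).
#' @param seed integer seed.
#' @param alpha significance level used for the printed verdicts.
#' @return An object of class `abundance_test`: data frame with cluster,
#'   per-condition proportions, observed difference, simulated-difference
#'   mean and SD, raw and Bonferroni-adjusted p-values and direction.
#' @export
bootstrap_diff_abundance <- function(table, B = 10000, seed = 1L,
                                     alpha = 0.05) {
  stopifnot(inherits(table, "proportion_table"))
  if (B < 100) stop("B must be >= 100")
  cn <- colnames(table)
  ctrl_col <- if ("control" %in% cn) "control" else cn[1]
  trt_col <- setdiff(cn, ctrl_col)[1]
  n_c <- attr(table, "totals")[[ctrl_col]]
  n_t <- attr(table, "totals")[[trt_col]]
  if (n_c < 1 || n_t < 1) stop("both condition totals must be >= 1")
  clusters <- rownames(table)
  skip <- rowSums(table) == 0
  if (any(skip))
    message("cluster(s) absent from both conditions skipped: ",
            paste(clusters[skip], collapse = ", "))
  use <- which(!skip)
  m <- length(use)
  res <- with_seed(seed, {
    out <- vector("list", m)
    for (ii in seq_along(use)) {
      i <- use[ii]
      p_c <- table[i, ctrl_col] / n_c
      p_t <- table[i, trt_col] / n_t
      sims <- stats::rbinom(B, n_t, p_t) / n_t -
        stats::rbinom(B, n_c, p_c) / n_c
      lo <- mean(sims <= 0); hi <- mean(sims >= 0)
      p_raw <- min(1, max(2 * min(lo, hi), 1 / (B + 1)))
      out[[ii]] <- data.frame(
        cluster = clusters[i],
        prop_control = p_c, prop_treated = p_t,
        diff = p_t - p_c,
        sim_mean = mean(sims), sim_sd = stats::sd(sims),
        p_raw = p_raw, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  res$p_adj <- pmin(1, res$p_raw * m)
  res$direction <- ifelse(res$diff > 0, "enriched",
                          ifelse(res$diff < 0, "depleted", "unchanged"))
  attr(res, "B") <- B
  attr(res, "alpha") <- alpha
  attr(res, "n_tested") <- m
  class(res) <- c("abundance_test", "data.frame")
  res
}

#' @export
print.abundance_test <- function(x, digits = 4, ...) {
  cat("Bootstrapped difference-of-proportion test (B = ", attr(x, "B"),
      ", Bonferroni over ", attr(x, "n_tested"), " clusters)\n", sep = "")
  df <- as.data.frame(x)
  df$prop_control <- round(df$prop_control, digits)
  df$prop_treated <- round(df$prop_treated, digits)
  df$diff <- round(df$diff, digits)
  df$sim_mean <- NULL; df$sim_sd <- NULL
  df$p_raw <- signif(df$p_raw, 3); df$p_adj <- signif(df$p_adj, 3)
  df$sig <- ifelse(df$p_adj < attr(x, "alpha"), "*", "")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Response rate: recruited cells over cells at risk
#'
#' `(p_treated - p_control) / (1 - p_control)`: the proportion of cells
#' recruited by the treatment among the cells that could be recruited
#' (those not already activated under control). Inputs may be given as
#' counts with totals or directly as fractions with totals of 1.
#'
#' @param activated_treated,total_treated,activated_control,total_control
#'   activated and total cell counts per condition.
#' @return The response rate, a fraction <= 1.
#' @export
compute_response_rate <- function(activated_treated, total_treated,
                                  activated_control, total_control) {
  if (total_treated < 1 || total_control < 1)
    stop("totals must be >= 1")
  p_t <- activated_treated / total_treated
  p_c <- activated_control / total_control
  if (any(c(p_t, p_c) < 0 | c(p_t, p_c) > 1))
    stop("activated counts must lie in [0, total]")
  if (p_c >= 1)
    stop("control activation is 1: no cells at risk, response rate ",
         "undefined")
  (p_t - p_c) / (1 - p_c)
}

#' Naive activation ratio
#'
#' The simple ratio of activated fractions between treated and control,
#' the statistic the response rate is designed to replace: it misleads
#' when baseline activation differs between populations (a 5-point gain on
#' a 15% baseline gives 0.20 / 0.15 = 1.33 although a larger share of the
#' recruitable cells responded than under a lower baseline).
#'
#' @param p_treated,p_control activated fractions.
#' @return `p_treated / p_control`.
#' @export
activation_ratio <- function(p_treated, p_control) {
  if (p_control <= 0) stop("control fraction must be positive")
  p_treated / p_control
}

#' Input table for the response-rate difference test
#'
#' @param population,condition,activated,total equal-length vectors; one
#'   row per population x condition cell (exactly two populations and the
#'   conditions control/treated).
#' @return A data frame of class `response_rate_input`.
#' @export
response_rate_input <- function(population, condition, activated, total) {
  df <- data.frame(population = as.character(population),
                   condition = as.character(condition),
                   activated = as.integer(activated),
                   total = as.integer(total), stringsAsFactors = FALSE)
  if (any(df$activated > df$total) || any(df$activated < 0))
    stop("activated counts must lie in [0, total]")
  if (any(df$total < 1)) stop("totals must be >= 1")
  class(df) <- c("response_rate_input", "data.frame")
  df
}

rr_cell <- function(input, population, condition) {
  row <- input[input$population == population &
                 input$condition == condition, ]
  if (nrow(row) != 1)
    stop("input must hold exactly one row for population ", population,
         ", condition ", condition)
  row
}

#' Monte-Carlo test of the difference in response rates
#'
#' The observed statistic is the difference of response rates between the
#' two populations. Its null assumes both populations share a common
#' activation probability within each condition (the pooled rate): in each
#' of `n_repeats` bootstrap repeats, `n_samples` simulated datasets draw
#' binomial activated counts at the observed group sizes under the pooled
#' rates and yield a null distribution of the difference. Per repeat, the
#' p-value is the fraction of null differences at least as extreme as the
#' observed one towards its own sign; the reported p-value is the maximum
#' over repeats, floored at 1/(n_samples + 1).
#'
#' @param input a `response_rate_input` with two populations and two
#'   conditions (control/treated).
#' @param n_repeats bootstrap repeats.
#' @param n_samples simulated datasets per repeat.
#' @param seed integer seed.
#' @return An object of class `response_rate_test`: list with per-population
#'   response rates, `observed_diff`, per-repeat p-values, `p_value`, and
#'   the pooled null rates.
#' @export
response_rate_difference_test <- function(input, n_repeats = 50,
                                          n_samples = 1000, seed = 1L) {
  stopifnot(inherits(input, "response_rate_input"))
  pops <- unique(input$population)
  if (length(pops) != 2) stop("exactly two populations are required")
  conds <- c("control", "treated")
  if (!all(conds %in% input$condition))
    stop("conditions must include control and treated")
  g <- list()
  for (p in pops) for (cd in conds) g[[paste(p, cd)]] <- rr_cell(input, p, cd)
  rr <- vapply(pops, function(p)
    compute_response_rate(g[[paste(p, "treated")]]$activated,
                          g[[paste(p, "treated")]]$total,
                          g[[paste(p, "control")]]$activated,
                          g[[paste(p, "control")]]$total), numeric(1))
  observed <- rr[[1]] - rr[[2]]
  pooled <- vapply(conds, function(cd) {
    rows <- input[input$condition == cd, ]
    sum(rows$activated) / sum(rows$total)
  }, numeric(1))
  if (pooled[["control"]] >= 1)
    stop("pooled control activation is 1; response rate undefined ",
         "under the null")
  sizes <- vapply(names(g), function(k) g[[k]]$total, numeric(1))
  p_repeats <- with_seed(seed, {
    vapply(seq_len(n_repeats), function(r) {
      rr_sim <- sapply(pops, function(p) {
        nt <- sizes[[paste(p, "treated")]]
        nc <- sizes[[paste(p, "control")]]
        at <- stats::rbinom(n_samples, nt, pooled[["treated"]])
        ac <- stats::rbinom(n_samples, nc, pooled[["control"]])
        out <- (at / nt - ac / nc) / (1 - ac / nc)
        out[ac == nc] <- NA_real_
        out
      })
      null_diff <- rr_sim[, 1] - rr_sim[, 2]
      null_diff <- null_diff[is.finite(null_diff)]
      frac <- if (observed <= 0) mean(null_diff <= observed)
        else mean(null_diff >= observed)
      max(frac, 1 / (n_samples + 1))
    }, numeric(1))
  })
  structure(list(response_rates = rr, observed_diff = observed,
                 pooled_null_rates = pooled, p_repeats = p_repeats,
                 p_value = max(p_repeats), n_repeats = n_repeats,
                 n_samples = n_samples),
            class = "response_rate_test")
}

#' @export
print.response_rate_test <- function(x, ...) {
  cat("Response-rate difference test (", x$n_repeats, " repeats x ",
      x$n_samples, " samples)\n", sep = "")
  for (p in names(x$response_rates))
    cat(sprintf("  response rate [%s]: %.4f\n", p, x$response_rates[[p]]))
  cat(sprintf("  observed difference: %.4f\n", x$observed_diff))
  cat(sprintf("  p-value (max over repeats): %.4g\n", x$p_value))
  invisible(x)
}

#' Bootstrap distribution of a measured proportion
#'
#' Binomial resamples of an observed proportion at the observed sample
#' size; used to visualise the sampling uncertainty of in-situ counts
#' (violin plots), not for testing.
#'
#' @param activated,total observed counts.
#' @param n_draws resamples.
#' @param seed integer seed.
#' @return Numeric vector of `n_draws` resampled proportions.
#' @export
bootstrap_proportion_distribution <- function(activated, total,
                                              n_draws = 10000, seed = 1L) {
  if (total < 1) stop("total must be >= 1")
  if (activated < 0 || activated > total)
    stop("activated must lie in [0, total]")
  with_seed(seed, stats::rbinom(n_draws, total, activated / total) / total)
}

#' Pearson chi-square test on a 2x2 table of proportions
#'
#' @param counts 2x2 integer matrix; all marginals must be positive.
#' @return A list (statistic, p_value, df = 1).
#' @export
chi_square_proportions <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("all marginals must be positive")
  ht <- stats::chisq.test(counts, correct = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value, df = 1)
}

#' Kruskal-Wallis rank test across groups
#'
#' Standard rank statistic with tie correction and chi-square approximation.
#' Degenerate input with all values identical yields statistic 0, p = 1.
#'
#' @param groups list of at least 3 numeric vectors, each of length >= 2.
#' @return A list (statistic, p_value, df).
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 3,
            all(lengths(groups) >= 2))
  values <- unlist(groups)
  if (length(unique(values)) == 1)
    return(list(statistic = 0, p_value = 1, df = length(groups) - 1))
  ht <- stats::kruskal.test(groups)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}
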