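## Group-comparison layer: Welch t / Mann-Whitney two-group tests and
## two-way ANOVA with Bonferroni-adjusted cell-wise post hoc comparisons.

#' Two-sided Mann-Whitney U test
#'
#' Exact when both groups have at most 8 observations and the pooled data
#' are tie-free; otherwise the tie-corrected normal approximation (with
#' continuity correction). The reported U is the statistic for the first
#' group (0 when every value of the first group precedes the second).
#'
#' @param a,b numeric vectors
#' @return list with `statistic` (U), `p_value`, `method`
#' @keywords internal
#' @export
mann_whitney <- function(a, b) {
  if (length(unique(c(a, b))) == 1L) {
    ## every pooled value tied: no evidence of a shift at all
    return(list(statistic = length(a) * length(b) / 2, p_value = 1,
                method = "degenerate (all values tied)"))
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- length(a) <= 8L && length(b) <= 8L && !ties
  w <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                           correct = TRUE))
  list(statistic = unname(w$statistic), p_value = w$p.value,
       method = if (exact) "exact" else "normal approximation, tie-corrected")
}

#' Compare two groups
#'
#' @param values_a,values_b numeric vectors (n >= 2 each)
#' @param test `"t_welch"` (unpaired Student's t with Welch correction) or
#'   `"mannwhitney"`
#' @return list with `statistic`, `p_value`, `method`
#' @export
compare_two <- function(values_a, values_b,
                        test = c("t_welch", "mannwhitney")) {
  test <- match.arg(test)
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs n >= 2")
  if (test == "t_welch") {
    if (stats::var(values_a) == 0 && stats::var(values_b) == 0)
      stop("degenerate variance: both groups are constant, t-test undefined")
    tt <- stats::t.test(values_a, values_b)
    return(list(statistic = unname(tt$statistic), p_value = tt$p.value,
                method = "Welch t"))
  }
  mw <- mann_whitney(values_a, values_b)
  list(statistic = mw$statistic, p_value = mw$p_value,
       method = paste("Mann-Whitney U,", mw$method))
}

#' Two-way ANOVA with Bonferroni-adjusted cell-wise post hoc comparisons
#'
#' Fits `value ~ factor_a * factor_b` with sum contrasts and Type-III sums
#' of squares (the layouts this package produces are frequently
#' unbalanced). Pairwise comparisons between the factor-combination cells
#' use the classical post hoc t statistic on the residual mean square, with
#' Bonferroni adjustment (raw p times the number of comparisons, capped at
#' 1).
#'
#' @param data data frame
#' @param value name of the response column
#' @param factor_a,factor_b names of the two factor columns
#' @return list with `anova_table` (Type-III tests) and `pairwise` (data
#'   frame: cell_a, cell_b, diff, t, df, p_raw, p_adj, n_comparisons)
#' @export
two_way_anova_bonferroni <- function(data, value, factor_a, factor_b) {
  fa <- factor(data[[factor_a]]); fb <- factor(data[[factor_b]])
  y <- data[[value]]
  cell <- interaction(fa, fb, drop = FALSE, sep = ":")
  tab <- table(cell)
  if (any(tab == 0L)) stop("empty cell in the two-way layout")
  if (any(tab < 2L)) stop("every cell needs >= 2 observations")
  df0 <- data.frame(y = y, a = fa, b = fb)
  fit <- stats::lm(y ~ a * b, data = df0,
                   contrasts = list(a = "contr.sum", b = "contr.sum"))
  an <- car::Anova(fit, type = 3)
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  lev <- levels(cell)
  m <- tapply(y, cell, mean)
  n <- as.integer(tab)
  pr <- utils::combn(length(lev), 2L)
  ncomp <- ncol(pr)
  rows <- lapply(seq_len(ncomp), function(k) {
    i <- pr[1L, k]; j <- pr[2L, k]
    se <- sqrt(mse * (1 / n[i] + 1 / n[j]))
    tstat <- (m[i] - m[j]) / se
    p_raw <- 2 * stats::pt(-abs(tstat), fit$df.residual)
    data.frame(cell_a = lev[i], cell_b = lev[j], diff = unname(m[i] - m[j]),
               t = unname(tstat), df = fit$df.residual, p_raw = p_raw,
               p_adj = min(1, p_raw * ncomp), stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, rows)
  pw$n_comparisons <- ncomp
  rownames(pw) <- NULL
  list(anova_table = an, pairwise = pw)
}

#' Bonferroni adjustment of raw p values
#'
#' Adjusted p = raw p x number of comparisons, capped at 1; with a single
#' comparison the adjusted value equals the raw one.
#'
#' @param p_raw numeric vector of raw p values
#' @param n_comparisons number of comparisons in the family (default:
#'   `length(p_raw)`)
#' @return adjusted p values
#' @export
bonferroni_adjust <- function(p_raw, n_comparisons = length(p_raw)) {
  pmin(1, p_raw * n_comparisons)
}

#' Assemble grouped measures for reporting
#'
#' Standardises pipeline outputs into the long layout consumed by the test
#' functions, keeping both the animal and the within-animal replicate level
#' so analyses can be run (and labelled) at either level.
#'
#' @param value numeric measurements
#' @param unit unit string
#' @param animal_id animal identifier per value
#' @param group group label per value (e.g. genotype x treatment)
#' @param replicate_id within-animal replicate (cell/image) id
#' @return data frame of class `grouped_measure`
#' @export
grouped_measure <- function(value, unit, animal_id, group,
                            replicate_id = seq_along(value)) {
  out <- data.frame(value = value, unit = unit, animal_id = animal_id,
                    group = group, replicate_id = replicate_id,
                    stringsAsFactors = FALSE)
  class(out) <- c("grouped_measure", class(out))
  out
}

#' Collapse a grouped measure to per-animal means
#'
#' Imaging measures are often replicated within animals (many cells per
#' mouse); this collapses to one value per animal so tests can be run at
#' the animal level alongside the replicate level.
#'
#' @param gm a [grouped_measure()]
#' @return data frame with one row per animal
#' @export
animal_level <- function(gm) {
  out <- aggregate(value ~ animal_id + group, gm, mean)
  out$unit <- gm$unit[1L]
  out
}
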