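# Two-way ANOVA (day x stain) and Tukey HSD post-hoc comparisons for the
# intensity, front-depth and area tables. Thin, tidy wrappers over the
# standard stats machinery.

#' Two-way analysis of variance (day x stain)
#'
#' Standard two-way decomposition with p-values from the F distribution.
#' With one observation per cell (the usual design here: one sample per
#' stain scanned once per day) the additive model is fitted — the
#' interaction would consume every residual degree of freedom; when cell
#' replicates exist the interaction term is included.
#'
#' @param values response (intensity, front depth, or area).
#' @param day,stain factors (coerced), each with >= 2 levels.
#' @return data.frame with one row per term plus residuals: `term`, `df`,
#'   `sumsq`, `meansq`, `statistic` (F), `p_value`. Attribute `"balanced"`
#'   flags equal cell counts.
#' @export
twoWayAnova <- function(values, day, stain) {
  day <- factor(day); stain <- factor(stain)
  stopifnot(length(values) == length(day), length(values) == length(stain))
  if (nlevels(day) < 2L || nlevels(stain) < 2L)
    stop("both factors need at least 2 levels")
  counts <- table(day, stain)
  if (any(counts == 0L))
    stop("empty day x stain cells: the two-way decomposition is undefined")
  balanced <- length(unique(as.vector(counts))) == 1L
  if (!balanced)
    warning("unbalanced design: sums of squares are sequential")
  withInteraction <- any(counts > 1L)
  form <- if (withInteraction) values ~ day * stain else values ~ day + stain
  fit <- aov(form, data = data.frame(values = values, day = day,
                                     stain = stain))
  tab <- summary(fit)[[1L]]
  out <- data.frame(term = trimws(rownames(tab)), df = tab[["Df"]],
                    sumsq = tab[["Sum Sq"]], meansq = tab[["Mean Sq"]],
                    statistic = tab[["F value"]],
                    p_value = tab[["Pr(>F)"]], row.names = NULL)
  attr(out, "balanced") <- balanced
  out
}

#' Tukey honest-significant-difference pairwise comparisons
#'
#' One-way Tukey HSD across groups: studentized-range-based pairwise mean
#' differences with family-wise adjusted p-values and simultaneous
#' confidence intervals. The `q` column is the studentized range statistic
#' \eqn{q_{ij} = (\bar y_i - \bar y_j) / \sqrt{(MSE/2)(1/n_i + 1/n_j)}}.
#'
#' @param values response vector.
#' @param groups group labels (>= 2 groups, each with >= 2 observations).
#' @param alpha family-wise significance level for the `significant` flag
#'   and the confidence intervals.
#' @return data.frame `group1`, `group2`, `diff`, `lwr`, `upr`, `q`,
#'   `p_adj`, `significant`.
#' @export
tukeyHsd <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  n <- table(groups)
  if (any(n < 2L)) stop("every group needs at least 2 observations: ",
                        paste(names(n)[n < 2L], collapse = ", "))
  fit <- aov(values ~ groups, data = data.frame(values = values,
                                                groups = groups))
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$groups
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  pair <- strsplit(rownames(tk), "-", fixed = TRUE)
  g1 <- vapply(pair, `[`, "", 1L)
  g2 <- vapply(pair, `[`, "", 2L)
  se <- sqrt(mse / 2 * (1 / n[g1] + 1 / n[g2]))
  data.frame(group1 = g1, group2 = g2, diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"],
             q = as.numeric(tk[, "diff"] / se),
             p_adj = tk[, "p adj"],
             significant = tk[, "p adj"] < alpha, row.names = NULL)
}
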