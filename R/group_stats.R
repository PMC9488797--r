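#' One-way ANOVA with Tukey's honest significance test
#'
#' Pairwise group comparisons via the studentized range with family-wise
#' adjustment (Tukey-Kramer for unbalanced designs), as implemented by
#' `stats::aov()` + `stats::TukeyHSD()`, returned as a tidy table.
#'
#' @param values per-mouse numeric values (typically ANCOVA-adjusted
#'   summaries).
#' @param groups group labels.
#' @param conf_level family-wise confidence level.
#' @return tibble with `contrast`, `estimate`, `conf_low`, `conf_high`,
#'   `p_adj`.
#' @export
anova_tukey <- function(values, groups, conf_level = 0.95) {
  groups <- droplevels(factor(groups))
  stopifnot(length(values) == length(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (all(table(groups) < 2)) {
    stop("need at least 2 observations in some group", call. = FALSE)
  }
  if (length(values) <= nlevels(groups)) {
    stop("no residual degrees of freedom (single observation per group)",
         call. = FALSE)
  }
  dat <- data.frame(value = values, group = groups)
  fit <- stats::aov(value ~ group, data = dat)
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$group
  tibble::tibble(contrast = rownames(tk),
                 estimate = tk[, "diff"],
                 conf_low = tk[, "lwr"],
                 conf_high = tk[, "upr"],
                 p_adj = tk[, "p adj"])
}

#' Least-squares linear fit
#'
#' Simple wrapper over `stats::lm()` for the regression reports used
#' throughout the pipeline (e.g. estimating lean mass without the cecum
#' from lean mass with the cecum).
#'
#' @param y response vector.
#' @param x design: a numeric vector, matrix or data frame of predictors
#'   (intercept added automatically).
#' @return list with `coefficients`, `residuals`, `r_squared`,
#'   `adj_r_squared` and the `lm` fit.
#' @export
fit_linear <- function(y, x) {
  if (is.numeric(x) && is.null(dim(x))) x <- data.frame(x = x)
  x <- as.data.frame(x)
  stopifnot(nrow(x) == length(y))
  mm <- stats::model.matrix(~ ., data = x)
  if (qr(mm)$rank < ncol(mm)) {
    stop("rank-deficient design (duplicated or collinear predictors)",
         call. = FALSE)
  }
  dat <- cbind(data.frame(.y = y), x)
  fit <- stats::lm(stats::as.formula(
    paste(".y ~", paste(names(x), collapse = " + "))), data = dat)
  s <- summary(fit)
  list(coefficients = stats::coef(fit),
       residuals = as.numeric(stats::residuals(fit)),
       r_squared = s$r.squared,
       adj_r_squared = s$adj.r.squared,
       model = fit)
}
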