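#' Regression-based (ANCOVA) covariate adjustment
#'
#' Mass-dependent outcomes (energy expenditure, hydrogen production) cannot
#' be compared across groups by dividing by body mass when body composition
#' differs systematically between groups — the germ-free cecum alone can be
#' ~10 % of body mass and is metabolically inert. Instead a linear model
#' `value ~ covariates + group` (single slope, group as a qualitative
#' covariate, no interactions) is fitted, and each individual value is
#' replaced by its residual plus the model prediction at the grand-mean
#' covariates (mouse-weighted means over all groups) with the mouse's own
#' group coefficient. Group contrasts on the adjusted values therefore
#' equal the ANCOVA adjusted means, and adding a constant to any covariate
#' changes no adjusted value.
#'
#' @param values per-mouse numeric summaries (e.g. phase EE AUC, kcal).
#' @param covariates data frame of per-mouse numeric covariates (e.g.
#'   `lean_mass_g`, `fat_total_g`); a single numeric vector is accepted.
#' @param groups group labels, same length as `values`.
#' @return an object of class `ancova_fit`: list with `response`,
#'   `covariate_names`, `coefficients`, `residuals`, `grand_means`,
#'   `adjusted` (per-mouse adjusted values), `groups` and the `lm` fit.
#' @export
ancova_adjust <- function(values, covariates, groups) {
  if (is.numeric(covariates)) {
    covariates <- data.frame(covariate = covariates)
  }
  covariates <- as.data.frame(covariates)
  n <- length(values)
  stopifnot(nrow(covariates) == n, length(groups) == n, n >= 2)
  if (!all(vapply(covariates, is.numeric, logical(1)))) {
    stop("covariates must be numeric", call. = FALSE)
  }
  degenerate <- vapply(covariates, function(x) stats::var(x) == 0, logical(1))
  if (any(degenerate)) {
    # a constant covariate shifts every prediction identically, so the
    # adjustment it would produce is exactly zero; drop it and carry on
    warning("degenerate covariate(s) dropped (zero variance): ",
            paste(names(covariates)[degenerate], collapse = ", "),
            call. = FALSE)
    covariates <- covariates[, !degenerate, drop = FALSE]
  }
  if (ncol(covariates) > 1) {
    cc <- stats::cor(as.matrix(covariates))
    diag(cc) <- 0
    if (any(abs(cc) > 1 - 1e-10)) {
      bad <- which(abs(cc) > 1 - 1e-10, arr.ind = TRUE)[1, ]
      stop("collinear covariates: ", colnames(cc)[bad[1]], " and ",
           colnames(cc)[bad[2]], call. = FALSE)
    }
  }
  groups <- factor(groups)
  small <- table(groups)
  if (any(small == 1)) {
    warning("group(s) with a single mouse: ",
            paste(names(small)[small == 1], collapse = ", "), call. = FALSE)
  }
  dat <- cbind(data.frame(.value = values), covariates)
  terms <- names(covariates)
  if (nlevels(droplevels(groups)) > 1) {
    dat$.group <- droplevels(groups)
    terms <- c(terms, ".group")
  }
  if (!length(terms)) terms <- "1"
  form <- stats::as.formula(paste(".value ~", paste(terms, collapse = " + ")))
  fit <- stats::lm(form, data = dat)
  grand <- vapply(covariates, mean, numeric(1))
  newdat <- if (length(grand)) {
    as.data.frame(as.list(grand))[rep(1, n), , drop = FALSE]
  } else data.frame(row.names = seq_len(n))
  if (".group" %in% terms) newdat$.group <- dat$.group
  adjusted <- as.numeric(stats::residuals(fit) + stats::predict(fit, newdata = newdat))
  structure(list(response = deparse(substitute(values)),
                 covariate_names = names(covariates),
                 coefficients = stats::coef(fit),
                 residuals = as.numeric(stats::residuals(fit)),
                 grand_means = grand,
                 grand_mean_weighting = "mouse-weighted (over all mice, pooled across groups)",
                 adjusted = adjusted,
                 groups = groups,
                 model = fit),
            class = "ancova_fit")
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat("<ancova_fit> value ~", paste(x$covariate_names, collapse = " + "),
      "+ group\n")
  cat("  grand means (", x$grand_mean_weighting, "):\n", sep = "")
  print(round(x$grand_means, 4))
  cat("  coefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Adjust hydrogen production by cecal mass
#'
#' Hydrogen output scales with the amount of fermenting biomass; cecal mass
#' (tissue plus luminal content) serves as the proxy for total gut
#' microbiota mass. Germ-free animals produce no hydrogen and carry no
#' microbial biomass, so they are excluded from the fit rather than
#' anchoring a meaningless slope.
#'
#' @param h2_auc per-mouse hydrogen AUC values.
#' @param cecal_mass_g per-mouse cecal mass (g).
#' @param groups group labels; mice in `exclude` groups are dropped.
#' @param exclude groups excluded from the fit (default `"GF"`).
#' @return an [ancova_adjust()] fit on the remaining mice.
#' @export
adjust_hydrogen <- function(h2_auc, cecal_mass_g, groups, exclude = "GF") {
  keep <- !(as.character(groups) %in% exclude)
  ancova_adjust(h2_auc[keep],
                data.frame(cecal_mass_g = cecal_mass_g[keep]),
                groups[keep])
}

#' Classical per-mass ratio normalization
#'
#' Divides each value by a body-mass measure. Provided for comparison with
#' [ancova_adjust()]: when groups differ systematically in inert mass (the
#' enlarged germ-free cecum), the total-mass ratio manufactures spurious
#' group differences that regression-based adjustment does not.
#'
#' @param values per-mouse values.
#' @param profiles per-mouse profile table with mass columns
#'   (`total_mass_g`, `total_mass_nocecum_g`, `lean_mass_g`), or a numeric
#'   vector of masses.
#' @param which mass to divide by: `"total"`, `"total_nocecum"` or
#'   `"lean"`; ignored when `profiles` is numeric.
#' @return values per gram.
#' @export
ratio_normalize <- function(values, profiles,
                            which = c("total", "total_nocecum", "lean")) {
  if (is.numeric(profiles)) {
    mass <- profiles
  } else {
    which <- match.arg(which)
    col <- switch(which, total = "total_mass_g",
                  total_nocecum = "total_mass_nocecum_g",
                  lean = "lean_mass_g")
    mass <- profiles[[col]]
  }
  if (any(mass <= 0, na.rm = TRUE)) {
    stop("non-positive mass in ratio normalization", call. = FALSE)
  }
  values / mass
}
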