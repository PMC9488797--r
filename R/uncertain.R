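#' Uncertain values (mean plus combined standard uncertainty)
#'
#' The substrate for energy-balance bookkeeping: a quantity is carried as
#' its mean together with a combined standard uncertainty `u` (same units),
#' and every derived quantity propagates `u` by the first-order Taylor
#' method under the assumption of independent Gaussian sources.
#' Correlated inputs are not supported. Reporting intervals are
#' `mean +/- 1.96 u`.
#'
#' @param mean numeric mean(s).
#' @param u combined standard uncertainty (same units, `>= 0`); recycled.
#' @return an object of class `uval`.
#' @export
#' @examples
#' uval(10, 0.5) - uval(2.5, 0.2)   # 7.5 +/- 0.539
uval <- function(mean, u = 0) {
  if (length(u) == 1L) u <- rep(u, length(mean))
  stopifnot(length(u) == length(mean), all(u >= 0 | is.na(u)))
  structure(list(mean = as.numeric(mean), u = as.numeric(u)), class = "uval")
}

#' @export
print.uval <- function(x, digits = 4, ...) {
  cat(paste0(format(signif(x$mean, digits)), " +/- ",
             format(signif(x$u, digits)),
             "  [", format(signif(x$mean - 1.96 * x$u, digits)), ", ",
             format(signif(x$mean + 1.96 * x$u, digits)), "] (95 %)"),
      sep = "\n")
  invisible(x)
}

#' @export
format.uval <- function(x, digits = 4, ...) {
  paste0(format(signif(x$mean, digits)), " +/- ", format(signif(x$u, digits)))
}

as_uval <- function(x) {
  if (inherits(x, "uval")) x else uval(x, 0)
}

#' Sum or difference of uncertain values
#'
#' `mean = a.mean + sign * b.mean`; `u = sqrt(a.u^2 + b.u^2)` (independent
#' inputs; the difference of a value with an independent copy of itself has
#' uncertainty `u * sqrt(2)`, not 0).
#'
#' @param a,b [uval()] objects (bare numerics are promoted with `u = 0`).
#' @param sign `+1` for addition, `-1` for subtraction.
#' @return a [uval()].
#' @export
u_add <- function(a, b, sign = 1) {
  stopifnot(sign %in% c(-1, 1))
  a <- as_uval(a); b <- as_uval(b)
  uval(a$mean + sign * b$mean, sqrt(a$u^2 + b$u^2))
}

#' Product of uncertain values
#'
#' First-order Taylor propagation with independence:
#' `u(xy) = sqrt((y u_x)^2 + (x u_y)^2)`.
#'
#' @inheritParams u_add
#' @return a [uval()].
#' @export
u_mul <- function(a, b) {
  a <- as_uval(a); b <- as_uval(b)
  uval(a$mean * b$mean, sqrt((b$mean * a$u)^2 + (a$mean * b$u)^2))
}

#' Quotient of uncertain values
#'
#' First-order Taylor propagation with independence:
#' `u(x/y) = sqrt((u_x / y)^2 + (x u_y / y^2)^2)`.
#'
#' @inheritParams u_add
#' @return a [uval()].
#' @export
u_div <- function(a, b) {
  a <- as_uval(a); b <- as_uval(b)
  if (any(b$mean == 0)) stop("division by zero-mean uncertain value",
                             call. = FALSE)
  uval(a$mean / b$mean,
       sqrt((a$u / b$mean)^2 + (a$mean * b$u / b$mean^2)^2))
}

#' @export
Ops.uval <- function(e1, e2) {
  switch(.Generic,
         "+" = u_add(e1, e2, 1),
         "-" = if (missing(e2)) uval(-as_uval(e1)$mean, as_uval(e1)$u)
               else u_add(e1, e2, -1),
         "*" = u_mul(e1, e2),
         "/" = u_div(e1, e2),
         stop("operation '", .Generic, "' not defined for uval", call. = FALSE))
}

#' Group-level uncertain value from per-mouse measurements
#'
#' Mean with the standard error of the mean as the combined standard
#' uncertainty, the form in which group estimates enter the energy-balance
#' bookkeeping.
#'
#' @param x per-mouse measurements.
#' @return a length-1 [uval()].
#' @export
group_uval <- function(x) {
  x <- x[!is.na(x)]
  stopifnot(length(x) >= 2)
  uval(mean(x), stats::sd(x) / sqrt(length(x)))
}
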