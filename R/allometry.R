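#' Major-axis regression
#'
#' Fits the major axis (perpendicular least squares) of a bivariate cloud:
#' the line minimizing the sum of squared orthogonal distances, the symmetric
#' line-fitting method appropriate when both variables are measured on the same
#' scale and both carry error — the standard choice for allometric slopes on
#' independent contrasts.  With (un)centered sums \eqn{S_{xx}, S_{yy}, S_{xy}}:
#' \deqn{\hat\beta = \frac{S_{yy} - S_{xx} + \sqrt{(S_{yy}-S_{xx})^2 + 4S_{xy}^2}}{2 S_{xy}}}
#' and \eqn{r^2 = S_{xy}^2 / (S_{xx} S_{yy})}.  Contrast regressions are
#' conventionally fit through the origin (`through_origin = TRUE`), using
#' uncentered sums and df = n - 1.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param through_origin force the line through (0, 0) (uncentered fit).
#' @return object of class `"ma"` with components `slope`, `intercept`, `r2`,
#'   `n`, `df`, `through_origin`, and the data.
#' @seealso [ma_slope_test()] for the isometry test, [rensch()] for the full
#'   caste-pair analysis.
#' @examples
#' fit <- ma_fit(c(1, 2, 3), c(2, 4, 6), through_origin = TRUE)
#' coef(fit)   # slope 2
#' @export
ma_fit <- function(x, y, through_origin = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values in x or y", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need >= 3 pairs", call. = FALSE)
  if (all(x == x[1L]) && all(y == y[1L]))
    stop("all points identical; line undefined", call. = FALSE)
  xc <- if (through_origin) x else x - mean(x)
  yc <- if (through_origin) y else y - mean(y)
  sxx <- sum(xc^2); syy <- sum(yc^2); sxy <- sum(xc * yc)
  if (sxy == 0) {
    if (isTRUE(all.equal(sxx, syy)))
      stop("isotropic cloud: major axis undefined", call. = FALSE)
    slope <- if (sxx > syy) 0 else Inf
    warning("zero covariance: major axis aligned with a coordinate axis",
            call. = FALSE)
  } else {
    slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  }
  r2 <- if (sxx > 0 && syy > 0) sxy^2 / (sxx * syy) else NA_real_
  intercept <- if (through_origin) 0 else mean(y) - slope * mean(x)
  structure(list(slope = slope, intercept = intercept, r2 = r2, n = n,
                 df = if (through_origin) n - 1L else n - 2L,
                 through_origin = through_origin, x = x, y = y,
                 call = match.call()),
            class = "ma")
}

#' Test a major-axis slope against a hypothesized value
#'
#' The classical MA slope test: rotate the data into the candidate axis
#' (scores \eqn{w_i = x_i + b_0 y_i}) and its normal-direction residuals
#' (\eqn{u_i = y_i - b_0 x_i}).  Under H0: beta = b0 these are uncorrelated, so
#' \deqn{F = \frac{r_{uw}^2 \, df}{1 - r_{uw}^2}, \quad F \sim F_{1, df}}
#' with df = n - 1 through the origin, n - 2 otherwise.  With b0 = 1 this is
#' the isometry test used to diagnose Rensch's rule (slope > 1) versus its
#' converse.
#'
#' @param fit an `"ma"` object from [ma_fit()].
#' @param b0 slope under the null (default 1, isometry).
#' @return list with `F`, `df`, `p`, `b0`, `r_uw`.
#' @export
ma_slope_test <- function(fit, b0 = 1) {
  stopifnot(inherits(fit, "ma"))
  x <- fit$x; y <- fit$y
  u <- y - b0 * x
  w <- x + b0 * y
  if (!fit$through_origin) {
    u <- u - mean(u)
    w <- w - mean(w)
  }
  su <- sum(u^2); sw <- sum(w^2)
  if (sw == 0)
    stop("degenerate b0: axis scores all zero (b0 orthogonal to the data axis)",
         call. = FALSE)
  if (su == 0)
    return(list(F = 0, df = fit$df, p = 1, b0 = b0, r_uw = 0))
  r <- sum(u * w) / sqrt(su * sw)
  df <- fit$df
  if (1 - r^2 <= .Machine$double.eps)
    return(list(F = Inf, df = df, p = 0, b0 = b0, r_uw = r))
  Fstat <- r^2 * df / (1 - r^2)
  list(F = Fstat, df = df, p = stats::pf(Fstat, 1, df, lower.tail = FALSE),
       b0 = b0, r_uw = r)
}

#' @export
print.ma <- function(x, ...) {
  cat("Major-axis regression", if (x$through_origin) " (through origin)",
      "\n", sep = "")
  cat("  n = ", x$n, ", df = ", x$df, "\n", sep = "")
  cat("  slope = ", format(x$slope, digits = 4),
      ", intercept = ", format(x$intercept, digits = 4),
      ", r2 = ", format(x$r2, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
coef.ma <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
summary.ma <- function(object, b0 = 1, ...) {
  tst <- ma_slope_test(object, b0)
  out <- c(unclass(object)[c("slope", "intercept", "r2", "n", "df",
                             "through_origin")],
           list(test = tst))
  class(out) <- "summary.ma"
  out
}

#' @export
print.summary.ma <- function(x, ...) {
  cat("Major-axis regression", if (x$through_origin) " (through origin)",
      "\n", sep = "")
  cat("  slope = ", format(x$slope, digits = 4),
      ", r2 = ", format(x$r2, digits = 4),
      ", n = ", x$n, "\n", sep = "")
  cat("  H0: beta = ", x$test$b0, ":  F(1,", x$df, ") = ",
      format(x$test$F, digits = 4), ", p = ", format.pval(x$test$p), "\n",
      sep = "")
  invisible(x)
}

#' @export
predict.ma <- function(object, newdata = NULL, ...) {
  xx <- if (is.null(newdata)) object$x else as.numeric(newdata)
  object$intercept + object$slope * xx
}

#' @export
residuals.ma <- function(object, type = c("perpendicular", "vertical"), ...) {
  type <- match.arg(type)
  v <- object$y - predict(object)
  if (type == "vertical") v else v / sqrt(1 + object$slope^2)
}

#' @export
plot.ma <- function(x, b0 = 1, ...) {
  graphics::plot(x$x, x$y, xlab = "x", ylab = "y", ...)
  graphics::abline(x$intercept, x$slope)
  graphics::abline(if (x$through_origin) 0 else mean(x$y) - b0 * mean(x$x),
                   b0, lty = 2)
  invisible(x)
}

# internally studentized perpendicular residuals, reported (never removed) in
# the pipeline's outlier screen
studentized_residuals <- function(fit) {
  r <- residuals.ma(fit)
  s <- sqrt(sum(r^2) / fit$df)
  if (s == 0) rep(0, fit$n) else r / s
}
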