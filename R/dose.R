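# Michaelis-Menten dose-response of the plate Z-score. The curve
# z(c) = z_max * c / (km + c) passes through the origin because DMSO defines
# Z = 0 by construction; z_max is free in sign (M1 responses saturate at
# negative Z, M2 at positive Z).

#' Fit a Michaelis-Menten dose-response to Z-scores
#'
#' Least-squares fit of \eqn{z(c) = z_{max} c / (K_m + c)} with
#' \eqn{K_m > 0} and \eqn{z_{max}} free in sign. For a fixed \eqn{K_m} the
#' model is linear in \eqn{z_{max}}, so the fit profiles \eqn{z_{max}} out
#' and minimizes the residual sum of squares over \eqn{K_m} on a fixed
#' logarithmic grid followed by deterministic 1-D refinement; the result does
#' not depend on random starts.
#'
#' @param concentrations Concentrations in uM (>= 0, at least 3 distinct).
#' @param z Matched signed Z-scores.
#' @param cutoff Optional polarization cutoff; when supplied, the effective
#'   concentration \code{ec} (see \code{\link{compute_ec}}) is stored in the
#'   fit.
#' @param compound_id Optional identifier carried in the result.
#' @return Object of class \code{"mm_fit"}: list with \code{z_max}, \code{km},
#'   \code{r2}, \code{ec} (uM or \code{NA}), \code{cutoff}, the data, and
#'   \code{fitted} values. Methods: \code{print}, \code{summary}, \code{coef},
#'   \code{predict}, \code{residuals}, \code{plot}.
#' @export
fit_mm <- function(concentrations, z, cutoff = NULL, compound_id = NA_character_) {
  conc <- as.numeric(concentrations); z <- as.numeric(z)
  if (length(conc) != length(z))
    stop("'concentrations' and 'z' must have equal length", call. = FALSE)
  keep <- is.finite(conc) & is.finite(z)
  conc <- conc[keep]; z <- z[keep]
  if (any(conc < 0)) stop("concentrations must be non-negative", call. = FALSE)
  if (length(unique(conc)) < 3)
    stop("need at least 3 distinct concentrations", call. = FALSE)
  if (!any(conc > 0)) stop("need at least one positive concentration", call. = FALSE)

  # profiled SSE: for fixed km, z_max = sum(z*f)/sum(f^2) with f = c/(km+c)
  prof <- function(log_km) {
    f <- conc / (exp(log_km) + conc)
    denom <- sum(f^2)
    zm <- if (denom > 0) sum(z * f) / denom else 0
    sum((z - zm * f)^2)
  }
  cpos <- conc[conc > 0]
  lo <- log(min(cpos)) - log(100)
  hi <- log(max(cpos)) + log(100)
  grid <- seq(lo, hi, length.out = 121)
  sse_grid <- vapply(grid, prof, numeric(1))
  i0 <- which.min(sse_grid)
  bracket <- c(grid[max(1, i0 - 1)], grid[min(length(grid), i0 + 1)])
  opt <- stats::optimize(prof, interval = bracket, tol = 1e-12)
  log_km <- opt$minimum
  km <- exp(log_km)
  f <- conc / (km + conc)
  z_max <- sum(z * f) / sum(f^2)
  fitted <- z_max * f
  sse <- sum((z - fitted)^2)
  sst <- sum((z - mean(z))^2)
  r2 <- if (sst > 0) 1 - sse / sst else if (sse <= 1e-12) 1 else -Inf
  out <- structure(list(compound_id = compound_id, z_max = z_max, km = km,
                        r2 = r2, ec = NA_real_, cutoff = NA_real_,
                        concentrations = conc, z = z, fitted = fitted),
                   class = "mm_fit")
  if (!is.null(cutoff)) {
    out$cutoff <- cutoff
    out$ec <- compute_ec(out, cutoff)
  }
  out
}

#' Effective concentration at which the fitted curve reaches a cutoff
#'
#' The effective concentration (EC) is defined as the concentration at which
#' the fitted dose-response reaches the polarization cutoff:
#' \eqn{EC = K_m \cdot cutoff / (z_{max} - cutoff)}. It is defined only when
#' the asymptote exceeds the cutoff in magnitude and shares its sign;
#' otherwise the curve never reaches the cutoff and \code{NA} is returned.
#'
#' @param fit An \code{\link{fit_mm}} result (or list with \code{z_max} and
#'   \code{km}).
#' @param cutoff Signed Z cutoff (nonzero).
#' @return EC in uM, or \code{NA} when the curve never reaches the cutoff.
#' @export
compute_ec <- function(fit, cutoff) {
  .check_number(cutoff, "cutoff")
  if (cutoff == 0)
    stop("cutoff of 0 requests no morphology change", call. = FALSE)
  if (sign(fit$z_max) != sign(cutoff) || abs(fit$z_max) <= abs(cutoff))
    return(NA_real_)
  fit$km * cutoff / (fit$z_max - cutoff)
}

#' Classify a compound as having a strong dosage effect
#'
#' TRUE iff the fit's effective concentration is defined and at most
#' \code{ec_threshold} (the screen used 10 uM).
#'
#' @param fit An \code{\link{fit_mm}} result carrying an \code{ec} field
#'   (fit with \code{cutoff=} set).
#' @param ec_threshold EC threshold in uM.
#' @return Logical scalar.
#' @export
classify_dosage_response <- function(fit, ec_threshold = 10) {
  .check_number(ec_threshold, "ec_threshold", 0, Inf, allow_lower = FALSE)
  !is.na(fit$ec) && fit$ec <= ec_threshold
}

#' @export
print.mm_fit <- function(x, ...) {
  cat("Michaelis-Menten dose-response fit")
  if (!is.na(x$compound_id)) cat(" [", x$compound_id, "]", sep = "")
  cat("\n")
  cat(sprintf("  z_max = %.4g, Km = %.4g uM, R2 = %.4f\n", x$z_max, x$km, x$r2))
  if (!is.na(x$cutoff))
    cat(sprintf("  EC at cutoff %.3g: %s uM\n", x$cutoff,
                if (is.na(x$ec)) "not reached" else sprintf("%.4g", x$ec)))
  invisible(x)
}

#' @export
summary.mm_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  n = %d points, residual SD = %.4g\n",
              length(object$z), stats::sd(object$z - object$fitted)))
  invisible(object)
}

#' @export
coef.mm_fit <- function(object, ...) c(z_max = object$z_max, km = object$km)

#' @export
predict.mm_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$concentrations
          else if (is.list(newdata)) newdata$concentrations else as.numeric(newdata)
  object$z_max * conc / (object$km + conc)
}

#' @export
residuals.mm_fit <- function(object, ...) object$z - object$fitted

#' @export
plot.mm_fit <- function(x, ...) {
  graphics::plot(x$concentrations, x$z, xlab = "concentration (uM)",
                 ylab = "Z-score", main = x$compound_id, ...)
  cc <- seq(0, max(x$concentrations) * 1.1, length.out = 200)
  graphics::lines(cc, predict(x, cc))
  if (!is.na(x$cutoff)) graphics::abline(h = x$cutoff, lty = 2)
  invisible(x)
}
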