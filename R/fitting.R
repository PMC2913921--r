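# Zero-intercept slope estimation for unwrapped residual vs. mass.
#
# Large reference sets use the exact least-squares solution; small,
# outlier-prone user sets use a robust M-estimator fitted by iteratively
# re-weighted least squares (IWLS) about the origin-constrained line.

new_slope_fit <- function(b, se_b, sse, n, method, converged = TRUE,
                          iterations = 0L, weights = NULL) {
  structure(
    list(b = b, se_b = se_b, sse = sse, n = n, method = method,
         converged = converged, iterations = iterations, weights = weights),
    class = "slope_fit"
  )
}

.check_fit_input <- function(mass, residual_unwrapped) {
  stopifnot(is.numeric(mass), is.numeric(residual_unwrapped),
            length(mass) == length(residual_unwrapped))
  if (length(mass) == 0) stop("no points to fit", call. = FALSE)
  if (any(mass <= 0)) stop("all masses must be positive", call. = FALSE)
}

#' Exact zero-intercept least-squares slope
#'
#' Fits the model `D_R = b * P_M` (intercept forced to zero) by minimising
#' the error sum of squares, giving the closed form
#' `b = sum(D_R * P_M) / sum(P_M^2)`. The standard error uses the
#' residual variance on `n - 1` degrees of freedom (one parameter).
#'
#' @param mass Peptide masses `P_M` in Da.
#' @param residual_unwrapped Unwrapped decimal residuals `D_R`.
#' @return A `slope_fit` with components `b`, `se_b` (`NA` for n = 1),
#'   `sse`, `n` and `method = "ols_zero_intercept"`.
#' @export
fit_slope_ols <- function(mass, residual_unwrapped) {
  .check_fit_input(mass, residual_unwrapped)
  sxx <- sum(mass^2)
  b <- sum(residual_unwrapped * mass) / sxx
  resid <- residual_unwrapped - b * mass
  sse <- sum(resid^2)
  n <- length(mass)
  se_b <- if (n >= 2) sqrt(sse / (n - 1) / sxx) else NA_real_
  new_slope_fit(b, se_b, sse, n, "ols_zero_intercept")
}

# Huber weight: 1 inside k*scale, declining as k*scale/|r| outside.
.weights_huber <- function(resid, scale, k = 1.345) {
  a <- abs(resid) / (k * scale)
  ifelse(a <= 1, 1, 1 / a)
}

# Tukey bisquare weight: smooth redescending, 0 beyond c*scale.
.weights_bisquare <- function(resid, scale, c = 4.685) {
  a <- abs(resid) / (c * scale)
  ifelse(a < 1, (1 - a^2)^2, 0)
}

#' Robust zero-intercept slope by IWLS M-estimation
#'
#' Iteratively re-weighted least squares about the origin-constrained
#' line: at each iteration the residual scale is re-estimated by the
#' median absolute deviation (MAD about zero, consistency factor 0.6745),
#' points are re-weighted by the chosen psi function, and the weighted
#' zero-intercept slope `b = sum(w * D_R * P_M) / sum(w * P_M^2)` is
#' updated until the relative slope change falls below `convergence_tol`.
#' Outlying points that would drag the least-squares slope are thereby
#' down-weighted; with Huber weights the breakdown behaviour approaches
#' that of the median (up to half the points must move to move the slope).
#'
#' Fewer than 3 points fall back to [fit_slope_ols()] with a warning.
#' A perfectly colinear set (zero scale) returns the least-squares slope
#' with uniform weights.
#'
#' @inheritParams fit_slope_ols
#' @param psi Weight function: `"huber"` (default, tuning constant 1.345)
#'   or `"bisquare"` (Tukey, tuning constant 4.685).
#' @param max_iterations Iteration cap (default 50).
#' @param convergence_tol Relative slope-change threshold (default 1e-8).
#' @return A `slope_fit` with `method = "robust_iwls"`; `converged` is
#'   `FALSE` if the cap was hit, `weights` holds the final weights, and
#'   `se_b` comes from the final weighted least-squares fit.
#' @export
fit_slope_robust <- function(mass, residual_unwrapped,
                             psi = c("huber", "bisquare"),
                             max_iterations = 50, convergence_tol = 1e-8) {
  .check_fit_input(mass, residual_unwrapped)
  psi <- match.arg(psi)
  n <- length(mass)
  if (n < 3) {
    warning("fewer than 3 points: falling back to the exact ",
            "least-squares fit", call. = FALSE)
    return(fit_slope_ols(mass, residual_unwrapped))
  }
  weight_fun <- switch(psi, huber = .weights_huber,
                       bisquare = .weights_bisquare)
  b <- fit_slope_ols(mass, residual_unwrapped)$b
  w <- rep.int(1, n)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iterations) {
    iter <- iter + 1L
    resid <- residual_unwrapped - b * mass
    scale <- stats::median(abs(resid)) / 0.6745
    tiny <- .Machine$double.eps * max(abs(residual_unwrapped), 1)
    if (scale <= tiny) {
      # (near-)perfect fit for at least half the points: done; any point
      # still off the line is a gross outlier and drops out
      w <- as.numeric(abs(resid) <= 8 * tiny)
      converged <- TRUE
      break
    }
    w <- weight_fun(resid, scale)
    if (all(w == 0)) {
      stop("all points zero-weighted; residual scale degenerate",
           call. = FALSE)
    }
    b_new <- sum(w * residual_unwrapped * mass) / sum(w * mass^2)
    delta <- abs(b_new - b) / max(abs(b_new), .Machine$double.eps)
    b <- b_new
    if (delta < convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("robust fit did not converge in ", max_iterations,
            " iterations; returning last iterate", call. = FALSE)
  }
  resid <- residual_unwrapped - b * mass
  swxx <- sum(w * mass^2)
  sse <- sum(resid^2)
  se_b <- sqrt(sum(w * resid^2) / (n - 1) / swxx)
  new_slope_fit(b, se_b, sse, n, "robust_iwls", converged, iter, w)
}

#' @export
print.slope_fit <- function(x, ...) {
  cat("Zero-intercept slope fit (", x$method, ")\n", sep = "")
  cat(sprintf("  b     = %.6e", x$b))
  if (!is.na(x$se_b)) cat(sprintf("  (se %.2e)", x$se_b))
  cat("\n")
  cat(sprintf("  SSE   = %.6g on n = %d points\n", x$sse, x$n))
  if (x$method == "robust_iwls") {
    cat(sprintf("  IWLS: %d iteration(s), %s\n", x$iterations,
                if (x$converged) "converged" else "NOT converged"))
  }
  invisible(x)
}
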