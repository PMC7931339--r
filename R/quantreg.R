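# Polynomial quantile regression by pinball-loss minimization.
#
# The tau-th conditional quantile of y given x is modelled as a degree-d
# polynomial in x.  The estimate minimizes the pinball (check) loss
#   rho_tau(r) = r * (tau - 1{r < 0}).
# Fitting proceeds in two stages: (1) a smoothed-loss quasi-Newton descent
# using rho_eps(r) = tau*r + eps*log(1 + exp(-r/eps)) with eps shrunk
# geometrically, which lands close to the optimum; (2) an exact polish that
# exploits the LP structure of the problem -- a minimizer interpolates
# degree+1 observations -- by enumerating interpolating bases among the
# points with the smallest absolute residuals and keeping the one with the
# lowest exact loss.

pinball_loss <- function(r, tau) sum(r * (tau - (r < 0)))

# raw polynomial design on a [-1, 1]-rescaled predictor for conditioning
poly_design <- function(x, degree, center, halfwidth) {
  z <- (x - center) / halfwidth
  outer(z, 0:degree, `^`)
}

#' Fit a polynomial quantile-regression curve
#'
#' Estimates the `tau`-th conditional quantile of `y` as a polynomial in
#' `x` by minimizing the pinball loss. Used by [adaptive_cutoff()] to draw
#' the 0.05/0.95 envelope on an MA plot; exported because the fit is
#' useful on its own.
#'
#' @param x,y Numeric vectors of equal length (non-finite pairs dropped).
#' @param tau Quantile level in (0, 1).
#' @param degree Polynomial degree (default 2, the quadratic model).
#' @return A list of class `quantile_poly_fit` with elements
#'   `coefficients` (on the internal rescaled basis), `center`,
#'   `halfwidth`, `degree`, `tau`, `fitted`, `loss`, and
#'   `predict(newx)` via the [predict()] method.
#' @examples
#' set.seed(1)
#' x <- runif(200); y <- rnorm(200)
#' f <- fit_quantile_poly(x, y, tau = 0.95)
#' mean(y > predict(f, x))  # close to 0.05
#' @export
fit_quantile_poly <- function(x, y, tau, degree = 2) {
  stopifnot(length(x) == length(y), tau > 0, tau < 1, degree >= 0)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  p <- degree + 1
  if (n < max(10, p)) {
    stop_fmt("quantile fit needs >= %d points with defined values, got %d",
             max(10, p), n)
  }
  center <- (max(x) + min(x)) / 2
  halfwidth <- max((max(x) - min(x)) / 2, .Machine$double.eps)
  X <- poly_design(x, degree, center, halfwidth)
  if (qr(X)$rank < p) {
    stop_fmt(paste0("degenerate quantile fit: design is rank-deficient ",
                    "(collinear predictor; %d unique x values for degree %d)"),
             length(unique(x)), degree)
  }

  # stage 1: smoothed pinball loss, shrinking eps
  softplus <- function(t) ifelse(t > 0, t + log1p(exp(-t)), log1p(exp(t)))
  beta <- stats::lm.fit(X, y)$coefficients
  for (eps in c(1, 0.1, 0.01, 1e-3, 1e-4)) {
    fn <- function(b) {
      r <- drop(y - X %*% b)
      sum(tau * r + eps * softplus(-r / eps))
    }
    gr <- function(b) {
      r <- drop(y - X %*% b)
      w <- tau - 1 / (1 + exp(r / eps))
      -drop(crossprod(X, w))
    }
    opt <- stats::optim(beta, fn, gr, method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-12))
    beta <- opt$par
  }
  best_loss <- pinball_loss(drop(y - X %*% beta), tau)

  # stage 2: exact polish over interpolating bases near the smoothed curve
  resid <- abs(drop(y - X %*% beta))
  k <- min(n, max(12, 3 * p))
  cand <- order(resid)[seq_len(k)]
  combos <- utils::combn(cand, p)
  for (j in seq_len(ncol(combos))) {
    idx <- combos[, j]
    Xi <- X[idx, , drop = FALSE]
    b <- tryCatch(solve(Xi, y[idx]), error = function(e) NULL)
    if (is.null(b)) next
    loss <- pinball_loss(drop(y - X %*% b), tau)
    if (loss < best_loss - 1e-12) {
      best_loss <- loss
      beta <- b
    }
  }

  structure(list(coefficients = drop(beta), center = center,
                 halfwidth = halfwidth, degree = degree, tau = tau,
                 fitted = drop(X %*% beta), loss = best_loss),
            class = "quantile_poly_fit")
}

#' @export
predict.quantile_poly_fit <- function(object, newx, ...) {
  X <- poly_design(newx, object$degree, object$center, object$halfwidth)
  drop(X %*% object$coefficients)
}

#' @export
print.quantile_poly_fit <- function(x, ...) {
  cat(sprintf("Polynomial quantile regression (tau = %g, degree = %d)\n",
              x$tau, x$degree))
  cat("rescaled-basis coefficients:",
      paste(signif(x$coefficients, 5), collapse = " "), "\n")
  cat(sprintf("pinball loss: %g on %d points\n", x$loss, length(x$fitted)))
  invisible(x)
}
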