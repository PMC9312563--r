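# Three-class multinomial logistic regression on a single predictor,
# healthy as the reference class. Fitted by BFGS on the (optionally
# ridge-penalized) negative log-likelihood with analytic gradient; the
# predictor is standardized internally and coefficients mapped back.

mlr_nll <- function(theta, x, yi, ridge = 0) {
  eta <- cbind(0, theta[1] + theta[2] * x, theta[3] + theta[4] * x)
  m <- apply(eta, 1, max)
  lse <- m + log(rowSums(exp(eta - m)))
  -sum(eta[cbind(seq_along(yi), yi)] - lse) +
    ridge / 2 * sum(theta[c(2, 4)]^2)
}

mlr_grad <- function(theta, x, yi, ridge = 0) {
  eta <- cbind(0, theta[1] + theta[2] * x, theta[3] + theta[4] * x)
  m <- apply(eta, 1, max)
  p <- exp(eta - m) / rowSums(exp(eta - m))
  d2 <- p[, 2] - (yi == 2)
  d3 <- p[, 3] - (yi == 3)
  g <- c(sum(d2), sum(d2 * x), sum(d3), sum(d3 * x))
  g + ridge * c(0, theta[2], 0, theta[4])
}

#' Fit a single-feature three-class multinomial logit
#'
#' Maximum-likelihood multinomial logistic regression of group (healthy as
#' reference, NAFL and NASH as contrasts) on one metabolite concentration,
#' with asymptotic standard errors from the inverse observed information
#' and two-tailed z-tests per coefficient. Complete or quasi-complete
#' separation (diverging standardized slopes) triggers a refit with a weak
#' ridge penalty (1e-6) and a `separation` flag.
#'
#' @param values Numeric concentration vector.
#' @param labels Group label per value; all of healthy/NAFL/NASH must be
#'   present.
#' @return List of class `mlr_fit`: `coef` (4-vector a_NAFL, b_NAFL,
#'   a_NASH, b_NASH on the raw concentration scale), `se`, `z`, `p_value`,
#'   `separation`, `classes`, plus the internal standardization.
#' @export
fit_single_feature_mlr <- function(values, labels) {
  labels <- as.character(labels)
  classes <- c("healthy", "NAFL", "NASH")
  if (!all(classes %in% labels)) stop("all three classes must be present")
  if (stats::sd(values) == 0) stop("predictor is constant")
  yi <- match(labels, classes)
  mu <- mean(values); sdev <- stats::sd(values)
  xs <- (values - mu) / sdev

  fit1 <- stats::optim(rep(0, 4), mlr_nll, mlr_grad, x = xs, yi = yi,
                       method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-12))
  separation <- fit1$convergence != 0 || max(abs(fit1$par)) > 15
  ridge <- if (separation) 1e-6 else 0
  if (separation)
    fit1 <- stats::optim(rep(0, 4), mlr_nll, mlr_grad, x = xs, yi = yi,
                         ridge = ridge, method = "BFGS",
                         control = list(maxit = 1000, reltol = 1e-12))
  H <- stats::optimHess(fit1$par, mlr_nll, mlr_grad, x = xs, yi = yi,
                        ridge = ridge)
  cov_std <- tryCatch(solve(H), error = function(e) matrix(NA, 4, 4))

  # theta_std = M theta_raw with per-class blocks [[1, mu], [0, sd]]
  Mb <- matrix(c(1, 0, mu, sdev), 2, 2)
  Minv <- solve(Mb)
  T4 <- matrix(0, 4, 4)
  T4[1:2, 1:2] <- Minv; T4[3:4, 3:4] <- Minv
  coef_raw <- as.numeric(T4 %*% fit1$par)
  cov_raw <- T4 %*% cov_std %*% t(T4)
  se <- sqrt(pmax(diag(cov_raw), 0))
  z <- coef_raw / se
  pv <- 2 * stats::pnorm(-abs(z))
  nm <- c("a_NAFL", "b_NAFL", "a_NASH", "b_NASH")
  structure(list(coef = stats::setNames(coef_raw, nm),
                 se = stats::setNames(se, nm),
                 z = stats::setNames(z, nm),
                 p_value = stats::setNames(pv, nm),
                 separation = separation, classes = classes,
                 logLik = -fit1$value, center = mu, scale = sdev),
            class = "mlr_fit")
}

#' Softmax probability curve of a fitted multinomial logit
#'
#' Evaluates the three class probabilities on a uniform grid (200 points
#' by default) spanning the observed concentration range; no
#' extrapolation.
#'
#' @param fit An [fit_single_feature_mlr()] result, or any list with a
#'   4-element `coef` vector ordered a_NAFL, b_NAFL, a_NASH, b_NASH.
#' @param values Observed concentrations defining the grid range.
#' @param n_grid Number of grid points.
#' @return data.frame of class `probability_curve` with columns `grid`,
#'   `p_healthy`, `p_nafl`, `p_nash` (each triple sums to one).
#' @export
probability_curve <- function(fit, values, n_grid = 200L) {
  th <- fit$coef
  grid <- seq(min(values), max(values), length.out = n_grid)
  eta <- cbind(0, th[1] + th[2] * grid, th[3] + th[4] * grid)
  m <- apply(eta, 1, max)
  p <- exp(eta - m) / rowSums(exp(eta - m))
  out <- data.frame(grid = grid, p_healthy = p[, 1], p_nafl = p[, 2],
                    p_nash = p[, 3])
  class(out) <- c("probability_curve", "data.frame")
  out
}

#' Detect the NASH-dominant "green window" of a probability curve
#'
#' The window starts at the smallest grid point from which the NASH
#' probability exceeds the NAFL probability and remains the maximum of the
#' three classes through the top of the observed range; the upper bound is
#' the observed maximum. A window narrower than `min_width_frac` of the
#' observed range exists but is flagged as not of acceptable width.
#'
#' @param curve A [probability_curve()].
#' @param min_width_frac Acceptable-width threshold as a fraction of the
#'   observed range (default 0.05).
#' @return List of class `green_window`: `exists`, `lower`, `upper`,
#'   `width`, `acceptable`.
#' @export
detect_green_window <- function(curve, min_width_frac = 0.05) {
  ok <- curve$p_nash > curve$p_nafl & curve$p_nash > curve$p_healthy
  # suffix-and: from which point on does NASH stay dominant?
  tail_ok <- rev(cumprod(rev(ok))) > 0
  if (!any(tail_ok))
    return(structure(list(exists = FALSE, lower = NA_real_,
                          upper = NA_real_, width = NA_real_,
                          acceptable = FALSE), class = "green_window"))
  lower <- curve$grid[which(tail_ok)[1]]
  upper <- max(curve$grid)
  width <- upper - lower
  rng <- diff(range(curve$grid))
  structure(list(exists = TRUE, lower = lower, upper = upper,
                 width = width, acceptable = width >= min_width_frac * rng),
            class = "green_window")
}

#' Green-window table for a set of features
#'
#' Fits a single-feature multinomial logit per feature and extracts its
#' green window.
#'
#' @param panel Numeric subjects x metabolites matrix.
#' @param labels Three-group label per subject.
#' @param features Character vector of panel columns to analyze.
#' @return data.frame with one row per feature: `feature`, `exists`,
#'   `lower`, `upper`, `width`, `acceptable`, `separation`.
#' @export
green_window_table <- function(panel, labels, features) {
  stopifnot(all(features %in% colnames(panel)))
  rows <- lapply(features, function(f) {
    fit <- fit_single_feature_mlr(panel[, f], labels)
    gw <- detect_green_window(probability_curve(fit, panel[, f]))
    data.frame(feature = f, exists = gw$exists, lower = gw$lower,
               upper = gw$upper, width = gw$width,
               acceptable = gw$acceptable, separation = fit$separation,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
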