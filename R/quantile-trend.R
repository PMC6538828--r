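## l1 (check-loss) quantile regression of component value against highest
## heating temperature, solved exactly as a linear program.

#' Quantile-regression check loss
#'
#' `sum_i rho_tau(u_i)` with `rho_tau(u) = u * (tau - 1[u < 0])`.
#'
#' @param u residuals.
#' @param tau quantile probability in (0, 1).
#' @return nonnegative loss.
#' @export
check_loss <- function(u, tau) {
  stopifnot(tau > 0, tau < 1)
  sum(u * (tau - (u < 0)))
}

# internal: primal simplex with Bland's rule for
#   min c'z  s.t.  A z = b, z >= 0
# starting from the feasible basis `basis` (indices into columns of A).
# Problem sizes here are small (tens of rows); a dense implementation
# with per-iteration solves is ample and has no degeneracy cycling under
# Bland's rule.
.simplex <- function(A, b, cost, basis, tol = 1e-9, max_iter = 10000L) {
  m <- nrow(A)
  for (iter in seq_len(max_iter)) {
    B <- A[, basis, drop = FALSE]
    xB <- solve(B, b)
    w <- solve(t(B), cost[basis])
    reduced <- cost - as.vector(crossprod(A, w))
    reduced[basis] <- 0
    enter <- which(reduced < -tol)
    if (!length(enter)) {
      z <- numeric(ncol(A)); z[basis] <- xB
      return(list(x = z, objective = sum(cost[basis] * xB), basis = basis))
    }
    j <- min(enter)                       # Bland: smallest entering index
    d <- solve(B, A[, j])
    pos <- which(d > tol)
    if (!length(pos)) abort("linear program unbounded")
    ratio <- xB[pos] / d[pos]
    rmin <- min(ratio)
    cand <- pos[ratio <= rmin + tol]
    leave <- cand[which.min(basis[cand])]  # Bland: smallest leaving index
    basis[leave] <- j
  }
  abort("simplex failed to converge")
}

#' l1 quantile regression of value against treatment temperature
#'
#' Fits the line `y = intercept + slope * x` minimizing the check loss
#' `sum_i rho_tau(y_i - intercept - slope x_i)`, formulated as a linear
#' program over split positive/negative residuals and solved exactly by a
#' primal simplex with Bland's rule. An optimal vertex interpolates at
#' least two data points; when alternative optima exist the vertex reached
#' by the pivoting order is returned (all optima share the same loss).
#'
#' @param x regressor, e.g. highest heating temperature in degC; at least
#'   two distinct values.
#' @param y response, e.g. component value in USD/Mg.
#' @param tau quantile probability in (0, 1); 0.5 gives the least
#'   absolute deviations line.
#' @return object of class `quantile_trend` with `coef()`, `fitted()`,
#'   `residuals()`, `predict()`, `print()` methods; `$check_loss` is the
#'   objective at the optimum.
#' @export
quantile_trend <- function(x, y, tau = 0.5) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3) abort("at least 3 points are required")
  if (anyNA(x) || anyNA(y)) abort("missing values in x or y")
  if (!(tau > 0 && tau < 1)) abort("tau must lie in (0, 1)")
  if (length(unique(x)) < 2)
    abort("slope unidentifiable: all x values identical")
  n <- length(x)
  # columns: a+, a-, b+, b-, u_1..n, v_1..n
  A <- cbind(1, -1, x, -x, diag(n), -diag(n))
  cost <- c(0, 0, 0, 0, rep(tau, n), rep(1 - tau, n))
  basis <- ifelse(y >= 0, 4L + seq_len(n), 4L + n + seq_len(n))
  b <- abs(y) * 0 + y
  # initial basic solution u_i = y_i (y_i >= 0) or v_i = -y_i: feasible
  sol <- .simplex(A, b, cost, basis)
  z <- sol$x
  intercept <- z[1] - z[2]
  slope <- z[3] - z[4]
  res <- y - intercept - slope * x
  structure(list(coefficients = c(intercept = intercept, slope = slope),
                 tau = tau, x = x, y = y,
                 fitted.values = intercept + slope * x,
                 residuals = res,
                 check_loss = check_loss(res, tau)),
            class = "quantile_trend")
}

#' @export
coef.quantile_trend <- function(object, ...) object$coefficients

#' @export
fitted.quantile_trend <- function(object, ...) object$fitted.values

#' @export
residuals.quantile_trend <- function(object, ...) object$residuals

#' @export
predict.quantile_trend <- function(object, newdata, ...) {
  x <- if (missing(newdata)) object$x else {
    if (is.data.frame(newdata)) newdata$x else newdata
  }
  object$coefficients[["intercept"]] + object$coefficients[["slope"]] * x
}

#' @export
print.quantile_trend <- function(x, ...) {
  cat(sprintf("l1 quantile trend (tau = %g): y = %.6g %+.6g * x\n",
              x$tau, x$coefficients[["intercept"]],
              x$coefficients[["slope"]]))
  cat(sprintf("  check loss %.6g over %d points\n", x$check_loss,
              length(x$x)))
  invisible(x)
}

#' Ratio of two fitted slopes
#'
#' Quantifies how much steeper the value-versus-temperature trend is at a
#' high price quantile than at a low one.
#'
#' @param fit_high,fit_low `quantile_trend` fits.
#' @return `slope(fit_high) / slope(fit_low)`.
#' @export
slope_ratio <- function(fit_high, fit_low) {
  stopifnot(inherits(fit_high, "quantile_trend"),
            inherits(fit_low, "quantile_trend"))
  b0 <- fit_low$coefficients[["slope"]]
  if (b0 == 0) abort("reference slope is zero; ratio undefined")
  fit_high$coefficients[["slope"]] / b0
}

#' Value-versus-temperature slopes for every component and quantile
#'
#' For each agronomic component and each price-quantile probability `p`,
#' fits [quantile_trend()] with `tau = p` to the component's value at that
#' price quantile against highest heating temperature. Compost (60 degC)
#' is excluded by default: it is a biological treatment, not a
#' thermochemical temperature on the torrefaction--pyrolysis scale.
#'
#' @param valuation an `hsw_valuation` from [bottom_up_value()].
#' @param include_compost include the 60 degC compost point in the
#'   regression (default FALSE).
#' @param compost_hht temperature identifying compost rows (60).
#' @return data.frame: `component`, `tau`, `slope` (USD/Mg per degC),
#'   `intercept`, `check_loss`.
#' @export
quantile_slopes <- function(valuation, include_compost = FALSE,
                            compost_hht = 60) {
  stopifnot(inherits(valuation, "hsw_valuation"))
  keep <- if (include_compost) rep(TRUE, length(valuation$hht_celsius))
          else valuation$hht_celsius != compost_hht
  x <- valuation$hht_celsius[keep]
  rows <- list()
  for (comp in valuation$components) {
    for (pj in seq_along(valuation$probs)) {
      y <- valuation$values[keep, comp, pj]
      fit <- quantile_trend(x, y, tau = valuation$probs[pj])
      rows[[length(rows) + 1L]] <- data.frame(
        component = comp, tau = valuation$probs[pj],
        slope = unname(coef(fit)["slope"]),
        intercept = unname(coef(fit)["intercept"]),
        check_loss = fit$check_loss, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
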