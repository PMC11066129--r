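#' Hill induction curve
#'
#' Relative competitor protein level \eqn{c_B(t)/c_A} after galactose
#' addition, modeled as a Hill function
#' \deqn{c_B(t)/c_A = X_P \frac{(t/t_{1/2ind})^n}{1 + (t/t_{1/2ind})^n}.}
#' The curve is 0 at \eqn{t = 0}, equals \eqn{X_P/2} at the induction
#' half-time and plateaus at \eqn{X_P}.
#'
#' @param t time since induction, minutes (vectorized, must be >= 0)
#' @param X_P plateau amplitude (dimensionless ratio)
#' @param t_half induction half-time \eqn{t_{1/2ind}}, minutes (> 0)
#' @param n Hill coefficient (> 0; fitted values are integers)
#' @return numeric vector of ratios, same length as `t`
#' @examples
#' hill_value(c(0, 43, 86), X_P = 1, t_half = 43, n = 4)
#' @export
hill_value <- function(t, X_P, t_half, n) {
  if (!is.numeric(t_half) || length(t_half) != 1L || !is.finite(t_half) ||
      t_half <= 0) {
    stop("`t_half` must be a single positive finite number")
  }
  if (!is.finite(X_P) || !is.finite(n) || n <= 0) {
    stop("`X_P` and `n` must be finite, with n > 0")
  }
  if (any(t < 0, na.rm = TRUE)) stop("`t` must be >= 0")
  r <- (t / t_half)^n
  out <- X_P * r / (1 + r)
  out[t == 0] <- 0
  out
}

#' Construct a Hill induction parameter set
#'
#' @param X_P plateau amplitude
#' @param t_half_ind induction half-time, minutes
#' @param n Hill coefficient (positive integer)
#' @param adj_r2 adjusted R-squared of the fit that produced the
#'   parameters (`NA` for parameters set by hand)
#' @param converged logical, `FALSE` for a failure record
#' @return object of class `hill_induction`
#' @export
hill_induction <- function(X_P, t_half_ind, n, adj_r2 = NA_real_,
                           converged = TRUE) {
  if (converged) {
    stopifnot(is.finite(X_P), X_P > 0, is.finite(t_half_ind), t_half_ind > 0,
              is.finite(n), n >= 1, n == as.integer(n))
  }
  structure(
    list(X_P = X_P, t_half_ind = t_half_ind, n = n, adj_r2 = adj_r2,
         converged = converged),
    class = "hill_induction"
  )
}

#' @export
print.hill_induction <- function(x, ...) {
  if (!x$converged) {
    cat("<hill_induction> fit failed\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<hill_induction> X_P = %.4g, t_half_ind = %.4g min, n = %d (adj R2 = %s)\n",
    x$X_P, x$t_half_ind, as.integer(x$n),
    ifelse(is.na(x$adj_r2), "NA", sprintf("%.4f", x$adj_r2))
  ))
  invisible(x)
}

# Adjusted R-squared with p free parameters: 1 - (1-R2)(N-1)/(N-p-1).
adj_r_squared <- function(observed, fitted, p) {
  n <- length(observed)
  ss_res <- sum((observed - fitted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(NA_real_)
  r2 <- 1 - ss_res / ss_tot
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

# Starting half-time: first linear-interpolation crossing of half-maximum.
half_time_start <- function(times, ratios, fallback = 40) {
  ymax <- max(ratios)
  if (!is.finite(ymax) || ymax <= 0) return(fallback)
  target <- ymax / 2
  above <- which(ratios >= target)
  if (length(above) == 0L) return(fallback)
  i <- above[1L]
  if (i == 1L) return(max(times[1L], fallback / 10))
  t0 <- times[i - 1L]; t1 <- times[i]
  y0 <- ratios[i - 1L]; y1 <- ratios[i]
  if (y1 == y0) return(t1)
  t0 + (target - y0) / (y1 - y0) * (t1 - t0)
}

#' Fit the competitor induction Hill model to western-blot ratios
#'
#' Fits \eqn{X_P} and the induction half-time by least squares on
#' replicate-averaged HA/Myc ratios, for every integer Hill coefficient in
#' `n_range`, and returns the fit with the highest adjusted R-squared
#' (p = 2 free parameters; ties broken toward the smaller `n`).
#'
#' @param series data frame with columns `time` (minutes, must include 0),
#'   `ratio` (>= 0) and optionally `replicate`
#' @param n_range candidate integer Hill coefficients
#' @return a [hill_induction()] object; `converged = FALSE` if no candidate
#'   coefficient yields a convergent fit
#' @examples
#' t <- c(0, 10, 20, 25, 30, 40, 60, 90, 120)
#' ws <- data.frame(time = t, ratio = hill_value(t, 1, 43, 4))
#' fit_induction(ws)
#' @export
fit_induction <- function(series, n_range = 1:10) {
  stopifnot(is.data.frame(series), all(c("time", "ratio") %in% names(series)))
  if (any(series$ratio < 0, na.rm = TRUE)) stop("ratios must be >= 0")
  if (!any(series$time == 0)) stop("`series` must include time 0")
  avg <- stats::aggregate(ratio ~ time, data = series, FUN = mean)
  avg <- avg[order(avg$time), ]
  if (nrow(avg) < 4L) stop("need >= 4 distinct time points")
  tt <- avg$time
  yy <- avg$ratio

  best <- NULL
  for (n_int in sort(as.integer(n_range))) {
    th0 <- half_time_start(tt, yy)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        yy ~ hill_value(tt, X_P, t_half, n_int),
        start = list(X_P = max(yy), t_half = th0),
        lower = c(1e-8, 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    co <- stats::coef(fit)
    ar2 <- adj_r_squared(yy, stats::fitted(fit), p = 2)
    if (is.na(ar2)) next
    if (is.null(best) || ar2 > best$adj_r2 + 1e-12) {
      best <- list(X_P = unname(co[["X_P"]]), t_half = unname(co[["t_half"]]),
                   n = n_int, adj_r2 = ar2)
    }
  }
  if (is.null(best)) {
    return(hill_induction(NA_real_, NA_real_, NA_integer_, NA_real_,
                          converged = FALSE))
  }
  hill_induction(best$X_P, best$t_half, best$n, best$adj_r2)
}
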