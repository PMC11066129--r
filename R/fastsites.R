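#' Hill half-time of a min-max normalized ratio series
#'
#' For sites without a reliable turnover fit, the normalized HA/Myc ratio
#' series is rescaled to range between zero and one (observed min/max) and
#' fitted to the induction Hill form with the Hill coefficient frozen at
#' the induction fit's value, using starting values
#' `t_half_CC = 40, X_CC = 1`. The fitted half-time feeds the fast-site
#' classification rule.
#'
#' @param series data frame with columns `time`, `R`
#' @param n_fixed integer Hill coefficient from [fit_induction()]
#' @param site_id identifier carried into the result
#' @return one-row data frame: `site_id`, `t_half_CC`, `X_CC`, `adj_r2`,
#'   `converged` (`FALSE` for a flat series or non-convergence)
#' @export
fit_normalized_hill <- function(series, n_fixed, site_id = NA_character_) {
  stopifnot(is.data.frame(series), all(c("time", "R") %in% names(series)))
  ok <- is.finite(series$R) & is.finite(series$time)
  tt <- series$time[ok]
  rr <- series$R[ok]
  fail <- data.frame(site_id = site_id, t_half_CC = NA_real_, X_CC = NA_real_,
                     adj_r2 = NA_real_, converged = FALSE,
                     stringsAsFactors = FALSE)
  rng <- diff(range(rr))
  if (length(rr) < 4L || !is.finite(rng) || rng <= 0) return(fail)
  y <- (rr - min(rr)) / rng
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ hill_value(tt, X_CC, t_half_CC, n_fixed),
      start = list(t_half_CC = 40, X_CC = 1),
      lower = c(1e-3, 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(fail)
  co <- stats::coef(fit)
  data.frame(site_id = site_id, t_half_CC = unname(co[["t_half_CC"]]),
             X_CC = unname(co[["X_CC"]]),
             adj_r2 = adj_r_squared(y, stats::fitted(fit), p = 2),
             converged = TRUE, stringsAsFactors = FALSE)
}

#' Classify a site as reliably fast
#'
#' A site without a retained turnover fit is classified as reliably fast --
#' residence time under 1 minute -- when its ratio curve lags the
#' competitor induction curve by less than 2 minutes:
#' \eqn{\Delta t_{1/2} = t_{1/2CC} - t_{1/2ind} < 2}. Fast sites carry the
#' class label `"<1 min"` and no numeric residence time.
#'
#' @param t_half_CC fitted half-time from [fit_normalized_hill()], minutes
#' @param ind [hill_induction()] induction parameters
#' @param site_id identifier carried into the result
#' @param threshold classification threshold for \eqn{\Delta t_{1/2}},
#'   minutes (strict inequality)
#' @return one-row data frame (`FastSiteCall`): `site_id`, `t_half_CC`,
#'   `delta_t_half`, `is_fast`, `class_label`, `plot_value` (`NA` until
#'   [plotting_values()] fills it)
#' @export
classify_fast <- function(t_half_CC, ind, site_id = NA_character_,
                          threshold = 2) {
  delta <- t_half_CC - ind$t_half_ind
  is_fast <- is.finite(delta) && delta < threshold
  data.frame(site_id = site_id, t_half_CC = t_half_CC, delta_t_half = delta,
             is_fast = is_fast,
             class_label = if (is_fast) "<1 min" else "unclassified",
             plot_value = NA_real_, stringsAsFactors = FALSE)
}

#' Reproducible plotting stand-ins for fast sites
#'
#' Fast sites have no numeric residence-time estimate; for display they are
#' given uniform values in `[0, 1)` minutes, reproducible under a fixed
#' seed (default 42). The values live in a separate `plot_value` column --
#' they are synthetic and must never enter downstream statistics.
#'
#' @param calls data frame of `FastSiteCall` rows ([classify_fast()])
#' @param seed integer seed
#' @return `calls` with `plot_value` filled for fast sites
#' @export
plotting_values <- function(calls, seed = 42L) {
  stopifnot(is.data.frame(calls), "is_fast" %in% names(calls))
  set.seed(seed)
  calls$plot_value <- NA_real_
  n_fast <- sum(calls$is_fast)
  calls$plot_value[calls$is_fast] <- stats::runif(n_fast, min = 0, max = 1)
  calls
}

#' Classify all sites left over by the turnover fit
#'
#' Applies [fit_normalized_hill()] + [classify_fast()] to every site in the
#' ratio table that lacks a retained turnover fit, then fills reproducible
#' plotting values. A site never carries both a retained turnover fit and
#' a fast-site call.
#'
#' @param rt ratio table from [ratio_table()] / [normalize_experiment()]
#' @param fits final `TurnoverFit` table ([apply_filters()])
#' @param ind [hill_induction()] induction parameters
#' @param seed seed for [plotting_values()]
#' @return data frame of `FastSiteCall` rows for all non-retained sites
#' @export
classify_leftover_sites <- function(rt, fits, ind, seed = 42L) {
  retained_ids <- fits$site_id[fits$retained]
  todo <- setdiff(rt$site_ids, retained_ids)
  if (length(todo) == 0) {
    return(data.frame(site_id = character(), t_half_CC = numeric(),
                      delta_t_half = numeric(), is_fast = logical(),
                      class_label = character(), plot_value = numeric(),
                      stringsAsFactors = FALSE))
  }
  calls <- do.call(rbind, lapply(todo, function(sid) {
    nh <- fit_normalized_hill(site_series(rt, sid), n_fixed = ind$n,
                              site_id = sid)
    classify_fast(nh$t_half_CC, ind, site_id = sid)
  }))
  plotting_values(calls, seed = seed)
}
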