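#' Solve the mass-action competition turnover model
#'
#' Numerically integrates the coupled occupancy equations for one binding
#' site shared by the constitutive (A, Myc) and induced competitor (B, HA)
#' isoform,
#' \deqn{d\theta_B/dt = k_{on}\, h(t) (1 - \theta_A - \theta_B) - k_{off}\theta_B}
#' \deqn{d\theta_A/dt = k_{on} (1 - \theta_A - \theta_B) - k_{off}\theta_A}
#' where \eqn{k_{on} = k_a c_A} is the effective on-rate, \eqn{k_{off} = k_d}
#' the molecular off-rate and \eqn{h(t) = c_B(t)/c_A} the competitor
#' induction curve ([hill_value()]). The initial state is the pre-induction
#' steady state \eqn{\theta_A(0) = k_{on}/(k_{on}+k_{off})},
#' \eqn{\theta_B(0) = 0}, so the occupancy ratio satisfies
#' \eqn{\theta_B(0)/\theta_A(0) = 0} and tends to \eqn{X_P} as
#' \eqn{t \to \infty}.
#'
#' Integration uses a compiled adaptive exponential-midpoint scheme
#' (relative tolerance 1e-8, absolute 1e-10 by default), tight enough that
#' fitting error dominates numerical error. The scheme exploits the
#' model's structure -- the system is linear in the occupancies for a
#' frozen induction level, so each step is a closed-form matrix
#' exponential -- and is A-stable, so the large-on-rate corner of the fit
#' parameter space costs no extra time.
#'
#' @param params list or vector with elements `k_on_eff` and `k_off`
#'   (both per minute, > 0)
#' @param ind [hill_induction()] parameters of the competitor induction
#' @param times evaluation times, minutes, strictly increasing and >= 0
#' @param rtol,atol integrator tolerances
#' @return data frame with columns `time`, `theta_A`, `theta_B`, `ratio`
#'   (`theta_B/theta_A`)
#' @examples
#' ind <- hill_induction(1, 43, 4)
#' solve_model(list(k_on_eff = 1, k_off = log(2) / 5), ind, cc_time_points())
#' @export
solve_model <- function(params, ind, times, rtol = 1e-8, atol = 1e-10) {
  kon <- params[["k_on_eff"]]
  koff <- params[["k_off"]]
  if (!is.finite(kon) || !is.finite(koff) || kon <= 0 || koff <= 0) {
    stop(sprintf("invalid kinetic parameters (k_on_eff=%s, k_off=%s)",
                 format(kon), format(koff)))
  }
  stopifnot(inherits(ind, "hill_induction"), isTRUE(ind$converged))
  times <- as.numeric(times)
  if (any(!is.finite(times)) || any(times < 0) || is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be finite, >= 0 and strictly increasing")
  }
  eval_times <- if (times[1] == 0) times else c(0, times)
  sol <- tryCatch(
    cc_integrate(kon, koff, ind$X_P, ind$t_half_ind, ind$n, eval_times,
                 rtol = rtol, atol = atol),
    error = function(e) {
      stop(sprintf("ODE integration failed (k_on_eff=%g, k_off=%g): %s",
                   kon, koff, conditionMessage(e)))
    }
  )
  keep <- if (times[1] == 0) seq_along(eval_times) else -1L
  th_a <- sol[keep, "theta_A"]
  th_b <- sol[keep, "theta_B"]
  data.frame(time = times, theta_A = th_a, theta_B = th_b,
             ratio = th_b / th_a)
}

#' Default competition ChIP sampling times
#'
#' Minutes after galactose addition at which samples are crosslinked:
#' 0, 10, 20, 25, 30, 40, 60, 90 and 120.
#'
#' @return numeric vector of 9 time points
#' @export
cc_time_points <- function() c(0, 10, 20, 25, 30, 40, 60, 90, 120)

#' Residence time from an off-rate
#'
#' \eqn{t_{1/2} = \ln 2 / k_d}: the half-life of a factor's occupancy at a
#' site.
#'
#' @param k_off off-rate, per minute (> 0)
#' @return residence time in minutes
#' @examples
#' residence_time(log(2))      # 1 minute
#' @export
residence_time <- function(k_off) {
  if (any(!is.finite(k_off)) || any(k_off <= 0)) {
    stop("`k_off` must be positive and finite")
  }
  log(2) / k_off
}

#' First-pass initial residence-time guess
#'
#' Heuristic starting value for the nonlinear turnover fit,
#' \eqn{t_{1/2}^0 = 0.6\,(t_{1/2CC} - t_{1/2ind}) + 0.1} by default, floored
#' at a small positive value so a negative lag still yields a usable start.
#'
#' @param t_half_CC site-level Hill half-time, minutes
#' @param t_half_ind induction half-time, minutes
#' @param coeffs slope and intercept of the linear map
#' @param floor smallest admissible guess, minutes
#' @return initial guess \eqn{t_{1/2}^0} in minutes
#' @examples
#' initial_guess(43, 43)   # 0.1
#' initial_guess(53, 43)   # 6.1
#' @export
initial_guess <- function(t_half_CC, t_half_ind, coeffs = c(0.6, 0.1),
                          floor = 0.05) {
  stopifnot(is.finite(t_half_CC), is.finite(t_half_ind))
  pmax(coeffs[1] * (t_half_CC - t_half_ind) + coeffs[2], floor)
}

#' Fit the turnover model to one site's occupancy-ratio series
#'
#' Derivative-based nonlinear least squares (Levenberg--Marquardt,
#' [minpack.lm::nls.lm()]) of the [solve_model()] occupancy ratio against an
#' observed series, over `(log k_on_eff, log k_off)` so both rates stay
#' positive, with box bounds `1e-4..1e3` per minute. The off-rate standard
#' error comes from the Jacobian-based parameter covariance at the optimum
#' (delta method on the log scale); adjusted R-squared uses p = 2.
#'
#' The default objective weights each residual by the model value
#' (`objective = "relative"`): ChIP count noise is multiplicative, so the
#' occupancy-ratio error scales with the ratio itself, and unweighted
#' least squares would let the large late-time values drown out the small
#' early-time lag that carries the off-rate information. Weights are
#' capped at `1 / (weight_floor * X_P)` so near-zero early model values
#' cannot dominate either. `objective = "ols"` gives plain unweighted
#' residuals.
#'
#' @param occ data frame with columns `time` and `theta_ratio`
#'   (estimated \eqn{\theta_B/\theta_A}); at least 5 finite points
#' @param ind [hill_induction()] induction parameters
#' @param t0 initial residence-time guess, minutes (see [initial_guess()])
#' @param kon_init starting effective on-rate, per minute
#' @param kon_fixed if non-`NULL`, freeze the on-rate at this value and fit
#'   only the off-rate (used for on-rate sensitivity analysis)
#' @param site_id identifier carried into the result
#' @param rate_bounds lower/upper bounds for both rates, per minute
#' @param objective `"relative"` (weighted, default) or `"ols"`
#' @param weight_floor relative-residual denominator floor, as a fraction
#'   of the induction plateau
#' @return one-row data frame (a `TurnoverFit` record): `site_id`,
#'   `k_on_eff`, `k_off`, `se_k_off`, `adj_r2`, `t_half`, `init_guess`,
#'   `converged`, `retained`, `reason`; `adj_r2` is computed on the data
#'   scale (unweighted) with p = 2
#' @export
fit_site <- function(occ, ind, t0, kon_init = 1, kon_fixed = NULL,
                     site_id = NA_character_, rate_bounds = c(1e-4, 1e3),
                     objective = c("relative", "ols"),
                     weight_floor = 0.01) {
  objective <- match.arg(objective)
  stopifnot(is.data.frame(occ), all(c("time", "theta_ratio") %in% names(occ)))
  ok <- is.finite(occ$theta_ratio) & is.finite(occ$time)
  occ <- occ[ok, ]
  occ <- occ[order(occ$time), ]
  if (nrow(occ) < 5L) {
    return(turnover_record(site_id, init_guess = t0, reason = "too_few_points"))
  }
  times <- occ$time
  obs <- occ$theta_ratio
  n_obs <- length(obs)
  koff0 <- min(max(log(2) / t0, rate_bounds[1] * 1.01), rate_bounds[2] * 0.99)
  lb <- log(rate_bounds[1]); ub <- log(rate_bounds[2])

  model_ratio <- function(kon, koff) {
    sm <- solve_model(list(k_on_eff = kon, k_off = koff), ind, times)
    sm$ratio
  }
  wfloor <- weight_floor * abs(ind$X_P)
  weigh <- function(raw, r) {
    if (objective == "ols") raw else raw / pmax(abs(r), wfloor)
  }
  resid_fn <- if (is.null(kon_fixed)) {
    function(p) {
      r <- tryCatch(model_ratio(exp(p[1]), exp(p[2])), error = function(e) NULL)
      if (is.null(r) || any(!is.finite(r))) return(rep(1e6, n_obs))
      weigh(r - obs, r)
    }
  } else {
    function(p) {
      r <- tryCatch(model_ratio(kon_fixed, exp(p[1])), error = function(e) NULL)
      if (is.null(r) || any(!is.finite(r))) return(rep(1e6, n_obs))
      weigh(r - obs, r)
    }
  }
  par0 <- if (is.null(kon_fixed)) c(log(kon_init), log(koff0)) else log(koff0)
  np <- length(par0)
  run_lm <- function(p0) {
    tryCatch(
      minpack.lm::nls.lm(
        par = p0, fn = resid_fn,
        lower = rep(lb, np), upper = rep(ub, np),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12)
      ),
      error = function(e) NULL
    )
  }
  if (is.null(kon_fixed)) {
    # Two-stage fit. The ratio is nearly flat in the on-rate, so a joint
    # fit from a poor off-rate start can slide along that valley into a
    # shallow local basin (typically at an extreme on-rate) that also
    # biases the off-rate. Stage 1 pins the on-rate at its moderate start
    # and fits the off-rate alone -- insensitivity guarantees this lands
    # close to the optimum -- and stage 2 releases both parameters from
    # there.
    stage1 <- tryCatch(
      minpack.lm::nls.lm(
        par = log(koff0),
        fn = function(p) {
          r <- tryCatch(model_ratio(kon_init, exp(p[1])),
                        error = function(e) NULL)
          if (is.null(r) || any(!is.finite(r))) return(rep(1e6, n_obs))
          weigh(r - obs, r)
        },
        lower = lb, upper = ub,
        control = minpack.lm::nls.lm.control(maxiter = 100)
      ),
      error = function(e) NULL
    )
    if (!is.null(stage1) && stage1$info != 0) {
      par0 <- c(log(kon_init), stage1$par[1])
    }
  }
  fit <- run_lm(par0)
  # Guard against residual on-rate drift: restart once from the moderate
  # on-rate and keep the lower-RSS solution.
  if (is.null(kon_fixed) && !is.null(fit) && fit$info != 0) {
    kon_fit <- exp(fit$par[1])
    if (kon_fit < 0.1 || kon_fit > 10) {
      fit2 <- run_lm(c(log(kon_init), fit$par[2]))
      if (!is.null(fit2) && fit2$info != 0 &&
          sum(fit2$fvec^2) < sum(fit$fvec^2)) {
        fit <- fit2
      }
    }
  }
  if (is.null(fit) || fit$info == 0) {
    return(turnover_record(site_id, init_guess = t0, reason = "no_convergence"))
  }
  p_hat <- fit$par
  kon_hat <- if (is.null(kon_fixed)) exp(p_hat[1]) else kon_fixed
  koff_hat <- exp(p_hat[length(p_hat)])
  rss <- sum(fit$fvec^2)
  sigma2 <- rss / max(n_obs - np, 1)
  # Curvature-aware covariance. The on-rate direction routinely carries
  # essentially zero curvature (the ratio is insensitive to k_on_eff),
  # making J'J numerically singular; such a direction is dropped and the
  # off-rate uncertainty stays well defined. But if a zero-curvature
  # direction loads substantially on the off-rate itself -- a fast site
  # whose lag is unresolvable -- the off-rate is unidentifiable and its
  # standard error is reported as Inf, so the retention filter routes the
  # site to the fast-site classifier.
  koff_axis <- length(p_hat)
  se_log_koff <- tryCatch({
    ev <- eigen(fit$hessian, symmetric = TRUE)
    weak <- ev$values <= max(ev$values) * 1e-12
    if (all(weak)) stop("zero curvature")
    if (any(abs(ev$vectors[koff_axis, weak]) > 0.5)) {
      Inf
    } else {
      v <- ev$vectors[, !weak, drop = FALSE]
      cov_log <- sigma2 * (v %*% diag(1 / ev$values[!weak], sum(!weak)) %*%
                             t(v))
      if (any(diag(cov_log) < 0)) stop("negative variance")
      sqrt(diag(cov_log)[koff_axis])
    }
  }, error = function(e) NULL)
  if (is.null(se_log_koff) || is.nan(se_log_koff)) {
    return(turnover_record(site_id, init_guess = t0,
                           reason = "singular_covariance"))
  }
  se_koff <- koff_hat * se_log_koff          # delta method
  fitted_vals <- tryCatch(model_ratio(kon_hat, koff_hat),
                          error = function(e) rep(NA_real_, n_obs))
  ar2 <- adj_r_squared(obs, fitted_vals, p = 2)
  turnover_record(site_id,
                  k_on_eff = kon_hat, k_off = koff_hat, se_k_off = se_koff,
                  adj_r2 = ar2, t_half = residence_time(koff_hat),
                  init_guess = t0, converged = TRUE, reason = "")
}

turnover_record <- function(site_id, k_on_eff = NA_real_, k_off = NA_real_,
                            se_k_off = NA_real_, adj_r2 = NA_real_,
                            t_half = NA_real_, init_guess = NA_real_,
                            converged = FALSE, reason = "failed") {
  data.frame(site_id = site_id, k_on_eff = k_on_eff, k_off = k_off,
             se_k_off = se_k_off, adj_r2 = adj_r2, t_half = t_half,
             init_guess = init_guess, converged = converged,
             retained = FALSE, reason = reason,
             stringsAsFactors = FALSE)
}

#' Retention filters for turnover fits
#'
#' A fit is retained for downstream residence-time analysis iff its
#' relative off-rate error satisfies \eqn{\Delta k_d / k_d < 3} and its
#' adjusted R-squared exceeds 0.7 (both strict inequalities).
#'
#' @param fits data frame of `TurnoverFit` records (see [fit_site()])
#' @param max_rel_se,min_adj_r2 filter thresholds
#' @return `fits` with `retained` and `reason` columns filled
#' @export
apply_filters <- function(fits, max_rel_se = 3, min_adj_r2 = 0.7) {
  stopifnot(all(c("k_off", "se_k_off", "adj_r2", "converged") %in% names(fits)))
  rel_se <- fits$se_k_off / fits$k_off
  ok_se <- is.finite(rel_se) & rel_se < max_rel_se
  ok_r2 <- is.finite(fits$adj_r2) & fits$adj_r2 > min_adj_r2
  conv <- fits$converged
  fits$retained <- conv & ok_se & ok_r2
  reason <- character(nrow(fits))
  reason[conv & !ok_se & ok_r2] <- "error"
  reason[conv & ok_se & !ok_r2] <- "fit_quality"
  reason[conv & !ok_se & !ok_r2] <- "error;fit_quality"
  keep_old <- !conv
  reason[keep_old] <- fits$reason[keep_old]
  fits$reason <- reason
  fits
}

#' Refine initial guesses from first-pass fits and refit every site
#'
#' Regresses first-pass residence times on the site lag
#' \eqn{\Delta t_{1/2} = t_{1/2CC} - t_{1/2ind}} with linear and quadratic
#' candidate maps, selects the candidate with the larger adjusted R-squared,
#' regenerates per-site initial guesses from the selected map, and refits the
#' turnover model at every site. Sites whose refit fails keep their
#' first-pass record. With fewer than `min_fits` retained first-pass fits
#' the input is passed through unchanged with a warning.
#'
#' @param first_pass data frame of first-pass `TurnoverFit` records, already
#'   passed through [apply_filters()]
#' @param hill_fits data frame of per-site Hill fits with columns `site_id`
#'   and `t_half_CC` (see [fit_site_hill()])
#' @param ind [hill_induction()] induction parameters
#' @param occ_list named list of occupancy-ratio data frames keyed by
#'   `site_id` (the same series the first pass was fitted to)
#' @param min_fits minimum number of retained fits needed to fit the map
#' @return list with `fits` (refitted `TurnoverFit` table, filters applied),
#'   `map` (the selected `lm` object), `map_form` ("linear" or "quadratic")
#' @export
refine_and_refit <- function(first_pass, hill_fits, ind, occ_list,
                             min_fits = 10) {
  stopifnot(all(c("site_id", "t_half_CC") %in% names(hill_fits)))
  merged <- merge(first_pass, hill_fits[, c("site_id", "t_half_CC")],
                  by = "site_id")
  merged$delta <- merged$t_half_CC - ind$t_half_ind
  train <- merged[merged$retained & is.finite(merged$delta), ]
  if (nrow(train) < min_fits) {
    warning(sprintf("only %d retained fits; refinement skipped", nrow(train)))
    return(list(fits = first_pass, map = NULL, map_form = "none"))
  }
  lin <- stats::lm(t_half ~ delta, data = train)
  quad <- stats::lm(t_half ~ delta + I(delta^2), data = train)
  ar2 <- c(linear = summary(lin)$adj.r.squared,
           quadratic = summary(quad)$adj.r.squared)
  map_form <- names(ar2)[which.max(ar2)]
  map <- if (map_form == "linear") lin else quad
  out <- vector("list", nrow(merged))
  for (i in seq_len(nrow(merged))) {
    sid <- merged$site_id[i]
    t0_new <- max(stats::predict(map, data.frame(delta = merged$delta[i])),
                  0.05)
    occ <- occ_list[[sid]]
    refit <- if (!is.null(occ) && is.finite(t0_new)) {
      fit_site(occ, ind, t0 = t0_new, site_id = sid)
    } else {
      NULL
    }
    first <- first_pass[first_pass$site_id == sid, ]
    out[[i]] <- if (!is.null(refit) && refit$converged) refit else first
  }
  left_out <- first_pass[!(first_pass$site_id %in% merged$site_id), ]
  fits <- apply_filters(rbind(do.call(rbind, out), left_out))
  list(fits = fits, map = map, map_form = map_form)
}

#' Fit the turnover model across a cohort of sites
#'
#' Convenience driver: per-site initial guesses from the site Hill
#' half-times via [initial_guess()], first-pass [fit_site()] at every site,
#' retention filters, then [refine_and_refit()].
#'
#' @param occ_list named list of occupancy-ratio data frames (columns
#'   `time`, `theta_ratio`), keyed by site id
#' @param hill_fits per-site Hill fit table ([fit_site_hill()]) with
#'   `site_id` and `t_half_CC`
#' @param ind [hill_induction()] induction parameters
#' @param refine logical; run the refinement/refit pass
#' @return list with `fits` (final `TurnoverFit` table), `first_pass`,
#'   `map_form`
#' @export
fit_turnover_cohort <- function(occ_list, hill_fits, ind, refine = TRUE) {
  stopifnot(length(occ_list) > 0, !is.null(names(occ_list)))
  rows <- vector("list", length(occ_list))
  for (i in seq_along(occ_list)) {
    sid <- names(occ_list)[i]
    thcc <- hill_fits$t_half_CC[match(sid, hill_fits$site_id)]
    t0 <- if (is.finite(thcc)) initial_guess(thcc, ind$t_half_ind) else 0.1
    rows[[i]] <- fit_site(occ_list[[i]], ind, t0 = t0, site_id = sid)
  }
  first_pass <- apply_filters(do.call(rbind, rows))
  if (!refine) {
    return(list(fits = first_pass, first_pass = first_pass, map_form = "none"))
  }
  refined <- tryCatch(
    refine_and_refit(first_pass, hill_fits, ind, occ_list),
    warning = function(w) {
      list(fits = first_pass, map = NULL, map_form = "none")
    }
  )
  list(fits = refined$fits, first_pass = first_pass,
       map_form = refined$map_form)
}
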