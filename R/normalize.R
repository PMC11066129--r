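#' Construct a site x time count matrix
#'
#' Container for per-site read counts of one tagged isoform over the
#' competition ChIP time course. `library_sizes` are the per-sample total
#' mapped read counts used for depth normalization; in-peak counts are a
#' fraction of them. Counts may be real-valued (expected counts from the
#' simulator, or depth-normalized values).
#'
#' @param counts numeric matrix, sites as rows, time points as columns,
#'   all values >= 0
#' @param times time points in minutes, one per column
#' @param tag `"HA"` (inducible competitor) or `"Myc"` (constitutive)
#' @param library_sizes per-sample totals, one per column, all > 0
#' @param site_ids row identifiers (default: rownames of `counts`)
#' @return object of class `cc_counts`
#' @export
count_matrix <- function(counts, times, tag = c("HA", "Myc"),
                         library_sizes, site_ids = rownames(counts)) {
  tag <- match.arg(tag)
  counts <- as.matrix(counts)
  if (is.null(site_ids)) site_ids <- sprintf("site_%04d", seq_len(nrow(counts)))
  stopifnot(ncol(counts) == length(times),
            length(library_sizes) == length(times),
            length(site_ids) == nrow(counts))
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be >= 0")
  rownames(counts) <- site_ids
  colnames(counts) <- paste0("t", times)
  structure(list(counts = counts, times = as.numeric(times), tag = tag,
                 library_sizes = as.numeric(library_sizes),
                 site_ids = site_ids),
            class = "cc_counts")
}

#' @export
print.cc_counts <- function(x, ...) {
  cat(sprintf("<cc_counts> %s: %d sites x %d time points\n",
              x$tag, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Depth normalization (counts per million)
#'
#' First step of the three-step normalization: each sample's column is
#' scaled to counts per million of its library size, removing sequencing-
#' depth differences between time points.
#'
#' @param cm [count_matrix()] with positive `library_sizes`
#' @return a [count_matrix()] with real-valued CPM entries and unit
#'   library sizes (scaled by 1e-6 so a second pass is a no-op)
#' @export
depth_normalize <- function(cm) {
  stopifnot(inherits(cm, "cc_counts"))
  if (any(!is.finite(cm$library_sizes)) || any(cm$library_sizes <= 0)) {
    stop("library sizes must be positive")
  }
  cpm <- sweep(cm$counts, 2, cm$library_sizes / 1e6, `/`)
  count_matrix(cpm, cm$times, cm$tag, library_sizes = rep(1e6, ncol(cpm)),
               site_ids = cm$site_ids)
}

#' Western scaling of the HA count matrix
#'
#' Second normalization step: the depth-normalized HA column at time `t` is
#' multiplied by the fitted induction curve value \eqn{h(t)}, restoring the
#' induction-driven global scale that per-sample depth normalization cannot
#' see. The `t = 0` column becomes exactly zero. Using the smoothed Hill
#' fit rather than raw blot averages avoids injecting replicate noise into
#' every site.
#'
#' @param ha_cpm depth-normalized HA [count_matrix()]
#' @param ind fitted [hill_induction()] parameters
#' @return scaled [count_matrix()]
#' @export
western_scale <- function(ha_cpm, ind) {
  stopifnot(inherits(ha_cpm, "cc_counts"), ha_cpm$tag == "HA",
            inherits(ind, "hill_induction"), isTRUE(ind$converged))
  h <- hill_value(ha_cpm$times, ind$X_P, ind$t_half_ind, ind$n)
  scaled <- sweep(ha_cpm$counts, 2, h, `*`)
  count_matrix(scaled, ha_cpm$times, "HA", ha_cpm$library_sizes,
               ha_cpm$site_ids)
}

#' Per-site normalized HA/Myc ratio series
#'
#' Third normalization step: elementwise division of the western-scaled HA
#' matrix by the depth-normalized Myc matrix. Sites with a zero Myc entry
#' at any time point are flagged and excluded (no pseudocount, to avoid
#' biasing R(t)).
#'
#' @param ha_scaled western-scaled HA [count_matrix()]
#' @param myc_cpm depth-normalized Myc [count_matrix()]
#' @return list with `ratios` (site x time matrix R(t) for retained sites),
#'   `times`, `site_ids`, `excluded` (ids of zero-Myc sites)
#' @export
ratio_table <- function(ha_scaled, myc_cpm) {
  stopifnot(inherits(ha_scaled, "cc_counts"), inherits(myc_cpm, "cc_counts"))
  if (!identical(dim(ha_scaled$counts), dim(myc_cpm$counts)) ||
      !identical(ha_scaled$site_ids, myc_cpm$site_ids) ||
      !identical(ha_scaled$times, myc_cpm$times)) {
    stop("HA and Myc matrices must have matching sites and time points")
  }
  zero_myc <- apply(myc_cpm$counts == 0, 1, any)
  ratios <- ha_scaled$counts[!zero_myc, , drop = FALSE] /
    myc_cpm$counts[!zero_myc, , drop = FALSE]
  list(ratios = ratios, times = ha_scaled$times,
       site_ids = ha_scaled$site_ids[!zero_myc],
       excluded = ha_scaled$site_ids[zero_myc])
}

# Extract one site's ratio series as a data frame.
site_series <- function(rt, site_id) {
  i <- match(site_id, rt$site_ids)
  if (is.na(i)) stop(sprintf("site '%s' not in ratio table", site_id))
  data.frame(time = rt$times, R = rt$ratios[i, ])
}

#' Site-level Hill fit with background
#'
#' Fits the normalized ratio series R(t) of one site to the induction Hill
#' form with the Hill coefficient frozen at the induction fit's integer
#' value and an added background term:
#' \eqn{R(t) = B + X_{CC}\, (t/t_{1/2CC})^n / (1 + (t/t_{1/2CC})^n)}.
#' Yields the amplitude \eqn{X_{CC}}, half-time rise \eqn{t_{1/2CC}} and
#' residual background \eqn{B} used for background subtraction and for the
#' first-pass residence-time initializer.
#'
#' @param series data frame with columns `time`, `R`
#' @param n_fixed integer Hill coefficient from [fit_induction()]
#' @param site_id identifier carried into the result
#' @return one-row data frame (`SiteHillFit`): `site_id`, `X_CC`,
#'   `t_half_CC`, `B`, `adj_r2`, `converged`
#' @export
fit_site_hill <- function(series, n_fixed, site_id = NA_character_) {
  stopifnot(is.data.frame(series), all(c("time", "R") %in% names(series)))
  ok <- is.finite(series$R) & is.finite(series$time)
  tt <- series$time[ok]
  rr <- series$R[ok]
  fail <- data.frame(site_id = site_id, X_CC = NA_real_, t_half_CC = NA_real_,
                     B = NA_real_, adj_r2 = NA_real_, converged = FALSE,
                     stringsAsFactors = FALSE)
  if (length(rr) < 5L || diff(range(rr)) == 0) return(fail)
  b0 <- min(rr)
  x0 <- max(rr) - b0
  th0 <- half_time_start(tt, rr - b0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rr ~ B + hill_value(tt, X_CC, t_half_CC, n_fixed),
      start = list(B = b0, X_CC = x0, t_half_CC = th0),
      lower = c(-Inf, 1e-8, 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(fail)
  co <- stats::coef(fit)
  data.frame(site_id = site_id, X_CC = unname(co[["X_CC"]]),
             t_half_CC = unname(co[["t_half_CC"]]), B = unname(co[["B"]]),
             adj_r2 = adj_r_squared(rr, stats::fitted(fit), p = 3),
             converged = TRUE, stringsAsFactors = FALSE)
}

#' Background-subtracted, scaled occupancy-ratio series
#'
#' Converts a normalized ratio series into the estimated occupancy ratio
#' \eqn{\theta_B(t)/\theta_A(t) = (X_P / X_{CC}) (R(t) - B)}, which
#' satisfies the model's boundary conditions (0 at t = 0, X_P at late
#' times) on noiseless data. Negative values after background subtraction
#' are retained (least squares handles them), not clamped.
#'
#' @param series data frame with columns `time`, `R`
#' @param fit one-row `SiteHillFit` from [fit_site_hill()]
#' @param ind [hill_induction()] induction parameters
#' @return data frame with `time`, `theta_ratio`, or `NULL` with a warning
#'   when the site is excluded (non-converged fit or `X_CC <= 0`)
#' @export
to_occupancy <- function(series, fit, ind) {
  stopifnot(is.data.frame(series), all(c("time", "R") %in% names(series)))
  if (!isTRUE(fit$converged)) {
    warning(sprintf("site %s: Hill fit did not converge; excluded",
                    fit$site_id))
    return(NULL)
  }
  if (!is.finite(fit$X_CC) || fit$X_CC <= 0) {
    warning(sprintf("site %s: non-positive amplitude X_CC; excluded",
                    fit$site_id))
    return(NULL)
  }
  data.frame(time = series$time,
             theta_ratio = (ind$X_P / fit$X_CC) * (series$R - fit$B))
}

#' Run the full normalization chain on a simulated or real experiment
#'
#' Depth-normalizes both count matrices, western-scales HA, forms the
#' ratio table, fits the per-site Hill model and converts every convergent
#' site to an occupancy-ratio series.
#'
#' @param counts list with `ha` and `myc` [count_matrix()] objects
#' @param ind fitted [hill_induction()] parameters
#' @return list with `ratio_table`, `hill_fits` (per-site table),
#'   `occupancy` (named list of data frames, one per converted site),
#'   `excluded` (named character vector of exclusion reasons)
#' @export
normalize_experiment <- function(counts, ind) {
  ha_cpm <- depth_normalize(counts$ha)
  myc_cpm <- depth_normalize(counts$myc)
  ha_scaled <- western_scale(ha_cpm, ind)
  rt <- ratio_table(ha_scaled, myc_cpm)
  excluded <- stats::setNames(rep("zero_myc", length(rt$excluded)),
                              rt$excluded)
  hill_fits <- list()
  occupancy <- list()
  for (sid in rt$site_ids) {
    ser <- site_series(rt, sid)
    hf <- fit_site_hill(ser, n_fixed = ind$n, site_id = sid)
    hill_fits[[sid]] <- hf
    if (!hf$converged) {
      excluded[sid] <- "hill_no_convergence"
      next
    }
    if (hf$X_CC <= 0) {
      excluded[sid] <- "nonpositive_amplitude"
      next
    }
    occupancy[[sid]] <- suppressWarnings(to_occupancy(ser, hf, ind))
  }
  list(ratio_table = rt, hill_fits = do.call(rbind, hill_fits),
       occupancy = occupancy, excluded = excluded)
}
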