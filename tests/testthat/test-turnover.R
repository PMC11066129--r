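test_that("solve_model meets boundary conditions and matches the RK4 oracle", {
  ind <- default_ind()
  grid <- expand.grid(t_half = c(0.5, 2, 5, 20), kon = c(0.1, 1, 10))
  for (i in seq_len(nrow(grid))) {
    kon <- grid$kon[i]
    koff <- log(2) / grid$t_half[i]
    sm <- solve_model(list(k_on_eff = kon, k_off = koff), ind,
                      cc_time_points())
    expect_equal(sm$ratio[1], 0)
    ref <- rk4_ratio(kon, koff, ind, cc_time_points(), step = 0.001)
    expect_equal(sm$ratio, ref, tolerance = 1e-5)
    late <- solve_model(list(k_on_eff = kon, k_off = koff), ind,
                        c(0, 1e4 * ind$t_half_ind))
    expect_equal(late$ratio[2], ind$X_P, tolerance = 1e-3)
  }
  expect_error(solve_model(list(k_on_eff = -1, k_off = 1), ind, c(0, 10)),
               "invalid")
  expect_error(solve_model(list(k_on_eff = 1, k_off = NaN), ind, c(0, 10)),
               "invalid")
})

test_that("initial guess follows the linear map with a positive floor", {
  expect_equal(initial_guess(43, 43), 0.1)
  expect_equal(initial_guess(53, 43), 6.1)
  expect_equal(initial_guess(38, 43), 0.05)  # negative lag floored
})

test_that("residence time is ln2 over the off-rate", {
  expect_equal(residence_time(log(2)), 1)
  expect_equal(residence_time(log(2) / 10), 10)
  expect_error(residence_time(0), "positive")
})

test_that("noiseless fits recover the off-rate essentially exactly", {
  ind <- default_ind()
  for (th in c(0.2, 1, 5, 15)) {
    occ <- occ_series_for(th, ind)
    fit <- fit_site(occ, ind, t0 = initial_guess(th + ind$t_half_ind,
                                                 ind$t_half_ind))
    expect_true(fit$converged)
    expect_equal(fit$t_half, th, tolerance = 0.02)
    expect_gt(fit$adj_r2, 0.999)
    expect_lt(fit$se_k_off / fit$k_off, 0.05)
  }
})

test_that("fitted residence time increases with true residence time", {
  ind <- default_ind()
  fits <- vapply(c(0.5, 1, 2, 4, 8, 16), function(th) {
    fit_site(occ_series_for(th, ind), ind, t0 = 0.6 * th + 0.1)$t_half
  }, numeric(1))
  expect_true(all(diff(fits) > 0))
})

test_that("off-rate is insensitive to a frozen mis-specified on-rate", {
  ind <- default_ind()
  for (th in c(1, 5, 20)) {
    occ <- occ_series_for(th, ind, kon = 1)
    t0 <- initial_guess(th + ind$t_half_ind, ind$t_half_ind)
    k_lo <- fit_site(occ, ind, t0, kon_fixed = 0.1)$k_off
    k_hi <- fit_site(occ, ind, t0, kon_fixed = 10)$k_off
    k_true <- log(2) / th
    expect_lt(abs(k_lo / k_true - 1), 0.05)
    expect_lt(abs(k_hi / k_true - 1), 0.05)
  }
})

test_that("noisy recovery stays within the expected error envelope", {
  ind <- default_ind()
  sdl <- sqrt(log(1 + 0.1^2))
  meds <- vapply(1:3, function(s) {
    set.seed(300 + s)
    ths <- exp(stats::runif(40, log(2), log(20)))
    errs <- vapply(ths, function(th) {
      r <- simulate_occupancy(list(k_on_eff = 1, k_off = log(2) / th), ind,
                              cc_time_points())
      robs <- r * exp(stats::rnorm(9, -sdl^2, sdl * sqrt(2)))
      robs[1] <- 0
      f <- fit_site(data.frame(time = cc_time_points(), theta_ratio = robs),
                    ind, t0 = initial_guess(th + 43, 43))
      abs(f$t_half / th - 1)
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_lt(median(meds), 0.15)
})

test_that("retention filters apply the strict printed thresholds", {
  fits <- data.frame(
    site_id = c("a", "b", "c", "d", "e"),
    k_on_eff = 1,
    k_off = 1,
    se_k_off = c(2.9, 3.1, 2.9, 3.0, 0.5),
    adj_r2 = c(0.71, 0.71, 0.69, 0.7, 0.7),
    t_half = log(2), init_guess = 1,
    converged = TRUE, retained = FALSE, reason = "",
    stringsAsFactors = FALSE
  )
  out <- apply_filters(fits)
  expect_identical(out$retained, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(out$reason[2], "error")
  expect_identical(out$reason[3], "fit_quality")
  # adj_r2 = 0.7 exactly is excluded: the threshold is a strict inequality
  expect_identical(out$reason[4], "error;fit_quality")
  expect_identical(out$reason[5], "fit_quality")
})

test_that("too few points or degenerate input yield failure records", {
  ind <- default_ind()
  short <- data.frame(time = c(0, 10, 20), theta_ratio = c(0, 0.1, 0.3))
  f <- fit_site(short, ind, t0 = 1)
  expect_false(f$converged)
  expect_identical(f$reason, "too_few_points")
})

test_that("refinement selects the generating linear map and is idempotent", {
  ind <- default_ind()
  # cohort constructed so that true t_half = 0.8 * delta + 0.05
  deltas <- seq(1, 25, length.out = 12)
  ths <- 0.8 * deltas + 0.05
  occ_list <- stats::setNames(
    lapply(ths, function(th) occ_series_for(th, ind)),
    sprintf("s%02d", seq_along(ths)))
  hill_fits <- data.frame(site_id = names(occ_list),
                          t_half_CC = ind$t_half_ind + deltas)
  first <- apply_filters(do.call(rbind, lapply(seq_along(occ_list), function(i) {
    fit_site(occ_list[[i]], ind, t0 = initial_guess(hill_fits$t_half_CC[i],
                                                    ind$t_half_ind),
             site_id = names(occ_list)[i])
  })))
  ref <- refine_and_refit(first, hill_fits, ind, occ_list)
  expect_identical(ref$map_form, "linear")
  expect_equal(unname(stats::coef(ref$map)["delta"]), 0.8, tolerance = 0.05)
  # noiseless first-pass estimates are already exact: refit reproduces them
  m <- merge(ref$fits, first, by = "site_id", suffixes = c("_refit", "_first"))
  expect_equal(m$t_half_refit, m$t_half_first, tolerance = 1e-6)
})

test_that("refinement passes through with a warning on tiny cohorts", {
  ind <- default_ind()
  occ_list <- stats::setNames(lapply(c(2, 5, 9), function(th)
    occ_series_for(th, ind)), c("a", "b", "c"))
  hill_fits <- data.frame(site_id = c("a", "b", "c"),
                          t_half_CC = c(45, 48, 52))
  first <- apply_filters(do.call(rbind, lapply(c("a", "b", "c"), function(s) {
    fit_site(occ_list[[s]], ind, t0 = 1, site_id = s)
  })))
  expect_warning(out <- refine_and_refit(first, hill_fits, ind, occ_list),
                 "refinement skipped")
  expect_identical(out$fits, first)
  expect_identical(out$map_form, "none")
})
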