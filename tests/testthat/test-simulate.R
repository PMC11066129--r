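test_that("occupancy ratio satisfies both boundary conditions", {
  ind <- default_ind()
  for (th in c(0.5, 5, 20)) {
    kin <- list(k_on_eff = 1, k_off = log(2) / th)
    r <- simulate_occupancy(kin, ind, cc_time_points())
    expect_equal(r[1], 0)
    late <- simulate_occupancy(kin, ind, c(0, 1e4 * ind$t_half_ind))
    expect_equal(late[2], ind$X_P, tolerance = 1e-3)
  }
})

test_that("compiled integrator matches an independent fixed-step RK4", {
  ind <- default_ind()
  kin <- list(k_on_eff = 1, k_off = log(2) / 5)
  r_pkg <- simulate_occupancy(kin, ind, cc_time_points())
  r_ref <- rk4_ratio(1, log(2) / 5, ind, cc_time_points(), step = 0.001)
  expect_equal(r_pkg, r_ref, tolerance = 1e-5)
})

test_that("occupancies stay in [0,1] with theta_A + theta_B <= 1", {
  ind <- default_ind()
  grid <- expand.grid(t_half = c(0.2, 2, 20), kon = c(0.1, 1, 10))
  for (i in seq_len(nrow(grid))) {
    sm <- solve_model(list(k_on_eff = grid$kon[i],
                           k_off = log(2) / grid$t_half[i]),
                      ind, seq(0, 120, by = 5))
    expect_true(all(sm$theta_A >= 0 & sm$theta_A <= 1))
    expect_true(all(sm$theta_B >= 0 & sm$theta_B <= 1))
    expect_true(all(sm$theta_A + sm$theta_B <= 1 + 1e-12))
  }
})

test_that("noiseless ratio series are non-decreasing in time", {
  ind <- default_ind()
  for (th in c(0.3, 3, 15)) {
    r <- simulate_occupancy(list(k_on_eff = 1, k_off = log(2) / th), ind,
                            cc_time_points())
    expect_true(all(diff(r) >= -1e-12))
  }
})

test_that("simulated counts are reproducible under a fixed seed", {
  cfg <- simulation_config(n_sites = 10, noise_cv = 0.15, seed = 42)
  e1 <- simulate_experiment(cfg)
  e2 <- simulate_experiment(cfg)
  expect_identical(e1$counts$ha$counts, e2$counts$ha$counts)
  expect_identical(e1$counts$myc$counts, e2$counts$myc$counts)
  expect_identical(e1$western, e2$western)
})

test_that("zero-noise counts round-trip exactly through normalization", {
  cfg <- simulation_config(n_sites = 15, noise_cv = 0, seed = 5)
  ex <- simulate_experiment(cfg)
  truth_ratio <- ex$occupancy$theta_B / ex$occupancy$theta_A
  truth_ratio[, 1] <- 0
  ha <- western_scale(depth_normalize(ex$counts$ha), cfg$induction)
  myc <- depth_normalize(ex$counts$myc)
  rt <- ratio_table(ha, myc)
  expect_identical(rt$excluded, character(0))
  expect_equal(rt$ratios[rownames(truth_ratio), ], truth_ratio,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("count noise spreads ratios within the expected CV bands", {
  # at CV 0.1 on each tag the HA/Myc ratio noise has CV ~ sqrt(2)*0.1;
  # >= 95% of entries must lie within 3 such bands of the truth
  cv <- 0.1
  band <- 3 * sqrt(2) * cv
  frac_in <- vapply(1:20, function(s) {
    cfg <- simulation_config(n_sites = 100, noise_cv = cv, seed = s)
    ex <- simulate_experiment(cfg)
    truth_ratio <- ex$occupancy$theta_B / ex$occupancy$theta_A
    ha <- western_scale(depth_normalize(ex$counts$ha), cfg$induction)
    myc <- depth_normalize(ex$counts$myc)
    rt <- ratio_table(ha, myc)
    obs <- rt$ratios[, -1]
    tr <- truth_ratio[rt$site_ids, -1]
    mean(abs(obs / tr - 1) <= band)
  }, numeric(1))
  expect_true(all(frac_in >= 0.95))
})

test_that("western simulation hits the Hill curve exactly at zero noise", {
  ind <- default_ind()
  ws <- simulate_western(ind, replicate_cv = 0, n_reps = 1, seed = 1)
  expect_equal(ws$ratio, hill_value(ws$time, 1, 43, 4))
  expect_equal(ws$ratio[ws$time == 0], 0)
  # Hill half-point
  ws2 <- simulate_western(ind, times = c(0, 43), replicate_cv = 0,
                          n_reps = 1, seed = 1)
  expect_equal(ws2$ratio[2], ind$X_P / 2)
})

test_that("site kinetics truth respects its invariants", {
  tr <- site_kinetics_truth(200, seed = 9)
  expect_true(all(tr$k_off > 0 & tr$k_on_eff > 0))
  expect_equal(tr$true_t_half, log(2) / tr$k_off)
  expect_true(all(tr$true_t_half >= 0.2 & tr$true_t_half <= 30))
})

test_that("synthetic annotation records match the assignment module", {
  sim <- simulate_annotation(n_genes = 60, seed = 21)
  asg <- assign_regions(sim$regions, sim$genes)
  kept_expected <- sim$expected$site_id[sim$expected$expected_kept]
  expect_setequal(asg$site_id, kept_expected)
  for (sid in kept_expected) {
    expect_identical(asg$gene_id[asg$site_id == sid],
                     sim$expected$expected_gene[sim$expected$site_id == sid])
  }
})

test_that("nascent counts invert the spike-in scale and track true rates", {
  rates <- c(a = 2, b = 1, c = 0)
  sim <- simulate_nascent(rates, pombe_totals = c(2e6, 4e6), seed = 1,
                          noise_cv = 0)
  norm <- spikein_normalize(sim$counts, sim$pombe_totals)
  expect_equal(norm[, 1], norm[, 2])
  expect_true(all(sim$counts["c", ] == 0))
  set.seed(10)
  rates2 <- exp(stats::rnorm(200, 0, 1))
  sim2 <- simulate_nascent(rates2, pombe_totals = c(1e6, 3e6), seed = 2,
                           noise_cv = 0.05)
  norm2 <- spikein_normalize(sim2$counts, sim2$pombe_totals)
  expect_gt(cor(rowMeans(norm2), rates2, method = "spearman"), 0.95)
})
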