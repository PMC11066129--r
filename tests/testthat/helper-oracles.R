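# Independent oracles and shared fixtures for the test suite.

# Default induction truth used across tests (plateau 1, half-time 43 min,
# Hill coefficient 4).
default_ind <- function() hill_induction(1, 43, 4)

hill_ref <- function(t, xp, th, n) {
  ifelse(t <= 0, 0, xp * (t / th)^n / (1 + (t / th)^n))
}

# Fixed-step classical RK4 integration of the coupled occupancy ODEs,
# written independently of the package's compiled integrator. Returns the
# occupancy ratio theta_B/theta_A at the requested times (which must start
# at 0).
rk4_ratio <- function(kon, koff, ind, times, step = 0.001) {
  deriv <- function(t, y) {
    h <- hill_ref(t, ind$X_P, ind$t_half_ind, ind$n)
    free <- 1 - y[1] - y[2]
    c(kon * free - koff * y[1], kon * h * free - koff * y[2])
  }
  y <- c(kon / (kon + koff), 0)
  out <- matrix(NA_real_, length(times), 2)
  out[1, ] <- y
  t <- 0
  io <- 2
  while (io <= length(times)) {
    hstep <- min(step, times[io] - t)
    k1 <- deriv(t, y)
    k2 <- deriv(t + hstep / 2, y + hstep / 2 * k1)
    k3 <- deriv(t + hstep / 2, y + hstep / 2 * k2)
    k4 <- deriv(t + hstep, y + hstep * k3)
    y <- y + hstep / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + hstep
    if (abs(t - times[io]) < 1e-9) {
      out[io, ] <- y
      io <- io + 1L
    }
  }
  out[, 2] / out[, 1]
}

# Brute-force sweep-line interval merge (bookended intervals merge), the
# oracle for merge_regions(). Operates per chromosome on 0-based half-open
# intervals.
sweep_merge <- function(regions) {
  out <- list()
  for (ch in sort(unique(regions$chrom))) {
    r <- regions[regions$chrom == ch, ]
    r <- r[order(r$start, r$end), ]
    cur_s <- r$start[1]
    cur_e <- r$end[1]
    for (i in seq_len(nrow(r))[-1]) {
      if (r$start[i] <= cur_e) {
        cur_e <- max(cur_e, r$end[i])
      } else {
        out[[length(out) + 1L]] <- data.frame(chrom = ch, start = cur_s,
                                              end = cur_e)
        cur_s <- r$start[i]
        cur_e <- r$end[i]
      }
    }
    out[[length(out) + 1L]] <- data.frame(chrom = ch, start = cur_s,
                                          end = cur_e)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# Multiplicative lognormal noise with mean 1 and the given CV, matching
# the simulator's count noise layer.
ln_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdl^2 / 2, sdl))
}

# Noiseless occupancy-ratio series for a given residence time, as a
# fit_site()-ready data frame.
occ_series_for <- function(t_half, ind = default_ind(),
                           times = cc_time_points(), kon = 1) {
  data.frame(time = times,
             theta_ratio = simulate_occupancy(
               list(k_on_eff = kon, k_off = log(2) / t_half), ind, times))
}
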