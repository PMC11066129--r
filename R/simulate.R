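#' Ground-truth kinetics for a cohort of simulated sites
#'
#' Draws per-site off-rates from a log-uniform residence-time distribution
#' spanning the fast (<1 min), moderate (1--10 min) and slow (>10 min)
#' turnover classes.
#'
#' @param n_sites number of sites
#' @param t_half_range residence-time range in minutes (log-uniform)
#' @param k_on_eff effective on-rate k_a c_A, per minute (recycled)
#' @param seed integer seed
#' @return data frame with `site_id`, `k_on_eff`, `k_off`, `true_t_half`
#' @export
site_kinetics_truth <- function(n_sites, t_half_range = c(0.2, 30),
                                k_on_eff = 1, seed = 1L) {
  stopifnot(n_sites >= 1, all(t_half_range > 0), all(k_on_eff > 0))
  set.seed(seed)
  t_half <- exp(stats::runif(n_sites, log(t_half_range[1]),
                             log(t_half_range[2])))
  data.frame(site_id = sprintf("site_%04d", seq_len(n_sites)),
             k_on_eff = rep_len(k_on_eff, n_sites),
             k_off = log(2) / t_half,
             true_t_half = t_half,
             stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles the study conditions of a simulated competition ChIP experiment:
#' sampling times, induction parameters, cohort size, sequencing depth and
#' count noise.
#'
#' @param time_points sampling times in minutes, strictly increasing,
#'   starting at 0
#' @param induction [hill_induction()] parameters of the competitor
#' @param n_sites number of binding sites
#' @param depth_per_sample nominal in-peak read total per sample
#' @param noise_cv coefficient of variation of multiplicative count noise
#' @param noise_model `"lognormal"` (strictly positive, real-valued) or
#'   `"nb"` (negative binomial, integer counts)
#' @param depth_jitter_cv CV of per-sample depth variation (inverted
#'   exactly by depth normalization)
#' @param seed single integer seed; all randomness flows from it
#' @return object of class `cc_sim_config`
#' @export
simulation_config <- function(time_points = cc_time_points(),
                              induction = hill_induction(1, 43, 4),
                              n_sites = 100,
                              depth_per_sample = 2e6,
                              noise_cv = 0.1,
                              noise_model = c("lognormal", "nb"),
                              depth_jitter_cv = 0.2,
                              seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(time_points) >= 2, time_points[1] == 0,
            !is.unsorted(time_points, strictly = TRUE),
            n_sites >= 1, noise_cv >= 0, depth_jitter_cv >= 0)
  if (depth_per_sample <= 0) stop("`depth_per_sample` must be positive")
  structure(list(time_points = time_points, induction = induction,
                 n_sites = n_sites, depth_per_sample = depth_per_sample,
                 noise_cv = noise_cv, noise_model = noise_model,
                 depth_jitter_cv = depth_jitter_cv, seed = as.integer(seed)),
            class = "cc_sim_config")
}

#' Noiseless occupancy-ratio series for one site
#'
#' Forward-simulates \eqn{\theta_B(t)/\theta_A(t)} for known kinetics under
#' a given induction curve by high-accuracy integration of the turnover
#' ODEs ([solve_model()]).
#'
#' @param kin one-row data frame or list with `k_on_eff` and `k_off`
#' @param ind [hill_induction()] induction parameters
#' @param times evaluation times, minutes
#' @return numeric vector of occupancy ratios at `times`
#' @export
simulate_occupancy <- function(kin, ind, times = cc_time_points()) {
  solve_model(list(k_on_eff = kin[["k_on_eff"]], k_off = kin[["k_off"]]),
              ind, times)$ratio
}

# Full occupancy solution for a cohort: site x time matrices of theta_A and
# theta_B.
simulate_occupancy_matrices <- function(truth, ind, times) {
  n <- nrow(truth)
  th_a <- th_b <- matrix(NA_real_, n, length(times),
                         dimnames = list(truth$site_id, paste0("t", times)))
  for (i in seq_len(n)) {
    sm <- solve_model(list(k_on_eff = truth$k_on_eff[i],
                           k_off = truth$k_off[i]), ind, times)
    th_a[i, ] <- sm$theta_A
    th_b[i, ] <- sm$theta_B
  }
  list(theta_A = th_a, theta_B = th_b)
}

mult_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # mean 1
}

#' Simulate HA and Myc count tables from occupancy truth
#'
#' Myc expected counts are proportional to \eqn{\theta_A} and sample depth;
#' HA expected counts are proportional to \eqn{\theta_B / h(t)} -- the
#' induction-driven global scale is divided out, emulating the fact that
#' per-library sequencing depth carries no absolute-abundance information,
#' so the normalize module must restore it from the western curve. The
#' `t = 0` HA column is exactly zero. Per-sample depth jitter multiplies
#' both the counts and the recorded `library_sizes`, so depth normalization
#' inverts it exactly. Multiplicative noise at `noise_cv` is applied on top
#' (lognormal with mean 1, or negative binomial when
#' `noise_model = "nb"`).
#'
#' @param occ list with site x time matrices `theta_A`, `theta_B` (from
#'   the internal occupancy solver; see [simulate_experiment()])
#' @param cfg [simulation_config()]
#' @return list with two count-matrix objects `ha` and `myc`
#'   (see [count_matrix()])
#' @export
simulate_counts <- function(occ, cfg) {
  stopifnot(inherits(cfg, "cc_sim_config"))
  times <- cfg$time_points
  ind <- cfg$induction
  th_a <- occ$theta_A
  th_b <- occ$theta_B
  stopifnot(ncol(th_a) == length(times), nrow(th_a) == nrow(th_b))
  n_sites <- nrow(th_a)
  set.seed(cfg$seed)

  h <- hill_value(times, ind$X_P, ind$t_half_ind, ind$n)
  x_ha <- th_b
  for (j in seq_along(times)) {
    x_ha[, j] <- if (h[j] > 0) th_b[, j] / h[j] else 0
  }
  x_myc <- th_a

  depth_scale <- function() {
    cfg$depth_per_sample * mult_noise(length(times), cfg$depth_jitter_cv)
  }
  lam_ha <- depth_scale()
  lam_myc <- depth_scale()

  expected <- function(x, lam) sweep(x, 2, lam / n_sites, `*`)
  noisify <- function(mu) {
    if (cfg$noise_cv <= 0) return(mu)
    if (cfg$noise_model == "lognormal") {
      mu * matrix(mult_noise(length(mu), cfg$noise_cv), nrow(mu), ncol(mu))
    } else {
      size <- 1 / cfg$noise_cv^2
      out <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                   size = size), nrow(mu), ncol(mu))
      dimnames(out) <- dimnames(mu)
      out
    }
  }
  counts_ha <- noisify(expected(x_ha, lam_ha))
  counts_myc <- noisify(expected(x_myc, lam_myc))
  list(
    ha = count_matrix(counts_ha, times, tag = "HA", library_sizes = lam_ha),
    myc = count_matrix(counts_myc, times, tag = "Myc", library_sizes = lam_myc)
  )
}

#' Simulate a western-blot induction series
#'
#' Replicate measurements of the relative competitor level
#' \eqn{c_B(t)/c_A} with multiplicative lognormal noise. The value at
#' `t = 0` is exactly zero (no competitor before galactose).
#'
#' @param ind [hill_induction()] truth
#' @param times measurement times, minutes
#' @param replicate_cv CV of multiplicative measurement noise
#' @param n_reps number of biological replicates (>= 1)
#' @param seed integer seed
#' @return data frame with `time`, `replicate`, `ratio`
#' @export
simulate_western <- function(ind, times = cc_time_points(),
                             replicate_cv = 0.05, n_reps = 2, seed = 1L) {
  stopifnot(n_reps >= 1, replicate_cv >= 0)
  set.seed(seed)
  truth <- hill_value(times, ind$X_P, ind$t_half_ind, ind$n)
  out <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
    data.frame(time = times, replicate = r,
               ratio = truth * mult_noise(length(times), replicate_cv))
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a gene annotation and peak regions with known assignments
#'
#' Places genes on a synthetic chromosome far enough apart that each
#' region's nearest TSS is unambiguous, then emits one or two peak regions
#' per sampled gene covering the cases the assignment rules must handle:
#' regions inside the -250..+100 bp TSS window (kept), regions outside it
#' (dropped), regions at tRNA genes (dropped), and gene pairs with two
#' in-window regions (only the closer kept). The expected outcome of every
#' region is recorded for testing.
#'
#' @param n_genes number of genes (>= 1)
#' @param genome_length chromosome length in bp (regions are 0-based
#'   half-open BED-style intervals)
#' @param seed integer seed
#' @param trna_fraction fraction of genes flagged as tRNA
#' @return list with `genes` (gene_id, chrom, tss, strand, biotype),
#'   `regions` (chrom, start, end, site_id) and `expected` (site_id,
#'   expected_kept, expected_gene)
#' @export
simulate_annotation <- function(n_genes = 50, genome_length = NULL,
                                seed = 1L, trna_fraction = 0.1) {
  stopifnot(n_genes >= 1)
  spacing <- 5000
  if (is.null(genome_length)) genome_length <- (n_genes + 2) * spacing
  stopifnot(genome_length >= (n_genes + 1) * spacing)
  set.seed(seed)
  tss <- spacing * seq_len(n_genes) + sample(-500:500, n_genes, replace = TRUE)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  biotype <- ifelse(stats::runif(n_genes) < trna_fraction, "tRNA",
                    "protein_coding")
  genes <- data.frame(gene_id = sprintf("gene_%03d", seq_len(n_genes)),
                      chrom = "chrS", tss = tss, strand = strand,
                      biotype = biotype, stringsAsFactors = FALSE)

  half_width <- 25L
  region_at <- function(gene_row, signed_dist) {
    sgn <- if (gene_row$strand == "+") 1 else -1
    mid <- gene_row$tss + sgn * signed_dist
    data.frame(chrom = "chrS", start = mid - half_width, end = mid + half_width)
  }
  scenarios <- sample(c("in_window", "outside", "two_regions"), n_genes,
                      replace = TRUE, prob = c(0.6, 0.2, 0.2))
  regions <- list(); expected <- list(); k <- 0L
  add_region <- function(gene_row, dist, kept, keeper_gene) {
    k <<- k + 1L
    r <- region_at(gene_row, dist)
    r$site_id <- sprintf("peak_%03d", k)
    regions[[k]] <<- r
    expected[[k]] <<- data.frame(site_id = r$site_id, expected_kept = kept,
                                 expected_gene = keeper_gene,
                                 stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_genes)) {
    g <- genes[i, ]
    is_trna <- g$biotype == "tRNA"
    if (scenarios[i] == "in_window") {
      d <- sample(-250:100, 1)
      add_region(g, d, kept = !is_trna,
                 keeper_gene = if (is_trna) NA_character_ else g$gene_id)
    } else if (scenarios[i] == "outside") {
      d <- sample(c(-(300:450), 150:400), 1)
      add_region(g, d, kept = FALSE, keeper_gene = NA_character_)
    } else {
      d_near <- sample(-100:50, 1)
      d_far <- sample(c(-(200:250), 80:100), 1)
      if (abs(d_far) <= abs(d_near)) d_far <- if (d_near < 0) -250 else 100
      add_region(g, d_near, kept = !is_trna,
                 keeper_gene = if (is_trna) NA_character_ else g$gene_id)
      add_region(g, d_far, kept = FALSE, keeper_gene = NA_character_)
    }
  }
  list(genes = genes, regions = do.call(rbind, regions),
       expected = do.call(rbind, expected))
}

#' Simulate spike-in normalized nascent-RNA count tables
#'
#' Gene counts proportional to the true synthesis rate and a per-sample
#' scale derived from the S. pombe spike-in total, with multiplicative
#' noise; dividing raw counts by `pombe_total / 2e6` recovers rate-
#' proportional values.
#'
#' @param rates named numeric vector of true synthesis rates (mRNA per cell
#'   per minute, >= 0); names are gene ids
#' @param pombe_totals per-sample S. pombe-mapped read totals
#' @param seed integer seed
#' @param noise_cv CV of multiplicative count noise
#' @param counts_per_rate_unit expected counts per unit rate at spike-in
#'   factor 1
#' @return list with `counts` (gene x sample matrix) and `pombe_totals`
#' @export
simulate_nascent <- function(rates, pombe_totals, seed = 1L, noise_cv = 0.05,
                             counts_per_rate_unit = 1e4) {
  stopifnot(all(rates >= 0), all(pombe_totals > 0))
  if (is.null(names(rates))) {
    names(rates) <- sprintf("gene_%04d", seq_along(rates))
  }
  set.seed(seed)
  n_s <- length(pombe_totals)
  factors <- pombe_totals / 2e6
  mu <- outer(rates * counts_per_rate_unit, factors)
  noise <- matrix(mult_noise(length(mu), noise_cv), nrow(mu), ncol(mu))
  counts <- mu * noise
  colnames(counts) <- sprintf("sample_%d", seq_len(n_s))
  list(counts = counts, pombe_totals = pombe_totals)
}

#' Simulate a complete competition ChIP experiment
#'
#' Draws ground-truth kinetics, solves the occupancy ODEs for every site,
#' and emits HA/Myc count tables plus a western-blot series -- everything
#' the estimation pipeline consumes, with the truth attached.
#'
#' @param cfg [simulation_config()]
#' @param truth optional data frame of site kinetics (defaults to
#'   [site_kinetics_truth()] under `cfg$seed`)
#' @param western_cv,western_reps western-blot noise CV and replicate count
#' @return list with `truth`, `occupancy` (list of `theta_A`, `theta_B`
#'   matrices), `counts` (list `ha`, `myc`), `western`, `config`
#' @export
simulate_experiment <- function(cfg = simulation_config(), truth = NULL,
                                western_cv = 0.05, western_reps = 2) {
  if (is.null(truth)) {
    truth <- site_kinetics_truth(cfg$n_sites, seed = cfg$seed)
  }
  stopifnot(nrow(truth) == cfg$n_sites)
  occ <- simulate_occupancy_matrices(truth, cfg$induction, cfg$time_points)
  counts <- simulate_counts(occ, cfg)
  western <- simulate_western(cfg$induction, cfg$time_points,
                              replicate_cv = western_cv,
                              n_reps = western_reps, seed = cfg$seed + 1L)
  list(truth = truth, occupancy = occ, counts = counts, western = western,
       config = cfg)
}
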