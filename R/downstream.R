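#' Spike-in normalization factors
#'
#' Per-sample factors from S. pombe spike-in totals:
#' `factor = pombe_total / 2e6`; normalized counts are raw counts divided
#' by the factor, putting all samples on a common absolute scale.
#'
#' @param pombe_totals per-sample S. pombe-mapped read totals (> 0)
#' @return numeric vector of factors
#' @examples
#' spikein_factors(c(2e6, 4e6))   # 1, 2
#' @export
spikein_factors <- function(pombe_totals) {
  if (any(!is.finite(pombe_totals)) || any(pombe_totals <= 0)) {
    stop("spike-in totals must be positive")
  }
  pombe_totals / 2e6
}

#' Apply spike-in normalization to a count table
#'
#' @param counts gene x sample matrix of raw counts
#' @param pombe_totals per-sample S. pombe totals
#' @return matrix of normalized counts
#' @export
spikein_normalize <- function(counts, pombe_totals) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == length(pombe_totals))
  sweep(counts, 2, spikein_factors(pombe_totals), `/`)
}

#' Filter genes with too many zero counts
#'
#' Drops genes with zero counts in strictly more than half of the samples.
#'
#' @param counts gene x sample matrix
#' @return filtered matrix
#' @export
filter_low_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 1) stop("need at least one sample")
  n_zero <- rowSums(counts == 0)
  counts[n_zero <= ncol(counts) / 2, , drop = FALSE]
}

#' Convert per-cell-cycle synthesis rates to per-minute rates
#'
#' Divides rates expressed per cell cycle by the cell-cycle length of
#' 150 minutes, yielding mRNA per cell per minute.
#'
#' @param cycle_rate synthesis rate per cell per cycle (>= 0)
#' @param cycle_length_min cell-cycle length, minutes
#' @return rate in mRNA per cell per minute
#' @examples
#' per_minute_rate(300)   # 2
#' @export
per_minute_rate <- function(cycle_rate, cycle_length_min = 150) {
  if (any(cycle_rate < 0, na.rm = TRUE)) stop("rates must be >= 0")
  cycle_rate / cycle_length_min
}

#' Transcription efficiency
#'
#' TE = synthesis rate x residence time: the expected number of mRNA
#' molecules synthesized per binding event of the factor. Only numeric
#' (fitted) residence times qualify; fast-class plotting stand-ins must be
#' excluded by the caller. A log2 column is included for reporting
#' (values below zero mean multiple binding events per mRNA).
#'
#' @param t_half residence times, minutes
#' @param rate synthesis rates, mRNA per cell per minute
#' @param gene_id optional identifiers
#' @return data frame with `gene_id`, `t_half`, `rate`, `TE`, `log2_TE`
#' @examples
#' transcription_efficiency(5, 0.2)    # TE = 1
#' @export
transcription_efficiency <- function(t_half, rate, gene_id = NULL) {
  stopifnot(length(t_half) == length(rate))
  if (any(rate < 0, na.rm = TRUE)) stop("rates must be >= 0")
  te <- rate * t_half
  data.frame(gene_id = if (is.null(gene_id)) seq_along(te) else gene_id,
             t_half = t_half, rate = rate, TE = te,
             log2_TE = ifelse(te > 0, log2(te), NA_real_),
             stringsAsFactors = FALSE)
}

#' Rank-based synthesis-rate quartiles
#'
#' Splits genes into four equal-size groups by synthesis rate (1 = lowest).
#' Ties are resolved by stable input order, so group sizes differ by at
#' most one and assignment is deterministic.
#'
#' @param rates numeric vector of synthesis rates (>= 4 values)
#' @return integer vector of quartile labels in 1..4
#' @export
synthesis_quartiles <- function(rates) {
  n <- length(rates)
  if (n < 4) stop("need >= 4 genes for quartiles")
  r <- rank(rates, ties.method = "first")
  as.integer(floor((r - 1) * 4 / n) + 1L)
}

#' Correlation and linear-model summary of kinetics vs synthesis
#'
#' Pearson correlations among per-factor residence-time columns and
#' between each factor's residence times and the synthesis rate
#' (pairwise-complete), Spearman rank correlation for rate--rate
#' comparisons, and ordinary least-squares coefficients for
#' `rate ~ t_half` models fitted per factor and jointly. Fast-class
#' plotting stand-ins must not be passed in.
#'
#' @param t_half_table data frame or matrix, genes as rows, one column of
#'   residence times per factor
#' @param rates synthesis-rate vector aligned to the rows
#' @param rates2 optional second rate vector for a rate--rate Spearman
#'   comparison
#' @return list with `pearson_rt` (factor x factor matrix),
#'   `pearson_rt_rate` (named vector), `spearman_rate_rate` (scalar or
#'   `NA`), `lm_single` (per-factor slope/intercept table), `lm_joint`
#'   (joint model coefficients)
#' @export
kinetics_correlations <- function(t_half_table, rates, rates2 = NULL) {
  rt <- as.data.frame(t_half_table)
  stopifnot(nrow(rt) == length(rates))
  complete_pairs <- colSums(!is.na(rt) & !is.na(rates))
  if (all(complete_pairs < 3)) stop("fewer than 3 paired observations")
  pearson_rt <- stats::cor(rt, use = "pairwise.complete.obs",
                           method = "pearson")
  pearson_rt_rate <- vapply(rt, function(x) {
    stats::cor(x, rates, use = "pairwise.complete.obs", method = "pearson")
  }, numeric(1))
  spearman_rr <- if (!is.null(rates2)) {
    stats::cor(rates, rates2, use = "pairwise.complete.obs",
               method = "spearman")
  } else {
    NA_real_
  }
  lm_single <- do.call(rbind, lapply(names(rt), function(f) {
    d <- data.frame(rate = rates, t_half = rt[[f]])
    d <- d[stats::complete.cases(d), ]
    if (nrow(d) < 3) {
      return(data.frame(factor = f, intercept = NA_real_, slope = NA_real_))
    }
    co <- stats::coef(stats::lm(rate ~ t_half, data = d))
    data.frame(factor = f, intercept = unname(co[1]), slope = unname(co[2]),
               stringsAsFactors = FALSE)
  }))
  joint_df <- data.frame(rate = rates, rt)
  joint_df <- joint_df[stats::complete.cases(joint_df), ]
  lm_joint <- if (nrow(joint_df) >= ncol(rt) + 2) {
    stats::coef(stats::lm(rate ~ ., data = joint_df))
  } else {
    NULL
  }
  list(pearson_rt = pearson_rt, pearson_rt_rate = pearson_rt_rate,
       spearman_rate_rate = spearman_rr, lm_single = lm_single,
       lm_joint = lm_joint)
}
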