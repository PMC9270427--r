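# Mutation-calling sensitivity from coverage and clonality, and burden
# correction. Sensitivity is the probability that a clonal mutation yields
# at least `min_alt_reads` variant reads when depth is Poisson around the
# sample's mean coverage and variant reads are binomial at the sample's
# median VAF.

#' Monte-Carlo sensitivity estimate
#'
#' Draws per-site depths from Poisson(`mean_coverage`) and variant reads
#' from Binomial(depth, `median_vaf`); sensitivity is the fraction of draws
#' with at least `min_alt_reads` variant reads.
#'
#' @param mean_coverage Mean sequencing depth (> 0).
#' @param median_vaf Sample median VAF in (0, 1].
#' @param min_alt_reads Caller's minimum variant-read requirement
#'   (default 4).
#' @param n_sims Number of simulated sites.
#' @param seed Integer seed.
#' @param truncate_depth If `TRUE`, condition the Poisson depth on being
#'   >= 1 (zero-truncated depth support); default `FALSE`.
#' @return List of class `sensitivity_estimate` with fields sensitivity,
#'   se (Monte-Carlo SE), mean_coverage, median_vaf, min_alt_reads, method.
#' @export
estimate_sensitivity_mc <- function(mean_coverage, median_vaf,
                                    min_alt_reads = 4, n_sims = 1e5,
                                    seed = 1L, truncate_depth = FALSE) {
  check_sens_args(mean_coverage, median_vaf)
  set.seed(seed)
  depth <- stats::rpois(n_sims, mean_coverage)
  if (truncate_depth) {
    while (any(depth == 0)) {
      z <- depth == 0
      depth[z] <- stats::rpois(sum(z), mean_coverage)
    }
  }
  alt <- stats::rbinom(n_sims, depth, median_vaf)
  s <- mean(alt >= min_alt_reads)
  structure(list(sensitivity = s, se = sqrt(s * (1 - s) / n_sims),
                 mean_coverage = mean_coverage, median_vaf = median_vaf,
                 min_alt_reads = min_alt_reads, method = "monte-carlo"),
            class = "sensitivity_estimate")
}

#' Exact sensitivity by enumeration
#'
#' Computes `sum_d Poisson(d; lambda) * P(Binomial(d, vaf) >= k)`,
#' truncating the depth support at the upper 1 - 1e-12 Poisson quantile.
#'
#' @inheritParams estimate_sensitivity_mc
#' @return Sensitivity in (0, 1].
#' @export
exact_sensitivity <- function(mean_coverage, median_vaf, min_alt_reads = 4,
                              truncate_depth = FALSE) {
  check_sens_args(mean_coverage, median_vaf)
  d_max <- stats::qpois(1 - 1e-12, mean_coverage)
  d <- 0:d_max
  w <- stats::dpois(d, mean_coverage)
  if (truncate_depth) {
    w[d == 0] <- 0
    w <- w / sum(w)
  }
  p_call <- stats::pbinom(min_alt_reads - 1, d, median_vaf, lower.tail = FALSE)
  sum(w * p_call)
}

check_sens_args <- function(mean_coverage, median_vaf) {
  if (mean_coverage <= 0) stop("degenerate input: mean_coverage must be > 0", call. = FALSE)
  if (median_vaf <= 0 || median_vaf > 1)
    stop("degenerate input: median_vaf must be in (0, 1]", call. = FALSE)
}

#' Correct a raw burden for calling sensitivity
#'
#' @param raw_burden Raw mutation count.
#' @param sensitivity Sensitivity in (0, 1].
#' @return Corrected burden `raw_burden / sensitivity` (always >= raw).
#' @export
correct_burden <- function(raw_burden, sensitivity) {
  if (any(sensitivity <= 0) || any(sensitivity > 1))
    stop("sensitivity must be in (0, 1]", call. = FALSE)
  raw_burden / sensitivity
}

#' Per-sample sensitivity table
#'
#' Convenience wrapper computing exact sensitivity and corrected burdens
#' for a metadata table.
#'
#' @param metadata data.frame with columns sample, mean_coverage,
#'   median_vaf.
#' @param raw_burden Named (by sample) or positional raw burden vector.
#' @param min_alt_reads Caller's minimum variant-read requirement.
#' @return data.frame sample, mean_coverage, median_vaf, sensitivity,
#'   raw_burden, corrected_burden.
#' @export
sensitivity_table <- function(metadata, raw_burden, min_alt_reads = 4) {
  sens <- mapply(exact_sensitivity, metadata$mean_coverage,
                 metadata$median_vaf, MoreArgs = list(min_alt_reads = min_alt_reads))
  if (!is.null(names(raw_burden))) raw_burden <- raw_burden[metadata$sample]
  data.frame(sample = metadata$sample,
             mean_coverage = metadata$mean_coverage,
             median_vaf = metadata$median_vaf,
             sensitivity = sens,
             raw_burden = as.numeric(raw_burden),
             corrected_burden = as.numeric(raw_burden) / sens,
             stringsAsFactors = FALSE)
}
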