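# Germline/somatic classification from multi-sample pileups: artefact
# threshold pass-through, aggregate exact binomial germline test, and
# beta-binomial overdispersion (rho) across samples.

#' Apply artefact annotation thresholds
#'
#' Removes variants failing the low-input library artefact thresholds: the
#' median alignment score of mutant reads must be at least `min_asmd` and
#' the clipped mutant-read fraction must not exceed `max_clipped`. Variants
#' removed here are recorded so classification can report them as
#' artefact-filtered. Pileups without annotation columns pass through
#' unchanged with a warning.
#'
#' @param pileup A [pileup_matrix()].
#' @param min_asmd Minimum median alignment score (default 140).
#' @param max_clipped Maximum clipped fraction (default 0, i.e. none).
#' @return The filtered pileup, with attribute `artefact_filtered` holding
#'   the removed variant ids.
#' @export
apply_artefact_thresholds <- function(pileup, min_asmd = 140, max_clipped = 0) {
  v <- pileup$variants
  if (!all(c("asmd", "clpm") %in% names(v))) {
    warning("pileup has no artefact annotations; passing through unfiltered")
    attr(pileup, "artefact_filtered") <- character(0)
    return(pileup)
  }
  keep <- v$asmd >= min_asmd & v$clpm <= max_clipped
  out <- pileup[keep, ]
  attr(out, "artefact_filtered") <- variant_ids(v)[!keep]
  out
}

#' Aggregate exact binomial germline test
#'
#' One-sided exact binomial p-value of observing at most `nv_total` variant
#' reads out of `nr_total` aggregated across all samples of a patient,
#' under the germline expectation `expected_vaf`. Small p-values indicate a
#' variant-read deficit incompatible with a germline variant.
#'
#' @param nv_total,nr_total Aggregate variant and total read counts
#'   (vectorised).
#' @param expected_vaf Expected germline VAF (0.5 for autosomes).
#' @return p-values; `NA` (untestable) where `nr_total == 0`.
#' @export
aggregate_binomial_test <- function(nv_total, nr_total, expected_vaf = 0.5) {
  p <- stats::pbinom(nv_total, nr_total, expected_vaf)
  p[nr_total == 0] <- NA_real_
  p
}

dbetabinom_log <- function(x, size, mu, rho) {
  # beta-binomial with mean mu and overdispersion rho (shearwater
  # parameterisation): alpha = mu(1-rho)/rho, beta = (1-mu)(1-rho)/rho
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  lchoose(size, x) + lbeta(x + a, size - x + b) - lbeta(a, b)
}

#' Beta-binomial overdispersion of per-sample VAFs
#'
#' Maximum-likelihood overdispersion (rho) of a beta-binomial whose mean is
#' fixed at the pooled VAF, maximised over a log-spaced grid. High rho means
#' variant reads are concentrated in a subset of samples (somatic); low rho
#' means the VAF is homogeneous across samples (germline-like).
#'
#' @param nv,nr Per-sample variant and total read counts for one variant.
#' @param grid Rho grid; default 100 log-spaced points in `[1e-6, 0.89]`.
#' @return Maximum-likelihood rho, or `NA` if fewer than two samples have
#'   reads (untestable).
#' @export
estimate_rho <- function(nv, nr, grid = rho_grid()) {
  keep <- nr > 0
  if (sum(keep) < 2) return(NA_real_)
  nv <- nv[keep]; nr <- nr[keep]
  mu <- sum(nv) / sum(nr)
  if (mu <= 0) return(min(grid))
  if (mu >= 1) mu <- 1 - 1e-9
  ll <- vapply(grid, function(r) sum(dbetabinom_log(nv, nr, mu, r)), numeric(1))
  grid[which.max(ll)]
}

#' @rdname estimate_rho
#' @export
rho_grid <- function() exp(seq(log(1e-6), log(0.89), length.out = 100))

#' Classify pileup variants as germline, somatic or artefact-filtered
#'
#' Per patient, read counts are aggregated across samples and the exact
#' binomial germline test applied; variants consistent with the germline
#' expectation are germline. Variants rejected by the binomial test are
#' somatic only if their per-sample VAF overdispersion exceeds
#' `rho_threshold`; rejected variants with homogeneous sub-germline VAFs
#' are artefact-filtered.
#'
#' @param pileup A [pileup_matrix()] (after [apply_artefact_thresholds()]).
#' @param patient_of Named character vector mapping sample -> patient.
#' @param binomial_alpha Significance cut-off of the germline test
#'   (default 1e-5).
#' @param rho_threshold Overdispersion threshold for genuine somatic
#'   variants (default 0.1).
#' @param expected_vaf Germline VAF expectation (default 0.5).
#' @param artefact_ids Variant ids removed upstream, reported with class
#'   `artefact-filtered` (taken from the pileup's `artefact_filtered`
#'   attribute if present).
#' @return data.frame with one row per variant: variant, patient,
#'   aggregate_nv, aggregate_nr, binom_p, rho, class.
#' @export
classify_variants <- function(pileup, patient_of, binomial_alpha = 1e-5,
                              rho_threshold = 0.1, expected_vaf = 0.5,
                              artefact_ids = attr(pileup, "artefact_filtered")) {
  stopifnot(all(pileup$samples %in% names(patient_of)))
  patients <- unique(patient_of[pileup$samples])
  ids <- variant_ids(pileup$variants)

  res <- lapply(patients, function(pt) {
    smp <- pileup$samples[patient_of[pileup$samples] == pt]
    NV <- pileup$NV[, smp, drop = FALSE]
    NR <- pileup$NR[, smp, drop = FALSE]
    agg_nv <- rowSums(NV); agg_nr <- rowSums(NR)
    # restrict to variants seen in this patient's samples
    seen <- agg_nv > 0
    if (!any(seen)) return(NULL)
    p <- aggregate_binomial_test(agg_nv[seen], agg_nr[seen], expected_vaf)
    rho <- vapply(which(seen), function(i) estimate_rho(NV[i, ], NR[i, ]),
                  numeric(1))
    cls <- ifelse(is.na(p), "artefact-filtered",
           ifelse(p >= binomial_alpha, "germline",
           ifelse(!is.na(rho) & rho > rho_threshold, "somatic",
                  "artefact-filtered")))
    data.frame(variant = ids[seen], patient = pt,
               aggregate_nv = agg_nv[seen], aggregate_nr = agg_nr[seen],
               binom_p = p, rho = rho, class = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (length(artefact_ids)) {
    out <- rbind(out, data.frame(variant = artefact_ids, patient = NA_character_,
                                 aggregate_nv = NA_real_, aggregate_nr = NA_real_,
                                 binom_p = NA_real_, rho = NA_real_,
                                 class = "artefact-filtered",
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Write a classification table to TSV
#'
#' @param classification Output of [classify_variants()].
#' @param path Output path.
#' @export
write_classification_tsv <- function(classification, path) {
  utils::write.table(classification, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
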