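# Rule-based candidate cancer-driver classification: truncating mutations
# in recessively acting genes, known activating hotspots in dominant (and
# recessive) genes, and database-flagged likely-oncogenic mutations, within
# a tissue-appropriate gene list.

CONSEQUENCES <- c("nonsense", "essential-splice", "splice-region",
                  "frameshift", "missense", "synonymous", "inframe", "other")
TRUNCATING <- c("nonsense", "essential-splice", "splice-region", "frameshift")

#' Classify one annotated mutation as a candidate driver
#'
#' Rules, applied only to genes in the tissue-appropriate list: (1)
#' truncating consequences (nonsense, essential splice, splice region,
#' frameshift) in recessively acting genes; (2) known activating hotspot
#' matches in dominant or recessive genes; (3) mutations flagged likely
#' oncogenic. Genes of intermediate role satisfy both the recessive and
#' dominant rules.
#'
#' @param gene Gene symbol.
#' @param consequence One of the fixed consequence vocabulary
#'   (nonsense, essential-splice, splice-region, frameshift, missense,
#'   synonymous, inframe, other).
#' @param protein_change Protein change string (e.g. `"G12D"`).
#' @param roles data.frame with columns `gene`, `role` (dominant /
#'   recessive / intermediate); genes absent from it are not drivers.
#' @param hotspots data.frame with columns `gene`, `protein_change` of
#'   known activating hotspots.
#' @param likely_oncogenic Optional data.frame with columns `gene`,
#'   `protein_change` of database-flagged likely-oncogenic mutations.
#' @return List of class `driver_call`: is_driver, reason (one of
#'   truncating-in-recessive, hotspot, likely-oncogenic, none).
#' @export
classify_driver <- function(gene, consequence, protein_change, roles,
                            hotspots = NULL, likely_oncogenic = NULL) {
  if (!consequence %in% CONSEQUENCES)
    stop("unknown consequence label: ", consequence, call. = FALSE)
  role <- roles$role[roles$gene == gene]
  reason <- "none"
  if (length(role) == 1L) {
    is_hotspot <- !is.null(hotspots) &&
      any(hotspots$gene == gene & hotspots$protein_change == protein_change)
    is_lo <- !is.null(likely_oncogenic) &&
      any(likely_oncogenic$gene == gene &
            likely_oncogenic$protein_change == protein_change)
    if (consequence %in% TRUNCATING && role %in% c("recessive", "intermediate")) {
      reason <- "truncating-in-recessive"
    } else if (is_hotspot) {
      reason <- "hotspot"
    } else if (is_lo) {
      reason <- "likely-oncogenic"
    }
  }
  structure(list(gene = gene, consequence = consequence,
                 protein_change = protein_change,
                 is_driver = reason != "none", reason = reason),
            class = "driver_call")
}

#' Classify a table of annotated mutations
#'
#' @param mutations data.frame with columns `gene`, `consequence`,
#'   `protein_change`, `sample`.
#' @inheritParams classify_driver
#' @return The input with `is_driver` and `reason` columns appended.
#' @export
classify_drivers <- function(mutations, roles, hotspots = NULL,
                             likely_oncogenic = NULL) {
  calls <- Map(classify_driver, mutations$gene, mutations$consequence,
               mutations$protein_change,
               MoreArgs = list(roles = roles, hotspots = hotspots,
                               likely_oncogenic = likely_oncogenic))
  mutations$is_driver <- vapply(calls, `[[`, logical(1), "is_driver")
  mutations$reason <- vapply(calls, `[[`, character(1), "reason")
  mutations
}

#' Fraction of crypts carrying at least one driver
#'
#' A crypt counts once however many drivers it carries. The percentage is
#' rounded to an integer for reporting; the raw fraction is retained.
#'
#' @param calls data.frame with columns `sample` and `is_driver`, or a
#'   vector of driver-bearing sample ids via `driver_samples`.
#' @param all_samples Character vector of every crypt in the denominator.
#' @param driver_samples Alternative to `calls`: sample ids with a driver.
#' @return List: n_with_driver, n_crypts, fraction, percent (integer).
#' @export
driver_fraction <- function(calls = NULL, all_samples,
                            driver_samples = NULL) {
  if (length(all_samples) == 0) stop("zero crypts", call. = FALSE)
  if (is.null(driver_samples)) {
    driver_samples <- unique(calls$sample[calls$is_driver])
  }
  n_with <- length(intersect(unique(driver_samples), all_samples))
  frac <- n_with / length(all_samples)
  list(n_with_driver = n_with, n_crypts = length(all_samples),
       fraction = frac, percent = round(100 * frac))
}

#' Per-consequence coding mutation-rate fold changes versus a control
#'
#' Fits a through-origin mixed-effects rate per consequence class
#' (reusing [fit_burden_lme()] with a single pooled genotype) and divides
#' by the control rate for that class.
#'
#' @param coding data.frame with columns `sample`, `patient`, `age`,
#'   `consequence`, `count` (mutations of that consequence in that
#'   sample).
#' @param control_rates Named numeric vector: control mutations/year per
#'   consequence class.
#' @return data.frame consequence, rate, control_rate, fold (NA where the
#'   control class is missing or zero).
#' @export
coding_rate_comparison <- function(coding, control_rates) {
  classes <- unique(coding$consequence)
  res <- lapply(classes, function(cl) {
    sub <- coding[coding$consequence == cl, ]
    obs <- data.frame(burden = sub$count, age = sub$age,
                      genotype = "cohort", patient = sub$patient)
    rate <- tryCatch(fit_burden_lme(obs)$rates$slope[1], error = function(e) NA_real_)
    ctrl <- unname(control_rates[cl])
    fold <- if (is.null(ctrl) || length(ctrl) == 0 || is.na(ctrl) || ctrl == 0)
      NA_real_ else rate / ctrl
    data.frame(consequence = cl, rate = rate,
               control_rate = if (length(ctrl)) ctrl else NA_real_,
               fold = fold, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Read a gene-role table
#'
#' @param path TSV with columns `gene`, `role`.
#' @return data.frame; duplicate gene entries are an error.
#' @export
read_gene_roles <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "role") %in% names(df)))
  if (anyDuplicated(df$gene)) stop("duplicate gene roles", call. = FALSE)
  df
}
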