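# End-to-end orchestration: simulate -> filter -> sensitivity -> trees ->
# signatures -> burden modelling, with every stage parameter and seed
# recorded in a run report. Configuration round-trips through YAML.

#' Default pipeline configuration
#'
#' Every published filtering threshold appears here explicitly:
#' `min_asmd = 140` and `max_clipped = 0` (alignment-artefact thresholds),
#' `rho_threshold = 0.1` (beta-binomial overdispersion floor for genuine
#' somatic variants), `min_alt_reads = 4` (caller requirement used for
#' sensitivity), `max_per_branch = 2500` and `min_branch = 100` (branch
#' catalogue subsampling window) and `min_exposure = 0.10` (signature
#' refit pruning floor).
#'
#' @param seed Master seed; stage seeds derive from it.
#' @return Named list of stage parameters.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    cohort = list(
      patients = list(
        list(id = "PT1", genotype = "MUTYH_biallelic", age = 50, n_crypts = 4,
             rate_per_year = 90, rate_sd_patient = 10,
             signature_mixture = list(SBS18like = 0.45, SBS36like = 0.35,
                                      SBS1like = 0.05, SBS5like = 0.15)),
        list(id = "PT2", genotype = "MUTYH_biallelic", age = 60, n_crypts = 4,
             rate_per_year = 90, rate_sd_patient = 10,
             signature_mixture = list(SBS18like = 0.45, SBS36like = 0.35,
                                      SBS1like = 0.05, SBS5like = 0.15))),
      mean_coverage = 28, clonality_vaf = 0.5, n_germline = 60,
      n_embryonic_shared = 4, indel_rate_per_year = 2.1,
      private_fraction = 0.9),
    filtering = list(min_asmd = 140, max_clipped = 0, binomial_alpha = 1e-5,
                     rho_threshold = 0.1, expected_vaf = 0.5),
    sensitivity = list(min_alt_reads = 4),
    tree = list(min_nv = 3, min_vaf = 0.2, clonality_vaf = 0.5,
                error_rate = 0.01),
    signatures = list(k = 2, restarts = 3, max_per_branch = 2500,
                      min_branch = 100, min_exposure = 0.10,
                      acceptance_cosine = 0.95)
  )
}

#' Write / read a run configuration as YAML
#'
#' @param config Run configuration list.
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config error: no such file: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

config_to_cohort <- function(cfg) {
  patients <- lapply(cfg$cohort$patients, function(p) {
    patient_spec(p$id, p$genotype, p$age, p$n_crypts, p$rate_per_year,
                 p$rate_sd_patient %||% 0,
                 unlist(p$signature_mixture))
  })
  cohort_config(patients,
                mean_coverage = cfg$cohort$mean_coverage,
                clonality_vaf = cfg$cohort$clonality_vaf,
                n_germline = cfg$cohort$n_germline,
                n_embryonic_shared = cfg$cohort$n_embryonic_shared,
                indel_rate_per_year = cfg$cohort$indel_rate_per_year,
                private_fraction = cfg$cohort$private_fraction,
                seed = cfg$seed)
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes simulate -> artefact/germline filtering -> sensitivity-corrected
#' burdens -> per-patient parsimony trees with ML branch assignment ->
#' branch catalogues -> de novo NMF extraction, reference decomposition and
#' exposure refitting -> genotype rate modelling. All artefacts are written
#' under `out_dir`; the run is deterministic under the config seed.
#'
#' @param config Run configuration (see [default_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @return A run report list: per-stage parameters, input/output counts and
#'   the key results (classification table path, sensitivity table, trees,
#'   exposures, rate fit).
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = tempfile("run")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = config, stages = list())
  stage <- function(name, ...) {
    report$stages[[name]] <<- list(...)
  }

  # -- simulate
  cohort_cfg <- config_to_cohort(config)
  sim <- simulate_cohort(cohort_cfg)
  write_pileup(sim$pileup, file.path(out_dir, "sites.vcf"),
               file.path(out_dir, "NV.tsv"), file.path(out_dir, "NR.tsv"))
  write_metadata_tsv(sim$metadata, file.path(out_dir, "metadata.tsv"))
  jsonlite::write_json(sim$truth$variants, file.path(out_dir, "truth.json"))
  stage("simulate", seed = config$seed, n_variants = nrow(sim$pileup$variants),
        n_samples = length(sim$pileup$samples))

  # -- filter
  fp <- config$filtering
  filtered <- apply_artefact_thresholds(sim$pileup, fp$min_asmd, fp$max_clipped)
  patient_of <- stats::setNames(sim$metadata$patient, sim$metadata$sample)
  classification <- classify_variants(filtered, patient_of,
                                      binomial_alpha = fp$binomial_alpha,
                                      rho_threshold = fp$rho_threshold,
                                      expected_vaf = fp$expected_vaf)
  write_classification_tsv(classification, file.path(out_dir, "classification.tsv"))
  stage("filter", params = fp,
        n_in = nrow(sim$pileup$variants),
        n_somatic = sum(classification$class == "somatic"),
        n_germline = sum(classification$class == "germline"))

  # -- somatic burden + sensitivity correction
  somatic_ids <- classification$variant[classification$class == "somatic"]
  som_idx <- variant_ids(filtered$variants) %in% somatic_ids
  somatic_pileup <- filtered[som_idx, ]
  # raw burden mirrors the caller's >= min_alt_reads variant-read rule,
  # which is exactly the dropout the sensitivity model corrects
  raw_burden <- colSums(somatic_pileup$NV >= config$sensitivity$min_alt_reads)
  raw_burden <- stats::setNames(raw_burden[sim$metadata$sample], sim$metadata$sample)
  raw_burden[is.na(raw_burden)] <- 0
  sens <- sensitivity_table(sim$metadata, raw_burden,
                            min_alt_reads = config$sensitivity$min_alt_reads)
  write_metadata_tsv(sens, file.path(out_dir, "burden.tsv"))
  stage("sensitivity", params = config$sensitivity,
        mean_sensitivity = mean(sens$sensitivity))

  # -- per-patient trees and branch catalogues
  trees <- list(); catalogues <- list()
  for (pt in unique(sim$metadata$patient)) {
    smp <- sim$metadata$sample[sim$metadata$patient == pt]
    if (length(smp) < 2) next
    sub <- somatic_pileup[, smp]
    sub <- sub[rowSums(sub$NV) > 0, ]
    G <- genotype_matrix(sub, config$tree$min_nv, config$tree$min_vaf)
    sub_called <- sub[variant_ids(sub$variants) %in% rownames(G), ]
    tree <- build_parsimony_tree(G)
    asg <- assign_mutations_ml(tree, sub_called, config$tree$clonality_vaf,
                               config$tree$error_rate)
    write_branch_newick(tree, asg, file.path(out_dir, paste0("tree_", pt, ".nwk")))
    trees[[pt]] <- list(tree = tree, assignments = asg)
    cats <- branch_catalogues(asg, sub_called,
                              max_per_branch = config$signatures$max_per_branch,
                              min_branch = config$signatures$min_branch,
                              seed = config$seed, label_prefix = pt)
    names(cats) <- paste0(pt, "_", names(cats))
    catalogues <- c(catalogues, cats)
  }
  stage("tree", params = config$tree, n_trees = length(trees),
        n_catalogues = length(catalogues))

  # -- signatures
  fits <- list(); signature_set <- NULL; decompositions <- NULL
  if (length(catalogues) >= config$signatures$k) {
    spectra <- lapply(catalogues, `[[`, "spectrum")
    signature_set <- extract_denovo(spectra, k = config$signatures$k,
                                    restarts = config$signatures$restarts,
                                    seed = config$seed)
    refs <- fixture_signatures()
    decompositions <- apply(signature_set$signatures, 2, decompose_to_reference,
                            references = refs,
                            acceptance_cosine = config$signatures$acceptance_cosine)
    allowed_names <- unique(unlist(lapply(decompositions, function(d)
      names(d$weights)[d$weights >= 0.05])))
    allowed <- refs[allowed_names]
    fits <- lapply(spectra, refit_exposures, allowed = allowed,
                   min_exposure = config$signatures$min_exposure)
    write_exposures_tsv(fits, file.path(out_dir, "exposures.tsv"))
    write_signature_tsv(signature_set$signatures,
                        file.path(out_dir, "denovo_signatures.tsv"))
  }
  stage("signatures", params = config$signatures, n_fits = length(fits))

  # -- burden modelling
  obs <- data.frame(burden = sens$corrected_burden,
                    age = sim$metadata$age, genotype = sim$metadata$genotype,
                    patient = sim$metadata$patient)
  rate_fit <- fit_burden_lme(obs)
  utils::write.table(rate_fit$rates, file.path(out_dir, "rates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage("burden", n_obs = nrow(obs), rates = rate_fit$rates)

  report$outputs <- list(dir = out_dir,
                         classification = classification, sensitivity = sens,
                         trees = trees, signature_set = signature_set,
                         decompositions = decompositions, exposures = fits,
                         rate_fit = rate_fit, truth = sim$truth,
                         metadata = sim$metadata)
  jsonlite::write_json(report$stages, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, force = TRUE)
  class(report) <- "run_report"
  report
}

#' @exportS3Method print run_report
print.run_report <- function(x, ...) {
  cat("<run_report> stages:", paste(names(x$stages), collapse = ", "), "\n")
  invisible(x)
}
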