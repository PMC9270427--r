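test_that("fixture signatures are unit-sum and the oxidative pair is separable", {
  sigs <- fixture_signatures()
  expect_true(all(abs(vapply(sigs, sum, numeric(1)) - 1) < 1e-9))
  cs <- cosine_similarity(sigs$SBS18like, sigs$SBS36like)
  expect_gt(cs, 0.3)
  expect_lt(cs, 0.9)
  ids <- fixture_id_signatures()
  expect_true(all(abs(vapply(ids, sum, numeric(1)) - 1) < 1e-9))
})

test_that("config validation rejects degenerate cohorts", {
  expect_error(patient_spec("P", "G", 50, 3, 90, signature_mixture = c(SBS18like = 0.7)),
               "sum to 1")
  expect_error(cohort_config(list(patient_spec("P", "G", 50, 0, 90))), "crypts")
  expect_error(cohort_config(list(patient_spec("P", "G", 50, 3, 90)),
                             mean_coverage = 0), "mean_coverage")
  expect_error(cohort_config(list(patient_spec("P", "G", 50, 3, 90)),
                             clonality_vaf = 0.7), "clonality_vaf")
  expect_error(cohort_config(list(patient_spec("P", "G", 50, 3, 90,
                 signature_mixture = c(nope = 1)))), "unknown signatures")
})

test_that("zero-rate cohorts contain only germline-like rows at VAF ~ 0.5", {
  cfg <- cohort_config(list(patient_spec("P1", "WT", 50, 3, 0)),
                       n_germline = 30, n_embryonic_shared = 0, seed = 4)
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$truth$variants$class == "germline"))
  vaf <- sim$pileup$NV / pmax(sim$pileup$NR, 1)
  expect_equal(mean(vaf), 0.5, tolerance = 0.05)
})

test_that("identical seeds give identical cohorts, different seeds differ", {
  cfg <- cohort_config(list(patient_spec("P1", "MUT", 40, 3, 20)),
                       n_germline = 10, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$pileup$NV, b$pileup$NV)
  expect_identical(a$truth$variants, b$truth$variants)
  cfg2 <- cohort_config(list(patient_spec("P1", "MUT", 40, 3, 20)),
                        n_germline = 10, seed = 10)
  c_ <- simulate_cohort(cfg2)
  expect_false(identical(a$pileup$NV, c_$pileup$NV))
})

test_that("true burdens are Poisson around age x rate", {
  # single crypt, rate 6/yr, age 10 -> mean 60; average over 200 seeds
  burdens <- vapply(1:200, function(s) {
    cfg <- cohort_config(list(patient_spec("P", "G", 10, 1, 6)),
                         n_germline = 0, n_embryonic_shared = 0, seed = s)
    simulate_cohort(cfg)$truth$burden$true_sbs_burden
  }, numeric(1))
  se <- sd(burdens) / sqrt(length(burdens))
  expect_lt(abs(mean(burdens) - 60), 3 * se)
})

test_that("truth classes partition the pileup rows", {
  cfg <- cohort_config(list(patient_spec("P1", "MUT", 45, 4, 25)),
                       n_germline = 15, n_embryonic_shared = 3, seed = 2)
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$truth$variants), nrow(sim$pileup$variants))
  expect_setequal(sim$truth$variants$variant, variant_ids(sim$pileup$variants))
  expect_true(all(sim$truth$variants$class %in%
                    c("germline", "embryonic", "somatic-private", "somatic-shared")))
})

test_that("simulate_lineage conserves configured mutation counts", {
  lin <- simulate_lineage(2, 5, 10, seed = 1)
  expect_equal(unname(lin$branch_counts[["root"]]), 5)
  term <- lin$branch_counts[names(lin$branch_counts) != "root"]
  expect_equal(unname(term), c(10, 10))

  lin3 <- simulate_lineage(3, 0, 9, seed = 2)
  internal <- !names(lin3$branch_counts) %in%
    as.character(lin3$branches$branch[lin3$branches$terminal])
  expect_true(all(lin3$branch_counts[internal] == 0))

  for (s in 1:5) {
    lin_r <- simulate_lineage(5, 17, 4, seed = s)
    expect_equal(sum(lin_r$branch_counts), 17 + 4 * 5)
  }
  expect_error(simulate_lineage(1, 5, 10), "at least 2")
})

test_that("simulated read depths and allele counts follow the coverage model", {
  cfg <- cohort_config(list(patient_spec("P1", "MUT", 50, 4, 30)),
                       mean_coverage = 28, n_germline = 40, seed = 6)
  sim <- simulate_cohort(cfg)
  expect_equal(mean(sim$pileup$NR), 28, tolerance = 0.1)
  germ <- sim$truth$variants$class == "germline"
  vaf_germ <- rowSums(sim$pileup$NV[germ, ]) / rowSums(sim$pileup$NR[germ, ])
  expect_equal(mean(vaf_germ), 0.5, tolerance = 0.02)
})
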