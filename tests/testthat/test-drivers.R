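roles <- data.frame(gene = c("APC", "KRAS", "TP53"),
                    role = c("recessive", "dominant", "intermediate"))
hot <- data.frame(gene = c("KRAS", "TP53"), protein_change = c("G12D", "R175H"))

test_that("driver rules fire on truncation, hotspot and likely-oncogenic", {
  d1 <- classify_driver("APC", "nonsense", "Q1338*", roles, hot)
  expect_true(d1$is_driver)
  expect_equal(d1$reason, "truncating-in-recessive")

  d2 <- classify_driver("KRAS", "missense", "A146P", roles, hot)
  expect_false(d2$is_driver)
  expect_equal(d2$reason, "none")

  d3 <- classify_driver("KRAS", "missense", "G12D", roles, hot)
  expect_true(d3$is_driver)
  expect_equal(d3$reason, "hotspot")

  # intermediate genes satisfy both rules
  d4 <- classify_driver("TP53", "frameshift", "fs", roles, hot)
  expect_equal(d4$reason, "truncating-in-recessive")
  d5 <- classify_driver("TP53", "missense", "R175H", roles, hot)
  expect_equal(d5$reason, "hotspot")

  lo <- data.frame(gene = "KRAS", protein_change = "K117N")
  d6 <- classify_driver("KRAS", "missense", "K117N", roles, hot, lo)
  expect_equal(d6$reason, "likely-oncogenic")

  # genes outside the tissue list never classify as drivers
  d7 <- classify_driver("GENEX", "nonsense", "Q1*", roles, hot)
  expect_false(d7$is_driver)

  # truncation in a purely dominant gene is not a driver by itself
  d8 <- classify_driver("KRAS", "nonsense", "Q61*", roles, hot)
  expect_false(d8$is_driver)

  expect_error(classify_driver("APC", "weird", "x", roles), "unknown consequence")
})

test_that("classification is pure and order-independent", {
  muts <- data.frame(gene = c("APC", "KRAS", "KRAS"),
                     consequence = c("nonsense", "missense", "missense"),
                     protein_change = c("Q1338*", "G12D", "A146P"),
                     sample = c("c1", "c2", "c3"))
  a <- classify_drivers(muts, roles, hot)
  b <- classify_drivers(muts[3:1, ], roles, hot)
  expect_equal(a$is_driver, rev(b$is_driver))
  expect_true(all(xor(a$is_driver, a$reason == "none")))
})

test_that("driver fractions match the published worked examples", {
  f1 <- driver_fraction(driver_samples = paste0("c", 1:22),
                        all_samples = paste0("c", 1:144))
  expect_equal(f1$percent, 15)
  expect_equal(f1$n_with_driver, 22)

  f2 <- driver_fraction(driver_samples = paste0("c", 1:25),
                        all_samples = paste0("c", 1:449))
  expect_equal(f2$percent, 6)

  f0 <- driver_fraction(driver_samples = character(0),
                        all_samples = paste0("c", 1:10))
  expect_equal(f0$percent, 0)

  # a crypt with several drivers counts once
  calls <- data.frame(sample = c("c1", "c1", "c2"), is_driver = c(TRUE, TRUE, FALSE))
  f3 <- driver_fraction(calls, all_samples = c("c1", "c2", "c3"))
  expect_equal(f3$n_with_driver, 1)
  expect_lte(f3$n_with_driver, f3$n_crypts)
  expect_error(driver_fraction(calls, all_samples = character(0)), "zero crypts")
})

test_that("per-consequence rate folds recover an enriched class", {
  set.seed(17)
  patients <- data.frame(patient = paste0("P", 1:6),
                         age = c(30, 40, 50, 60, 45, 55))
  mk <- function(rate_per_class) {
    do.call(rbind, lapply(seq_len(nrow(patients)), function(i) {
      do.call(rbind, lapply(names(rate_per_class), function(cl) {
        data.frame(sample = paste0(patients$patient[i], "_", 1:4),
                   patient = patients$patient[i], age = patients$age[i],
                   consequence = cl,
                   count = rpois(4, patients$age[i] * rate_per_class[[cl]]))
      }))
    }))
  }
  control <- c(nonsense = 0.05, missense = 0.5, synonymous = 0.2)
  cohort <- mk(c(nonsense = 0.5, missense = 0.5, synonymous = 0.2))
  res <- coding_rate_comparison(cohort, control)
  expect_equal(res$fold[res$consequence == "nonsense"], 10, tolerance = 0.2)
  expect_equal(res$fold[res$consequence == "missense"], 1, tolerance = 0.15)

  # identical cohort against its own rates -> folds of 1
  self_rates <- setNames(res$rate, res$consequence)
  res_self <- coding_rate_comparison(cohort, self_rates)
  expect_equal(res_self$fold, rep(1, 3), tolerance = 1e-8)

  # missing control class reports NA, not an error
  res_na <- coding_rate_comparison(cohort, control[c("missense", "synonymous")])
  expect_true(is.na(res_na$fold[res_na$consequence == "nonsense"]))
})

test_that("gene role tables reject duplicates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(roles, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_gene_roles(path)$gene, roles$gene)
  write.table(rbind(roles, roles[1, ]), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_gene_roles(path), "duplicate")
})
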