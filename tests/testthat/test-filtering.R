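make_pileup <- function(nv, nr, asmd = 145, clpm = 0) {
  n <- nrow(nv)
  variants <- data.frame(chrom = "1", pos = seq_len(n), ref = "C", alt = "A",
                         trinuc = "ACA", asmd = asmd, clpm = clpm)
  pileup_matrix(variants, nv, nr)
}

test_that("artefact thresholds drop low-ASMD and clipped variants", {
  nv <- matrix(5, 3, 2); nr <- matrix(10, 3, 2)
  p <- make_pileup(nv, nr, asmd = c(139, 140, 150), clpm = c(0, 0, 0.2))
  out <- apply_artefact_thresholds(p)
  expect_equal(nrow(out$variants), 1)
  expect_equal(out$variants$asmd, 140)
  expect_setequal(attr(out, "artefact_filtered"),
                  variant_ids(p$variants)[c(1, 3)])

  p2 <- make_pileup(nv, nr)
  p2$variants$asmd <- NULL; p2$variants$clpm <- NULL
  expect_warning(out2 <- apply_artefact_thresholds(p2), "no artefact annotations")
  expect_equal(nrow(out2$variants), 3)
})

test_that("aggregate binomial test separates germline from somatic depths", {
  # half the reads variant at 496x aggregate depth: consistent with germline
  expect_gt(aggregate_binomial_test(248, 496, 0.5), 0.4)
  # 4 variant reads in 496: far below the germline expectation
  oracle <- pbinom(4, 496, 0.5)   # exact binomial tail
  expect_equal(aggregate_binomial_test(4, 496, 0.5), oracle)
  expect_lt(oracle, 1e-100)
  expect_true(is.na(aggregate_binomial_test(0, 0, 0.5)))
})

test_that("rho estimates agree with a dense-grid likelihood oracle", {
  dense <- exp(seq(log(1e-6), log(0.89), length.out = 2000))
  ll_oracle <- function(nv, nr) {
    mu <- sum(nv) / sum(nr)
    a <- function(r) mu * (1 - r) / r
    b <- function(r) (1 - mu) * (1 - r) / r
    ll <- vapply(dense, function(r) {
      sum(lchoose(nr, nv) + lbeta(nv + a(r), nr - nv + b(r)) - lbeta(a(r), b(r)))
    }, numeric(1))
    dense[which.max(ll)]
  }
  set.seed(21)
  grid <- rho_grid()
  step <- max(diff(log(grid)))
  for (rep in 1:8) {
    nr <- rpois(10, 30) + 1
    nv <- rbinom(10, nr, runif(1, 0.1, 0.5))
    r_pkg <- estimate_rho(nv, nr)
    r_orc <- ll_oracle(nv, nr)
    expect_lt(abs(log(r_pkg) - log(r_orc)), step + 1e-9)
  }
})

test_that("rho is high for subset-restricted variants, low for homogeneous ones", {
  # even spread at constant VAF
  expect_lt(estimate_rho(rep(15, 10), rep(30, 10)), 0.01)
  # concentrated in one of ten samples
  expect_gt(estimate_rho(c(15, rep(0, 9)), rep(30, 10)), 0.1)
  # single informative sample: untestable
  expect_true(is.na(estimate_rho(5, 10)))
  # all-zero NV: minimum of the grid
  expect_equal(estimate_rho(rep(0, 5), rep(20, 5)), min(rho_grid()))
})

test_that("classification is invariant to sample order", {
  set.seed(31)
  cfg <- cohort_config(list(patient_spec("P1", "MUT", 40, 4, 8)),
                       n_germline = 12, seed = 14)
  sim <- simulate_cohort(cfg)
  po <- setNames(sim$metadata$patient, sim$metadata$sample)
  a <- classify_variants(sim$pileup, po)
  perm <- sample(length(sim$pileup$samples))
  b <- classify_variants(sim$pileup[, perm], po)
  m <- merge(a[, c("variant", "class")], b[, c("variant", "class")], by = "variant")
  expect_equal(m$class.x, m$class.y)
})

test_that("germline recall and somatic precision are high on synthetic cohorts", {
  cfg <- cohort_config(list(
    patient_spec("P1", "MUT", 50, 8, 35,
                 signature_mixture = c(SBS18like = 0.6, SBS5like = 0.4)),
    patient_spec("P2", "MUT", 60, 8, 35,
                 signature_mixture = c(SBS18like = 0.6, SBS5like = 0.4))),
    n_germline = 150, n_embryonic_shared = 5, mean_coverage = 28, seed = 8)
  sim <- simulate_cohort(cfg)     # aggregate depth ~ 8 x 28 = 224 per patient
  po <- setNames(sim$metadata$patient, sim$metadata$sample)
  cl <- classify_variants(apply_artefact_thresholds(sim$pileup), po)
  m <- merge(cl, sim$truth$variants, by = "variant")

  germ <- m[m$class.y == "germline", ]
  expect_gte(mean(germ$class.x == "germline"), 0.99)

  som_called <- m[m$class.x == "somatic", ]
  expect_gte(mean(som_called$class.y != "germline"), 0.95)

  # clonal private somatic variants are recovered as somatic
  priv <- m[m$class.y == "somatic-private", ]
  expect_gte(mean(priv$class.x == "somatic"), 0.95)

  # shared embryonic variants in a clade subset classify as somatic
  emb <- m[m$class.y == "embryonic", ]
  if (nrow(emb) > 0) expect_gte(mean(emb$class.x == "somatic"), 0.5)
})
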