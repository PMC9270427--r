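sigs <- fixture_signatures()

test_that("NMF recovers a single generating profile", {
  set.seed(1)
  cats <- lapply(1:6, function(i) draw_spectrum_from(sigs$SBS18like, 1500))
  ss <- extract_denovo(cats, k = 1, restarts = 3, seed = 2)
  expect_gte(cosine_similarity(ss$signatures[, 1], sigs$SBS18like), 0.99)
  expect_error(extract_denovo(cats, k = 0), "k must be")
  expect_error(extract_denovo(cats, k = 7), "exceeds")
})

test_that("NMF separates two well-separated fixtures from varying mixtures", {
  set.seed(2)
  props <- seq(0.05, 0.95, length.out = 12)
  cats <- lapply(props, function(p) {
    draw_spectrum_from(mixture_profile(list(SBS18like = p, SBS88like = 1 - p),
                                       sigs), 2000)
  })
  ss <- extract_denovo(cats, k = 2, restarts = 4, seed = 3)
  for (truth in list(sigs$SBS18like, sigs$SBS88like)) {
    best <- max(apply(ss$signatures, 2, cosine_similarity, b = truth))
    expect_gte(best, 0.95)
  }
  # exposure conservation per sample
  totals <- rowSums(ss$exposures)
  expect_equal(unname(totals), vapply(cats, sum, numeric(1)), tolerance = 1e-6)
})

test_that("KL divergence is non-increasing across multiplicative updates", {
  set.seed(3)
  cats <- lapply(1:5, function(i)
    draw_spectrum_from(mixture_profile(list(SBS18like = runif(1),
                                            SBS88like = 1), sigs), 800))
  ss <- extract_denovo(cats, k = 2, restarts = 1, seed = 4)
  expect_true(all(diff(ss$divergence_trace) <= 1e-8))
})

test_that("EM decomposition recovers reference mixture weights", {
  refs <- sigs[c("SBS18like", "SBS88like")]
  d_pure <- decompose_to_reference(sigs$SBS18like, refs)
  expect_equal(unname(d_pure$weights), c(1, 0), tolerance = 1e-4)
  expect_true(d_pure$accepted)

  comp <- mixture_profile(list(SBS18like = 0.6, SBS88like = 0.4), sigs)
  d <- decompose_to_reference(comp, refs)
  expect_equal(unname(d$weights), c(0.6, 0.4), tolerance = 0.02)
  oracle <- nnls_simplex_weights(comp, refs)
  expect_lt(sum(abs(d$weights - oracle)), 0.02)

  # a single-channel spike has no counterpart among the references
  spike <- c(rep(0, 95), 1)
  d_bad <- decompose_to_reference(spike, refs)
  expect_false(d_bad$accepted)
  expect_error(decompose_to_reference(comp, list()), "empty reference")
})

test_that("EM weights track the NNLS oracle on random mixtures", {
  set.seed(5)
  refs <- sigs[c("SBS1like", "SBS18like", "SBS88like")]
  for (rep in 1:6) {
    w <- as.numeric(rmultinom(1, 100, rep(1, 3))) / 100
    comp <- mixture_profile(setNames(as.list(w), names(refs)), sigs)
    d <- decompose_to_reference(comp, refs)
    oracle <- nnls_simplex_weights(comp, refs)
    expect_lt(sum(abs(d$weights - oracle)), 1e-3)
  }
})

test_that("exposure refitting prunes minor signatures and conserves counts", {
  pure <- 5000 * as.numeric(sigs$SBS36like)
  f_pure <- refit_exposures(pure, sigs[c("SBS36like", "SBS88like")])
  expect_equal(unname(f_pure$fractions[["SBS36like"]]), 1, tolerance = 1e-6)

  spec <- 10000 * mixture_profile(list(SBS18like = 0.5, SBS88like = 0.45,
                                       SBS1like = 0.05), sigs)
  f <- refit_exposures(spec, sigs[c("SBS18like", "SBS88like", "SBS1like")])
  expect_equal(f$pruned, "SBS1like")
  expect_equal(unname(f$fractions),
               c(0.5, 0.45) / 0.95, tolerance = 0.02)
  expect_equal(sum(f$exposures), 10000, tolerance = 1e-6)
  expect_true(all(f$fractions >= 0.10))
  expect_error(refit_exposures(spec, list()), "empty allowed")
})

test_that("the same machinery fits 83-channel indel spectra", {
  idsigs <- fixture_id_signatures()
  set.seed(6)
  cats <- lapply(1:4, function(i) draw_spectrum_from(idsigs$ID1like, 600))
  ss <- extract_denovo(cats, k = 1, restarts = 2, seed = 7)
  expect_gte(cosine_similarity(ss$signatures[, 1], idsigs$ID1like), 0.99)
  f <- refit_exposures(600 * as.numeric(idsigs$ID2like), idsigs)
  expect_equal(names(which.max(f$fractions)), "ID2like")
})

test_that("end-to-end exposure recovery on a MUTYH-like mixture is accurate", {
  # branches at 2000 mutations from SBS1/5/18/36-like mixtures: the summed
  # oxidative (SBS18+SBS36) exposure fraction is recovered within 0.05 MAE
  set.seed(8)
  refs <- sigs[c("SBS1like", "SBS5like", "SBS18like", "SBS36like")]
  errs <- vapply(1:6, function(i) {
    w18 <- runif(1, 0.2, 0.5); w36 <- runif(1, 0.2, 0.5)
    rest <- 1 - w18 - w36
    mix <- list(SBS1like = 0.3 * rest, SBS5like = 0.7 * rest,
                SBS18like = w18, SBS36like = w36)
    spec <- draw_spectrum_from(mixture_profile(mix, sigs), 2000)
    f <- refit_exposures(spec, refs, min_exposure = 0.0)
    ox_hat <- sum(f$fractions[c("SBS18like", "SBS36like")], na.rm = TRUE)
    abs(ox_hat - (w18 + w36))
  }, numeric(1))
  expect_lte(mean(errs), 0.05)
})
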