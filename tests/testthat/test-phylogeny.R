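pileup_from_genotypes <- function(G, depth = 30, vaf = 0.5) {
  n <- nrow(G)
  variants <- data.frame(chrom = "1", pos = seq_len(n), ref = "C", alt = "A",
                         trinuc = "ACA", asmd = 145, clpm = 0)
  NR <- matrix(depth, n, ncol(G), dimnames = list(NULL, colnames(G)))
  NV <- round(G * vaf * depth)
  pileup_matrix(variants, NV, NR)
}

test_that("perfect nested variant sets give the caterpillar tree", {
  G <- rbind(m1 = c(A = 1, B = 1, C = 1),
             m2 = c(A = 1, B = 1, C = 0),
             m3 = c(A = 1, B = 0, C = 0))
  tree <- build_parsimony_tree(G)
  expect_equal(attr(tree, "parsimony_score"), 3)
  expect_true(ape::is.monophyletic(tree, c("A", "B")))
  # m1 spans all tips (root trunk), m2 the (A,B) cherry
  p <- pileup_from_genotypes(G)
  asg <- assign_mutations_ml(tree, p)
  tb <- tree_branches(tree)
  clades <- setNames(lapply(tb$clade, sort), tb$branch)
  expect_equal(clades[[asg$branch[1]]], c("A", "B", "C"))
  expect_equal(clades[[asg$branch[2]]], c("A", "B"))
  expect_equal(clades[[asg$branch[3]]], "A")
})

test_that("exact search matches brute-force enumeration on random matrices", {
  set.seed(99)
  for (n_tips in 4:6) {
    for (rep in 1:4) {
      G <- matrix(rbinom(12 * n_tips, 1, 0.4), nrow = 12,
                  dimnames = list(NULL, LETTERS[1:n_tips]))
      G <- G[rowSums(G) > 0, , drop = FALSE]
      if (nrow(G) == 0) next
      tree <- build_parsimony_tree(G)
      expect_equal(attr(tree, "parsimony_score"), oracle_parsimony_min(G),
                   info = paste("tips", n_tips, "rep", rep))
      # the reported score is also the score of the reported tree
      expect_equal(parsimony_score(tree, G), attr(tree, "parsimony_score"))
    }
  }
})

test_that("conflict-free simulated lineages are reconstructed exactly", {
  cfg <- cohort_config(list(patient_spec("P1", "MUT", 50, 6, 30,
                signature_mixture = c(SBS18like = 0.7, SBS5like = 0.3))),
                n_germline = 0, n_embryonic_shared = 0, seed = 13)
  sim <- simulate_cohort(cfg)
  G <- genotype_matrix(sim$pileup)
  tree <- build_parsimony_tree(G)
  expect_equal(ape::dist.topo(ape::unroot(tree),
                              ape::unroot(sim$truth$trees$P1)), 0,
               ignore_attr = TRUE)
})

test_that("ML assignment places private and shared mutations correctly", {
  G <- rbind(c(A = 1, B = 0, C = 0),        # private to A
             c(A = 1, B = 1, C = 0))        # cherry (A,B)
  tree <- build_parsimony_tree(rbind(G, c(A = 1, B = 1, C = 1)))
  p <- pileup_from_genotypes(G)
  asg <- assign_mutations_ml(tree, p)
  tb <- tree_branches(tree)
  clades <- setNames(lapply(tb$clade, sort), tb$branch)
  expect_equal(clades[[asg$branch[1]]], "A")
  expect_equal(clades[[asg$branch[2]]], c("A", "B"))
  expect_true(all(asg$prob > 0.99))

  # zero depth everywhere -> unassigned
  z <- matrix(0, 1, 3, dimnames = list(NULL, c("A", "B", "C")))
  p0 <- pileup_matrix(p$variants[1, ], z, z)
  asg0 <- assign_mutations_ml(tree, p0)
  expect_true(is.na(asg0$branch))
})

test_that("branch assignment is >= 95% correct at cohort coverage", {
  cfg <- cohort_config(list(patient_spec("P1", "MUT", 55, 6, 40,
                signature_mixture = c(SBS18like = 0.6, SBS5like = 0.4))),
                mean_coverage = 28, n_germline = 0, n_embryonic_shared = 0,
                seed = 23)
  sim <- simulate_cohort(cfg)
  po <- setNames(sim$metadata$patient, sim$metadata$sample)
  cl <- classify_variants(sim$pileup, po)
  som <- sim$pileup[variant_ids(sim$pileup$variants) %in%
                      cl$variant[cl$class == "somatic"], ]
  tree <- build_parsimony_tree(genotype_matrix(som))
  asg <- assign_mutations_ml(tree, som)

  inferred <- clade_strings_pkg(tree)
  truth_cl <- clade_strings(sim$truth$trees$P1)
  m <- merge(asg, sim$truth$variants, by = "variant")
  m <- m[m$class %in% c("somatic-private", "somatic-shared") & !is.na(m$branch.x), ]
  acc <- mean(inferred[m$branch.x] == truth_cl[m$branch.y])
  expect_gte(acc, 0.95)
  # conservation: every somatic input is either assigned or unassigned
  expect_equal(nrow(asg), nrow(som$variants))
})

test_that("branch catalogues obey the subsampling window", {
  n <- 5000
  variants <- data.frame(chrom = "1", pos = 1:n, ref = "C", alt = "A",
                         trinuc = sample(c("ACA", "TCT", "GCA"), n, TRUE),
                         asmd = 145, clpm = 0)
  p <- pileup_matrix(variants, matrix(15, n, 2), matrix(30, n, 2))
  ids <- variant_ids(variants)
  asg <- data.frame(variant = ids,
                    branch = rep(c("big", "mid", "tiny"), c(4601, 300, 99)),
                    prob = 1)
  suppressMessages(cats <- branch_catalogues(asg, p, seed = 3))
  expect_null(cats$tiny)           # 99 < 100: excluded
  expect_equal(sum(cats$big$spectrum), 2500)
  expect_equal(cats$big$n_total, 4601)
  expect_equal(sum(cats$mid$spectrum), 300)

  # subsampling preserves channel proportions within binomial error
  big_tri <- variants$trinuc[asg$branch == "big"]
  full_prop <- prop.table(table(big_tri))
  sub <- cats$big$spectrum
  sub_prop <- sub[c("A[C>A]A", "G[C>A]A", "T[C>A]T")] / sum(sub)
  for (k in seq_along(sub_prop)) {
    p_hat <- full_prop[c("ACA", "GCA", "TCT")[k]]
    se <- sqrt(p_hat * (1 - p_hat) / 2500)
    expect_lt(abs(sub_prop[k] - p_hat), 4 * se)
  }
})
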