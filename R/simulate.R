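# Synthetic cohort generator. Emulates the statistical structure of a
# multi-crypt whole-genome study: per-patient lineage trees, age-proportional
# somatic burdens, signature-mixture mutation contexts, shared germline and
# embryonic variants, and Poisson coverage with binomial allele counts.

#' Describe one simulated patient
#'
#' @param id Patient identifier.
#' @param genotype Germline genotype label (grouping variable for rate
#'   modelling, e.g. `"Y179C/G396D"` or `"WT"`).
#' @param age Age in years (> 0).
#' @param n_crypts Number of clonal units sampled from this patient.
#' @param rate_per_year Genotype-level somatic SBS rate, mutations/year.
#' @param rate_sd_patient SD of the patient-level rate deviation
#'   (mutations/year); the realised patient rate is
#'   `max(0, rate_per_year + Normal(0, rate_sd_patient))`.
#' @param signature_mixture Named weights over signature profiles (must sum
#'   to 1); names must match the cohort's signature set.
#' @return A `patient_spec` list.
#' @export
patient_spec <- function(id, genotype, age, n_crypts, rate_per_year,
                         rate_sd_patient = 0,
                         signature_mixture = c(SBS18like = 0.5, SBS5like = 0.5)) {
  stopifnot(age > 0, n_crypts >= 1, rate_per_year >= 0, rate_sd_patient >= 0)
  if (abs(sum(signature_mixture) - 1) > 1e-6)
    stop("signature_mixture weights must sum to 1", call. = FALSE)
  structure(list(id = id, genotype = genotype, age = age, n_crypts = n_crypts,
                 rate_per_year = rate_per_year,
                 rate_sd_patient = rate_sd_patient,
                 signature_mixture = signature_mixture),
            class = "patient_spec")
}

#' Cohort simulation configuration
#'
#' @param patients List of [patient_spec()] entries.
#' @param mean_coverage Mean per-site sequencing depth (reads); per-site
#'   depths are Poisson around this.
#' @param clonality_vaf Expected variant allele fraction of clonal somatic
#'   variants in carrying crypts, in (0, 0.5].
#' @param n_germline Germline heterozygous variants per patient (VAF 0.5 in
#'   every crypt).
#' @param n_embryonic_shared Early-embryonic variants per patient, placed on
#'   internal lineage branches at VAF 0.5 in the carrying clade.
#' @param indel_rate_per_year Indel rate (ID/year) used for per-crypt true
#'   indel burdens.
#' @param private_fraction Expected fraction of a crypt's lifetime spent on
#'   its terminal branch (long terminal branches; default 0.9).
#' @param signatures Named list of signature profiles the mixtures refer to;
#'   defaults to [fixture_signatures()].
#' @param seed Integer seed; every draw is reproducible under it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(patients, mean_coverage = 28, clonality_vaf = 0.5,
                          n_germline = 50, n_embryonic_shared = 5,
                          indel_rate_per_year = 2.1, private_fraction = 0.9,
                          signatures = fixture_signatures(), seed = 1L) {
  if (length(patients) < 1) stop("config error: need at least one patient", call. = FALSE)
  if (inherits(patients, "patient_spec")) patients <- list(patients)
  if (mean_coverage <= 0) stop("config error: mean_coverage must be > 0", call. = FALSE)
  if (clonality_vaf <= 0 || clonality_vaf > 0.5)
    stop("config error: clonality_vaf must be in (0, 0.5]", call. = FALSE)
  if (private_fraction <= 0 || private_fraction >= 1)
    stop("config error: private_fraction must be in (0, 1)", call. = FALSE)
  for (p in patients) {
    if (p$n_crypts < 1) stop("config error: zero crypts", call. = FALSE)
    missing_sigs <- setdiff(names(p$signature_mixture), names(signatures))
    if (length(missing_sigs))
      stop("config error: unknown signatures in mixture: ",
           paste(missing_sigs, collapse = ", "), call. = FALSE)
  }
  structure(list(patients = patients, mean_coverage = mean_coverage,
                 clonality_vaf = clonality_vaf, n_germline = n_germline,
                 n_embryonic_shared = n_embryonic_shared,
                 indel_rate_per_year = indel_rate_per_year,
                 private_fraction = private_fraction,
                 signatures = signatures, seed = as.integer(seed)),
            class = "cohort_config")
}

# Random rooted binary topology over given tip labels, built by sequential
# attachment; returns an ape "phylo". Deterministic under the current RNG
# state.
random_topology <- function(tips) {
  n <- length(tips)
  stopifnot(n >= 2)
  if (n == 2) {
    tr <- ape::read.tree(text = paste0("(", tips[1], ",", tips[2], ");"))
    return(tr)
  }
  tr <- ape::rtree(n, rooted = TRUE, br = NULL)
  tr$tip.label <- sample(tips)
  ape::reorder.phylo(tr, "postorder")
}

# Branch table for a rooted phylo: one row per edge, with the set of tips
# descended from the edge's child. Branch ids are the child node numbers.
branch_table <- function(tree) {
  n_tip <- length(tree$tip.label)
  clades <- lapply(seq_len(max(tree$edge)), function(node) {
    if (node <= n_tip) tree$tip.label[node]
    else tree$tip.label[unlist(phangorn_free_descendants(tree, node))]
  })
  child <- tree$edge[, 2]
  data.frame(branch = child,
             terminal = child <= n_tip,
             stringsAsFactors = FALSE) |>
    (\(df) { df$tips <- clades[child]; df })()
}

# Tip indices under a node, without depending on phangorn.
phangorn_free_descendants <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, phangorn_free_descendants, tree = tree))
}

#' Simulate a crypt lineage with fixed mutation counts
#'
#' Builds a random rooted binary tree over `n_crypts` crypts, spreads
#' `n_shared` mutations multinomially over the internal branches (the branch
#' above the root's first split acts as the shared trunk for two-crypt
#' trees) and places exactly `n_private` mutations on each terminal branch.
#'
#' @param n_crypts Number of crypts (>= 2).
#' @param n_shared Total shared (ancestral) mutations.
#' @param n_private Private mutations per crypt.
#' @param seed Integer seed.
#' @return List with `tree` (ape phylo), `branches` (branch table) and
#'   `branch_counts` (named mutation counts per branch; the root trunk is
#'   branch `"root"`). `sum(branch_counts) == n_shared + n_private * n_crypts`.
#' @export
simulate_lineage <- function(n_crypts, n_shared, n_private, seed = 1L) {
  if (n_crypts < 2) stop("config error: need at least 2 crypts", call. = FALSE)
  set.seed(seed)
  tips <- paste0("crypt", seq_len(n_crypts))
  tree <- random_topology(tips)
  br <- branch_table(tree)
  internal <- c("root", br$branch[!br$terminal])
  counts <- stats::setNames(numeric(length(internal) + sum(br$terminal)),
                            c(internal, br$branch[br$terminal]))
  if (n_shared > 0) {
    alloc <- stats::rmultinom(1, n_shared, rep(1, length(internal)))[, 1]
    counts[internal] <- alloc
  }
  counts[as.character(br$branch[br$terminal])] <- n_private
  list(tree = tree, branches = br, branch_counts = counts)
}

# Timed lineage used by simulate_cohort: internal node times uniform in
# (0, 1 - private_fraction) of the lifetime, tips at 1. Each tip's
# root-to-tip durations sum to exactly 1, so branch-wise Poisson mutation
# counts give each crypt a Poisson(age * rate) total burden.
timed_lineage <- function(n_crypts, private_fraction) {
  tips <- paste0("crypt", seq_len(n_crypts))
  if (n_crypts == 1) {
    return(list(tree = NULL,
                branches = data.frame(branch = 1L, terminal = TRUE),
                durations = stats::setNames(1, "1"),
                clades = list(`1` = tips), tips = tips))
  }
  tree <- random_topology(tips)
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  times <- numeric(n_node)
  root <- n_tip + 1L
  internal <- setdiff(unique(tree$edge[, 1]), integer(0))
  depths <- node_depths(tree)
  for (nd in internal[order(depths[internal])]) {
    times[nd] <- if (nd == root) 0 else
      stats::runif(1, times[parent_of(tree, nd)], 1 - private_fraction)
  }
  times[seq_len(n_tip)] <- 1
  child <- tree$edge[, 2]
  durations <- times[child] - times[tree$edge[, 1]]
  clades <- lapply(child, function(nd) tree$tip.label[phangorn_free_descendants(tree, nd)])
  names(durations) <- as.character(child)
  names(clades) <- as.character(child)
  list(tree = tree,
       branches = data.frame(branch = child, terminal = child <= n_tip),
       durations = durations, clades = clades, tips = tree$tip.label)
}

node_depths <- function(tree) {
  n_node <- max(tree$edge)
  depth <- rep(0L, n_node)
  ord <- tree$edge[order(match(tree$edge[, 1], tree$edge[, 1])), , drop = FALSE]
  # edges in preorder: parent always seen before child after reorder
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(tr$edge))) {
    depth[tr$edge[k, 2]] <- depth[tr$edge[k, 1]] + 1L
  }
  depth
}

parent_of <- function(tree, node) tree$edge[tree$edge[, 2] == node, 1]

draw_contexts <- function(n, mixture, signatures) {
  if (n == 0) return(list(sig = character(0), channel = integer(0)))
  sig <- sample(names(mixture), n, replace = TRUE, prob = mixture)
  channel <- vapply(sig, function(s) {
    sample.int(96L, 1L, prob = as.numeric(signatures[[s]]))
  }, integer(1))
  list(sig = unname(sig), channel = unname(channel))
}

channel_context <- function(idx) {
  labs <- sbs_channels()[idx]
  trinuc <- paste0(substr(labs, 1, 1), substr(labs, 3, 3), substr(labs, 7, 7))
  alt <- substr(labs, 5, 5)
  list(trinuc = trinuc, ref = substr(labs, 3, 3), alt = alt)
}

#' Simulate a clonal-crypt cohort
#'
#' Generates a full synthetic cohort under a [cohort_config()]: per-patient
#' lineage trees with long terminal branches, per-crypt true SBS burdens
#' distributed Poisson(age x patient rate), mutation contexts drawn from the
#' patient's signature mixture, shared germline and early-embryonic variants
#' at VAF 0.5, clonal somatic variants at the configured clonality VAF, and
#' read counts NR ~ Poisson(mean coverage), NV ~ Binomial(NR, VAF).
#'
#' @param config A [cohort_config()].
#' @return List with elements `pileup` (a [pileup_matrix()]), `metadata`
#'   (per-sample data.frame: sample, patient, genotype, age, tissue,
#'   mean_coverage, median_vaf), and `truth` (list: `variants` with one row
#'   per pileup row carrying class/signature/branch/patient, `burden` with
#'   per-crypt true SBS and indel burdens, `trees` per patient,
#'   `patient_rates`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  sigs <- config$signatures

  trees <- list(); rates <- list()
  all_samples <- character(0)
  pos_counter <- 0L

  per_patient <- lapply(config$patients, function(p) {
    rate_p <- max(0, p$rate_per_year + stats::rnorm(1, 0, p$rate_sd_patient))
    samples <- paste0(p$id, "_crypt", seq_len(p$n_crypts))
    lin <- if (p$n_crypts >= 2) timed_lineage(p$n_crypts, config$private_fraction) else NULL

    # somatic mutations branch by branch
    som <- list()
    if (!is.null(lin)) {
      for (b in names(lin$durations)) {
        n_b <- stats::rpois(1, p$age * rate_p * lin$durations[[b]])
        if (n_b == 0) next
        carriers <- paste0(p$id, "_", lin$clades[[b]])
        terminal <- length(lin$clades[[b]]) == 1L
        som[[b]] <- list(n = n_b, carriers = carriers, branch = b,
                         class = if (terminal) "somatic-private" else "somatic-shared")
      }
      tree <- lin$tree
      tree$tip.label <- paste0(p$id, "_", tree$tip.label)
    } else {
      n_b <- stats::rpois(1, p$age * rate_p)
      if (n_b > 0)
        som[["1"]] <- list(n = n_b, carriers = samples, branch = "1",
                           class = "somatic-private")
      tree <- NULL
    }

    # embryonic shared variants on internal branches (subset of crypts)
    emb <- NULL
    if (config$n_embryonic_shared > 0 && !is.null(lin)) {
      internal <- names(lin$durations)[!lin$branches$terminal]
      if (length(internal) > 0) {
        pick <- sample(internal, config$n_embryonic_shared, replace = TRUE)
        emb <- pick
      }
    }

    id_burden <- stats::rpois(p$n_crypts, p$age * config$indel_rate_per_year)

    list(spec = p, rate = rate_p, samples = samples, lineage = lin, tree = tree,
         somatic = som, embryonic = emb, id_burden = id_burden)
  })

  # assemble variants
  variants <- list(); truth <- list(); carriers_of <- list(); vaf_of <- list()
  patient_of_sample <- character(0)
  for (pp in per_patient) {
    p <- pp$spec
    all_samples <- c(all_samples, pp$samples)
    patient_of_sample <- c(patient_of_sample,
                           stats::setNames(rep(p$id, length(pp$samples)), pp$samples))

    add_variants <- function(n, class, branch, carriers, vaf, mixture) {
      if (n == 0) return()
      ctx <- draw_contexts(n, mixture, sigs)
      cc <- channel_context(ctx$channel)
      pos <- pos_counter + seq_len(n)
      pos_counter <<- pos_counter + n
      variants[[length(variants) + 1L]] <<- data.frame(
        chrom = "1", pos = pos, ref = cc$ref, alt = cc$alt, trinuc = cc$trinuc,
        asmd = 145, clpm = 0, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <<- data.frame(
        patient = p$id, class = class, signature = ctx$sig, branch = branch,
        stringsAsFactors = FALSE)
      carriers_of[[length(carriers_of) + 1L]] <<- replicate(n, carriers, simplify = FALSE)
      vaf_of[[length(vaf_of) + 1L]] <<- rep(vaf, n)
    }

    flat <- c(SBS5like = 1)
    add_variants(config$n_germline, "germline", NA_character_, pp$samples, 0.5, flat)
    if (!is.null(pp$embryonic)) {
      for (b in pp$embryonic) {
        carriers <- paste0(p$id, "_", pp$lineage$clades[[b]])
        add_variants(1L, "embryonic", b, carriers, 0.5, flat)
      }
    }
    for (s in pp$somatic) {
      add_variants(s$n, s$class, s$branch, s$carriers, config$clonality_vaf,
                   p$signature_mixture)
    }

    trees[[p$id]] <- pp$tree
    rates[[p$id]] <- pp$rate
  }

  variants <- do.call(rbind, variants)
  truth <- do.call(rbind, truth)
  carriers_of <- do.call(c, carriers_of)
  vaf_of <- do.call(c, vaf_of)
  n_var <- nrow(variants)
  n_smp <- length(all_samples)

  # read counts: depth Poisson, variant reads Binomial(depth, vaf)
  NR <- matrix(stats::rpois(n_var * n_smp, config$mean_coverage),
               nrow = n_var, ncol = n_smp, dimnames = list(NULL, all_samples))
  vaf_mat <- matrix(0, n_var, n_smp, dimnames = list(NULL, all_samples))
  for (i in seq_len(n_var)) vaf_mat[i, carriers_of[[i]]] <- vaf_of[i]
  # a variant is only observable in samples of its own patient; other
  # patients' sites carry reference reads only
  NV <- matrix(stats::rbinom(n_var * n_smp, as.vector(NR), as.vector(vaf_mat)),
               nrow = n_var, ncol = n_smp, dimnames = list(NULL, all_samples))

  pileup <- pileup_matrix(variants, NV, NR)
  truth$variant <- variant_ids(variants)
  truth <- truth[, c("variant", "patient", "class", "signature", "branch")]

  metadata <- do.call(rbind, lapply(per_patient, function(pp) {
    data.frame(sample = pp$samples, patient = pp$spec$id,
               genotype = pp$spec$genotype, age = pp$spec$age,
               tissue = "intestine", mean_coverage = config$mean_coverage,
               median_vaf = config$clonality_vaf, stringsAsFactors = FALSE)
  }))
  rownames(metadata) <- NULL

  burden <- do.call(rbind, lapply(per_patient, function(pp) {
    true_sbs <- vapply(pp$samples, function(s) {
      sum(vapply(pp$somatic, function(b) {
        if (s %in% b$carriers) b$n else 0L
      }, numeric(1)))
    }, numeric(1))
    data.frame(sample = pp$samples, patient = pp$spec$id,
               genotype = pp$spec$genotype, age = pp$spec$age,
               true_sbs_burden = unname(true_sbs),
               true_id_burden = pp$id_burden, stringsAsFactors = FALSE)
  }))
  rownames(burden) <- NULL

  list(pileup = pileup, metadata = metadata,
       truth = list(variants = truth, burden = burden, trees = trees,
                    patient_rates = unlist(rates)))
}

#' Simulate crypt burdens only
#'
#' Lightweight generator for rate-modelling studies: per-crypt true burdens
#' Poisson(age x patient rate) with truncated-Normal patient-level rate
#' heterogeneity, skipping read-level simulation.
#'
#' @inheritParams simulate_cohort
#' @param rate_field `"sbs"` to use each patient's `rate_per_year`, `"id"`
#'   to use the cohort indel rate.
#' @return data.frame of [fit_burden_lme()]-ready observations with columns
#'   sample, patient, genotype, age, burden.
#' @export
simulate_burdens <- function(config, rate_field = c("sbs", "id")) {
  stopifnot(inherits(config, "cohort_config"))
  rate_field <- match.arg(rate_field)
  set.seed(config$seed)
  do.call(rbind, lapply(config$patients, function(p) {
    base <- if (rate_field == "sbs") p$rate_per_year else config$indel_rate_per_year
    rate_p <- max(0, base + stats::rnorm(1, 0, p$rate_sd_patient))
    data.frame(sample = paste0(p$id, "_crypt", seq_len(p$n_crypts)),
               patient = p$id, genotype = p$genotype, age = p$age,
               burden = stats::rpois(p$n_crypts, p$age * rate_p),
               stringsAsFactors = FALSE)
  }))
}

#' Simulate a duplex-sequencing catalogue
#'
#' Allocates interrogated pyrimidine-context bases over the 32 trinucleotide
#' contexts by the experimental frequencies and draws substitution counts so
#' that the trinucleotide-normalised corrected burden is an unbiased
#' estimate of `true_rate_per_base`: in context `i` with genomic frequency
#' `f_i^g`, substitution `j` is drawn Poisson(t_i x rate x m_ij / f_i^g)
#' where `m` is the signature-mixture channel distribution.
#'
#' @param true_rate_per_base Genomic per-base mutation rate.
#' @param genomic_trinuc_freqs,experimental_trinuc_freqs Length-32 frequency
#'   vectors, each summing to 1.
#' @param total_duplex_bases Total interrogated duplex bases (> 0).
#' @param signature_mixture Named weights over the cohort signature set.
#' @param signatures Named list of signature profiles.
#' @param seed Integer seed.
#' @return A [duplex_catalogue()] (uncorrected; pass to
#'   [correct_catalogue()]).
#' @export
simulate_duplex <- function(true_rate_per_base, genomic_trinuc_freqs,
                            experimental_trinuc_freqs, total_duplex_bases,
                            signature_mixture = c(SBS18like = 1),
                            signatures = fixture_signatures(), seed = 1L) {
  check_freqs <- function(f, what) {
    if (length(f) != 32) stop("config error: ", what, " must have length 32", call. = FALSE)
    if (abs(sum(f) - 1) > 1e-6) stop("config error: ", what, " must sum to 1", call. = FALSE)
  }
  check_freqs(genomic_trinuc_freqs, "genomic_trinuc_freqs")
  check_freqs(experimental_trinuc_freqs, "experimental_trinuc_freqs")
  if (total_duplex_bases <= 0) stop("empty catalogue: total_duplex_bases must be > 0", call. = FALSE)
  set.seed(seed)

  mix <- rep(0, 96)
  for (s in names(signature_mixture))
    mix <- mix + signature_mixture[[s]] * as.numeric(signatures[[s]])
  mix <- mix / sum(mix)
  m_ctx <- channel_context_matrix(mix)   # 32 x 3

  t_i <- as.vector(stats::rmultinom(1, round(total_duplex_bases),
                                    experimental_trinuc_freqs))
  names(t_i) <- trinuc_contexts()
  lam <- t_i * true_rate_per_base * m_ctx / genomic_trinuc_freqs
  lam[genomic_trinuc_freqs == 0, ] <- 0
  s_ij <- matrix(stats::rpois(length(lam), as.vector(lam)), nrow = 32,
                 dimnames = dimnames(m_ctx))
  duplex_catalogue(t = t_i, s = s_ij, f_genome = genomic_trinuc_freqs)
}

#' The 32 pyrimidine-centred trinucleotide contexts in canonical order
#'
#' @return Character vector of length 32 (`ACA` ... `TTT`), C contexts first.
#' @export
trinuc_contexts <- function() {
  out <- character(0)
  for (ref in c("C", "T")) for (p5 in BASES) for (p3 in BASES)
    out <- c(out, paste0(p5, ref, p3))
  out
}

# Fold a 96-channel vector into a 32 x 3 (context x substitution-class)
# matrix following the canonical orderings.
channel_context_matrix <- function(x) {
  stopifnot(length(x) == 96)
  m <- matrix(0, 32, 3, dimnames = list(trinuc_contexts(), c("toA", "toB", "toC")))
  for (k in 1:96) {
    cls <- (k - 1) %/% 16 + 1          # 1..6
    ctx16 <- (k - 1) %% 16 + 1         # 1..16
    ref_t <- cls > 3
    i <- ctx16 + if (ref_t) 16 else 0
    j <- if (ref_t) cls - 3 else cls
    m[i, j] <- m[i, j] + x[k]
  }
  colnames(m) <- c("j1", "j2", "j3")
  m
}
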