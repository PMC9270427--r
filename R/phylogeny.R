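# Per-patient crypt phylogenies: Camin-Sokal maximum parsimony (mutations
# are irreversible 0 -> 1 characters), exact by branch-and-bound stepwise
# addition at small sample numbers, and maximum-likelihood assignment of
# mutations to branches from the read counts.

#' Binary genotype matrix from a pileup
#'
#' Presence rule: a variant is present in a sample when `NV >= min_nv` and
#' `NV/NR >= min_vaf`. Variants absent from every sample are removed.
#'
#' @param pileup A [pileup_matrix()].
#' @param min_nv Minimum variant reads (default 3).
#' @param min_vaf Minimum VAF (default 0.2).
#' @return Binary integer matrix variants x samples, rownames = variant ids.
#' @export
genotype_matrix <- function(pileup, min_nv = 3, min_vaf = 0.2) {
  vaf <- pileup$NV / pmax(pileup$NR, 1)
  G <- (pileup$NV >= min_nv & vaf >= min_vaf) * 1L
  G[rowSums(G) > 0, , drop = FALSE]
}

# ---- Camin-Sokal scoring ----------------------------------------------------

# Tree representation during search: nested list; a tip is a character
# scalar, an internal node is list(left, right).

tree_tips <- function(node) {
  if (is.character(node)) node else c(tree_tips(node[[1]]), tree_tips(node[[2]]))
}

# Cost of one presence pattern (character vector of tip names carrying the
# mutation) on a tree: the minimal number of irreversible 0->1 changes,
# i.e. the number of maximal clades wholly contained in the pattern.
# Returns list(cost, covered) where covered means the whole subtree is in S.
pattern_cost <- function(node, s) {
  if (is.character(node)) {
    inS <- node %in% s
    return(list(cost = as.integer(inS), covered = inS))
  }
  l <- pattern_cost(node[[1]], s)
  r <- pattern_cost(node[[2]], s)
  if (l$covered && r$covered) list(cost = 1L, covered = TRUE)
  else list(cost = l$cost + r$cost, covered = FALSE)
}

tree_score <- function(tree, patterns, weights) {
  total <- 0
  for (k in seq_along(patterns)) {
    total <- total + weights[k] * pattern_cost(tree, patterns[[k]])$cost
  }
  total
}

# All ways to insert a new tip into a rooted tree: on every edge, plus as a
# new sister of the whole tree (above the root).
insert_tip <- function(node, tip) {
  placements <- list(list(node, tip))       # above the root
  recurse <- function(nd) {
    if (is.character(nd)) return(list())
    res <- list()
    for (side in 1:2) {
      other <- nd[[3 - side]]
      # insert on the edge above nd[[side]]
      res <- c(res, lapply(insert_edge(nd[[side]], tip), function(sub) {
        if (side == 1) list(sub, other) else list(other, sub)
      }))
    }
    res
  }
  c(placements, recurse(node))
}

insert_edge <- function(node, tip) {
  here <- list(list(node, tip))
  if (is.character(node)) return(here)
  below <- list()
  for (side in 1:2) {
    other <- node[[3 - side]]
    below <- c(below, lapply(insert_edge(node[[side]], tip), function(sub) {
      if (side == 1) list(sub, other) else list(other, sub)
    }))
  }
  c(here, below)
}

tree_to_newick <- function(node) {
  if (is.character(node)) return(node)
  paste0("(", tree_to_newick(node[[1]]), ",", tree_to_newick(node[[2]]), ")")
}

#' Exact maximum-parsimony tree under irreversible mutations
#'
#' Finds the rooted binary topology minimising the Camin-Sokal parsimony
#' score (each mutation arises once per required origin and never reverts).
#' Exact branch-and-bound stepwise addition is used up to `exact_max`
#' samples; beyond that an average-linkage agglomerative topology on
#' Hamming distances is returned. Tips are added in lexicographic order and
#' only strictly better trees replace the incumbent, so ties break
#' deterministically.
#'
#' @param genotypes Binary matrix variants x samples (see
#'   [genotype_matrix()]).
#' @param exact_max Largest sample count for the exact search (default 12).
#' @return An ape `phylo` rooted tree with attribute `parsimony_score`.
#' @export
build_parsimony_tree <- function(genotypes, exact_max = 12L) {
  samples <- colnames(genotypes)
  if (is.null(samples) || length(samples) < 2)
    stop("need at least 2 samples to build a tree", call. = FALSE)

  G <- genotypes[rowSums(genotypes) > 0, , drop = FALSE]
  pat_key <- apply(G, 1, paste, collapse = "")
  tab <- table(pat_key)
  patterns <- lapply(names(tab), function(k) {
    samples[strsplit(k, "")[[1]] == "1"]
  })
  weights <- as.numeric(tab)

  tips <- sort(samples)
  if (length(tips) <= exact_max) {
    best <- NULL
    best_score <- Inf
    grow <- function(tree, added) {
      score_now <- tree_score(tree, patterns_restrict(patterns, added), weights)
      if (score_now >= best_score) return()
      if (length(added) == length(tips)) {
        best <<- tree; best_score <<- score_now
        return()
      }
      nxt <- tips[length(added) + 1L]
      for (cand in insert_tip(tree, nxt)) grow(cand, c(added, nxt))
    }
    grow(list(tips[1], tips[2]), tips[1:2])
    tree <- ape::read.tree(text = paste0(tree_to_newick(best), ";"))
    score <- best_score
  } else {
    d <- stats::dist(t(G), method = "manhattan")
    hc <- stats::hclust(d, method = "average")
    tree <- ape::as.phylo(hc)
    tree$edge.length <- NULL
    tree <- ape::multi2di(tree)
    score <- tree_score(phylo_to_nested(tree), patterns, weights)
  }
  attr(tree, "parsimony_score") <- score
  tree
}

patterns_restrict <- function(patterns, added) {
  lapply(patterns, function(s) intersect(s, added))
}

phylo_to_nested <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  build <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (length(kids) != 2) stop("tree must be binary", call. = FALSE)
    list(build(kids[1]), build(kids[2]))
  }
  build(root)
}

#' Parsimony score of a given tree (utility for oracles and reports)
#'
#' @param tree Rooted binary ape `phylo`.
#' @param genotypes Binary matrix variants x samples.
#' @return Camin-Sokal parsimony score.
#' @export
parsimony_score <- function(tree, genotypes) {
  samples <- colnames(genotypes)
  G <- genotypes[rowSums(genotypes) > 0, , drop = FALSE]
  nested <- phylo_to_nested(tree)
  pat_key <- apply(G, 1, paste, collapse = "")
  tab <- table(pat_key)
  patterns <- lapply(names(tab), function(k) samples[strsplit(k, "")[[1]] == "1"])
  tree_score(nested, patterns, as.numeric(tab))
}

# ---- ML branch assignment ---------------------------------------------------

#' Enumerate branches of a rooted tree with their descendant samples
#'
#' Includes a `"root"` trunk branch whose clade is every tip (mutations
#' shared by all samples map there).
#'
#' @param tree Rooted ape `phylo`.
#' @return data.frame with columns branch (character), terminal (logical)
#'   and a list-column `clade` of tip labels.
#' @export
tree_branches <- function(tree) {
  n_tip <- length(tree$tip.label)
  child <- tree$edge[, 2]
  clades <- lapply(child, function(nd) tree$tip.label[phangorn_free_descendants(tree, nd)])
  df <- data.frame(branch = c(as.character(child), "root"),
                   terminal = c(child <= n_tip, FALSE),
                   stringsAsFactors = FALSE)
  df$clade <- c(clades, list(tree$tip.label))
  df
}

#' Maximum-likelihood assignment of mutations to tree branches
#'
#' For each mutation, each branch `b` implies an expected VAF vector:
#' `clonality_vaf` in samples descended from `b`, `error_rate` elsewhere.
#' The branch maximising the product of per-sample binomial read-count
#' likelihoods is chosen, with its posterior probability under a uniform
#' branch prior.
#'
#' @param tree Rooted ape `phylo` whose tips match the pileup samples.
#' @param pileup A [pileup_matrix()] of somatic variants.
#' @param clonality_vaf Expected VAF in carrying samples (default 0.5).
#' @param error_rate Expected false-positive VAF elsewhere (default 0.01).
#' @return data.frame: variant, branch, prob; mutations with zero depth in
#'   every sample get branch `NA` (unassigned).
#' @export
assign_mutations_ml <- function(tree, pileup, clonality_vaf = 0.5,
                                error_rate = 0.01) {
  smp <- tree$tip.label
  if (!all(smp %in% pileup$samples))
    stop("tree tips must match pileup samples", call. = FALSE)
  NV <- pileup$NV[, smp, drop = FALSE]
  NR <- pileup$NR[, smp, drop = FALSE]
  br <- tree_branches(tree)

  A <- stats::dbinom(NV, NR, clonality_vaf, log = TRUE)
  B <- stats::dbinom(NV, NR, error_rate, log = TRUE)
  D <- A - B
  baseline <- rowSums(B)
  ll <- vapply(seq_len(nrow(br)), function(k) {
    baseline + rowSums(D[, smp %in% br$clade[[k]], drop = FALSE])
  }, numeric(nrow(NV)))
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1)

  pick <- max.col(ll, ties.method = "first")
  m <- apply(ll, 1, max)
  prob <- exp(m - m) / rowSums(exp(ll - m))   # softmax at the max
  ids <- variant_ids(pileup$variants)
  out <- data.frame(variant = ids, branch = br$branch[pick],
                    prob = prob, stringsAsFactors = FALSE)
  dead <- rowSums(NR) == 0
  out$branch[dead] <- NA_character_
  out$prob[dead] <- NA_real_
  out
}

#' Per-branch mutation catalogues for signature analysis
#'
#' Groups assigned mutations by branch, drops branches with fewer than
#' `min_branch` mutations, subsamples branches uniformly without
#' replacement to at most `max_per_branch`, and builds a 96-channel
#' spectrum per branch.
#'
#' @param assignments Output of [assign_mutations_ml()].
#' @param pileup The pileup the assignments refer to (source of
#'   trinucleotide contexts).
#' @param max_per_branch Subsampling cap (default 2500).
#' @param min_branch Minimum branch size retained (default 100).
#' @param seed Integer seed for the subsampling.
#' @param label_prefix Prefix for catalogue labels.
#' @return List of catalogues: each has branch, spectrum (a
#'   [build_spectrum()] vector), n_total (pre-subsampling count).
#' @export
branch_catalogues <- function(assignments, pileup, max_per_branch = 2500,
                              min_branch = 100, seed = 1L,
                              label_prefix = "branch") {
  set.seed(seed)
  ids <- variant_ids(pileup$variants)
  keep <- !is.na(assignments$branch)
  split_idx <- split(match(assignments$variant[keep], ids),
                     assignments$branch[keep])
  out <- list()
  for (b in names(split_idx)) {
    idx <- split_idx[[b]]
    n_total <- length(idx)
    if (n_total < min_branch) {
      message("branch ", b, " excluded: ", n_total, " < ", min_branch, " mutations")
      next
    }
    if (n_total > max_per_branch) idx <- sample(idx, max_per_branch)
    v <- pileup$variants[idx, ]
    spec <- build_spectrum(v$trinuc, v$alt, label = paste0(label_prefix, "_", b))
    out[[b]] <- list(branch = b, spectrum = spec, n_total = n_total)
  }
  out
}

#' Write a tree with branch lengths equal to assigned mutation counts
#'
#' @param tree Rooted ape `phylo`.
#' @param assignments Output of [assign_mutations_ml()].
#' @param path Newick output path.
#' @export
write_branch_newick <- function(tree, assignments, path) {
  counts <- table(assignments$branch)
  child <- as.character(tree$edge[, 2])
  tree$edge.length <- as.numeric(counts[child])
  tree$edge.length[is.na(tree$edge.length)] <- 0
  ape::write.tree(tree, file = path)
  invisible(path)
}
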