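# Independent oracles used across the suite. These deliberately re-derive
# quantities by different routes from the implementation.

# --- rooted-tree enumeration + Sankoff scoring for irreversible characters ---

# All rooted binary topologies over the given tips, as nested lists
# (tip = character scalar, node = list(left, right)).
all_rooted_topologies <- function(tips) {
  if (length(tips) == 1) return(list(tips[1]))
  if (length(tips) == 2) return(list(list(tips[1], tips[2])))
  rest <- all_rooted_topologies(tips[-length(tips)])
  tip <- tips[length(tips)]
  out <- list()
  for (tr in rest) out <- c(out, attach_everywhere(tr, tip))
  out
}

attach_everywhere <- function(node, tip) {
  res <- list(list(node, tip))   # above this (sub)tree
  if (is.list(node)) {
    for (side in 1:2) {
      subs <- attach_everywhere(node[[side]], tip)
      other <- node[[3 - side]]
      res <- c(res, lapply(subs, function(s) {
        if (side == 1) list(s, other) else list(other, s)
      }))
    }
  }
  res
}

# Minimal number of 0->1 changes for one presence pattern on a nested tree,
# by Sankoff dynamic programming with an irreversible cost matrix
# (1 -> 0 transitions forbidden, root constrained to state 0).
sankoff_irreversible <- function(node, present) {
  dp <- function(nd) {
    if (is.character(nd)) {
      if (nd %in% present) c(Inf, 0) else c(0, Inf)   # cost of (state0, state1)
    } else {
      l <- dp(nd[[1]]); r <- dp(nd[[2]])
      edge <- function(child, s) {
        # min over child state t of transition(s -> t) + child cost
        if (s == 1) child[2] else min(child[1], child[2] + 1)
      }
      c(edge(l, 0) + edge(r, 0), edge(l, 1) + edge(r, 1))
    }
  }
  v <- dp(node)
  # the tree has a stem above the root: a change there (cost 1) puts the
  # root in state 1, covering mutations carried by every sample
  min(v[1], v[2] + 1)
}

oracle_parsimony_min <- function(genotypes) {
  samples <- colnames(genotypes)
  topos <- all_rooted_topologies(samples)
  patterns <- apply(genotypes, 1, function(row) samples[row == 1], simplify = FALSE)
  scores <- vapply(topos, function(tr) {
    sum(vapply(patterns, function(s) {
      if (length(s) == 0) 0 else sankoff_irreversible(tr, s)
    }, numeric(1)))
  }, numeric(1))
  min(scores)
}

# --- NNLS on the simplex, the oracle for EM signature decomposition ---------

nnls_simplex_weights <- function(component, references) {
  S <- do.call(cbind, lapply(references, as.numeric))
  S <- sweep(S, 2, colSums(S), "/")
  m <- as.numeric(component); m <- m / sum(m)
  w <- pracma::lsqnonneg(S, m)$x
  w / sum(w)
}

# --- small simulation helpers ------------------------------------------------

draw_spectrum_from <- function(profile, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tabulate(sample.int(length(profile), n, replace = TRUE,
                      prob = as.numeric(profile)), length(profile))
}

mixture_profile <- function(weights, signatures) {
  out <- 0
  for (nm in names(weights)) out <- out + weights[[nm]] * as.numeric(signatures[[nm]])
  out / sum(out)
}

# clade-label map from the package's own branch table
clade_strings_pkg <- function(tree) {
  tb <- tree_branches(tree)
  stats::setNames(vapply(tb$clade, function(x) paste(sort(x), collapse = "+"),
                         character(1)), tb$branch)
}

# clade-label maps used to compare branch assignments against truth trees
clade_strings <- function(tree) {
  ch <- tree$edge[, 2]
  n_tip <- length(tree$tip.label)
  desc <- function(nd) {
    if (nd <= n_tip) return(nd)
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    unlist(lapply(kids, desc))
  }
  out <- vapply(ch, function(nd) paste(sort(tree$tip.label[desc(nd)]), collapse = "+"),
                character(1))
  stats::setNames(out, as.character(ch))
}
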