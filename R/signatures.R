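# De novo mutational-signature extraction by KL non-negative matrix
# factorisation, expectation-maximisation decomposition of components into
# reference signatures, and constrained per-sample exposure refitting with
# pruning of minor signatures.

#' De novo signature extraction by KL-divergence NMF
#'
#' Factorises the catalogue matrix `V` (channels x samples) as `W H` with
#' multiplicative updates minimising the generalised Kullback-Leibler
#' divergence. The best of `restarts` seeded random initialisations is
#' kept. Convergence when the relative divergence change falls below `tol`
#' or after `max_iter` iterations. Exposures are rescaled so each sample's
#' reconstruction total equals its input total.
#'
#' @param catalogues List of spectra (equal-length non-negative vectors) or
#'   a channels x samples matrix.
#' @param k Number of signatures to extract (>= 1).
#' @param restarts Number of random restarts (default 5).
#' @param seed Integer seed.
#' @param max_iter Maximum iterations per restart (default 10000).
#' @param tol Relative divergence-change convergence tolerance
#'   (default 1e-6).
#' @return List of class `signature_set`: `signatures` (channels x k matrix
#'   of unit-sum profiles), `exposures` (samples x k, absolute counts),
#'   `divergence` (final KL divergence), `divergence_trace` of the winning
#'   restart.
#' @export
extract_denovo <- function(catalogues, k, restarts = 5, seed = 1L,
                           max_iter = 10000, tol = 1e-6) {
  V <- if (is.list(catalogues)) {
    do.call(cbind, lapply(catalogues, as.numeric))
  } else as.matrix(catalogues)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > ncol(V)) stop("k exceeds the number of catalogues", call. = FALSE)
  set.seed(seed)

  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- nmf_kl_once(V, k, max_iter, tol)
    if (is.null(best) || fit$divergence < best$divergence) best <- fit
  }
  W <- best$W; H <- best$H
  # normalise profiles to sum 1, push scale into H
  scale <- colSums(W)
  W <- sweep(W, 2, scale, "/")
  H <- H * scale
  # exact per-sample count conservation
  recon <- W %*% H
  H <- sweep(H, 2, colSums(V) / pmax(colSums(recon), 1e-300), "*")
  colnames(W) <- rownames(H) <- paste0("N", seq_len(k))
  if (!is.null(rownames(V))) rownames(W) <- rownames(V)
  exposures <- t(H)
  rownames(exposures) <- colnames(V) %||% paste0("sample", seq_len(ncol(V)))
  structure(list(signatures = W, exposures = exposures, divergence = best$divergence,
                 divergence_trace = best$trace),
            class = "signature_set")
}

nmf_kl_once <- function(V, k, max_iter, tol) {
  n <- nrow(V); m <- ncol(V)
  W <- matrix(stats::runif(n * k, 0.1, 1), n, k)
  H <- matrix(stats::runif(k * m, 0.1, 1), k, m)
  eps <- 1e-12
  kl <- function(WH) sum(V * log((V + eps) / (WH + eps)) - V + WH)
  WH <- W %*% H
  d_prev <- kl(WH)
  trace <- d_prev
  for (it in seq_len(max_iter)) {
    # H update
    H <- H * (t(W) %*% (V / (WH + eps))) / pmax(colSums(W), eps)
    WH <- W %*% H
    # W update
    W <- W * ((V / (WH + eps)) %*% t(H)) / matrix(rowSums(H), nrow(W), k, byrow = TRUE)
    WH <- W %*% H
    d <- kl(WH)
    trace <- c(trace, d)
    if (abs(d_prev - d) < tol * max(d_prev, eps)) break
    d_prev <- d
  }
  list(W = W, H = H, divergence = d, trace = trace)
}

#' Decompose a de novo component into reference signatures
#'
#' Expectation-maximisation over mixture weights `w`:
#' `w_r <- w_r * sum_c S_rc m_c / sum_j w_j S_jc` (normalised each step),
#' where `S` holds the reference profiles and `m` the component. The
#' decomposition is accepted when the cosine similarity between the
#' reconstruction and the component reaches `acceptance_cosine`; components
#' failing it should be retained in their de novo form.
#'
#' @param component A signature profile (non-negative, will be normalised).
#' @param references Named list of reference profiles.
#' @param acceptance_cosine Acceptance threshold (default 0.95).
#' @param max_iter,tol EM iteration controls.
#' @return List of class `decomposition`: weights (named, sum 1),
#'   reconstruction cosine `cosine`, `accepted` flag.
#' @export
decompose_to_reference <- function(component, references,
                                   acceptance_cosine = 0.95,
                                   max_iter = 5000, tol = 1e-10) {
  if (length(references) == 0) stop("empty reference set", call. = FALSE)
  m <- as.numeric(component); m <- m / sum(m)
  S <- do.call(cbind, lapply(references, as.numeric))   # channels x refs
  S <- sweep(S, 2, colSums(S), "/")
  w <- em_mixture_weights(m, S, max_iter, tol)
  names(w) <- names(references) %||% paste0("ref", seq_len(ncol(S)))
  recon <- as.numeric(S %*% w)
  cs <- cosine_similarity(recon, m)
  structure(list(weights = w, cosine = cs,
                 accepted = cs >= acceptance_cosine),
            class = "decomposition")
}

# EM for the mixture-of-categoricals weights; m must sum to 1, S columns too.
em_mixture_weights <- function(m, S, max_iter = 5000, tol = 1e-10) {
  k <- ncol(S)
  w <- rep(1 / k, k)
  eps <- 1e-300
  for (it in seq_len(max_iter)) {
    denom <- as.numeric(S %*% w)
    w_new <- w * as.numeric(t(S) %*% (m / (denom + eps)))
    w_new <- w_new / sum(w_new)
    if (sum(abs(w_new - w)) < tol) { w <- w_new; break }
    w <- w_new
  }
  w
}

#' Refit signature exposures with pruning of minor signatures
#'
#' Fits mixture weights of the allowed reference signatures to a spectrum
#' by EM, then iteratively removes the smallest signature whose exposure
#' fraction is below `min_exposure` and refits, until every surviving
#' signature is at or above the floor. Exposures are scaled to the
#' spectrum's mutation count. If pruning would remove every signature, the
#' single best-cosine signature is kept with a warning.
#'
#' @param spectrum A mutation-count spectrum.
#' @param allowed Named list of reference profiles the fit is restricted to.
#' @param min_exposure Minimum exposure fraction (default 0.10).
#' @param max_iter,tol EM controls.
#' @return List of class `exposure_fit`: `exposures` (named absolute
#'   counts summing to the spectrum total), `fractions`, `pruned` (names
#'   removed).
#' @export
refit_exposures <- function(spectrum, allowed, min_exposure = 0.10,
                            max_iter = 5000, tol = 1e-10) {
  if (length(allowed) == 0) stop("empty allowed signature set", call. = FALSE)
  total <- sum(spectrum)
  m <- as.numeric(spectrum)
  if (total <= 0) stop("empty spectrum", call. = FALSE)
  m <- m / total
  active <- names(allowed) %||% paste0("sig", seq_along(allowed))
  names(allowed) <- active
  pruned <- character(0)
  repeat {
    S <- do.call(cbind, lapply(allowed[active], as.numeric))
    S <- sweep(S, 2, colSums(S), "/")
    w <- em_mixture_weights(m, S, max_iter, tol)
    names(w) <- active
    if (all(w >= min_exposure) || length(active) == 1L) break
    drop <- names(which.min(w))
    pruned <- c(pruned, drop)
    active <- setdiff(active, drop)
  }
  if (length(active) == 1L && length(pruned) == length(allowed) - 1L &&
      w[1] < min_exposure) {
    warning("all signatures pruned; keeping single best-cosine signature")
    cs <- vapply(allowed, function(s) cosine_similarity(m, as.numeric(s)), numeric(1))
    active <- names(which.max(cs))
    w <- stats::setNames(1, active)
  }
  structure(list(exposures = w * total, fractions = w, pruned = pruned),
            class = "exposure_fit")
}

#' Write branch-by-signature exposures to TSV
#'
#' @param fits Named list of [refit_exposures()] results (one per
#'   branch/sample).
#' @param path Output path.
#' @return The path, invisibly. Columns are the union of signatures.
#' @export
write_exposures_tsv <- function(fits, path) {
  sigs <- sort(unique(unlist(lapply(fits, function(f) names(f$exposures)))))
  m <- t(vapply(fits, function(f) {
    out <- stats::setNames(numeric(length(sigs)), sigs)
    out[names(f$exposures)] <- f$exposures
    out
  }, numeric(length(sigs))))
  df <- data.frame(sample = names(fits), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
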