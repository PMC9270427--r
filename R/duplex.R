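# Duplex-sequencing burden normalisation: project substitution counts onto
# genomic trinucleotide frequencies and compute the corrected per-base
# mutation burden. The machinery is context-length-agnostic (32
# pyrimidine-centred trinucleotides in production; toy catalogues with
# fewer contexts behave identically).

#' Construct a duplex catalogue
#'
#' @param t Non-negative interrogated-base counts per trinucleotide context
#'   (length 32 in production).
#' @param s Substitution counts: a contexts x classes matrix (32 x 3 for
#'   the 96 channels) or a vector of one class per context.
#' @param f_genome Genomic trinucleotide frequencies (same length as `t`,
#'   summing to 1).
#' @return List of class `duplex_catalogue` (uncorrected; see
#'   [correct_catalogue()]).
#' @export
duplex_catalogue <- function(t, s, f_genome) {
  s <- if (is.matrix(s)) s else matrix(s, ncol = 1)
  stopifnot(length(t) == nrow(s), length(t) == length(f_genome), all(t >= 0),
            all(s >= 0))
  if (abs(sum(f_genome) - 1) > 1e-6)
    stop("f_genome must sum to 1", call. = FALSE)
  structure(list(t = t, s = s, f_genome = f_genome), class = "duplex_catalogue")
}

#' Trinucleotide frequencies from interrogated-base counts
#'
#' `f_i = t_i / sum(t)`.
#'
#' @param t Non-negative context counts with positive total.
#' @return Frequencies summing to 1.
#' @export
trinuc_frequencies <- function(t) {
  if (any(t < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(t)
  if (total == 0) stop("empty catalogue: sum of trinucleotide counts is 0", call. = FALSE)
  t / total
}

#' Correct a duplex catalogue onto genomic trinucleotide frequencies
#'
#' Computes the experimental frequencies `f^e` from `t`, the per-context
#' ratios `r_i = f_i^g / f_i^e`, the corrected substitution counts
#' `s'_ij = s_ij * r_i` (the substitution profile projected onto the
#' genome) and the corrected per-base burden
#' `beta' = sum(s') / sum(t)`.
#'
#' @param catalogue A [duplex_catalogue()].
#' @return The catalogue completed with `f_experiment`, `r`, `s_corrected`
#'   and `burden_corrected`.
#' @export
correct_catalogue <- function(catalogue) {
  stopifnot(inherits(catalogue, "duplex_catalogue"))
  t <- catalogue$t; s <- catalogue$s; fg <- catalogue$f_genome
  fe <- trinuc_frequencies(t)
  zero <- fe == 0
  if (any(zero & rowSums(s) > 0))
    stop("inconsistent catalogue: substitutions in a context with zero interrogated bases",
         call. = FALSE)
  r <- ifelse(zero, 0, fg / fe)
  s_corr <- s * r
  catalogue$f_experiment <- fe
  catalogue$r <- r
  catalogue$s_corrected <- s_corr
  catalogue$burden_corrected <- sum(s_corr) / sum(t)
  catalogue
}

#' Per-cell mutation burden from a per-base rate
#'
#' @param burden_per_base Corrected per-base burden (beta').
#' @param genome_size Diploid genome size in bases (default 6.2e9, two
#'   copies of ~3.1e9; the constant is configurable and recorded in
#'   outputs).
#' @return Mutations per cell.
#' @export
burden_per_cell <- function(burden_per_base, genome_size = 6.2e9) {
  if (genome_size <= 0) stop("genome_size must be > 0", call. = FALSE)
  burden_per_base * genome_size
}

#' Write a corrected duplex catalogue to TSV
#'
#' @param catalogue A corrected [duplex_catalogue()].
#' @param path Output path.
#' @export
write_duplex_tsv <- function(catalogue, path) {
  if (is.null(catalogue$r)) stop("catalogue not corrected; run correct_catalogue()", call. = FALSE)
  ctx <- names(catalogue$t) %||% paste0("ctx", seq_along(catalogue$t))
  df <- data.frame(context = ctx, t = catalogue$t,
                   f_genome = catalogue$f_genome,
                   f_experiment = catalogue$f_experiment, r = catalogue$r,
                   catalogue$s, s_corrected = catalogue$s_corrected,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat("# burden_corrected\t", format(catalogue$burden_corrected, digits = 12),
      "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}
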