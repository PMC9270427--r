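#' Construct a pileup matrix
#'
#' The substrate of filtering, phylogeny reconstruction and truth
#' evaluation: a table of variant sites with per-sample variant-supporting
#' (NV) and total (NR) read counts.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `trinuc`, and optionally artefact annotations `asmd` (median
#'   alignment score of mutant reads) and `clpm` (clipped mutant-read
#'   fraction).
#' @param NV,NR Integer matrices, variants x samples, with `0 <= NV <= NR`.
#' @return A `pileup` object.
#' @export
pileup_matrix <- function(variants, NV, NR) {
  NV <- as.matrix(NV); NR <- as.matrix(NR)
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)),
            nrow(variants) == nrow(NV), nrow(variants) == nrow(NR),
            identical(dim(NV), dim(NR)))
  if (any(NV < 0) || any(NV > NR))
    stop("pileup invariant violated: need 0 <= NV <= NR elementwise", call. = FALSE)
  if (is.null(colnames(NV))) colnames(NV) <- colnames(NR) <- paste0("S", seq_len(ncol(NV)))
  rownames(NV) <- rownames(NR) <- variant_ids(variants)
  structure(list(variants = variants, NV = NV, NR = NR,
                 samples = colnames(NV)), class = "pileup")
}

#' Stable variant identifiers
#'
#' `chrom_pos_ref_alt` strings used to link pileup rows to classification,
#' assignment and truth tables.
#'
#' @param variants Variant data.frame (see [pileup_matrix()]).
#' @return Character vector of ids.
#' @export
variant_ids <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = "_")
}

#' @exportS3Method print pileup
print.pileup <- function(x, ...) {
  cat("<pileup> ", nrow(x$variants), " variants x ", length(x$samples),
      " samples\n", sep = "")
  invisible(x)
}

#' @export
dim.pileup <- function(x) c(nrow(x$variants), length(x$samples))

#' Subset a pileup by variant and/or sample
#'
#' @param x A `pileup`.
#' @param i Variant index (logical or integer).
#' @param j Sample index.
#' @param ... Unused.
#' @export
`[.pileup` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$variants))
  if (missing(j)) j <- seq_along(x$samples)
  pileup_matrix(x$variants[i, , drop = FALSE],
                x$NV[i, j, drop = FALSE],
                x$NR[i, j, drop = FALSE])
}
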