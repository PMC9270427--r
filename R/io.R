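# Standard-format I/O for the pipeline: sites-only VCF 4.2 plus NV/NR
# count matrices as TSV, sample metadata TSV, and truth JSON. Coordinates
# are 1-based inclusive following VCF throughout.

#' Write a pileup as VCF sites + NV/NR TSV matrices
#'
#' @param pileup A [pileup_matrix()].
#' @param vcf_path Sites-only VCF 4.2 output path.
#' @param nv_path,nr_path TSV matrix output paths (rows = variant ids,
#'   columns = samples).
#' @export
write_pileup <- function(pileup, vcf_path, nv_path, nr_path) {
  v <- pileup$variants
  info <- paste0("TRI=", v$trinuc %||% ".",
                 ";ASMD=", v$asmd %||% ".", ";CLPM=", v$clpm %||% ".")
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=TRI,Number=1,Type=String,Description=\"Pyrimidine-strand trinucleotide context\">",
              "##INFO=<ID=ASMD,Number=1,Type=Float,Description=\"Median alignment score of mutant reads\">",
              "##INFO=<ID=CLPM,Number=1,Type=Float,Description=\"Clipped mutant-read fraction\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- paste(v$chrom, v$pos, variant_ids(v), v$ref, v$alt, ".", "PASS",
                info, sep = "\t")
  writeLines(c(header, body), vcf_path)
  utils::write.table(data.frame(variant = variant_ids(v), pileup$NV,
                                check.names = FALSE),
                     nv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(variant = variant_ids(v), pileup$NR,
                                check.names = FALSE),
                     nr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(vcf_path)
}

#' Read a pileup from VCF sites + NV/NR TSVs
#'
#' Multiallelic VCF rows are split into biallelic records; NV/NR rows are
#' matched to variants by id and must be dimension-consistent.
#'
#' @param vcf_path Sites VCF 4.2.
#' @param nv_path,nr_path NV/NR TSV matrices with a `variant` id column.
#' @return A [pileup_matrix()].
#' @export
read_pileup <- function(vcf_path, nv_path, nr_path) {
  lines <- readLines(vcf_path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) stop("format error: empty VCF", call. = FALSE)
  f <- strsplit(body, "\t", fixed = TRUE)
  n_fields <- lengths(f)
  if (any(n_fields < 8)) stop("format error: VCF row with fewer than 8 fields", call. = FALSE)
  rows <- lapply(f, function(x) {
    alts <- strsplit(x[5], ",", fixed = TRUE)[[1]]
    info <- parse_info(x[8])
    data.frame(chrom = x[1], pos = as.integer(x[2]), ref = x[4], alt = alts,
               trinuc = info[["TRI"]] %||% NA_character_,
               asmd = as.numeric(info[["ASMD"]] %||% NA),
               clpm = as.numeric(info[["CLPM"]] %||% NA),
               stringsAsFactors = FALSE)
  })
  variants <- do.call(rbind, rows)
  ids <- variant_ids(variants)

  read_counts <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, setdiff(names(df), "variant"), drop = FALSE])
    rownames(m) <- df$variant
    m
  }
  NV <- read_counts(nv_path); NR <- read_counts(nr_path)
  if (!setequal(rownames(NV), ids) || !setequal(rownames(NR), ids) ||
      !identical(colnames(NV), colnames(NR)))
    stop("format error: NV/NR matrices inconsistent with VCF rows (",
         nrow(NV), "/", nrow(NR), " rows vs ", length(ids), " variants)",
         call. = FALSE)
  pileup_matrix(variants, NV[ids, , drop = FALSE], NR[ids, , drop = FALSE])
}

parse_info <- function(x) {
  kv <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- lapply(kv, function(p) if (length(p) == 2) p[2] else TRUE)
  stats::setNames(vals, vapply(kv, `[[`, character(1), 1))
}

#' Write sample metadata to TSV
#' @param metadata Per-sample data.frame.
#' @param path Output path.
#' @export
write_metadata_tsv <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata TSV
#' @param path Metadata TSV.
#' @return data.frame.
#' @export
read_metadata_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
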