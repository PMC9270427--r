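BASES <- c("A", "C", "G", "T")
PYRIMIDINES <- c("C", "T")
SBS_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Canonical 96-channel substitution labels
#'
#' Returns the fixed channel ordering used throughout the package and by
#' COSMIC-style signature tables: the six pyrimidine substitution classes in
#' the order C>A, C>G, C>T, T>A, T>C, T>G, and within each class the sixteen
#' trinucleotide contexts ordered alphabetically by (5' base, 3' base).
#' Labels follow the `A[C>A]A` convention.
#'
#' @return Character vector of length 96.
#' @export
sbs_channels <- function() {
  out <- character(96)
  k <- 1L
  for (cls in SBS_CLASSES) {
    ref <- substr(cls, 1, 1)
    for (p5 in BASES) {
      for (p3 in BASES) {
        out[k] <- paste0(p5, "[", cls, "]", p3)
        k <- k + 1L
      }
    }
  }
  out
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of ACGT strings.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(x, ""), function(b) {
    if (!all(b %in% BASES)) stop("invalid sequence: non-ACGT base", call. = FALSE)
    paste(rev(unname(comp[b])), collapse = "")
  }, character(1))
}

#' Map a mutation to its 96-channel substitution class
#'
#' Purine-centred mutations are collapsed onto the pyrimidine strand by
#' reverse complement, so `channel_of` is invariant under strand flips.
#'
#' @param trinuc Character vector of 3-base reference contexts (mutated base
#'   in the middle).
#' @param alt Character vector of alternate bases.
#' @return Integer vector of channel indices in 1..96, named with the channel
#'   label (e.g. `A[C>T]G`).
#' @export
channel_of <- function(trinuc, alt) {
  trinuc <- toupper(trinuc)
  alt <- toupper(alt)
  stopifnot(length(trinuc) == length(alt))
  if (any(nchar(trinuc) != 3L)) stop("invalid sequence: trinucleotide must be 3 bases", call. = FALSE)
  chars <- cbind(substr(trinuc, 1, 1), substr(trinuc, 2, 2), substr(trinuc, 3, 3), alt)
  if (!all(chars %in% BASES)) stop("invalid sequence: non-ACGT base", call. = FALSE)
  if (any(chars[, 2] == alt)) stop("invalid mutation: alt equals reference base", call. = FALSE)

  flip <- !(chars[, 2] %in% PYRIMIDINES)
  if (any(flip)) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    trinuc[flip] <- reverse_complement(trinuc[flip])
    alt[flip] <- unname(comp[alt[flip]])
    chars[flip, ] <- cbind(substr(trinuc[flip], 1, 1), substr(trinuc[flip], 2, 2),
                           substr(trinuc[flip], 3, 3), alt[flip])
  }
  labels <- paste0(chars[, 1], "[", chars[, 2], ">", chars[, 4], "]", chars[, 3])
  idx <- match(labels, sbs_channels())
  names(idx) <- labels
  idx
}

#' Build a 96-channel mutation spectrum
#'
#' @param trinuc Character vector of trinucleotide contexts.
#' @param alt Character vector of alternate bases.
#' @param label Optional name for the spectrum.
#' @return A `spectrum` object: named numeric length-96 vector of counts with
#'   attribute `label`. Counts sum to the number of input mutations.
#' @export
build_spectrum <- function(trinuc, alt, label = "spectrum") {
  channels <- sbs_channels()
  counts <- stats::setNames(numeric(96), channels)
  if (length(trinuc) == 0L) {
    warning("empty mutation list: returning zero spectrum")
  } else {
    idx <- channel_of(trinuc, alt)
    tab <- tabulate(idx, nbins = 96)
    counts[] <- tab
  }
  structure(counts, label = label, class = c("spectrum", "numeric"))
}

#' Spectrum from channel indices
#'
#' Convenience constructor used by the simulator, which draws channels
#' directly from signature mixtures.
#'
#' @param idx Integer channel indices in 1..96.
#' @param label Spectrum name.
#' @param n_channels Number of channels (96 for SBS, 83 for ID).
#' @return A `spectrum` object.
#' @export
spectrum_from_channels <- function(idx, label = "spectrum", n_channels = 96L) {
  stopifnot(all(idx >= 1L & idx <= n_channels))
  channels <- if (n_channels == 96L) sbs_channels() else id_channels()
  counts <- stats::setNames(as.numeric(tabulate(idx, nbins = n_channels)), channels)
  structure(counts, label = label, class = c("spectrum", "numeric"))
}

#' Cosine similarity between two spectra or signature profiles
#'
#' @param a,b Non-negative numeric vectors of equal length.
#' @return Cosine similarity in `[0, 1]`; 1 for identical directions.
#' @export
cosine_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("undefined similarity: zero vector", call. = FALSE)
  sum(a * b) / (na * nb)
}

#' Normalise a spectrum to a signature profile
#'
#' @param x Non-negative numeric vector with positive sum.
#' @param name Profile name.
#' @return Named numeric vector summing to 1.
#' @export
as_signature <- function(x, name = attr(x, "label") %||% "signature") {
  x <- as.numeric(x) / sum(x)
  structure(x, name = name, class = c("signature", "numeric"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- 83-channel indel classification (COSMIC ID dialect) --------------------

#' Canonical 83-channel indel labels
#'
#' Standard COSMIC ID83 classification: 1-bp deletions and insertions of
#' C/T by homopolymer length, longer deletions/insertions at repeats by
#' repeat-unit count, and deletions with microhomology by flank-match length.
#'
#' @return Character vector of length 83.
#' @export
id_channels <- function() {
  out <- character(0)
  for (type in c("Del", "Ins")) {
    for (base in c("C", "T")) {
      lens <- if (type == "Del") c("1", "2", "3", "4", "5", "6+") else c("0", "1", "2", "3", "4", "5+")
      out <- c(out, paste0("1:", type, ":", base, ":", lens))
    }
  }
  for (type in c("Del", "Ins")) {
    start <- if (type == "Del") "1" else "0"
    reps <- if (type == "Del") c("1", "2", "3", "4", "5", "6+") else c("0", "1", "2", "3", "4", "5+")
    for (len in c("2", "3", "4", "5+")) {
      out <- c(out, paste0(len, ":", type, ":R:", reps))
    }
  }
  for (len in c("2", "3", "4", "5+")) {
    mh_max <- c(`2` = 1, `3` = 2, `4` = 3, `5+` = 5)[[len]]
    mh <- as.character(seq_len(mh_max))
    if (len == "5+") mh[5] <- "5+"
    out <- c(out, paste0(len, ":Del:M:", mh))
  }
  stopifnot(length(out) == 83L)
  out
}

#' Classify an indel into the 83-channel scheme
#'
#' Implemented to the depth needed to bin simulated indels: the caller
#' supplies the indel type and its repeat/microhomology context rather than
#' a reference genome.
#'
#' @param is_insertion Logical.
#' @param length Indel length in bp (>= 1).
#' @param base For 1-bp events, the inserted/deleted base (purines collapsed
#'   to the complementary pyrimidine).
#' @param repeat_units Number of copies of the indel sequence adjacent in the
#'   reference (homopolymer length for 1-bp events).
#' @param microhomology Length of the longest flank match for non-repetitive
#'   deletions (0 if none).
#' @return Integer channel index in 1..83, named with the label.
#' @export
id_channel_of <- function(is_insertion, length, base = "T", repeat_units = 0L,
                          microhomology = 0L) {
  stopifnot(length >= 1)
  channels <- id_channels()
  cap <- function(x, top) if (x >= top) paste0(top, "+") else as.character(x)
  if (length == 1L) {
    base <- toupper(base)
    if (base %in% c("A", "G")) base <- c(A = "T", G = "C")[[base]]
    if (!base %in% c("C", "T")) stop("invalid sequence: non-ACGT base", call. = FALSE)
    lab <- if (is_insertion) {
      paste0("1:Ins:", base, ":", cap(repeat_units, 5))
    } else {
      paste0("1:Del:", base, ":", cap(max(repeat_units, 1), 6))
    }
  } else {
    len <- cap(length, 5)
    if (is_insertion) {
      lab <- paste0(len, ":Ins:R:", cap(repeat_units, 5))
    } else if (repeat_units >= 2L) {
      lab <- paste0(len, ":Del:R:", cap(repeat_units, 6))
    } else if (microhomology >= 1L) {
      mh_top <- c(`2` = 1, `3` = 2, `4` = 3, `5+` = 5)[[len]]
      mh <- min(microhomology, mh_top)
      lab <- paste0(len, ":Del:M:",
                    if (len == "5+" && mh >= 5) "5+" else as.character(mh))
    } else {
      lab <- paste0(len, ":Del:R:1")
    }
  }
  idx <- match(lab, channels)
  if (is.na(idx)) stop("unclassifiable indel: ", lab, call. = FALSE)
  stats::setNames(idx, lab)
}

# ---- signature table I/O (COSMIC v3 dialect) --------------------------------

#' Write signatures or spectra to a COSMIC-style TSV
#'
#' 96 rows (or 83 for ID), first column `Type` holding the channel labels in
#' canonical order, one column per signature/sample.
#'
#' @param x Numeric matrix (channels x signatures) or a list of equal-length
#'   named vectors.
#' @param path Output path.
#' @export
write_signature_tsv <- function(x, path) {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(cbind, x)
  x <- as.matrix(x)
  labels <- if (nrow(x) == 96L) sbs_channels() else if (nrow(x) == 83L) id_channels()
    else stop("expected 96 or 83 channel rows", call. = FALSE)
  df <- data.frame(Type = labels, x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a COSMIC-style signature TSV
#'
#' Channel labels are checked against the canonical ordering and rows are
#' reordered to it; unknown labels are an error.
#'
#' @param path Input TSV with a `Type` column.
#' @return Numeric matrix channels x signatures with canonical rownames.
#' @export
read_signature_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"Type" %in% names(df)) stop("signature TSV must have a 'Type' column", call. = FALSE)
  labels <- if (nrow(df) == 96L) sbs_channels() else if (nrow(df) == 83L) id_channels()
    else stop("expected 96 or 83 channel rows", call. = FALSE)
  if (!setequal(df$Type, labels)) stop("signature TSV channel labels do not match the canonical set", call. = FALSE)
  m <- as.matrix(df[match(labels, df$Type), setdiff(names(df), "Type"), drop = FALSE])
  rownames(m) <- labels
  m
}
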