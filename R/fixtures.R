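# Built-in signature fixtures emulating the shapes of the reference
# signatures relevant to base-excision-repair-deficient tissue. They are
# synthetic stand-ins for tests and simulation, not COSMIC data.

profile_from_peaks <- function(peaks, class_background = NULL, flat = 0.05,
                               name = "fixture") {
  channels <- sbs_channels()
  p <- stats::setNames(rep(flat / 96, 96), channels)
  if (!is.null(class_background)) {
    for (cls in names(class_background)) {
      sel <- grepl(paste0("\\[", cls, "\\]"), channels, fixed = FALSE)
      p[sel] <- p[sel] + class_background[[cls]] / sum(sel)
    }
  }
  p[names(peaks)] <- p[names(peaks)] + unlist(peaks)
  as_signature(p, name = name)
}

#' Built-in fixture signature profiles
#'
#' Synthetic 96-channel profiles emulating the qualitative shapes of the
#' signatures that dominate MUTYH-deficient tissue: a CpG C>T clock-like
#' profile (`SBS1like`), a flat profile (`SBS5like`), two correlated but
#' distinguishable C>A oxidative-damage profiles (`SBS18like` with peaks at
#' ACA/CCA/GCA/TCT, `SBS36like` with a different context preference), a
#' T>C/T>G colibactin-like profile (`SBS88like`) and an OGG1-loss-like C>A
#' profile peaking at GCA/ACA (`OGG1like`). Pairwise cosine similarity of
#' the two oxidative profiles is in (0.3, 0.9): correlated, separable.
#'
#' @return Named list of `signature` vectors (each sums to 1).
#' @export
fixture_signatures <- function() {
  list(
    SBS1like = profile_from_peaks(
      c(`A[C>T]G` = 0.22, `C[C>T]G` = 0.18, `G[C>T]G` = 0.18, `T[C>T]G` = 0.22),
      class_background = list(`C>T` = 0.10), flat = 0.10, name = "SBS1like"),
    SBS5like = profile_from_peaks(
      c(`T[T>C]T` = 0.02, `A[T>C]A` = 0.02),
      class_background = list(`T>C` = 0.10, `C>T` = 0.06), flat = 0.80,
      name = "SBS5like"),
    SBS18like = profile_from_peaks(
      c(`A[C>A]A` = 0.17, `C[C>A]A` = 0.15, `G[C>A]A` = 0.16, `T[C>A]T` = 0.14),
      class_background = list(`C>A` = 0.23), flat = 0.15, name = "SBS18like"),
    SBS36like = profile_from_peaks(
      c(`T[C>A]A` = 0.15, `C[C>A]T` = 0.14, `G[C>A]T` = 0.13, `A[C>A]T` = 0.10,
        `T[C>A]T` = 0.10),
      class_background = list(`C>A` = 0.23), flat = 0.15, name = "SBS36like"),
    SBS88like = profile_from_peaks(
      c(`T[T>C]T` = 0.18, `A[T>C]A` = 0.12, `T[T>G]T` = 0.16, `G[T>G]G` = 0.10),
      class_background = list(`T>C` = 0.15, `T>G` = 0.15), flat = 0.14,
      name = "SBS88like"),
    OGG1like = profile_from_peaks(
      c(`G[C>A]A` = 0.30, `A[C>A]A` = 0.22, `C[C>A]A` = 0.08),
      class_background = list(`C>A` = 0.20), flat = 0.20, name = "OGG1like")
  )
}

#' Built-in fixture indel signature profiles
#'
#' 83-channel stand-ins: a T-insertion slippage profile (`ID1like`), a
#' T-deletion slippage profile (`ID2like`) and a longer-deletion
#' colibactin-like profile (`ID18like`).
#'
#' @return Named list of `signature` vectors over the 83 indel channels.
#' @export
fixture_id_signatures <- function() {
  channels <- id_channels()
  mk <- function(peaks, name) {
    p <- stats::setNames(rep(0.10 / 83, 83), channels)
    p[names(peaks)] <- p[names(peaks)] + unlist(peaks)
    as_signature(p, name = name)
  }
  list(
    ID1like = mk(c(`1:Ins:T:4` = 0.30, `1:Ins:T:5+` = 0.45, `1:Ins:T:3` = 0.15),
                 "ID1like"),
    ID2like = mk(c(`1:Del:T:5` = 0.25, `1:Del:T:6+` = 0.50, `1:Del:T:4` = 0.15),
                 "ID2like"),
    ID18like = mk(c(`2:Del:R:3` = 0.25, `3:Del:R:2` = 0.25, `2:Del:R:2` = 0.20,
                    `4:Del:R:2` = 0.20), "ID18like")
  )
}
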