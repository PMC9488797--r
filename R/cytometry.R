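#' Describe a bead-normalized flow-cytometry counting assay
#'
#' Cecal content is homogenized in buffer, a small volume of homogenate is
#' stained in a bead-spiked mix of known bead concentration, and events are
#' acquired for a fixed time. Because beads and bacteria are acquired from
#' the same mix, the bacteria-per-bead ratio converts event counts to an
#' absolute concentration without needing the acquired volume. Every
#' dilution factor is an explicit field so any lab's bookkeeping maps onto
#' the chain.
#'
#' @param bacterial_events gated bacterial event count.
#' @param bead_events gated bead event count.
#' @param bead_conc_per_ul bead concentration in the mix (beads/uL).
#' @param mix_volume_ul total stained-mix volume (uL).
#' @param sample_volume_ul homogenate volume added to the mix (uL).
#' @param homogenate_volume_ul total homogenate volume (uL).
#' @param sample_mass_g mass of cecal content homogenized (g).
#' @return an object of class `cytometry_assay`.
#' @export
cytometry_assay <- function(bacterial_events, bead_events,
                            bead_conc_per_ul = 4.55e3,
                            mix_volume_ul = 200,
                            sample_volume_ul = 2,
                            homogenate_volume_ul = 1000,
                            sample_mass_g) {
  stopifnot(all(bacterial_events >= 0), all(bead_events >= 0),
            bead_conc_per_ul > 0, mix_volume_ul > 0, sample_volume_ul > 0,
            homogenate_volume_ul > 0, all(sample_mass_g > 0))
  structure(list(bacterial_events = bacterial_events,
                 bead_events = bead_events,
                 bead_conc_per_ul = bead_conc_per_ul,
                 mix_volume_ul = mix_volume_ul,
                 sample_volume_ul = sample_volume_ul,
                 homogenate_volume_ul = homogenate_volume_ul,
                 sample_mass_g = sample_mass_g),
            class = "cytometry_assay")
}

#' Absolute bacterial density from a counting assay
#'
#' Dimensional chain: events-per-bead times bead concentration gives
#' cells/uL of mix; times mix volume gives total cells, which came from
#' `sample_volume_ul` of homogenate; scaling to the full homogenate and
#' dividing by the homogenized mass gives cells per gram of content.
#'
#' `cells/g = (bacterial/bead events) * bead_conc * (mix/sample volume) *
#' (homogenate volume / sample mass)`
#'
#' @param a a [cytometry_assay()].
#' @param blank_density density (cells/g) at or below which a sample is
#'   flagged as indistinguishable from the blank (germ-free negative
#'   controls set the gates; their apparent densities define this floor).
#' @return tibble with `cells_per_g` and logical `at_blank`.
#' @export
density_from_events <- function(a, blank_density = 0) {
  stopifnot(inherits(a, "cytometry_assay"))
  if (any(a$bead_events == 0)) {
    stop("assay failure: zero bead events", call. = FALSE)
  }
  dens <- (a$bacterial_events / a$bead_events) * a$bead_conc_per_ul *
    (a$mix_volume_ul / a$sample_volume_ul) *
    (a$homogenate_volume_ul / a$sample_mass_g)
  tibble::tibble(cells_per_g = dens, at_blank = dens <= blank_density)
}
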