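#' Physical properties of the supported radionuclides
#'
#' Returns the physical constants used throughout the package for the two
#' clinically used PSMA-RLT labels: the beta emitter 177Lu and the alpha
#' emitter 225Ac.
#'
#' The decay constant is derived as `log(2) / half_life`. For 177Lu the
#' half-life of 6.70 d reproduces the decay constant used in the transport
#' model (1.197e-6 s^-1); for 225Ac, 9.92 d gives 8.087e-7 s^-1.
#' `energy_per_decay_MeV` is the mean energy assumed to be absorbed locally
#' per parent decay: the mean beta energy for 177Lu (gammas escape the
#' microscopic domain and are neglected) and the summed alpha energies of the
#' full decay chain for 225Ac, whose short-lived daughters are assumed to
#' decay at the parent decay site. `range_um` is the kernel support radius:
#' the approximate particle range in soft tissue (~1.6 mm for 177Lu betas,
#' ~50 um for 225Ac alphas).
#'
#' @param nuclide `"Lu177"` or `"Ac225"`.
#' @return A list with elements `nuclide`, `half_life_s`, `lambda_dec`
#'   (s^-1), `energy_per_decay_MeV`, and `range_um`.
#' @examples
#' nuclide_properties("Lu177")$lambda_dec
#' @export
nuclide_properties <- function(nuclide = c("Lu177", "Ac225")) {
  nuclide <- match.arg(nuclide)
  props <- switch(nuclide,
    Lu177 = list(half_life_d = 6.70, energy_per_decay_MeV = 0.1335,
                 range_um = 1600),
    Ac225 = list(half_life_d = 9.92, energy_per_decay_MeV = 27.5,
                 range_um = 50)
  )
  half_life_s <- props$half_life_d * 86400
  list(
    nuclide = nuclide,
    half_life_s = half_life_s,
    lambda_dec = log(2) / half_life_s,
    energy_per_decay_MeV = props$energy_per_decay_MeV,
    range_um = props$range_um
  )
}

#' Radioactive decay constant from half-life
#'
#' @param half_life_s Half-life in seconds (> 0).
#' @return Decay constant `log(2) / half_life_s` in s^-1.
#' @examples
#' decay_constant(6.70 * 86400)  # 177Lu
#' @export
decay_constant <- function(half_life_s) {
  stopifnot(is.numeric(half_life_s), half_life_s > 0)
  log(2) / half_life_s
}

# J per MeV
.MeV_to_J <- 1.602176634e-13
# molecules per nmol
.molecules_per_nmol <- 6.02214076e14
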