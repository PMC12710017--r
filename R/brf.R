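#' Spectral mixing parameters
#'
#' Parameters of the four-component linear mixing model with a
#' spectral-invariant multiple-scattering gain. `skyl` is the diffuse-sky
#' fraction illuminating shaded components; the recollision probability is
#' p = min(p0 + p1 * shadow_fraction, p_max), so denser mutual shading
#' increases multiple scattering. Defaults are calibrated so that visible
#' reflectance decreases and NIR reflectance increases with the crown shadow
#' fraction while the mixed reflectance stays below 1 over the realistic
#' shadow range (see the methods vignette).
#'
#' @param skyl diffuse illumination fraction on shaded components.
#' @param p0 recollision probability at zero shadow fraction.
#' @param p1 slope of recollision probability vs shadow fraction.
#' @param p_max cap on the recollision probability.
#' @return list of class `mixing_params`.
#' @export
mixing_params <- function(skyl = 0.2, p0 = 0.2, p1 = 0.6, p_max = 0.95) {
  if (skyl < 0 || skyl > 1 || p0 < 0 || p_max >= 1)
    stop("mixing_params: invalid parameters")
  structure(list(skyl = skyl, p0 = p0, p1 = p1, p_max = p_max),
            class = "mixing_params")
}

#' Synthesize canopy reflectance from component fractions
#'
#' Linear four-component mixture with a spectral-invariant
#' multiple-scattering term:
#' BRF = f_sl rho_leaf (1 + M) + f_sh rho_leaf (skyl + M)
#'     + f_sg rho_soil + f_shg skyl rho_soil,
#' where M = p w / (1 - p w), w = rho_leaf + tau_leaf is the leaf
#' single-scattering albedo and p the recollision probability derived from
#' the crown shadow fraction.
#'
#' @param fractions numeric `c(f_sl, f_sh, f_sg, f_shg)` summing to 1.
#' @param leaf a `leaf_optics` object, or a list with `reflectance` and
#'   `transmittance` vectors.
#' @param soil soil reflectance on the same grid as `leaf`.
#' @param shadow_fraction shaded-leaf share of crown leaf area, `[0, 1]`.
#' @param mixing a [mixing_params()] object.
#' @return reflectance-factor spectrum on the leaf grid.
#' @export
synthesize_canopy_brf <- function(fractions, leaf, soil, shadow_fraction = 0,
                                  mixing = mixing_params()) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != 4 || abs(sum(fractions) - 1) > 1e-9)
    stop("synthesize_canopy_brf: fractions must be 4 values summing to 1")
  if (shadow_fraction < 0 || shadow_fraction > 1)
    stop("synthesize_canopy_brf: shadow_fraction must be in [0, 1]")
  rho <- leaf$reflectance
  tau <- leaf$transmittance
  if (length(soil) != length(rho))
    stop("synthesize_canopy_brf: soil grid must match leaf grid")
  w <- rho + tau
  p <- min(max(mixing$p0 + mixing$p1 * shadow_fraction, 0), mixing$p_max)
  M <- p * w / (1 - p * w)
  fractions[1] * rho * (1 + M) + fractions[2] * rho * (mixing$skyl + M) +
    fractions[3] * soil + fractions[4] * mixing$skyl * soil
}
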