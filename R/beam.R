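## Bessel-Gaussian beam model: J0 extrema, comb weights, main-lobe FWHM.

## First extremum of J0 away from the origin (first zero of J1); used by
## validity checks before any root finding is available.
J0_FIRST_MIN <- 3.8317059702075125

## kr * FWHM for the intensity profile J0(kr r)^2: twice the root of
## J0(x)^2 = 1/2 on (0, first zero of J0). Computed once at load time.
j0HalfIntensityArg <- function() {
  uniroot(function(x) besselJ(x, 0)^2 - 0.5, c(0.5, 2.4), tol = 1e-12)$root
}

#' Locate the extrema of the Bessel function J0
#'
#' Interior extrema of J0 coincide with the zeros of J1 (since
#' J0'(u) = -J1(u)); they are found by sign-change bracketing of J1
#' followed by root polishing. The origin (the global maximum) is not
#' included; callers mirror the returned positive extrema to negative
#' arguments when building the symmetric comb.
#'
#' @param maxArgument upper end of the search interval (dimensionless
#'   J0 argument), must be positive
#' @return data.frame with columns \code{u} (extremum position) and
#'   \code{j0} (J0 value there); zero rows when no extremum lies in
#'   (0, maxArgument]
#' @export
#' @examples
#' findJ0Extrema(12)
findJ0Extrema <- function(maxArgument) {
  if (!is.numeric(maxArgument) || length(maxArgument) != 1L ||
      !is.finite(maxArgument) || maxArgument <= 0) {
    stop("maxArgument must be a single positive number")
  }
  if (maxArgument < J0_FIRST_MIN - 1e-3) {
    return(data.frame(u = numeric(0), j0 = numeric(0)))
  }
  j1 <- function(x) besselJ(x, 1)
  ## J1 zeros are ~pi apart; a 0.05 step cannot skip a sign change
  grid <- seq(1, maxArgument + 0.05, by = 0.05)
  s <- sign(j1(grid))
  flips <- which(s[-1] * s[-length(s)] < 0)
  u <- vapply(flips, function(i) {
    uniroot(j1, c(grid[i], grid[i + 1]), tol = 1e-12)$root
  }, numeric(1))
  u <- u[u <= maxArgument + 1e-9]
  data.frame(u = u, j0 = besselJ(u, 0))
}

#' Construct beam parameters, defaulting kr to a printed observable
#'
#' When \code{kr} is omitted it is chosen so that the main-lobe intensity
#' FWHM equals \code{fwhm} (default 1.2 um, the midpoint of the measured
#' 1-1.5 um band): kr = 2 x* / FWHM where J0(x*)^2 = 1/2.
#'
#' @param kr transverse wavevector (rad/um), or NULL to match \code{fwhm}
#' @param w0 Gaussian envelope waist (um)
#' @param fwhm target main-lobe intensity FWHM (um) used when kr is NULL
#' @param wavelength vacuum wavelength (um)
#' @param n0 medium refractive index
#' @param sidelobeSpan half-width of modeled sidelobes (um)
#' @return a \linkS4class{BeamParameters} object
#' @export
BeamParameters <- function(kr = NULL, w0 = 10, fwhm = 1.2,
                           wavelength = 0.488, n0 = 1.33,
                           sidelobeSpan = 20) {
  if (is.null(kr)) {
    kr <- 2 * j0HalfIntensityArg() / fwhm
  }
  new("BeamParameters", wavelength = wavelength, kr = kr, w0 = w0,
      n0 = n0, sidelobeSpan = sidelobeSpan)
}

#' Build the weighted delta-comb approximation of the beam
#'
#' Enumerates J0 extrema out to u = kr * sidelobeSpan, mirrors them about
#' the origin, and assigns each lobe the intensity weight
#' a_l^2 = J0(u_l)^2 exp(-2 u_l^2 / (kr w0)^2). The central lobe (u = 0)
#' has coefficient and weight exactly 1.
#'
#' @param params a \linkS4class{BeamParameters} object
#' @return a \linkS4class{BesselComb} object
#' @export
combWeights <- function(params) {
  stopifnot(is(params, "BeamParameters"))
  ex <- findJ0Extrema(params@kr * params@sidelobeSpan)
  u <- c(-rev(ex$u), 0, ex$u)
  cf <- c(rev(ex$j0), 1, ex$j0)
  w <- cf^2 * exp(-2 * u^2 / (params@kr * params@w0)^2)
  new("BesselComb", positions = u, coefficients = cf, weights = w,
      kr = params@kr)
}

#' Main-lobe intensity FWHM of the beam
#'
#' Full width at half maximum of the central-lobe intensity profile
#' J0(kr r)^2, i.e. 2 r* with J0(kr r*)^2 = 1/2 (a camera measures
#' intensity, so the width is defined on the squared profile).
#'
#' @param params a \linkS4class{BeamParameters} object
#' @return FWHM in um
#' @export
mainLobeFWHM <- function(params) {
  stopifnot(is(params, "BeamParameters"))
  2 * j0HalfIntensityArg() / params@kr
}
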