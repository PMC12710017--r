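#' Exponential integral E1
#'
#' Vectorised E1(x) for x > 0, used by the plate-model diffuse transmission.
#' Power series below 1, rational approximation (Abramowitz & Stegun 5.1.56)
#' above; absolute error < 2e-7 over the range exercised by leaf absorption.
#'
#' @param x positive numeric vector.
#' @return E1(x), same length as `x`.
#' @keywords internal
expint_e1 <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("expint_e1: x must be >= 0")
  out <- numeric(length(x))
  out[x == 0] <- Inf
  lo <- x > 0 & x < 1
  if (any(lo)) {
    xl <- x[lo]
    # E1(x) = -gamma - log(x) + sum_{k>=1} (-1)^(k+1) x^k / (k k!)
    s <- numeric(length(xl))
    term <- rep(1, length(xl))
    for (k in 1:24) {
      term <- term * xl / k
      s <- s + (-1)^(k + 1) * term / k
    }
    out[lo] <- -0.57721566490153286 - log(xl) + s
  }
  hi <- x >= 1
  if (any(hi)) {
    xh <- x[hi]
    a <- c(8.5733287401, 18.0590169730, 8.6347608925, 0.2677737343)
    b <- c(9.5733223454, 25.6329561486, 21.0996530827, 3.9584969228)
    num <- ((( xh + a[1]) * xh + a[2]) * xh + a[3]) * xh + a[4]
    den <- ((( xh + b[1]) * xh + b[2]) * xh + b[3]) * xh + b[4]
    out[hi] <- exp(-xh) / xh * num / den
  }
  out
}

#' Diffuse transmission of one absorbing plate
#'
#' Transmission of isotropic radiation through a layer of absorption
#' coefficient `k`: tau = (1 - k) exp(-k) + k^2 E1(k), with tau(0) = 1.
#'
#' @param k non-negative absorption coefficient vector.
#' @return transmission fraction in (0, 1].
#' @keywords internal
plate_transmission <- function(k) {
  if (any(k < 0, na.rm = TRUE)) stop("plate_transmission: k must be >= 0")
  tau <- rep(1, length(k))
  pos <- k > 0
  if (any(pos)) {
    kp <- k[pos]
    tau[pos] <- (1 - kp) * exp(-kp) + kp^2 * expint_e1(kp)
  }
  pmin(pmax(tau, 0), 1)
}

#' Average transmissivity of a dielectric interface
#'
#' Directional-hemispherical transmissivity of a plane dielectric surface for
#' radiation incident within a cone of half-angle `alpha`, after Stern (1964)
#' and Allen (1973). This is the interface term of the plate model: `alpha =
#' 40` degrees for the upper leaf surface, `alpha = 90` for internal
#' (isotropic) incidence.
#'
#' @param alpha cone half-angle in degrees, in (0, 90].
#' @param n refractive index (>= 1). Vectorised over `n`.
#' @return transmissivity fraction in (0, 1].
#' @examples
#' tav(90, 1.0)   # no index contrast: 1
#' tav(40, 1.45)
#' @export
tav <- function(alpha, n) {
  if (length(alpha) != 1 || !is.finite(alpha) || alpha <= 0 || alpha > 90)
    stop("tav: alpha must be a single value in (0, 90]")
  if (any(!is.finite(n)) || any(n < 1))
    stop("tav: refractive index must be >= 1")
  out <- numeric(length(n))
  unit <- abs(n - 1) < 1e-12
  out[unit] <- 1
  if (all(unit)) return(out)
  ref <- n[!unit]
  s  <- sin(alpha * pi / 180)
  r2 <- ref^2
  rp <- r2 + 1
  rm <- r2 - 1
  a  <- (ref + 1)^2 / 2
  k  <- -(r2 - 1)^2 / 4
  k2 <- k^2
  rm2 <- rm^2
  if (alpha == 90) b1 <- 0 else b1 <- sqrt((s^2 - rp / 2)^2 + k)
  b2 <- s^2 - rp / 2
  b  <- b1 - b2
  ts <- (k2 / (6 * b^3) + k / b - b / 2) - (k2 / (6 * a^3) + k / a - a / 2)
  tp1 <- -2 * r2 * (b - a) / rp^2
  tp2 <- -2 * r2 * rp * log(b / a) / rm2
  tp3 <- r2 * (1 / b - 1 / a) / 2
  rp3 <- rp^3
  tp4 <- 16 * r2^2 * (r2^2 + 1) * log((2 * rp * b - rm2) / (2 * rp * a - rm2)) / (rp3 * rm2)
  tp5 <- 16 * r2^3 * (1 / (2 * rp * b - rm2) - 1 / (2 * rp * a - rm2)) / rp3
  tp  <- tp1 + tp2 + tp3 + tp4 + tp5
  out[!unit] <- (ts + tp) / (2 * s^2)
  out
}

#' Leaf biochemistry parameter set
#'
#' Container for the plate-model inputs: structure parameter N (number of
#' equivalent plates, >= 1), chlorophyll a+b `cab` (ug/cm2), carotenoids
#' `cxc` (ug/cm2, by default tied to `cab` via `cxc_ratio`), brown pigment
#' `cbrown` (arbitrary units), equivalent water thickness `cw` (cm) and dry
#' matter `cm` (g/cm2).
#'
#' @param n_struct leaf structure parameter, >= 1.
#' @param cab chlorophyll a+b content, ug/cm2.
#' @param cxc carotenoid content, ug/cm2; default `cab * cxc_ratio`.
#' @param cbrown brown pigment, arbitrary units.
#' @param cw equivalent water thickness, cm.
#' @param cm dry matter content, g/cm2.
#' @param cxc_ratio carotenoid-to-chlorophyll ratio used when `cxc` is
#'   missing (conventional pigment ratio 1/4).
#' @return an object of class `leaf_biochem`.
#' @export
leaf_biochem <- function(n_struct = 1.5, cab = 40, cxc = NULL, cbrown = 0,
                         cw = 0.01, cm = 0.009, cxc_ratio = 0.25) {
  if (is.null(cxc)) cxc <- cab * cxc_ratio
  vals <- c(n_struct = n_struct, cab = cab, cxc = cxc, cbrown = cbrown,
            cw = cw, cm = cm)
  if (any(!is.finite(vals))) stop("leaf_biochem: all parameters must be finite")
  if (n_struct < 1) stop("leaf_biochem: n_struct must be >= 1")
  if (any(vals[-1] < 0)) stop("leaf_biochem: contents must be >= 0")
  structure(as.list(vals), class = "leaf_biochem")
}

#' Synthetic plate-model calibration tables
#'
#' Refractive index and specific absorption coefficients on the 400-2500 nm
#' 1-nm grid. These tables are SYNTHETIC surrogates generated from analytic
#' band shapes (the published calibration data cannot be redistributed here):
#' a smoothly decreasing refractive index, chlorophyll absorption confined to
#' the visible (two bands at 430 and 660 nm, asymmetric red flank, zero above
#' 780 nm), carotenoid absorption in the blue, brown-pigment absorption
#' decaying from the UV edge, water bands at 1200/1450/1940/2500 nm (zero
#' below 900 nm) and a dry-matter continuum rising into the SWIR. Users with
#' the published tables can supply them via [read_coefficients()].
#'
#' @return a data.frame of class `absorption_coefficients` with columns
#'   `wavelength`, `refractive_index`, `k_cab`, `k_cxc`, `k_cbrown`, `k_cw`,
#'   `k_cm`.
#' @export
prospect_coefficients <- function() {
  wl <- 400:2500
  gauss <- function(mu, sig) exp(-((wl - mu)^2) / (2 * sig^2))
  agauss <- function(mu, sig_l, sig_r) {
    s <- ifelse(wl < mu, sig_l, sig_r)
    exp(-((wl - mu)^2) / (2 * s^2))
  }
  nr <- 1.32 + 0.22 * exp(-(wl - 400) / 350)
  k_cab <- 0.065 * (0.85 * gauss(430, 30) + agauss(660, 60, 25))
  k_cab[wl > 780] <- 0
  k_cxc <- 0.04 * (gauss(450, 25) + 0.7 * gauss(480, 20))
  k_cxc[wl > 560] <- 0
  k_cbrown <- 0.45 * exp(-(wl - 400) / 150)
  k_cbrown[wl > 1300] <- 0
  k_cw <- 6 * gauss(1200, 60) + 35 * gauss(1450, 70) +
    85 * gauss(1940, 100) + 70 * gauss(2500, 220) +
    2 * pmax(0, (wl - 900) / 1600)^2
  k_cw[wl < 900] <- 0
  k_cm <- 6 * (1 - exp(-(wl - 400) / 1200)) +
    2 * gauss(2100, 150) + 1.5 * gauss(1720, 80)
  out <- data.frame(wavelength = wl, refractive_index = nr, k_cab = k_cab,
                    k_cxc = k_cxc, k_cbrown = k_cbrown, k_cw = k_cw, k_cm = k_cm)
  class(out) <- c("absorption_coefficients", "data.frame")
  out
}

#' Read plate-model calibration tables from CSV
#'
#' Expects columns `wavelength`, `refractive_index`, `k_cab`, `k_cxc`,
#' `k_cbrown`, `k_cw`, `k_cm` on a contiguous 1-nm grid.
#'
#' @param path CSV file path.
#' @return an `absorption_coefficients` data.frame.
#' @export
read_coefficients <- function(path) {
  out <- utils::read.csv(path)
  need <- c("wavelength", "refractive_index", "k_cab", "k_cxc", "k_cbrown",
            "k_cw", "k_cm")
  miss <- setdiff(need, names(out))
  if (length(miss)) stop("read_coefficients: missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(out$refractive_index <= 1)) stop("read_coefficients: refractive_index must be > 1")
  if (any(out[, need[-(1:2)]] < 0)) stop("read_coefficients: absorption coefficients must be >= 0")
  class(out) <- c("absorption_coefficients", "data.frame")
  out
}

#' Plate-model leaf reflectance and transmittance
#'
#' Computes directional-hemispherical leaf reflectance and transmittance on
#' the coefficient wavelength grid from leaf biochemistry, using the
#' generalised plate model: a compound absorption coefficient
#' k(lambda) = sum_i C_i k_i(lambda) / N per elementary layer, one surface
#' layer with oblique incidence (default 40 degrees) and N - 1 internal
#' layers solved with the Stokes system (non-integer N supported).
#'
#' @param biochem a [leaf_biochem()] object.
#' @param coeffs calibration tables; default [prospect_coefficients()].
#' @param alpha incidence cone half-angle for the upper surface, degrees.
#' @return an object of class `leaf_optics`: list with `wavelength`,
#'   `reflectance`, `transmittance`.
#' @examples
#' lo <- prospect5(leaf_biochem(cab = 40))
#' range(lo$reflectance + lo$transmittance)
#' @export
prospect5 <- function(biochem, coeffs = prospect_coefficients(), alpha = 40) {
  if (!inherits(biochem, "leaf_biochem")) biochem <- do.call(leaf_biochem, as.list(biochem))
  N <- biochem$n_struct
  k <- (biochem$cab * coeffs$k_cab + biochem$cxc * coeffs$k_cxc +
          biochem$cbrown * coeffs$k_cbrown + biochem$cw * coeffs$k_cw +
          biochem$cm * coeffs$k_cm) / N
  tau <- plate_transmission(k)
  nr <- coeffs$refractive_index

  talf <- tav(alpha, nr)
  ralf <- 1 - talf
  t12 <- tav(90, nr)
  r12 <- 1 - t12
  t21 <- t12 / nr^2
  r21 <- 1 - t21

  denom <- 1 - r21^2 * tau^2
  Ta <- talf * tau * t21 / denom
  Ra <- ralf + r21 * tau * Ta
  t <- t12 * tau * t21 / denom
  r <- r12 + r21 * tau * t

  # Stokes solution for the remaining N - 1 layers
  te <- pmax(t, 1e-60)
  rt <- r + t
  cons <- rt >= 1 - 1e-10      # non-absorbing limit: closed form degenerates
  D <- sqrt(pmax((1 + r + te) * (1 + r - te) * (1 - r + te) * (1 - r - te), 0))
  rq <- r^2
  tq <- te^2
  a <- (1 + rq - tq + D) / (2 * r)
  b <- (1 - rq + tq + D) / (2 * te)
  bNm1 <- b^(N - 1)
  bN2 <- bNm1^2
  a2 <- a^2
  denom2 <- a2 * bN2 - 1
  Rsub <- a * (bN2 - 1) / denom2
  Tsub <- bNm1 * (a2 - 1) / denom2
  Tsub_c <- te / (te + (1 - te) * (N - 1))
  Rsub[cons] <- 1 - Tsub_c[cons]
  Tsub[cons] <- Tsub_c[cons]

  denom3 <- 1 - Rsub * r
  Tl <- Ta * Tsub / denom3
  Rl <- Ra + Ta * Rsub * t / denom3

  if (any(!is.finite(Rl)) || any(!is.finite(Tl)))
    stop("prospect5: non-finite output; check coefficient tables")
  structure(list(wavelength = coeffs$wavelength,
                 reflectance = pmin(pmax(Rl, 0), 1),
                 transmittance = pmin(pmax(Tl, 0), 1)),
            class = "leaf_optics")
}

#' @export
print.leaf_optics <- function(x, ...) {
  cat("<leaf_optics> ", length(x$wavelength), " wavelengths (",
      min(x$wavelength), "-", max(x$wavelength), " nm)\n", sep = "")
  cat("  R: ", sprintf("%.3f", min(x$reflectance)), "-",
      sprintf("%.3f", max(x$reflectance)),
      "  T: ", sprintf("%.3f", min(x$transmittance)), "-",
      sprintf("%.3f", max(x$transmittance)), "\n", sep = "")
  invisible(x)
}

#' Write leaf optics to CSV
#' @param x a `leaf_optics` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_leaf_optics <- function(x, path) {
  utils::write.csv(data.frame(wavelength = x$wavelength,
                              reflectance = x$reflectance,
                              transmittance = x$transmittance),
                   path, row.names = FALSE)
  invisible(path)
}

#' Synthetic soil background reflectance
#'
#' Smooth bright-soil curve rising from the blue into the SWIR with water
#' absorption dips; a stand-in for a field-measured soil spectrum.
#'
#' @param wavelength nm grid (default 400:2500).
#' @return reflectance fractions.
#' @export
soil_spectrum <- function(wavelength = 400:2500) {
  wl <- wavelength
  r <- 0.06 + 0.20 * (1 - exp(-(wl - 400) / 600)) -
    0.04 * exp(-((wl - 1450)^2) / (2 * 80^2)) -
    0.06 * exp(-((wl - 1940)^2) / (2 * 100^2))
  pmin(pmax(r, 0), 1)
}

#' Synthetic bark reflectance
#'
#' Brownish branch-bark curve (dark in the visible, brighter in the NIR);
#' packaged as a scene component optic.
#'
#' @param wavelength nm grid (default 400:2500).
#' @return reflectance fractions.
#' @export
bark_spectrum <- function(wavelength = 400:2500) {
  wl <- wavelength
  r <- 0.08 + 0.25 * (1 - exp(-(wl - 400) / 500)) -
    0.03 * exp(-((wl - 1940)^2) / (2 * 120^2))
  pmin(pmax(r, 0), 1)
}
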