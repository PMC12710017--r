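# Independent oracles used by the test-suite. These deliberately take
# different computational routes from the package implementation:
# - tav_numeric: Fresnel transmission integrated numerically over the cone
# - plate_tau_numeric: diffuse plate transmission by quadrature (no E1 approx)
# - prospect_oracle: plate model with numeric tau/tav and the N-1 layer
#   Stokes system solved by eigendecomposition of the intensity transfer
#   matrix (Sylvester's formula) instead of the closed-form a/b expressions
# - michalsky_sun: approximate solar ephemeris of the Astronomical Almanac
#   (Michalsky 1988), an algorithm family independent of the NOAA/Meeus
#   implementation in the package

tav_numeric <- function(alpha, n) {
  if (abs(n - 1) < 1e-12) return(1)
  fresnel_t <- function(theta) {
    st <- sin(theta) / n
    tt <- asin(pmin(st, 1))
    rs <- ((cos(theta) - n * cos(tt)) / (cos(theta) + n * cos(tt)))^2
    rp <- ((cos(tt) - n * cos(theta)) / (cos(tt) + n * cos(theta)))^2
    1 - (rs + rp) / 2
  }
  a <- alpha * pi / 180
  num <- stats::integrate(function(th) fresnel_t(th) * sin(th) * cos(th),
                          0, a, rel.tol = 1e-10)$value
  den <- stats::integrate(function(th) sin(th) * cos(th), 0, a,
                          rel.tol = 1e-10)$value
  num / den
}

plate_tau_numeric <- function(k) {
  vapply(k, function(kk) {
    if (kk == 0) return(1)
    2 * stats::integrate(function(th) exp(-kk / cos(th)) * cos(th) * sin(th),
                         0, pi / 2, rel.tol = 1e-10)$value
  }, numeric(1))
}

# M^m for the 2x2 intensity transfer matrix of one symmetric layer (r, t),
# via Sylvester's formula; det(M) = 1 so the eigenvalues are lam, 1/lam
.stack_rt <- function(r, t, m) {
  if (m <= 0) return(c(R = 0, T = 1))
  a11 <- (t^2 - r^2) / t; a12 <- r / t
  a21 <- -r / t;          a22 <- 1 / t
  tr <- a11 + a22
  if (abs(tr - 2) < 1e-12) {        # degenerate (conservative) limit
    Tm <- t / (t + (1 - t) * m)
    return(c(R = 1 - Tm, T = Tm))
  }
  disc <- sqrt(tr^2 - 4)
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  c1 <- (l1^m - l2^m) / (l1 - l2)
  c0 <- (l1^m * (-l2) - l2^m * (-l1)) / (l1 - l2)
  m21 <- c1 * a21
  m22 <- c1 * a22 + c0
  m11 <- c1 * a11 + c0
  m12 <- c1 * a12
  R <- -m21 / m22
  c(R = R, T = m11 + m12 * R)
}

prospect_oracle <- function(biochem, coeffs = prospect_coefficients(),
                            alpha = 40) {
  N <- biochem$n_struct
  k <- (biochem$cab * coeffs$k_cab + biochem$cxc * coeffs$k_cxc +
          biochem$cbrown * coeffs$k_cbrown + biochem$cw * coeffs$k_cw +
          biochem$cm * coeffs$k_cm) / N
  tau <- plate_tau_numeric(k)
  nr <- coeffs$refractive_index
  talf <- vapply(nr, function(x) tav_numeric(alpha, x), numeric(1))
  t12 <- vapply(nr, function(x) tav_numeric(90, x), numeric(1))
  ralf <- 1 - talf
  r12 <- 1 - t12
  t21 <- t12 / nr^2
  r21 <- 1 - t21
  denom <- 1 - r21^2 * tau^2
  Ta <- talf * tau * t21 / denom
  Ra <- ralf + r21 * tau * Ta
  t <- t12 * tau * t21 / denom
  r <- r12 + r21 * tau * t
  sub <- t(vapply(seq_along(t), function(i) .stack_rt(r[i], t[i], N - 1),
                  numeric(2)))
  Rsub <- sub[, 1]; Tsub <- sub[, 2]
  den3 <- 1 - Rsub * r
  list(wavelength = coeffs$wavelength,
       reflectance = Ra + Ta * Rsub * t / den3,
       transmittance = Ta * Tsub / den3)
}

michalsky_sun <- function(lat, lon, date, hour, utc_offset = 0) {
  rad <- pi / 180
  ut <- hour - utc_offset
  jd <- as.numeric(as.Date(date)) + 2440587.5 + ut / 24
  n <- jd - 2451545
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- (357.528 + 0.9856003 * n) %% 360
  lam <- (L + 1.915 * sin(g * rad) + 0.020 * sin(2 * g * rad)) %% 360
  eps <- 23.439 - 0.0000004 * n
  ra <- (atan2(cos(eps * rad) * sin(lam * rad), cos(lam * rad)) / rad) %% 360
  dec <- asin(sin(eps * rad) * sin(lam * rad)) / rad
  gmst <- (6.697375 + 0.0657098242 * n + ut) %% 24
  lmst <- (gmst + lon / 15) %% 24
  ha <- lmst * 15 - ra
  ha <- ((ha + 180) %% 360) - 180
  el <- asin(sin(dec * rad) * sin(lat * rad) +
               cos(dec * rad) * cos(lat * rad) * cos(ha * rad)) / rad
  az <- (atan2(-cos(dec * rad) * sin(ha * rad),
               sin(dec * rad) * cos(lat * rad) -
                 cos(dec * rad) * sin(lat * rad) * cos(ha * rad)) / rad) %% 360
  list(zenith = 90 - el, azimuth = az)
}
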