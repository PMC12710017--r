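#' Parameter grid for canopy-spectrum simulation
#'
#' Full-factorial levels for the varied inputs: leaf structure N, chlorophyll
#' `cab`, equivalent water thickness `cw` and per-tree LAI. Carotenoids
#' follow chlorophyll (`cxc = cab/4`), brown pigment is 0 and dry matter is
#' fixed. The default level counts (8, 70, 4, 9) reproduce the 20,160
#' spectra per acquisition moment of the reference configuration.
#'
#' @param n_levels named integer vector of level counts for
#'   `n_struct`, `cab`, `cw`, `lai`.
#' @param ranges named list of `c(min, max)` ranges.
#' @param cm fixed dry matter content, g/cm2.
#' @param cxc_ratio carotenoid-to-chlorophyll ratio.
#' @return list of class `lut_grid` with level vectors and fixed values.
#' @export
lut_grid <- function(n_levels = c(n_struct = 8, cab = 70, cw = 4, lai = 9),
                     ranges = list(n_struct = c(1, 3), cab = c(20, 70),
                                   cw = c(0.01, 0.03), lai = c(0.5, 7)),
                     cm = 0.01, cxc_ratio = 0.25) {
  if (any(n_levels < 1)) stop("lut_grid: level counts must be >= 1")
  lv <- function(nm) {
    n <- n_levels[[nm]]; r <- ranges[[nm]]
    if (n == 1) mean(r) else seq(r[1], r[2], length.out = n)
  }
  structure(list(n_struct = lv("n_struct"), cab = lv("cab"), cw = lv("cw"),
                 lai = lv("lai"), cm = cm, cxc_ratio = cxc_ratio),
            class = "lut_grid")
}

#' Mini grid for fast tests and demos
#' @return a small [lut_grid()] with level counts (2, 5, 2, 3).
#' @export
lut_grid_mini <- function() {
  lut_grid(n_levels = c(n_struct = 2, cab = 5, cw = 2, lai = 3))
}

#' Number of grid combinations per acquisition time
#' @param grid a [lut_grid()].
#' @return product of level counts.
#' @export
lut_size <- function(grid) {
  length(grid$n_struct) * length(grid$cab) * length(grid$cw) * length(grid$lai)
}

#' Default simulation scene for spectrum lookup tables
#'
#' A compact 3 x 3 block of the row-structured orchard (3.5 m row spacing,
#' 2 m tree spacing, 1 x 1 x 1.5 m crown semi-axes, 0.8 m crown base); the
#' centre tree is used for crown-level statistics so that its neighbours
#' provide realistic mutual shading.
#'
#' @return an [orchard_scene()].
#' @export
lut_scene <- function() {
  orchard_scene(orchard_layout(3, 3, row_spacing = 3.5, tree_spacing = 2),
                margin = 1)
}

#' Site and acquisition-date defaults
#'
#' Location of the simulated orchard (116.133 deg E, 40.154 deg N), local
#' clock UTC+8 without daylight saving, acquisition date 2021-08-31.
#'
#' @return list with `latitude`, `longitude`, `date`, `utc_offset`.
#' @export
site_defaults <- function() {
  list(latitude = 40.154, longitude = 116.133, date = "2021-08-31",
       utc_offset = 8)
}

#' Build a canopy-spectrum lookup table
#'
#' For each acquisition hour, renders the four-component image of the scene
#' per LAI level (crown shadow fraction, component fractions and photon
#' escape probability are geometry-only, hence shared across leaf
#' biochemistry), runs the leaf model for every biochemistry combination,
#' resamples leaf optics to the sensor bands and mixes the crown-level band
#' reflectance. The result is the full factorial of
#' (times x n_struct x cab x cw x lai).
#'
#' @param grid a [lut_grid()].
#' @param times local clock hours (default 9:16, the eight hourly cases).
#' @param scene simulation scene, default [lut_scene()].
#' @param site list as [site_defaults()].
#' @param mixing a [mixing_params()].
#' @param coeffs leaf calibration tables.
#' @param bands sensor definition.
#' @param resolution,supersample render settings for the geometry pass.
#' @param fesc_photons Monte-Carlo photon budget per (time, LAI).
#' @param seed seed for the geometry and fesc sampling.
#' @param verbose print per-time progress.
#' @return data.frame of class `canopy_lut`: one row per sample with
#'   `time, sza, saa, shadow_fraction, fesc, n_struct, cab, cxc, cbrown, cw,
#'   cm, lai` and band reflectances `BLUE..NIR`.
#' @export
build_lut <- function(grid = lut_grid(), times = 9:16, scene = lut_scene(),
                      site = site_defaults(), mixing = mixing_params(),
                      coeffs = prospect_coefficients(), bands = uav_bands(),
                      resolution = 0.08, supersample = 2,
                      fesc_photons = 2000, seed = 1L, verbose = FALSE) {
  if (lut_size(grid) < 1) stop("build_lut: empty grid")
  if (length(times) < 1) stop("build_lut: no times")
  soil_b <- resample_to_bands(400:2500, soil_spectrum(), bands)

  # leaf optics per biochemistry combination (shared across times and LAI)
  bio <- expand.grid(n_struct = grid$n_struct, cab = grid$cab, cw = grid$cw,
                     KEEP.OUT.ATTRS = FALSE)
  nbio <- nrow(bio)
  rho_b <- matrix(0, nbio, nrow(bands))
  tau_b <- matrix(0, nbio, nrow(bands))
  for (i in seq_len(nbio)) {
    lo <- prospect5(leaf_biochem(n_struct = bio$n_struct[i], cab = bio$cab[i],
                                 cw = bio$cw[i], cm = grid$cm,
                                 cxc_ratio = grid$cxc_ratio), coeffs)
    rho_b[i, ] <- resample_to_bands(lo$wavelength, lo$reflectance, bands)
    tau_b[i, ] <- resample_to_bands(lo$wavelength, lo$transmittance, bands)
  }
  omega_b <- rho_b + tau_b

  # centre tree of the scene
  ctr <- c(mean(scene$extent[c("xmin", "xmax")]),
           mean(scene$extent[c("ymin", "ymax")]))
  center_tree <- scene$trees$tree_id[
    which.min((scene$trees$x - ctr[1])^2 + (scene$trees$y - ctr[2])^2)]

  out <- vector("list", length(times))
  for (ti in seq_along(times)) {
    tm <- times[ti]
    sun <- sun_position(site$latitude, site$longitude, site$date, tm,
                       site$utc_offset)
    if (!sun$daylight) stop("build_lut: night time ", tm)
    geo <- vector("list", length(grid$lai))
    for (li in seq_along(grid$lai)) {
      sc <- scene_with_lai(scene, grid$lai[li])
      gseed <- seed + 1000L * ti + li
      img <- render_four_component(sc, sun, resolution = resolution,
                                   supersample = supersample, seed = gseed)
      fr <- component_fractions(img, center_tree)
      sf <- crown_shadow_fraction(img, center_tree)
      fe <- estimate_fesc(sc, sun, n_photons = fesc_photons, seed = gseed)
      geo[[li]] <- list(fr = fr, sf = sf, fesc = fe$fesc)
    }
    blocks <- vector("list", length(grid$lai))
    for (li in seq_along(grid$lai)) {
      g <- geo[[li]]
      p <- min(max(mixing$p0 + mixing$p1 * g$sf, 0), mixing$p_max)
      M <- p * omega_b / (1 - p * omega_b)
      brf <- g$fr[1] * rho_b * (1 + M) + g$fr[2] * rho_b * (mixing$skyl + M) +
        outer(rep(1, nbio), g$fr[3] * soil_b + g$fr[4] * mixing$skyl * soil_b)
      df <- data.frame(time = tm, sza = sun$zenith, saa = sun$azimuth,
                       shadow_fraction = g$sf, fesc = g$fesc,
                       n_struct = bio$n_struct, cab = bio$cab,
                       cxc = bio$cab * grid$cxc_ratio, cbrown = 0,
                       cw = bio$cw, cm = grid$cm, lai = grid$lai[li])
      brf <- as.data.frame(brf)
      names(brf) <- bands$name
      blocks[[li]] <- cbind(df, brf)
    }
    out[[ti]] <- do.call(rbind, blocks)
    if (verbose) message("build_lut: time ", tm, ":00 done (",
                         nrow(out[[ti]]), " samples)")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("canopy_lut", "data.frame")
  res
}

#' Write a lookup table to CSV
#' @param lut a `canopy_lut`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lut <- function(lut, path) {
  utils::write.csv(lut, path, row.names = FALSE)
  invisible(path)
}
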