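#' Orchard presets
#'
#' Row-grid presets for the two mapped orchards (429 and 215 trees) and a
#' small `mini` block for fast demonstrations and tests.
#'
#' @param name one of `"orchard1"` (13 x 33 = 429 trees), `"orchard2"`
#'   (5 x 43 = 215 trees), `"mini"` (6 x 8 = 48 trees).
#' @param jitter positional jitter sd, m.
#' @param seed RNG seed for the jitter.
#' @return an [orchard_layout()].
#' @export
orchard_preset <- function(name = c("mini", "orchard1", "orchard2"),
                           jitter = 0.15, seed = 1L) {
  name <- match.arg(name)
  dims <- switch(name,
                 orchard1 = c(13, 33),
                 orchard2 = c(5, 43),
                 mini = c(6, 8))
  orchard_layout(dims[1], dims[2], row_spacing = 3.5, tree_spacing = 2,
                 jitter = jitter, seed = seed)
}

# inverse-CDF truncated normal sampler
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (lo >= hi) stop("sample_truth: bounds inverted")
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Sample per-tree ground truth
#'
#' Truncated-normal leaf chlorophyll and LAI, independent across trees, with
#' CCC formed as the exact product. Defaults emulate an orchard whose LCC
#' lies mainly between 45 and 80 ug/cm2 and whose per-tree LAI is moderate.
#'
#' @param n_trees number of trees.
#' @param lcc_mean,lcc_sd,lcc_bounds LCC distribution, ug/cm2.
#' @param lai_mean,lai_sd,lai_bounds LAI distribution, m2/m2.
#' @param seed RNG seed.
#' @return data.frame of class `ground_truth`: `tree_id`, `lcc`, `lai`,
#'   `ccc`.
#' @export
sample_truth <- function(n_trees, lcc_mean = 60, lcc_sd = 10,
                         lcc_bounds = c(40, 85), lai_mean = 3.5,
                         lai_sd = 0.8, lai_bounds = c(1, 6), seed = 1L) {
  if (n_trees < 1) stop("sample_truth: n_trees must be >= 1")
  set.seed(seed)
  lcc <- .rtruncnorm(n_trees, lcc_mean, lcc_sd, lcc_bounds[1], lcc_bounds[2])
  lai <- .rtruncnorm(n_trees, lai_mean, lai_sd, lai_bounds[1], lai_bounds[2])
  out <- data.frame(tree_id = seq_len(n_trees), lcc = lcc, lai = lai,
                    ccc = lcc * lai)
  class(out) <- c("ground_truth", "data.frame")
  out
}

#' Render a synthetic five-band orchard survey
#'
#' Builds the 3D scene from the layout with per-tree foliage density from
#' the true LAI, renders the nadir four-component image, computes per-tree
#' leaf optics from the true chlorophyll, mixes per-pixel band reflectance
#' from the pixel's own component fractions (with the owning tree's crown
#' shadow fraction driving multiple scattering), and adds clipped Gaussian
#' sensor noise. Background pixels mix soil only.
#'
#' @param layout an [orchard_layout()].
#' @param truth a [sample_truth()] table (one row per tree).
#' @param time local clock hour of acquisition.
#' @param site list as [site_defaults()].
#' @param crown crown geometry, see [orchard_scene()].
#' @param resolution pixel size, m (<= 0.1).
#' @param supersample subrays per pixel side.
#' @param noise_std additive Gaussian reflectance noise sd.
#' @param mixing a [mixing_params()].
#' @param coeffs leaf calibration tables.
#' @param bands sensor definition.
#' @param leaf_defaults list of fixed leaf parameters (`n_struct`, `cw`,
#'   `cm`, `cxc_ratio`).
#' @param min_crown_px minimum resolved pixels per crown.
#' @param seed RNG seed (render + noise).
#' @return object of class `synthetic_survey`: `bands` (ny x nx x 5 array),
#'   `crown_id`, `labels`, `truth`, `shadow_fraction` (per tree),
#'   `resolution`, `extent`, `time`, `sun`, `noise_std`.
#' @export
render_survey <- function(layout, truth, time = 12, site = site_defaults(),
                          crown = list(ax = 1, ay = 1, az = 1.5, base = 0.8),
                          resolution = 0.05, supersample = 2,
                          noise_std = 0.01, mixing = mixing_params(),
                          coeffs = prospect_coefficients(),
                          bands = uav_bands(),
                          leaf_defaults = list(n_struct = 1.5, cw = 0.02,
                                               cm = 0.01, cxc_ratio = 0.25),
                          min_crown_px = 20, seed = 1L) {
  if (resolution > 0.1) stop("render_survey: resolution must be <= 0.1 m")
  if (nrow(truth) != nrow(layout))
    stop("render_survey: truth must have one row per tree")
  scene <- orchard_scene(layout, crown = crown, lai = truth$lai)
  sun <- sun_position(site$latitude, site$longitude, site$date, time,
                     site$utc_offset)
  img <- render_four_component(scene, sun, resolution = resolution,
                               supersample = supersample, seed = seed)
  npx_tree <- tabulate(img$crown_id[img$crown_id > 0], nbins = nrow(truth))
  if (any(npx_tree < min_crown_px))
    stop("render_survey: crowns with < ", min_crown_px,
         " pixels; use a finer resolution")

  soil_b <- resample_to_bands(400:2500, soil_spectrum(), bands)
  nb <- nrow(bands)
  ntree <- nrow(truth)
  rho_b <- matrix(0, ntree, nb)
  tau_b <- matrix(0, ntree, nb)
  for (i in seq_len(ntree)) {
    lo <- prospect5(leaf_biochem(n_struct = leaf_defaults$n_struct,
                                 cab = truth$lcc[i],
                                 cw = leaf_defaults$cw, cm = leaf_defaults$cm,
                                 cxc_ratio = leaf_defaults$cxc_ratio), coeffs)
    rho_b[i, ] <- resample_to_bands(lo$wavelength, lo$reflectance, bands)
    tau_b[i, ] <- resample_to_bands(lo$wavelength, lo$transmittance, bands)
  }

  sfr <- vapply(seq_len(ntree), function(j)
    tryCatch(crown_shadow_fraction(img, j), error = function(e) NA_real_),
    numeric(1))
  sf_fill <- stats::median(sfr, na.rm = TRUE)
  sfr[is.na(sfr)] <- sf_fill

  dims <- dim(img$labels)
  arr <- array(0, c(dims[1], dims[2], nb))
  cid <- img$crown_id
  soil_part <- array(0, c(dims[1], dims[2], nb))
  for (b in seq_len(nb))
    soil_part[, , b] <- (img$f_sg + img$f_shg * mixing$skyl) * soil_b[b]
  mean_rho <- colMeans(rho_b)
  mean_tau <- colMeans(tau_b)
  for (j in c(0L, seq_len(ntree))) {
    sel <- cid == j
    if (!any(sel)) next
    if (j == 0L) {               # background: stray leaf subrays use the
      rho <- mean_rho            # orchard-mean leaf optics
      tau <- mean_tau
      sf <- sf_fill
    } else {
      rho <- rho_b[j, ]
      tau <- tau_b[j, ]
      sf <- sfr[j]
    }
    p <- min(max(mixing$p0 + mixing$p1 * sf, 0), mixing$p_max)
    w <- rho + tau
    M <- p * w / (1 - p * w)
    for (b in seq_len(nb)) {
      arr[, , b][sel] <- img$f_sl[sel] * rho[b] * (1 + M[b]) +
        img$f_sh[sel] * rho[b] * (mixing$skyl + M[b]) +
        soil_part[, , b][sel]
    }
  }
  if (noise_std > 0) {
    set.seed(seed + 7L)
    arr <- arr + array(stats::rnorm(length(arr), 0, noise_std), dim(arr))
  }
  arr <- pmin(pmax(arr, 0), 1)
  dimnames(arr) <- list(NULL, NULL, bands$name)
  structure(list(bands = arr, crown_id = cid, labels = img$labels,
                 truth = truth, shadow_fraction = sfr,
                 resolution = resolution, extent = img$extent,
                 time = time, sun = sun, noise_std = noise_std),
            class = "synthetic_survey")
}

#' @export
print.synthetic_survey <- function(x, ...) {
  cat(sprintf("<synthetic_survey> %d x %d px @ %.3g m, %d trees, %02d:00, noise sd %.3g\n",
              dim(x$bands)[1], dim(x$bands)[2], x$resolution,
              nrow(x$truth), x$time, x$noise_std))
  invisible(x)
}

#' Per-tree crown-mean band reflectance
#'
#' Mean reflectance over all crown pixels per band; with `mask = "sunlit"`
#' shaded pixels (shaded leaf and shaded ground) are excluded, emulating
#' threshold-based shadow-pixel removal, which keeps every sunlit pixel
#' within the crown footprint.
#'
#' @param survey a [render_survey()] result.
#' @param mask `"none"` (all crown pixels) or `"sunlit"`.
#' @return data.frame with `tree_id`, `n_px` and one column per band; trees
#'   with no eligible pixels get `NA` band values.
#' @export
extract_crown_reflectance <- function(survey, mask = c("none", "sunlit")) {
  mask <- match.arg(mask)
  bands <- dimnames(survey$bands)[[3]]
  ntree <- nrow(survey$truth)
  out <- data.frame(tree_id = survey$truth$tree_id, n_px = 0L)
  for (b in bands) out[[b]] <- NA_real_
  keep <- if (mask == "sunlit")
    survey$labels == 1L | survey$labels == 3L else TRUE
  for (j in seq_len(ntree)) {
    sel <- survey$crown_id == j & keep
    out$n_px[j] <- sum(sel)
    if (!any(sel)) next
    for (bi in seq_along(bands))
      out[[bands[bi]]][j] <- mean(survey$bands[, , bi][sel])
  }
  out
}
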