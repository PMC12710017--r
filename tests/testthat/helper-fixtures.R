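# Expensive fixtures are built lazily and cached for the whole test run.
# All fixtures are generated in code under fixed seeds; whichever test file
# needs one first triggers the build.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

fx_mini_lut <- function() fixture("mini_lut", function()
  build_lut(grid = lut_grid_mini(), seed = 1))

# full default grid: 20160 samples per hour, 161280 total
fx_full_lut <- function() fixture("full_lut", function() build_lut(seed = 1))

fx_ranking <- function() fixture("ranking", function()
  rank_vis(vi_case_r2(fx_full_lut())))

fx_selection <- function() fixture("selection", function()
  iterative_vi_selection(fx_ranking()$table$vi, fx_full_lut(), seed = 1,
                         max_train = 500, n_val = 2000))

# hourly four-component geometry at the default simulation scene, LAI 3
fx_diurnal <- function() fixture("diurnal", function() {
  site <- site_defaults()
  sc <- scene_with_lai(lut_scene(), 3)
  hours <- 9:16
  sf <- numeric(length(hours)); fe <- numeric(length(hours))
  imgs <- vector("list", length(hours))
  for (i in seq_along(hours)) {
    sun <- sun_position(site$latitude, site$longitude, site$date, hours[i],
                       site$utc_offset)
    imgs[[i]] <- render_four_component(sc, sun, resolution = 0.08,
                                       supersample = 2)
    sf[i] <- crown_shadow_fraction(imgs[[i]], 5)
    fe[i] <- estimate_fesc(sc, sun, n_photons = 20000, seed = 1)$fesc
  }
  list(hours = hours, shadow_fraction = sf, fesc = fe, images = imgs,
       scene = sc)
})

fx_survey <- function() fixture("survey", function() {
  layout <- orchard_preset("mini", seed = 11)
  truth <- sample_truth(nrow(layout), seed = 12)
  render_survey(layout, truth, time = 12, noise_std = 0.01, seed = 13)
})

fx_lcc_model <- function() fixture("lcc_model", function()
  train_lcc_model(fx_full_lut(), fx_selection()$chosen, seed = 5,
                  max_train = 800))

# full end-to-end inversion of the synthetic survey (masked and unmasked)
fx_inversion <- function() fixture("inversion", function() {
  survey <- fx_survey()
  truth <- survey$truth
  m_lcc <- fx_lcc_model()
  run_branch <- function(mask) {
    cr <- extract_crown_reflectance(survey, mask = mask)
    vis <- compute_vis(cr[, uav_bands()$name])
    vis$tree_id <- cr$tree_id
    set.seed(21)
    lai_meas <- truth$lai + stats::rnorm(nrow(truth), 0, 0.3)
    m_lai <- train_lai_model(vis, lai_meas, seed = 6)
    est <- predict_traits(m_lcc, m_lai, vis)
    list(est = est,
         lcc = evaluate_accuracy(truth$lcc, est$lcc),
         ccc = evaluate_accuracy(truth$ccc, est$ccc))
  }
  list(truth = truth, unmasked = run_branch("none"),
       masked = run_branch("sunlit"))
})

# hand-built four-component image for pure-function tests
manual_four_component <- function(labels, crown_id = NULL) {
  ny <- nrow(labels); nx <- ncol(labels)
  if (is.null(crown_id)) crown_id <- matrix(1L, ny, nx)
  f <- function(code) (labels == code) * 1.0
  structure(list(labels = labels, f_sl = f(1L), f_sh = f(2L), f_sg = f(3L),
                 f_shg = f(4L),
                 sunlit_leaf_fraction = ifelse(labels <= 2L, (labels == 1L) * 1.0, NA),
                 crown_id = crown_id, resolution = 1, supersample = 1,
                 extent = c(xmin = 0, xmax = nx, ymin = 0, ymax = ny),
                 sun = NULL),
            class = "four_component_image")
}
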