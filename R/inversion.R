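#' Seeded train/validation split
#'
#' Disjoint, exhaustive split with `round(ratio * n)` training rows from a
#' seeded shuffle.
#'
#' @param n number of samples (or a data.frame, whose rows are counted).
#' @param ratio training fraction in (0, 1); default 0.7 (the 7:3 split).
#' @param seed RNG seed.
#' @return list with integer index vectors `train` and `validation`.
#' @export
split_dataset <- function(n, ratio = 0.7, seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  if (n < 10) stop("split_dataset: need >= 10 samples")
  if (ratio <= 0 || ratio >= 1) stop("split_dataset: ratio must be in (0, 1)")
  set.seed(seed)
  idx <- sample.int(n)
  ntr <- round(ratio * n)
  list(train = sort(idx[seq_len(ntr)]), validation = sort(idx[-seq_len(ntr)]))
}

#' Accuracy metrics
#'
#' R2 (squared Pearson correlation; 0 when either side is constant), RMSE in
#' trait units and nRMSE = RMSE / mean(observed) * 100 (%).
#'
#' @param observed reference values.
#' @param predicted estimates, same length.
#' @return list with `r2`, `rmse`, `nrmse`.
#' @export
evaluate_accuracy <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2)
    stop("evaluate_accuracy: need equal lengths >= 2")
  if (mean(observed) == 0) stop("evaluate_accuracy: zero mean observed")
  r <- suppressWarnings(stats::cor(observed, predicted))
  r2 <- if (is.na(r)) 0 else r^2
  rmse <- sqrt(mean((observed - predicted)^2))
  list(r2 = r2, rmse = rmse, nrmse = rmse / mean(observed) * 100)
}

#' Iterative forward selection of shadow-resistant VIs
#'
#' Starting from the summed-rank order, VI prefixes of growing size are used
#' as features of a chlorophyll GPR model trained on the 7:3 split of the
#' lookup table. Under the default `"first_minimum"` rule the iteration
#' adds indices sequentially until the validation RMSE worsens materially
#' (exceeds the best value so far by more than `rel_tol` relative), then
#' picks the smallest evaluated prefix within `rel_tol` of the best - the
#' sequential add-until-accuracy-is-minimized procedure; `"within_tol"`
#' instead evaluates all `k_max` prefixes before applying the same
#' smallest-within-tolerance choice.
#'
#' @param ranked_vis character vector of VI names, best first.
#' @param lut a `canopy_lut`.
#' @param seed RNG seed (split, GPR).
#' @param k_max largest prefix evaluated.
#' @param rel_tol relative improvement / closeness tolerance.
#' @param rule stopping rule, see description.
#' @param max_train,n_val caps on GPR training rows and validation rows.
#' @param target trait column, default `"cab"`.
#' @return list of class `selection_result`: `ranked_vis`, `step_rmse`
#'   (evaluated prefixes), `chosen`, `split_seed`.
#' @export
iterative_vi_selection <- function(ranked_vis, lut, seed = 1L, k_max = 8,
                                   rel_tol = 0.01,
                                   rule = c("first_minimum", "within_tol"),
                                   max_train = 1000, n_val = 3000,
                                   target = "cab") {
  rule <- match.arg(rule)
  if (length(ranked_vis) < 1) stop("iterative_vi_selection: empty ranking")
  k_max <- min(k_max, length(ranked_vis))
  vis <- compute_vis(lut[, uav_bands()$name])
  sp <- split_dataset(nrow(lut), seed = seed)
  val <- sp$validation
  if (length(val) > n_val) {
    set.seed(seed + 1L)
    val <- sort(sample(val, n_val))
  }
  y_tr <- lut[[target]][sp$train]
  y_va <- lut[[target]][val]
  step_rmse <- numeric(0)
  for (k in seq_len(k_max)) {
    feats <- ranked_vis[seq_len(k)]
    m <- gpr_fit(vis[sp$train, feats, drop = FALSE], y_tr,
                 seed = seed + k, max_train = max_train)
    pred <- gpr_predict(m, vis[val, feats, drop = FALSE])
    step_rmse[k] <- sqrt(mean((y_va - pred)^2))
    if (rule == "first_minimum" && k > 1 &&
        step_rmse[k] > min(step_rmse[-k]) * (1 + rel_tol)) break
  }
  chosen_k <- min(which(step_rmse <= min(step_rmse) * (1 + rel_tol)))
  structure(list(ranked_vis = ranked_vis[seq_len(k_max)],
                 step_rmse = step_rmse,
                 chosen = ranked_vis[seq_len(chosen_k)],
                 split_seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> chosen ", length(x$chosen), " VIs: ",
      paste(x$chosen, collapse = ", "), "\n", sep = "")
  cat("  validation RMSE by prefix: ",
      paste(sprintf("%.3f", x$step_rmse), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' VI feature set of the LAI model
#' @return character vector of registry names.
#' @export
lai_feature_vis <- function() {
  c("NDVI", "MTVI2", "OSAVI", "NDVI-RE", "CIre", "CIgreen")
}

#' Train the chlorophyll GPR on a lookup table
#'
#' @param lut a `canopy_lut`.
#' @param chosen VI feature names (e.g. from [iterative_vi_selection()]).
#' @param seed RNG seed.
#' @param max_train GPR training-row cap.
#' @param target trait column, default `"cab"`.
#' @return a `gpr_model` with the feature names attached.
#' @export
train_lcc_model <- function(lut, chosen, seed = 1L, max_train = 1000,
                            target = "cab") {
  vis <- compute_vis(lut[, uav_bands()$name])
  sp <- split_dataset(nrow(lut), seed = seed)
  gpr_fit(vis[sp$train, chosen, drop = FALSE], lut[[target]][sp$train],
          seed = seed, max_train = max_train)
}

#' Calibrate the LAI GPR on measured trees
#'
#' Mirrors the field calibration: a modest set of trees with (noisy) LAI
#' measurements and their crown VI vectors trains a GPR with the fixed
#' six-VI feature set of [lai_feature_vis()].
#'
#' @param vis data.frame of VI values for the calibration trees (must
#'   contain the [lai_feature_vis()] columns).
#' @param lai_measured measured LAI per calibration tree.
#' @param seed RNG seed.
#' @return a `gpr_model`.
#' @export
train_lai_model <- function(vis, lai_measured, seed = 1L) {
  feats <- lai_feature_vis()
  miss <- setdiff(feats, names(vis))
  if (length(miss)) stop("train_lai_model: missing VI columns: ",
                         paste(miss, collapse = ", "))
  gpr_fit(vis[, feats, drop = FALSE], lai_measured, seed = seed)
}

#' Per-tree trait retrieval
#'
#' Applies the chlorophyll and LAI models to per-tree VI vectors (computed
#' from crown-mean band reflectance) and forms the canopy chlorophyll
#' content as the exact product CCC = LCC x LAI.
#'
#' @param model_lcc chlorophyll `gpr_model` (features must be VI columns of
#'   `vis`).
#' @param model_lai LAI `gpr_model`.
#' @param vis data.frame of per-tree VI values; a `tree_id` column is
#'   carried through when present.
#' @return data.frame of class `trait_estimates` with `tree_id`, `lcc`,
#'   `lcc_sd`, `lai`, `lai_sd`, `ccc`.
#' @export
predict_traits <- function(model_lcc, model_lai, vis) {
  tree_id <- if ("tree_id" %in% names(vis)) vis$tree_id else seq_len(nrow(vis))
  f_lcc <- model_lcc$feature_names
  f_lai <- model_lai$feature_names
  miss <- setdiff(union(f_lcc, f_lai), names(vis))
  if (length(miss)) stop("predict_traits: missing VI columns: ",
                         paste(miss, collapse = ", "))
  p_lcc <- gpr_predict(model_lcc, vis[, f_lcc, drop = FALSE], se = TRUE)
  p_lai <- gpr_predict(model_lai, vis[, f_lai, drop = FALSE], se = TRUE)
  out <- data.frame(tree_id = tree_id,
                    lcc = p_lcc$mean, lcc_sd = p_lcc$sd,
                    lai = p_lai$mean, lai_sd = p_lai$sd)
  out$ccc <- out$lcc * out$lai
  class(out) <- c("trait_estimates", "data.frame")
  out
}
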