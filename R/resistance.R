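#' Best curve-fit R2 between a VI and chlorophyll
#'
#' Least-squares fits of chlorophyll on the index value (calibration
#' direction: the VI is the regressor) over a configurable family set;
#' returns the maximum R2 = 1 - SS_res/SS_tot. Zero variance in `cab`
#' returns 0 by convention.
#'
#' @param vi index values.
#' @param cab chlorophyll values.
#' @param families subset of `c("linear", "quadratic")`.
#' @return R2 in `[0, 1]`.
#' @export
fit_vi_cab_r2 <- function(vi, cab, families = c("linear", "quadratic")) {
  ok <- is.finite(vi) & is.finite(cab)
  vi <- vi[ok]; cab <- cab[ok]
  if (length(vi) < 3) stop("fit_vi_cab_r2: need >= 3 finite pairs")
  sstot <- sum((cab - mean(cab))^2)
  if (sstot == 0) return(0)
  r2 <- 0
  for (fam in families) {
    X <- switch(fam,
                linear = cbind(1, vi),
                quadratic = cbind(1, vi, vi^2),
                stop("fit_vi_cab_r2: unknown family ", fam))
    fit <- stats::lm.fit(X, cab)
    ssres <- sum(fit$residuals^2)
    r2 <- max(r2, 1 - ssres / sstot)
  }
  min(max(r2, 0), 1)
}

#' Per-case R2 table for all registry VIs
#'
#' Splits a lookup table into shadow scenarios (one per acquisition hour,
#' pooling all structural levels at that hour) and computes the curve-fit
#' R2 of every VI against chlorophyll in each scenario.
#'
#' @param lut a `canopy_lut` (needs band columns, `time` and `cab`).
#' @param families fit family set, see [fit_vi_cab_r2()].
#' @return numeric matrix (VI x case) with case columns in time order;
#'   attribute `times` maps cases to hours.
#' @export
vi_case_r2 <- function(lut, families = c("linear", "quadratic")) {
  vis <- compute_vis(lut[, uav_bands()$name])
  times <- sort(unique(lut$time))
  out <- matrix(NA_real_, ncol(vis), length(times),
                dimnames = list(names(vis), paste0("case", seq_along(times))))
  for (ci in seq_along(times)) {
    sel <- lut$time == times[ci]
    if (sum(sel) < 30) stop("vi_case_r2: fewer than 30 samples in case ", ci)
    for (vi in seq_len(ncol(vis)))
      out[vi, ci] <- fit_vi_cab_r2(vis[sel, vi], lut$cab[sel], families)
  }
  attr(out, "times") <- times
  out
}

#' Rank VIs by shadow resistance
#'
#' Within each case, VIs are ranked by descending R2 (rank 1 = highest,
#' ties broken by registry order); ranks are summed over cases and the
#' result sorted by ascending summed rank. Small summed ranks mark indices
#' whose relationship with chlorophyll is stable across shadow scenarios.
#'
#' @param r2_table matrix VI x case, as from [vi_case_r2()].
#' @return list of class `ranking_table`: `table` (data.frame `vi`,
#'   `summed_rank`, sorted), `ranks` (VI x case), `r2` (input matrix).
#' @export
rank_vis <- function(r2_table) {
  if (any(!is.finite(r2_table))) stop("rank_vis: missing cells in R2 table")
  nvi <- nrow(r2_table)
  ranks <- apply(r2_table, 2, function(col) {
    ord <- order(-col, seq_len(nvi))   # registry order breaks ties
    rk <- integer(nvi); rk[ord] <- seq_len(nvi); rk
  })
  dimnames(ranks) <- dimnames(r2_table)
  summed <- rowSums(ranks)
  ord <- order(summed, seq_len(nvi))
  tab <- data.frame(vi = rownames(r2_table)[ord], summed_rank = summed[ord],
                    row.names = NULL)
  structure(list(table = tab, ranks = ranks, r2 = r2_table),
            class = "ranking_table")
}

#' @export
print.ranking_table <- function(x, ...) {
  cat("<ranking_table> ", nrow(x$r2), " VIs x ", ncol(x$r2), " cases\n", sep = "")
  print(utils::head(x$table, 8))
  invisible(x)
}

#' Baseline-referenced rate of change
#'
#' Absolute relative change of a diurnal series against a reference time,
#' |x_t - x_ref| / |x_ref| (the reference time, usually the minimum-shadow
#' hour, maps to 0).
#'
#' @param series named numeric vector (names = times).
#' @param reference name of the reference time.
#' @return named vector of non-negative relative changes.
#' @export
rate_of_change <- function(series, reference) {
  reference <- as.character(reference)
  if (!reference %in% names(series)) stop("rate_of_change: reference not in series")
  xr <- series[[reference]]
  if (xr == 0) stop("rate_of_change: zero reference value")
  out <- abs(series - xr) / abs(xr)
  names(out) <- names(series)
  out
}

#' VI sensitivity to the target and to disturbance factors
#'
#' Computes each VI's curve-fit R2 against the target variable (chlorophyll)
#' and against each nuisance column of the lookup table, using the same
#' machinery as the shadow-resistance ranking. A useful index has high
#' target R2 and low nuisance R2.
#'
#' @param lut a `canopy_lut`.
#' @param target column name of the target (default `"cab"`).
#' @param nuisances column names of disturbance factors.
#' @param families fit family set.
#' @return data.frame VI x (target, nuisances) of R2 values.
#' @export
disturbance_sensitivity <- function(lut, target = "cab",
                                    nuisances = c("lai", "shadow_fraction"),
                                    families = c("linear", "quadratic")) {
  vars <- c(target, nuisances)
  for (v in vars) {
    if (!v %in% names(lut)) stop("disturbance_sensitivity: no column ", v)
    if (length(unique(lut[[v]])) < 3)
      stop("disturbance_sensitivity: degenerate grid for ", v)
  }
  vis <- compute_vis(lut[, uav_bands()$name])
  out <- matrix(NA_real_, ncol(vis), length(vars),
                dimnames = list(names(vis), vars))
  for (v in vars) for (vi in seq_len(ncol(vis)))
    out[vi, v] <- fit_vi_cab_r2(vis[[vi]], lut[[v]], families)
  as.data.frame(out)
}
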