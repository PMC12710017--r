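#' Write a matrix as an ESRI ASCII grid
#'
#' Plain-text raster format readable by standard GIS tools. Matrix rows are
#' written north-up (row 1 = northernmost), so the input matrix (row 1 =
#' ymin) is flipped on output.
#'
#' @param m numeric matrix (rows = y ascending, cols = x ascending).
#' @param path output `.asc` path.
#' @param xll,yll lower-left corner coordinates.
#' @param cellsize pixel size.
#' @param nodata value written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(m, path, xll = 0, yll = 0, cellsize = 1,
                             nodata = -9999) {
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)),
               paste("nrows", nrow(m)),
               paste("xllcorner", xll),
               paste("yllcorner", yll),
               paste("cellsize", cellsize),
               paste("NODATA_value", nodata)), con)
  utils::write.table(m[rev(seq_len(nrow(m))), , drop = FALSE], con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a four-component image to disk
#'
#' Single-band label raster (codes per [component_levels()]) plus the
#' crown-id raster, both as ASCII grids.
#'
#' @param img a `four_component_image`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return written paths, invisibly.
#' @export
write_four_component <- function(img, dir, prefix = "four_component") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  xll <- img$extent["xmin"]; yll <- img$extent["ymin"]
  p1 <- file.path(dir, paste0(prefix, "_labels.asc"))
  p2 <- file.path(dir, paste0(prefix, "_crown_id.asc"))
  write_ascii_grid(img$labels, p1, xll, yll, img$resolution)
  write_ascii_grid(img$crown_id, p2, xll, yll, img$resolution, nodata = 0)
  invisible(c(p1, p2))
}

#' Write a synthetic survey to disk
#'
#' One ASCII grid per band, one for the crown-id map, one for the
#' four-component labels, plus the ground-truth CSV.
#'
#' @param survey a [render_survey()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_survey <- function(survey, dir, prefix = "survey") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  xll <- survey$extent["xmin"]; yll <- survey$extent["ymin"]
  cs <- survey$resolution
  paths <- character(0)
  for (b in dimnames(survey$bands)[[3]]) {
    p <- file.path(dir, paste0(prefix, "_", tolower(b), ".asc"))
    write_ascii_grid(survey$bands[, , b], p, xll, yll, cs)
    paths <- c(paths, p)
  }
  p <- file.path(dir, paste0(prefix, "_crown_id.asc"))
  write_ascii_grid(survey$crown_id, p, xll, yll, cs, nodata = 0)
  paths <- c(paths, p)
  p <- file.path(dir, paste0(prefix, "_labels.asc"))
  write_ascii_grid(survey$labels, p, xll, yll, cs)
  paths <- c(paths, p)
  p <- file.path(dir, paste0(prefix, "_truth.csv"))
  utils::write.csv(cbind(survey$truth,
                         shadow_fraction = survey$shadow_fraction),
                   p, row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
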