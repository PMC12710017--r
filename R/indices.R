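#' Five-band UAV sensor definition
#'
#' Band centres 450 (BLUE), 560 (GREEN), 650 (RED), 730 (REDEDGE) and
#' 840 nm (NIR), each with a 16 nm half-width boxcar response. Note the
#' conventional green/red assignment is used (green at 560 nm, red at
#' 650 nm).
#'
#' @return data.frame with `name`, `center`, `halfwidth`.
#' @export
uav_bands <- function() {
  data.frame(name = c("BLUE", "GREEN", "RED", "REDEDGE", "NIR"),
             center = c(450, 560, 650, 730, 840),
             halfwidth = 16)
}

#' Resample a 1-nm spectrum to sensor bands
#'
#' Boxcar response: per band, the mean of the spectrum over
#' `[center - halfwidth, center + halfwidth]`.
#'
#' @param wavelength nm grid of the spectrum.
#' @param values reflectance values on that grid.
#' @param bands band definition, default [uav_bands()].
#' @return named numeric vector of band reflectances.
#' @export
resample_to_bands <- function(wavelength, values, bands = uav_bands()) {
  out <- numeric(nrow(bands))
  for (i in seq_len(nrow(bands))) {
    lo <- bands$center[i] - bands$halfwidth[i]
    hi <- bands$center[i] + bands$halfwidth[i]
    sel <- wavelength >= lo & wavelength <= hi
    if (!any(sel) || min(wavelength) > lo || max(wavelength) < hi)
      stop("resample_to_bands: spectrum does not cover band ", bands$name[i])
    out[i] <- mean(values[sel])
  }
  names(out) <- bands$name
  out
}

# division that propagates undefined values instead of returning Inf
.sdiv <- function(num, den) {
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Broadband vegetation-index registry
#'
#' Twenty-one canonical broadband VI definitions over the five sensor bands
#' (B, G, R, RE, N). The registry order is the deterministic tie-break used
#' by the shadow-resistance ranking. Each entry is a function of a list of
#' band reflectance vectors; zero denominators yield `NA`.
#'
#' @return named list of functions.
#' @export
vi_registry <- function() {
  list(
    "NDVI-RE" = function(b) .sdiv(b$N - b$RE, b$N + b$RE),
    "CIre" = function(b) .sdiv(b$N, b$RE) - 1,
    "TVI" = function(b) 0.5 * (120 * (b$N - b$G) - 200 * (b$R - b$G)),
    "CIgreen" = function(b) .sdiv(b$N, b$G) - 1,
    "GNDVI" = function(b) .sdiv(b$N - b$G, b$N + b$G),
    "SR(RE/G)" = function(b) .sdiv(b$RE, b$G),
    "SR(NIR/R)" = function(b) .sdiv(b$N, b$R),
    "mSR" = function(b) .sdiv(.sdiv(b$N, b$R) - 1, sqrt(.sdiv(b$N, b$R)) + 1),
    "MTVI1" = function(b) 1.2 * (1.2 * (b$N - b$G) - 2.5 * (b$R - b$G)),
    "NDVI" = function(b) .sdiv(b$N - b$R, b$N + b$R),
    "NLI" = function(b) .sdiv(b$N^2 - b$R, b$N^2 + b$R),
    "TCARI" = function(b) 3 * ((b$RE - b$R) - 0.2 * (b$RE - b$G) * .sdiv(b$RE, b$R)),
    "TCARI/OSAVI" = function(b) {
      tcari <- 3 * ((b$RE - b$R) - 0.2 * (b$RE - b$G) * .sdiv(b$RE, b$R))
      osavi <- 1.16 * (b$N - b$R) / (b$N + b$R + 0.16)
      .sdiv(tcari, osavi)
    },
    "OSAVI" = function(b) 1.16 * (b$N - b$R) / (b$N + b$R + 0.16),
    "EVI" = function(b) 2.5 * .sdiv(b$N - b$R, b$N + 6 * b$R - 7.5 * b$B + 1),
    "MSAVI" = function(b) 0.5 * (2 * b$N + 1 - sqrt(pmax((2 * b$N + 1)^2 - 8 * (b$N - b$R), 0))),
    "RDVI" = function(b) .sdiv(b$N - b$R, sqrt(pmax(b$N + b$R, 0))),
    "TDVI" = function(b) 1.5 * (b$N - b$R) / sqrt(b$N^2 + b$R + 0.5),
    "DVI" = function(b) b$N - b$R,
    "MCARI" = function(b) ((b$RE - b$R) - 0.2 * (b$RE - b$G)) * .sdiv(b$RE, b$R),
    "MTVI2" = function(b) {
      disc <- (2 * b$N + 1)^2 - (6 * b$N - 5 * sqrt(pmax(b$R, 0))) - 0.5
      .sdiv(1.5 * (1.2 * (b$N - b$G) - 2.5 * (b$R - b$G)), sqrt(pmax(disc, 0)))
    }
  )
}

# accepts a named vector/list/data.frame of band reflectances and returns a
# list of vectors keyed B, G, R, RE, N
.band_list <- function(bands) {
  if (is.data.frame(bands)) bands <- as.list(bands)
  if (is.numeric(bands)) bands <- as.list(bands)
  key <- c(BLUE = "B", GREEN = "G", RED = "R", REDEDGE = "RE", NIR = "N",
           B = "B", G = "G", R = "R", RE = "RE", N = "N")
  out <- list()
  for (nm in names(bands)) if (nm %in% names(key)) out[[key[[nm]]]] <- bands[[nm]]
  need <- c("B", "G", "R", "RE", "N")
  if (!all(need %in% names(out)))
    stop("compute_vi: bands must include ", paste(need, collapse = ", "))
  out
}

#' Compute one vegetation index
#' @param bands named band reflectances (names `BLUE..NIR` or `B,G,R,RE,N`);
#'   values may be vectors.
#' @param name registry name, e.g. `"NDVI-RE"`.
#' @return index value(s).
#' @export
compute_vi <- function(bands, name) {
  reg <- vi_registry()
  if (!name %in% names(reg)) stop("compute_vi: unknown VI ", name)
  reg[[name]](.band_list(bands))
}

#' Compute the full vegetation-index set
#' @param bands named band reflectances; values may be vectors (e.g. columns
#'   of a sample table).
#' @return data.frame with one column per registry VI, registry order.
#' @export
compute_vis <- function(bands) {
  b <- .band_list(bands)
  reg <- vi_registry()
  out <- lapply(reg, function(f) f(b))
  as.data.frame(out, check.names = FALSE, optional = TRUE)
}
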