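#' Geometric sequence of granularity band scales
#'
#' Scales grow geometrically from `start` by `factor` while not exceeding
#' `end`; the defaults (2 px to 100 px, factor 1.414) give 12 bands
#' 2, 2.83, 4, ..., 90.5 px.
#'
#' @param start Smallest marking scale in px.
#' @param end Largest scale allowed in px.
#' @param factor Geometric step (> 1).
#' @return Numeric vector of band scales (possibly empty if `end < start`).
#' @export
granularity_bands <- function(start = 2, end = 100, factor = 1.414) {
  if (start < 1) stop("start must be >= 1", call. = FALSE)
  if (factor <= 1) stop("factor must be > 1", call. = FALSE)
  if (end < start) return(numeric(0))
  kmax <- floor(log(end / start) / log(factor) + 1e-9)
  start * factor^(0:kmax)
}

# Raised-cosine radial band-pass response for one band, on the log-wavelength
# axis: full response at wavelength == scale, falling to zero at the
# geometric midpoints to the adjacent bands (t = +/- 1/2 in units of
# log(factor)). H(0 frequency) is identically 0, so every band is
# mean-invariant.
band_response <- function(wavelength, scale, factor) {
  t <- log(wavelength / scale) / log(factor)
  h <- numeric(length(t))
  in_band <- is.finite(t) & abs(t) <= 0.5
  h[in_band] <- cos(pi * t[in_band])^2
  dim(h) <- dim(t)
  h
}

# Frequency-domain filter matrix for an nr x nc image.
band_filter_matrix <- function(nr, nc, scale, factor) {
  fx <- seq_len(nr) - 1L
  fx <- ifelse(fx > nr / 2, fx - nr, fx) / nr
  fy <- seq_len(nc) - 1L
  fy <- ifelse(fy > nc / 2, fy - nc, fy) / nc
  r <- sqrt(outer(fx^2, fy^2, "+"))
  wavelength <- ifelse(r > 0, 1 / r, Inf)
  band_response(wavelength, scale, factor)
}

#' Granularity spectrum of an image region
#'
#' Decomposes the luminance image into a geometric series of spatial
#' frequency bands by Fourier band-pass filtering, and measures the "energy"
#' of each band as the standard deviation of the band-filtered pixels inside
#' the region of interest. A band's scale is the Fourier wavelength in px it
#' passes at full response. Pixels outside the mask are replaced by the ROI
#' mean before the transform to avoid spurious mask-edge energy; the image
#' is cropped to the mask's bounding box.
#'
#' @param x A numeric matrix (luminance image) or a `multichannel_specimen`
#'   (its `lw` channel is used, the luminance convention here).
#' @param roi For a specimen: ROI label (`"FW"`, `"HW"`, `"TH"`, `"AB"`).
#' @param mask For a matrix: optional logical matrix selecting the ROI
#'   (default: whole image).
#' @param bands Band scales, see [granularity_bands()].
#' @param factor Geometric step used for the band shapes.
#' @return List of class `granularity_spectrum`: `scales`, `energy`.
#' @export
granularity_spectrum <- function(x, roi = NULL, mask = NULL,
                                 bands = granularity_bands(),
                                 factor = 1.414) {
  if (inherits(x, "multichannel_specimen")) {
    if (is.null(roi)) stop("roi required for a specimen", call. = FALSE)
    mask <- x$mask == ROI_CODES[[roi]]
    x <- x$channels$lw
  }
  stopifnot(is.matrix(x))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(x), ncol(x))
  if (!any(mask)) stop("empty ROI", call. = FALSE)
  if (length(bands) == 0L) {
    return(structure(list(scales = numeric(0), energy = numeric(0)),
                     class = "granularity_spectrum"))
  }

  # crop to bounding box, mean-pad outside the mask
  rows <- range(which(apply(mask, 1, any)))
  cols <- range(which(apply(mask, 2, any)))
  sub <- x[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  msub <- mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  mu <- mean(sub[msub])
  sub[!msub] <- mu
  if (max(bands) * 2 > max(dim(sub))) {
    warning(warningCondition(
      paste("ROI bounding box is less than twice the largest band scale;",
            "large-scale energies are poorly resolved"),
      class = "granularity_scale_warning"))
  }

  ft <- stats::fft(sub)
  energy <- vapply(bands, function(s) {
    h <- band_filter_matrix(nrow(sub), ncol(sub), s, factor)
    filt <- Re(stats::fft(ft * h, inverse = TRUE)) / length(sub)
    stats::sd(filt[msub])
  }, numeric(1))

  structure(list(scales = bands, energy = energy),
            class = "granularity_spectrum")
}

#' Summarise a granularity spectrum
#'
#' * dominance (`maxPower`): the peak band energy;
#' * diversity (`propPower`): peak energy over summed energy (0, flagged, if
#'   all energies are zero);
#' * marking size (`maxFreq`): the scale of the peak band (ties broken
#'   toward the smallest scale and flagged);
#' * pattern contrast: the root of the summed squared band energies, a
#'   package convention for an otherwise loosely specified summary.
#'
#' @param gs A `granularity_spectrum`.
#' @return List: `dominance`, `diversity`, `marking_size`,
#'   `pattern_contrast`, `flags` (character vector).
#' @export
pattern_summaries <- function(gs) {
  stopifnot(inherits(gs, "granularity_spectrum"))
  if (length(gs$energy) < 1L) stop("empty spectrum", call. = FALSE)
  flags <- character(0)
  total <- sum(gs$energy)
  peak <- max(gs$energy)
  if (total == 0) {
    diversity <- 0
    flags <- c(flags, "all-zero energies")
  } else {
    diversity <- peak / total
  }
  at_peak <- which(gs$energy == peak)
  if (length(at_peak) > 1L) flags <- c(flags, "peak tie (smallest scale used)")
  list(dominance = peak,
       diversity = diversity,
       marking_size = gs$scales[at_peak[1L]],
       pattern_contrast = sqrt(sum(gs$energy^2)),
       flags = flags)
}
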