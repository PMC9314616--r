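#' Calibrate raw camera responses to reflectance
#'
#' Affine calibration against two grey standards that reflect 7% and 93%
#' across the working spectrum: the dark standard's response maps to 0.07
#' and the bright standard's to 0.93; results are clipped to `[0, 1]`.
#'
#' @param raw Numeric raster (or vector) of raw responses, one channel.
#' @param dark_std_response,bright_std_response Measured responses of the
#'   7% and 93% standards in this channel.
#' @return Calibrated reflectance raster in `[0, 1]`.
#' @export
calibrate_reflectance <- function(raw, dark_std_response,
                                  bright_std_response) {
  if (!is.numeric(dark_std_response) || !is.numeric(bright_std_response) ||
      bright_std_response <= dark_std_response) {
    stop("bright standard response must exceed dark standard response",
         call. = FALSE)
  }
  slope <- (0.93 - 0.07) / (bright_std_response - dark_std_response)
  clip01(0.07 + (raw - dark_std_response) * slope)
}

#' Mean reflectance per channel over one ROI
#'
#' @param spec A `multichannel_specimen`.
#' @param roi ROI label.
#' @return List: `means` (named over uv/sw/mw/lw), `area` (pixel count).
#' @export
roi_colour_means <- function(spec, roi) {
  stopifnot(inherits(spec, "multichannel_specimen"))
  roi <- match.arg(roi, ROIS)
  sel <- spec$mask == ROI_CODES[[roi]]
  if (!any(sel)) stop("empty ROI: ", roi, call. = FALSE)
  means <- vapply(spec$channels[CHANNELS],
                  function(ch) mean(ch[sel]), numeric(1))
  list(means = means, area = sum(sel))
}

#' Luminance histogram over equal-width bands
#'
#' The long-wave channel is the luminance proxy; reflectance is rescaled to
#' the `[0, 65535]` dynamic range of a 32-bit image and binned into
#' `n_bands` equal-width bands (first band closed at 0, last closed at the
#' maximum).
#'
#' @param spec A `multichannel_specimen`.
#' @param roi ROI label.
#' @param n_bands Number of bands (default 20).
#' @param max_value Top of the luminance range (default 65535).
#' @return Numeric vector of band proportions summing to 1.
#' @export
luminance_band_histogram <- function(spec, roi, n_bands = 20L,
                                     max_value = 65535) {
  stopifnot(inherits(spec, "multichannel_specimen"))
  roi <- match.arg(roi, ROIS)
  sel <- spec$mask == ROI_CODES[[roi]]
  if (!any(sel)) stop("empty ROI: ", roi, call. = FALSE)
  lum <- spec$channels$lw[sel] * max_value
  breaks <- seq(0, max_value, length.out = n_bands + 1L)
  counts <- tabulate(pmin(findInterval(lum, breaks, rightmost.closed = TRUE,
                                       left.open = FALSE),
                          n_bands),
                     nbins = n_bands)
  counts / sum(counts)
}

#' Allometric area ratios between ROIs
#'
#' @param areas Named numeric vector of pixel areas with entries `FW`, `HW`,
#'   `TH`, `AB`.
#' @return Named vector `FW_AB`, `FW_TH`, `FW_HW`, `TH_AB`.
#' @export
allometric_ratios <- function(areas) {
  needed <- c("FW", "HW", "TH", "AB")
  if (!all(needed %in% names(areas))) {
    stop("areas must be named with FW, HW, TH, AB", call. = FALSE)
  }
  if (any(areas[needed] <= 0)) stop("zero-area ROI", call. = FALSE)
  c(FW_AB = unname(areas["FW"] / areas["AB"]),
    FW_TH = unname(areas["FW"] / areas["TH"]),
    FW_HW = unname(areas["FW"] / areas["HW"]),
    TH_AB = unname(areas["TH"] / areas["AB"]))
}

specimen_features <- function(spec, bands, include_luminance) {
  areas <- numeric(0)
  row <- list()
  for (roi in ROIS) {
    cm <- roi_colour_means(spec, roi)
    areas[roi] <- cm$area
    row[[paste0(roi, "_area")]] <- cm$area
    for (ch in CHANNELS) row[[paste0(roi, "_", ch)]] <- unname(cm$means[ch])
    # bands larger than the ROI box carry zero energy by construction;
    # the scale warning is expected here and muffled
    gs <- withCallingHandlers(
      granularity_spectrum(spec, roi, bands = bands),
      granularity_scale_warning = function(w) invokeRestart("muffleWarning"))
    ps <- pattern_summaries(gs)
    row[[paste0(roi, "_pattern_dominance")]] <- ps$dominance
    row[[paste0(roi, "_pattern_diversity")]] <- ps$diversity
    row[[paste0(roi, "_marking_size")]] <- ps$marking_size
    row[[paste0(roi, "_pattern_contrast")]] <- ps$pattern_contrast
    if (include_luminance) {
      lb <- luminance_band_histogram(spec, roi)
      for (b in seq_along(lb)) {
        row[[sprintf("%s_lum%02d", roi, b)]] <- lb[b]
      }
    }
  }
  ar <- allometric_ratios(areas)
  for (nm in names(ar)) row[[paste0("ratio_", nm)]] <- unname(ar[nm])
  row
}

#' Build the per-specimen feature table of a cohort
#'
#' Applies the colour, pattern and allometry metrics to every specimen.
#' Columns follow the `ROI_metric` convention (area, four channel means and
#' four pattern summaries per ROI, plus the four area ratios); the 20-band
#' luminance histograms are computed on request but excluded from the
#' default set. Per-specimen failures are caught and flagged rather than
#' aborting the table.
#'
#' @param cohort A `specimen_cohort` (or plain list of specimens).
#' @param bands Granularity band scales.
#' @param include_luminance Append `ROI_lumNN` histogram columns?
#' @return Data frame with `id`, `genotype`, `sex`, a logical `failed`
#'   column and one column per feature.
#' @export
build_feature_table <- function(cohort, bands = granularity_bands(),
                                include_luminance = FALSE) {
  specimens <- if (inherits(cohort, "specimen_cohort")) {
    cohort$specimens
  } else {
    cohort
  }
  rows <- lapply(specimens, function(sp) {
    feat <- tryCatch(specimen_features(sp, bands, include_luminance),
                     error = function(e) NULL)
    meta <- data.frame(id = sp$id, genotype = sp$genotype, sex = sp$sex,
                       failed = is.null(feat), stringsAsFactors = FALSE)
    if (is.null(feat)) meta else cbind(meta, as.data.frame(feat))
  })
  ok <- rows[!vapply(rows, function(r) isTRUE(r$failed), logical(1))]
  if (!length(ok)) stop("no specimen yielded features", call. = FALSE)
  template <- names(ok[[1]])
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(template, names(r))) r[[nm]] <- NA_real_
    r[template]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Greedy correlation filter over feature columns
#'
#' Computes pairwise Pearson correlations and repeatedly drops, from the
#' most correlated remaining pair above the threshold, the member with the
#' larger mean absolute correlation to all other remaining features (a
#' deterministic order). Zero-variance columns are dropped first with their
#' own reason.
#'
#' @param table Feature data frame (non-numeric columns are carried along,
#'   never dropped).
#' @param threshold Absolute correlation above which a pair is reduced.
#' @return List: `retained` (column names), `dropped` (data frame
#'   `feature`, `reason`), `table` (filtered data frame).
#' @export
drop_correlated_features <- function(table, threshold = 0.9) {
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  num <- setdiff(num, "failed")
  if (nrow(table) < 2L) stop("need at least 2 rows", call. = FALSE)
  dropped <- data.frame(feature = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  sds <- vapply(table[num], stats::sd, numeric(1))
  zv <- num[sds == 0 | is.na(sds)]
  if (length(zv)) {
    dropped <- rbind(dropped, data.frame(feature = zv, reason = "zero variance",
                                         stringsAsFactors = FALSE))
  }
  keep <- setdiff(num, zv)
  if (length(keep) >= 2L) {
    cm <- abs(stats::cor(table[keep]))
    diag(cm) <- 0
    while (max(cm) > threshold) {
      ij <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
      cand <- rownames(cm)[ij]
      mean_abs <- colMeans(cm[, cand, drop = FALSE])
      drop <- cand[order(-mean_abs, cand)][1L]
      other <- setdiff(cand, drop)
      dropped <- rbind(dropped, data.frame(
        feature = drop,
        reason = sprintf("|r| = %.3f with %s", max(cm), other),
        stringsAsFactors = FALSE))
      keepers <- setdiff(rownames(cm), drop)
      cm <- cm[keepers, keepers, drop = FALSE]
      if (length(keepers) < 2L) break
    }
    keep <- rownames(cm)
  }
  retained <- c(setdiff(names(table), num), keep)
  list(retained = keep,
       dropped = dropped,
       table = table[, names(table) %in% retained, drop = FALSE])
}
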