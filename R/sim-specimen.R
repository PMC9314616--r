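CHANNELS <- c("uv", "sw", "mw", "lw")
ROIS <- c("FW", "HW", "TH", "AB")
ROI_CODES <- c(background = 0L, FW = 1L, HW = 2L, TH = 3L, AB = 4L)

#' Appearance configuration for synthetic specimen images
#'
#' Per (genotype, sex, ROI, channel) mean reflectance and pixel noise sd,
#' plus forewing marking parameters per (genotype, sex), the image size and
#' the fixed ROI layout. The defaults encode the qualitative genotype
#' effects the downstream analyses probe:
#'
#' * `WW` vs `Wy` (both white-hindwinged) differ only in UV reflectance —
#'   lower thorax, abdomen and hindwing UV in the homozygote — so receivers
#'   and classifiers without UV access cannot tell them apart;
#' * `yy` hindwings have high long-wave and low short-wave reflectance
#'   (yellow) and smaller forewing markings.
#'
#' Two noise scales: `specimen_sd` perturbs each (ROI, channel) mean once per
#' individual (between-specimen variation), `sd` in `means` is per-pixel
#' noise. Values are clipped to the `[0, 1]` reflectance range.
#'
#' @param image_size Side of the square image in px.
#' @param specimen_sd Between-specimen sd applied to each ROI x channel mean.
#' @param means Data frame `genotype, sex, roi, channel, mean, sd`;
#'   `NULL` uses the defaults described above.
#' @param markings Data frame `genotype, sex, scale, count, reflectance`
#'   describing dark forewing markings (disk diameter `scale` px).
#' @return List of class `appearance_config`.
#' @export
appearance_config <- function(image_size = 96L,
                              specimen_sd = 0.03,
                              means = NULL,
                              markings = NULL) {
  image_size <- check_count(image_size, "image_size", min = 16L)
  if (is.null(means)) means <- default_appearance_means()
  if (is.null(markings)) markings <- default_markings()
  stopifnot(all(c("genotype", "sex", "roi", "channel", "mean", "sd") %in%
                  names(means)))
  if (any(means$mean < 0 | means$mean > 1 | means$sd < 0 | means$sd > 1)) {
    stop("reflectance means and sds must lie in [0, 1]", call. = FALSE)
  }
  if (any(markings$scale < 2 | markings$scale > image_size)) {
    stop("marking scale must be >= 2 px and <= image size", call. = FALSE)
  }
  structure(
    list(image_size = image_size, specimen_sd = specimen_sd,
         means = means, markings = markings,
         layout = default_layout(image_size)),
    class = "appearance_config"
  )
}

# Fixed ROI layout: wings on the left, body (thorax over abdomen) on the
# right, scaled to the image size. Rectangles given as row/col ranges.
default_layout <- function(size) {
  u <- size / 96
  rect <- function(r1, r2, c1, c2) {
    c(r1 = max(1L, round(r1 * u)), r2 = round(r2 * u),
      c1 = max(1L, round(c1 * u)), c2 = round(c2 * u))
  }
  list(FW = rect(6, 45, 6, 45),
       HW = rect(51, 90, 6, 45),
       TH = rect(6, 45, 56, 75),
       AB = rect(51, 90, 56, 75))
}

default_appearance_means <- function() {
  base <- expand.grid(genotype = GENOTYPES,
                      sex = c("male", "female"),
                      roi = ROIS, channel = CHANNELS,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  m <- function(geno, roi, channel) {
    # shared (genotype-independent) base reflectances
    v <- switch(roi,
      FW = c(uv = 0.25, sw = 0.70, mw = 0.70, lw = 0.75),
      HW = c(uv = 0.30, sw = 0.80, mw = 0.80, lw = 0.85),
      TH = c(uv = 0.30, sw = 0.25, mw = 0.30, lw = 0.35),
      AB = c(uv = 0.28, sw = 0.30, mw = 0.35, lw = 0.40))[channel]
    # genotype effects
    if (roi == "HW") {
      if (geno == "yy") {
        v <- c(uv = 0.15, sw = 0.25, mw = 0.55, lw = 0.85)[channel]
      } else if (geno == "WW" && channel == "uv") {
        v <- 0.30
      } else if (geno == "Wy" && channel == "uv") {
        v <- 0.42
      }
    }
    if (roi == "TH" && channel == "uv") {
      v <- c(WW = 0.20, Wy = 0.30, yy = 0.28)[geno]
    }
    if (roi == "AB" && channel == "uv") {
      v <- c(WW = 0.18, Wy = 0.28, yy = 0.30)[geno]
    }
    unname(v)
  }
  base$mean <- mapply(m, base$genotype, base$roi, base$channel)
  base$sd <- 0.02
  base
}

default_markings <- function() {
  data.frame(
    genotype = rep(GENOTYPES, 2L),
    sex = rep(c("male", "female"), each = 3L),
    scale = c(9, 9, 5, 9, 9, 5),
    count = 6L,
    reflectance = 0.10,
    stringsAsFactors = FALSE
  )
}

#' Simulate one multichannel specimen image
#'
#' Produces four co-registered reflectance rasters (`uv`, `sw`, `mw`, `lw`)
#' in `[0, 1]` with disjoint ROI masks (FW, HW, TH, AB), per-specimen and
#' per-pixel noise, and dark disk markings of the configured scale placed
#' inside the forewing. Deterministic in (`g`, `sex`, `app`, `seed`).
#'
#' @param g Genotype.
#' @param sex `"male"` or `"female"`.
#' @param app An [appearance_config()].
#' @param seed Integer seed.
#' @param id Optional specimen id string.
#' @return List of class `multichannel_specimen`: `channels` (named list of
#'   matrices), `mask` (integer matrix, codes 0 background, 1 FW, 2 HW,
#'   3 TH, 4 AB), `id`, `genotype`, `sex`.
#' @export
simulate_specimen <- function(g, sex, app = appearance_config(), seed = 1L,
                              id = NULL) {
  g <- as_genotype(g)
  sex <- match.arg(sex, c("male", "female"))
  stopifnot(inherits(app, "appearance_config"))
  n <- app$image_size
  for (roi in ROIS) {
    r <- app$layout[[roi]]
    if (r["r2"] > n || r["c2"] > n || r["r1"] < 1 || r["c1"] < 1) {
      stop("ROI layout does not fit the image", call. = FALSE)
    }
  }
  mask <- matrix(0L, n, n)
  for (roi in ROIS) {
    r <- app$layout[[roi]]
    mask[r["r1"]:r["r2"], r["c1"]:r["c2"]] <- ROI_CODES[[roi]]
  }

  mm <- app$means[app$means$genotype == g & app$means$sex == sex, ]
  channels <- with_seed(seed, {
    # per-specimen offsets, one per ROI x channel
    off <- stats::rnorm(nrow(mm), 0, app$specimen_sd)
    chans <- lapply(CHANNELS, function(ch) {
      img <- matrix(0, n, n)
      rows <- which(mm$channel == ch)
      for (i in rows) {
        roi <- mm$roi[i]
        sel <- mask == ROI_CODES[[roi]]
        npx <- sum(sel)
        img[sel] <- mm$mean[i] + off[i] +
          stats::rnorm(npx, 0, mm$sd[i])
      }
      img
    })
    names(chans) <- CHANNELS

    # forewing markings: dark disks, all channels
    mk <- app$markings[app$markings$genotype == g & app$markings$sex == sex, ]
    if (nrow(mk) == 1L && mk$count > 0L) {
      fw <- app$layout$FW
      rad <- mk$scale / 2
      cr <- stats::runif(mk$count, fw["r1"] + rad, fw["r2"] - rad)
      cc <- stats::runif(mk$count, fw["c1"] + rad, fw["c2"] - rad)
      rr <- matrix(seq_len(n), n, n)
      ccol <- matrix(seq_len(n), n, n, byrow = TRUE)
      disk <- matrix(FALSE, n, n)
      for (j in seq_len(mk$count)) {
        disk <- disk | ((rr - cr[j])^2 + (ccol - cc[j])^2 <= rad^2)
      }
      disk <- disk & (mask == ROI_CODES[["FW"]])
      for (ch in CHANNELS) chans[[ch]][disk] <- mk$reflectance
    }
    lapply(chans, clip01)
  })

  structure(
    list(channels = channels, mask = mask,
         id = if (is.null(id)) sprintf("%s_%s_s%d", g, sex, seed) else id,
         genotype = g, sex = sex),
    class = "multichannel_specimen"
  )
}

#' Generate a cohort of specimens with a truth table
#'
#' Per-specimen seeds are derived by hashing (cohort seed, index), so any
#' specimen is reproducible independently of cohort size.
#'
#' @param n_per_genotype Named counts, e.g. `c(WW = 37, Wy = 88, yy = 42)`
#'   (the default mirrors the male sample analysed in the source system).
#' @param sex Sex of all specimens.
#' @param app An [appearance_config()].
#' @param seed Integer cohort seed.
#' @return List of class `specimen_cohort`: `specimens` (list) and `truth`
#'   (data frame `id`, `genotype`, `sex`, `seed`).
#' @export
generate_cohort <- function(n_per_genotype = c(WW = 37L, Wy = 88L, yy = 42L),
                            sex = "male", app = appearance_config(),
                            seed = 1L) {
  stopifnot(all(names(n_per_genotype) %in% GENOTYPES),
            all(n_per_genotype >= 0))
  genos <- rep(names(n_per_genotype), times = n_per_genotype)
  specimens <- vector("list", length(genos))
  truth <- data.frame(id = character(length(genos)),
                      genotype = genos, sex = sex,
                      seed = integer(length(genos)),
                      stringsAsFactors = FALSE)
  for (i in seq_along(genos)) {
    si <- derive_seed(seed, i, 11L)
    sp <- simulate_specimen(genos[i], sex, app, seed = si,
                            id = sprintf("S%04d_%s", i, genos[i]))
    specimens[[i]] <- sp
    truth$id[i] <- sp$id
    truth$seed[i] <- si
  }
  structure(list(specimens = specimens, truth = truth),
            class = "specimen_cohort")
}

#' Write / read a specimen to disk
#'
#' One multi-page 32-bit float TIFF per specimen (pages in channel order
#' uv, sw, mw, lw) plus one grayscale PNG mask whose pixel values encode the
#' ROI codes (code/255). A cohort is written with a manifest CSV.
#'
#' @param spec A `multichannel_specimen`.
#' @param tiff_path,mask_path Output paths.
#' @return `read_specimen` returns the reconstructed specimen.
#' @export
write_specimen <- function(spec, tiff_path, mask_path) {
  stopifnot(inherits(spec, "multichannel_specimen"))
  tiff::writeTIFF(unname(spec$channels[CHANNELS]), tiff_path,
                  bits.per.sample = 32L)
  png::writePNG(spec$mask / 255, mask_path)
  invisible(tiff_path)
}

#' @rdname write_specimen
#' @param id,genotype,sex Metadata to attach on read (TIFF/PNG carry none).
#' @export
read_specimen <- function(tiff_path, mask_path, id = NA_character_,
                          genotype = NA_character_, sex = NA_character_) {
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (length(pages) != 4L) stop("expected a 4-page TIFF", call. = FALSE)
  channels <- stats::setNames(pages, CHANNELS)
  mask <- round(png::readPNG(mask_path) * 255)
  storage.mode(mask) <- "integer"
  structure(list(channels = channels, mask = mask, id = id,
                 genotype = genotype, sex = sex),
            class = "multichannel_specimen")
}

#' @rdname write_specimen
#' @param cohort A `specimen_cohort`.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "specimen_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- cohort$truth
  manifest$tiff <- file.path(dir, paste0(manifest$id, ".tif"))
  manifest$mask <- file.path(dir, paste0(manifest$id, "_mask.png"))
  for (i in seq_along(cohort$specimens)) {
    write_specimen(cohort$specimens[[i]], manifest$tiff[i], manifest$mask[i])
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}
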