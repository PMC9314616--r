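#' Receiver (visual system) models
#'
#' A receiver model names its ordered receptor channels, their relative cone
#' abundances and the Weber fraction of the most abundant cone. Built-ins:
#'
#' * `"human"` — trichromat, channels sw/mw/lw, cone ratios
#'   0.057 : 0.314 : 0.629;
#' * `"bluetit"` (alias `"avian"`) — tetrachromat, uv/sw/mw/lw, ratios
#'   1 : 1.92 : 2.68 : 2.7;
#' * `"moth"` — trichromat, uv/sw/mw, ratios 1 : 1 : 1 (the species ratio
#'   being unknown).
#'
#' All built-ins use Weber fraction 0.05 for the most abundant cone. Camera
#' channels map to receptor channels by identity selection unless a linear
#' `mapping` matrix (receptors x camera channels) is supplied.
#'
#' @param name Built-in name, or any label when `channels` is given.
#' @param channels Receptor channel names (subset of uv/sw/mw/lw under the
#'   default mapping).
#' @param ratios Positive cone abundance ratios, one per channel.
#' @param weber Weber fraction of the most abundant cone (> 0).
#' @param mapping Optional linear mapping matrix with one row per receptor
#'   channel and named columns over camera channels.
#' @return List of class `receiver_model`.
#' @export
receiver_model <- function(name, channels = NULL, ratios = NULL,
                           weber = 0.05, mapping = NULL) {
  if (is.null(channels)) {
    builtin <- switch(name,
      human = list(channels = c("sw", "mw", "lw"),
                   ratios = c(0.057, 0.314, 0.629)),
      avian = ,
      bluetit = list(channels = c("uv", "sw", "mw", "lw"),
                     ratios = c(1, 1.92, 2.68, 2.7)),
      moth = list(channels = c("uv", "sw", "mw"),
                  ratios = c(1, 1, 1)),
      stop("unknown built-in receiver: ", name, call. = FALSE))
    channels <- builtin$channels
    ratios <- builtin$ratios
  }
  if (length(channels) < 2L) stop("need >= 2 receptor channels", call. = FALSE)
  if (length(ratios) != length(channels) || any(ratios <= 0)) {
    stop("ratios must be positive, one per channel", call. = FALSE)
  }
  if (!is.numeric(weber) || weber <= 0) stop("weber must be > 0", call. = FALSE)
  if (!is.null(mapping)) {
    if (nrow(mapping) != length(channels) || is.null(colnames(mapping))) {
      stop("mapping needs one row per receptor channel and named camera columns",
           call. = FALSE)
    }
  }
  structure(list(name = name, channels = channels,
                 ratios = stats::setNames(ratios, channels),
                 weber = weber, mapping = mapping),
            class = "receiver_model")
}

#' Receptor noise per channel
#'
#' Noise scales inversely with the square root of cone abundance,
#' `e_i = weber * sqrt(eta_max / eta_i)`, anchoring the stated Weber
#' fraction to the most abundant cone (which gets `e = weber` exactly).
#'
#' @param rx A `receiver_model`.
#' @return Named numeric noise vector.
#' @export
receptor_noise <- function(rx) {
  stopifnot(inherits(rx, "receiver_model"))
  rx$weber * sqrt(max(rx$ratios) / rx$ratios)
}

#' Quantum catches of a receiver for one colour measurement
#'
#' Default camera-to-receptor mapping selects the receiver's channels from
#' the camera channels by name (uv to uv, and so on); a `mapping` matrix on
#' the receiver applies a general linear combination instead. Catches are
#' floored at `1e-6` (flagged) so log ratios stay finite.
#'
#' @param roi_means Named reflectances over camera channels (uv/sw/mw/lw).
#' @param rx A `receiver_model`.
#' @return List of class `quantum_catch`: `q` (named catches), `floored`.
#' @export
quantum_catches <- function(roi_means, rx) {
  stopifnot(inherits(rx, "receiver_model"))
  if (is.null(rx$mapping)) {
    missing <- setdiff(rx$channels, names(roi_means))
    if (length(missing)) {
      stop("missing camera channel(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    q <- unlist(roi_means)[rx$channels]
  } else {
    cams <- colnames(rx$mapping)
    missing <- setdiff(cams, names(roi_means))
    if (length(missing)) {
      stop("missing camera channel(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    q <- drop(rx$mapping %*% unlist(roi_means)[cams])
    names(q) <- rx$channels
  }
  floored <- q < 1e-6
  q[floored] <- 1e-6
  structure(list(q = q, floored = any(floored)), class = "quantum_catch")
}

# RNL chromatic quadratic form: Q = D^-1 - (D^-1 1 1' D^-1) / (1' D^-1 1)
# with D = diag(e^2). dS^2 = df' Q df restricted to the chromatic subspace.
rnl_quadratic_form <- function(e) {
  d_inv <- 1 / e^2
  diag(d_inv, length(e)) - tcrossprod(d_inv) / sum(d_inv)
}

#' Receptor-noise-limited chromatic contrast (dS)
#'
#' Contrast between two stimuli in JND units under the
#' receptor-noise-limited model, using log catch ratios
#' `df_i = ln(qA_i / qB_i)` and the general n-channel quadratic form of the
#' noise-weighted chromatic distance (achromatic/luminance contrast is not
#' part of this model). The general form reduces exactly to the published
#' dichromat, trichromat and tetrachromat closed forms (see
#' [rnl_contrast_closed()]); dS < 1 is conventionally indistinguishable.
#'
#' @param qA,qB `quantum_catch` objects (or named positive catch vectors)
#'   with identical channel sets.
#' @param rx The `receiver_model` (supplies the noise vector).
#' @return Non-negative dS.
#' @export
chromatic_contrast <- function(qA, qB, rx) {
  if (inherits(qA, "quantum_catch")) qA <- qA$q
  if (inherits(qB, "quantum_catch")) qB <- qB$q
  if (!identical(names(qA), names(qB)) ||
      !identical(names(qA), rx$channels)) {
    stop("channel sets of the two stimuli and the receiver must match",
         call. = FALSE)
  }
  if (any(qA <= 0) || any(qB <= 0)) {
    stop("quantum catches must be positive", call. = FALSE)
  }
  e <- receptor_noise(rx)
  df <- log(qA / qB)
  sqrt(max(0, drop(t(df) %*% rnl_quadratic_form(e) %*% df)))
}

#' Closed-form RNL contrasts for 2-4 receptor channels
#'
#' The published dichromat, trichromat and tetrachromat formulas, provided
#' as an independent route to the same quantity as [chromatic_contrast()]:
#' e.g. the dichromat form is `|df1 - df2| / sqrt(e1^2 + e2^2)` and the
#' trichromat form is
#' `dS^2 = (e1^2 (df3-df2)^2 + e2^2 (df3-df1)^2 + e3^2 (df1-df2)^2) /
#'  ((e1 e2)^2 + (e1 e3)^2 + (e2 e3)^2)`.
#'
#' @param df Log catch-ratio differences, length 2, 3 or 4.
#' @param e Receptor noise vector of the same length.
#' @return Non-negative dS.
#' @export
rnl_contrast_closed <- function(df, e) {
  stopifnot(length(df) == length(e))
  n <- length(df)
  df <- unname(df); e <- unname(e)
  if (n == 2L) {
    return(abs(df[1] - df[2]) / sqrt(e[1]^2 + e[2]^2))
  }
  if (n == 3L) {
    num <- e[1]^2 * (df[3] - df[2])^2 +
      e[2]^2 * (df[3] - df[1])^2 +
      e[3]^2 * (df[1] - df[2])^2
    den <- (e[1] * e[2])^2 + (e[1] * e[3])^2 + (e[2] * e[3])^2
    return(sqrt(num / den))
  }
  if (n == 4L) {
    num <- (e[1] * e[2])^2 * (df[4] - df[3])^2 +
      (e[1] * e[3])^2 * (df[4] - df[2])^2 +
      (e[1] * e[4])^2 * (df[3] - df[2])^2 +
      (e[2] * e[3])^2 * (df[4] - df[1])^2 +
      (e[2] * e[4])^2 * (df[3] - df[1])^2 +
      (e[3] * e[4])^2 * (df[2] - df[1])^2
    den <- (e[1] * e[2] * e[3])^2 + (e[1] * e[2] * e[4])^2 +
      (e[1] * e[3] * e[4])^2 + (e[2] * e[3] * e[4])^2
    return(sqrt(num / den))
  }
  stop("closed forms cover 2-4 channels", call. = FALSE)
}

#' Pairwise chromatic contrast table over a cohort
#'
#' Computes dS for every unordered specimen pair, per ROI and per receiver,
#' from ROI channel means in a feature table (columns `<ROI>_<channel>`).
#' Genotype-pair labels (e.g. `WW-Wy`) are attached for summarising; both
#' within- and between-genotype pairs are emitted, labelled.
#'
#' @param features Feature data frame with `id`, `genotype` and
#'   `<ROI>_<channel>` columns.
#' @param rois ROI labels to compare (default abdomen, forewing, hindwing).
#' @param receivers List of `receiver_model`s (default human, bluetit,
#'   moth).
#' @return Data frame: `id_a`, `id_b`, `genotype_pair`, `roi`, `receiver`,
#'   `dS`, `discriminable` (dS > 1).
#' @export
pairwise_contrast_table <- function(features,
                                    rois = c("AB", "FW", "HW"),
                                    receivers = list(receiver_model("human"),
                                                     receiver_model("bluetit"),
                                                     receiver_model("moth"))) {
  stopifnot(all(c("id", "genotype") %in% names(features)))
  n <- nrow(features)
  if (n < 2L) stop("need at least 2 specimens", call. = FALSE)
  pair_idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  gp <- function(a, b) {
    g <- sort(c(a, b))
    paste(g, collapse = "-")
  }
  pair_lab <- mapply(gp, features$genotype[pair_idx[, 1]],
                     features$genotype[pair_idx[, 2]])

  out <- list()
  for (rx in receivers) {
    e <- receptor_noise(rx)
    Q <- rnl_quadratic_form(e)
    for (roi in rois) {
      cols <- paste0(roi, "_", rx$channels)
      missing <- setdiff(cols, names(features))
      if (length(missing)) {
        stop("feature table missing column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
      q <- as.matrix(features[cols])
      q[q < 1e-6] <- 1e-6
      f <- log(q)
      G <- f %*% Q %*% t(f)
      d2 <- outer(diag(G), diag(G), "+") - 2 * G
      dS <- sqrt(pmax(0, d2[pair_idx]))
      out[[length(out) + 1L]] <- data.frame(
        id_a = features$id[pair_idx[, 1]],
        id_b = features$id[pair_idx[, 2]],
        genotype_pair = pair_lab,
        roi = roi, receiver = rx$name, dS = dS,
        discriminable = dS > 1,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Summarise discriminability by genotype pair, ROI and receiver
#'
#' @param table Output of [pairwise_contrast_table()].
#' @return Data frame with median dS and the fraction of pairs above the
#'   1 JND threshold per (genotype pair, ROI, receiver).
#' @export
discriminability_summary <- function(table) {
  if (!nrow(table)) stop("empty contrast table", call. = FALSE)
  agg <- stats::aggregate(
    table$dS,
    by = list(genotype_pair = table$genotype_pair, roi = table$roi,
              receiver = table$receiver),
    FUN = function(v) c(median = stats::median(v), frac = mean(v > 1),
                        n = length(v))
  )
  out <- cbind(agg[c("genotype_pair", "roi", "receiver")],
               median_dS = agg$x[, "median"],
               frac_above_1jnd = agg$x[, "frac"],
               n_pairs = agg$x[, "n"])
  out[order(out$receiver, out$roi, out$genotype_pair), ]
}
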