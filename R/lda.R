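numeric_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    x <- as.matrix(x[, num, drop = FALSE])
  }
  storage.mode(x) <- "double"
  x
}

#' Fit a linear discriminant model
#'
#' Classical multi-group LDA: features are standardized internally
#' (zero-variance columns get unit scale), class means and the pooled
#' within-class covariance are estimated, and discriminant axes are the
#' leading generalized eigenvectors of the between- against the
#' within-class scatter, normalized to unit within-class variance
#' (whitened). Classification is by Mahalanobis distance to the class means
#' plus log prior; priors default to uniform over the groups so unequal
#' group sizes do not bias assignment. If the pooled covariance is
#' (near-)singular it is ridge-regularized by `1e-6 * trace/d` on the
#' diagonal and the model records that this happened.
#'
#' @param x Feature matrix or data frame (non-numeric columns ignored).
#' @param labels Class labels, one per row; every class needs >= 2 members.
#' @param prior `"uniform"` or a named probability vector over the classes.
#' @return List of class `discriminant_model`.
#' @export
fit_discriminant <- function(x, labels, prior = "uniform") {
  xm <- numeric_feature_matrix(x)
  labels <- as.character(labels)
  if (nrow(xm) != length(labels)) stop("labels must match rows", call. = FALSE)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  counts <- table(labels)
  if (any(counts < 2L)) {
    stop("every class needs at least 2 members", call. = FALSE)
  }
  if (nrow(xm) <= 2L) stop("need more than 2 rows", call. = FALSE)

  center <- colMeans(xm)
  scale <- apply(xm, 2L, stats::sd)
  scale[scale == 0 | is.na(scale)] <- 1
  z <- scale(xm, center = center, scale = scale)

  d <- ncol(z)
  mu <- t(vapply(classes, function(cl) colMeans(z[labels == cl, , drop = FALSE]),
                 numeric(d)))
  rownames(mu) <- classes

  # pooled within-class covariance
  Sw <- matrix(0, d, d)
  for (cl in classes) {
    zc <- z[labels == cl, , drop = FALSE]
    zc <- sweep(zc, 2L, mu[cl, ])
    Sw <- Sw + crossprod(zc)
  }
  Sw <- Sw / (nrow(z) - length(classes))

  ridged <- FALSE
  ch <- tryCatch(chol(Sw), error = function(e) NULL)
  if (is.null(ch) || rcond(Sw) < 1e-10) {
    eps <- 1e-6 * sum(diag(Sw)) / d
    Sw <- Sw + diag(eps, d)
    ridged <- TRUE
    ch <- chol(Sw)
  }
  Sw_inv <- chol2inv(ch)

  # between-class scatter (class-size weighted) and whitened axes
  grand <- colMeans(mu[labels, , drop = FALSE])
  Sb <- matrix(0, d, d)
  for (cl in classes) {
    dm <- mu[cl, ] - grand
    Sb <- Sb + as.numeric(counts[cl]) * tcrossprod(dm)
  }
  Sb <- Sb / (nrow(z) - 1L)
  # generalized eigenproblem via whitening: W = chol(Sw)^-1
  Wt <- backsolve(ch, diag(d))          # Sw^{-1/2} (upper-tri inverse)
  M <- t(Wt) %*% Sb %*% Wt
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  n_axes <- min(length(classes) - 1L, d)
  axes <- Wt %*% eg$vectors[, seq_len(n_axes), drop = FALSE]
  # normalize: unit within-class variance along each axis
  for (j in seq_len(n_axes)) {
    a <- axes[, j]
    axes[, j] <- a / sqrt(drop(t(a) %*% Sw %*% a))
  }
  colnames(axes) <- paste0("LD", seq_len(n_axes))

  pr <- if (identical(prior, "uniform")) {
    stats::setNames(rep(1 / length(classes), length(classes)), classes)
  } else {
    if (!all(classes %in% names(prior))) {
      stop("prior must name every class", call. = FALSE)
    }
    prior[classes] / sum(prior[classes])
  }

  structure(
    list(classes = classes, features = colnames(xm),
         center = center, scale = scale,
         means = mu, cov = Sw, cov_inv = Sw_inv,
         axes = axes, eigenvalues = eg$values[seq_len(n_axes)],
         prior = pr, ridged = ridged,
         train_center = colMeans(z)),
    class = "discriminant_model"
  )
}

standardize_new <- function(model, x) {
  xm <- numeric_feature_matrix(x)
  if (!all(model$features %in% colnames(xm))) {
    stop("feature schema mismatch with training data", call. = FALSE)
  }
  xm <- xm[, model$features, drop = FALSE]
  scale(xm, center = model$center, scale = model$scale)
}

#' Predict class labels from a discriminant model
#'
#' @param object A `discriminant_model`.
#' @param newdata Feature matrix or data frame with the training columns.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.discriminant_model <- function(object, newdata, ...) {
  z <- standardize_new(object, newdata)
  score <- vapply(object$classes, function(cl) {
    dm <- sweep(z, 2L, object$means[cl, ])
    -0.5 * rowSums((dm %*% object$cov_inv) * dm) + log(object$prior[[cl]])
  }, numeric(nrow(z)))
  if (is.null(dim(score))) score <- matrix(score, nrow = 1L)
  object$classes[max.col(score, ties.method = "first")]
}

#' Project specimens onto the discriminant axes
#'
#' Scores are the whitened projections (unit pooled within-class variance
#' per axis) of the standardized, training-mean-centred features; the
#' training mean maps to the origin and axis 1 carries the largest
#' between/within variance ratio.
#'
#' @param model A `discriminant_model`.
#' @param x Feature matrix or data frame.
#' @return Numeric matrix of scores, one column per axis.
#' @export
project <- function(model, x) {
  stopifnot(inherits(model, "discriminant_model"))
  z <- standardize_new(model, x)
  z <- sweep(z, 2L, model$train_center)
  z %*% model$axes
}

#' Leave-one-out evaluation of the discriminant classifier
#'
#' Refits the model with each specimen held out in turn and predicts it,
#' giving a deterministic out-of-sample confusion report.
#'
#' @param x Feature matrix or data frame.
#' @param labels True class labels.
#' @param prior Passed to [fit_discriminant()].
#' @return List of class `confusion_report`: `confusion` (true x predicted),
#'   `accuracy`, `per_class_accuracy`, `predicted`.
#' @export
evaluate_loo <- function(x, labels, prior = "uniform") {
  xm <- numeric_feature_matrix(x)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  pred <- character(nrow(xm))
  for (i in seq_len(nrow(xm))) {
    fit <- fit_discriminant(xm[-i, , drop = FALSE], labels[-i], prior = prior)
    pred[i] <- predict(fit, xm[i, , drop = FALSE])
  }
  confusion <- table(true = factor(labels, classes),
                     predicted = factor(pred, classes))
  acc <- sum(diag(confusion)) / sum(confusion)
  per_class <- diag(confusion) / rowSums(confusion)
  structure(list(confusion = confusion, accuracy = acc,
                 per_class_accuracy = per_class, predicted = pred),
            class = "confusion_report")
}
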