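# Maximum-margin classifier contract: features are standardized by
# training-set mean/sd, then a support-vector machine (radial-basis kernel
# by default, C = 1, kernel width 1/n_features on the standardized scale)
# separates the two attention classes.

#' Train the margin classifier
#'
#' @param features a [feature_matrix()], or a plain trials x features
#'   matrix combined with `labels`.
#' @param labels class labels when `features` is a plain matrix.
#' @param kernel `"radial"` (default) or `"linear"`.
#' @param cost soft-margin regularization constant C.
#' @param gamma radial-basis kernel width; defaults to `1/n_features` on
#'   standardized features.
#' @return object of class `sa_classifier`.
#' @export
train_classifier <- function(features, labels = NULL,
                             kernel = c("radial", "linear"),
                             cost = 1, gamma = NULL) {
  kernel <- match.arg(kernel)
  if (inherits(features, "feature_matrix")) {
    x <- features$values
    labels <- features$labels
  } else {
    x <- as.matrix(features)
  }
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2)
    stop("training data contains a single class")
  centre <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  xs <- scale(x, center = centre, scale = scale)
  fit <- e1071::svm(xs, labels, type = "C-classification", kernel = kernel,
                    cost = cost, gamma = gamma %||% (1 / ncol(xs)),
                    scale = FALSE)
  structure(list(fit = fit, centre = centre, scale = scale,
                 kernel = kernel, levels = levels(labels)),
            class = "sa_classifier")
}

#' Predict attention labels
#'
#' @param object an `sa_classifier`.
#' @param newdata a `feature_matrix` or trials x features matrix.
#' @param ... unused.
#' @return factor of predicted labels.
#' @export
predict.sa_classifier <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_matrix")) newdata$values
       else as.matrix(newdata)
  xs <- scale(x, center = object$centre, scale = object$scale)
  stats::predict(object$fit, xs)
}
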