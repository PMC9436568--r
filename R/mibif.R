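# Mutual-information-based best individual feature (MIBIF) selection:
# Parzen-window estimate of the mutual information between each scalar
# feature and the binary class label, descending-MI ranking, and
# pair-completed selection that always keeps a feature together with its
# eigenvalue-complement partner from the same band.

#' Parzen-window mutual information between a feature and the class label
#'
#' Estimates `I(omega; f) = H(omega) - H(omega | f)` in bits. The class
#' entropy uses empirical class frequencies. The conditional entropy is
#' computed by leave-one-out: class-conditional densities are Gaussian
#' kernel estimates with the normal-reference bandwidth
#' `h = sd * (4 / (3 n))^(1/5)` per class, each evaluation point is excluded
#' from its own kernel sum, posteriors follow from Bayes' rule, and the
#' conditional entropy is averaged over the held-out points. For balanced
#' binary labels the result lies in `[0, 1]` bits; it is clipped at 0.
#'
#' @param feature numeric per-trial feature values.
#' @param labels binary class labels, at least two trials per class.
#' @return mutual information in bits.
#' @export
mutual_information <- function(feature, labels) {
  labels <- as.factor(labels)
  classes <- levels(labels)
  if (length(classes) != 2) stop("labels must have exactly two classes")
  n_c <- table(labels)
  if (min(n_c) < 2) stop("need at least 2 trials per class")
  n <- length(feature)
  if (length(labels) != n) stop("feature/label length mismatch")
  if (stats::sd(feature) == 0) {
    warning("zero-variance feature carries no information")
    return(0)
  }
  priors <- as.numeric(n_c) / n
  h_omega <- -sum(priors * log2(priors))

  dens <- matrix(0, n, 2)
  for (k in 1:2) {
    xk <- feature[labels == classes[k]]
    nk <- length(xk)
    sk <- stats::sd(xk)
    if (sk == 0) sk <- stats::sd(feature)
    h <- sk * (4 / (3 * nk))^(1 / 5)
    ker <- stats::dnorm(outer(feature, xk, "-") / h) / h   # n x nk
    own <- labels == classes[k]
    tot <- rowSums(ker)
    # leave-one-out: a class member's own kernel contributes dnorm(0)/h
    tot[own] <- tot[own] - stats::dnorm(0) / h
    dens[, k] <- tot / ifelse(own, nk - 1, nk)
  }
  joint <- sweep(dens, 2, priors, "*")
  tot <- rowSums(joint)
  post <- joint / tot
  # points in the far tails of both classes fall back to the priors
  deg <- tot <= 0 | !is.finite(tot)
  if (any(deg)) post[deg, ] <- matrix(priors, sum(deg), 2, byrow = TRUE)
  plogp <- ifelse(post > 0, post * log2(post), 0)
  h_cond <- -mean(rowSums(plogp))
  max(0, h_omega - h_cond)
}

#' Rank features by mutual information
#'
#' Computes the Parzen-window MI of every feature column with the class
#' label and returns the descending-MI ordering (ties broken by ascending
#' feature index).
#'
#' @param features a [feature_matrix()].
#' @return list of class `mibif_ranking` with `mi` (bits, per feature) and
#'   `order` (feature indices, best first).
#' @export
mibif_rank <- function(features) {
  stopifnot(inherits(features, "feature_matrix"))
  mi <- vapply(seq_len(ncol(features$values)), function(j)
    suppressWarnings(mutual_information(features$values[, j],
                                        features$labels)),
    numeric(1))
  structure(list(mi = mi, order = order(-mi, seq_along(mi))),
            class = "mibif_ranking")
}

#' @export
print.mibif_ranking <- function(x, ...) {
  cat(sprintf("<mibif_ranking> %d features; top MI %.3f bits (feature %d)\n",
              length(x$mi), x$mi[x$order[1]], x$order[1]))
  invisible(x)
}

# index of each feature's complement partner: same band, kept position
# i <-> n_kept + 1 - i (largest-eigenvalue component pairs with smallest)
.pair_index <- function(meta) {
  partner <- integer(nrow(meta))
  for (j in seq_len(nrow(meta))) {
    want <- meta$n_kept[j] + 1L - meta$kept[j]
    hit <- which(meta$band == meta$band[j] & meta$kept == want)
    if (length(hit) != 1L)
      stop("feature metadata does not define a unique complement pair ",
           "for feature ", j)
    partner[j] <- hit
  }
  partner
}

#' Pair-completed MIBIF selection
#'
#' Walks the MI ranking from the top; each visited feature is selected
#' together with its complement partner (the component from the same band
#' whose eigenvalue is the complement of its own, e.g. kept components 1
#' and 4, 2 and 3 when two components are kept from each end). A feature
#' already brought in as a partner is not counted again. Selection stops
#' once `k_pairs` complete pairs (`2 * k_pairs` features) are chosen.
#'
#' @param ranking a [mibif_rank()] result.
#' @param features the `feature_matrix` the ranking was computed on (its
#'   metadata defines the pair map).
#' @param k_pairs number of complete pairs to select (default 5, i.e. 10
#'   of the 28 filter-bank features).
#' @return integer vector of selected feature indices, in selection order.
#' @export
select_pairs <- function(ranking, features, k_pairs = 5) {
  stopifnot(inherits(ranking, "mibif_ranking"),
            inherits(features, "feature_matrix"))
  n_feat <- ncol(features$values)
  if (2 * k_pairs > n_feat)
    stop("k_pairs = ", k_pairs, " needs ", 2 * k_pairs,
         " features but only ", n_feat, " are available")
  partner <- .pair_index(features$meta)
  selected <- integer(0)
  for (j in ranking$order) {
    if (length(selected) >= 2L * k_pairs) break
    if (j %in% selected) next
    selected <- c(selected, j, partner[j])
  }
  selected
}
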