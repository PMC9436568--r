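# Bootstrap evaluation protocol: per repetition, a stratified 80/20
# train-test split, with-replacement resampling of the training portion,
# the full feature pipeline (band filtering is linear and parameter-free,
# so it is applied once up front; covariance averaging, CSP fitting, MIBIF
# selection and classifier training happen inside the split on training
# trials only), and held-out accuracy on the untouched 20%.

#' Evaluation specification
#'
#' @param method `"CSP"` (broadband 2-120 Hz, all-component log-variance
#'   features), `"FBCSP"` (per-band first/last-2 features, 28 with the
#'   default bank), or `"FBCSP_MIBIF"` (FBCSP followed by 5-pair MIBIF
#'   selection).
#' @param n_reps bootstrap repetitions (default 100).
#' @param train_frac training fraction of each class (default 0.8).
#' @param seed RNG seed; all draws of the protocol derive from it.
#' @param kernel,cost,gamma classifier parameters, see
#'   [train_classifier()].
#' @param broadband broadband filter edges for the CSP method, Hz.
#' @param bank filter bank for the FBCSP methods.
#' @param m per-band components kept from each end.
#' @param k_pairs MIBIF pairs to select.
#' @param reg covariance shrinkage.
#' @return validated list of class `eval_spec`.
#' @export
eval_spec <- function(method = c("FBCSP", "CSP", "FBCSP_MIBIF"),
                      n_reps = 100, train_frac = 0.8, seed = 1,
                      kernel = "radial", cost = 1, gamma = NULL,
                      broadband = c(2, 120), bank = build_filter_bank(),
                      m = 2, k_pairs = 5, reg = 1e-6) {
  method <- match.arg(method)
  if (!(train_frac > 0 && train_frac < 1))
    stop("`train_frac` must lie in (0, 1)")
  if (n_reps < 1) stop("`n_reps` must be >= 1")
  structure(list(method = method, n_reps = as.integer(n_reps),
                 train_frac = train_frac, seed = seed, kernel = kernel,
                 cost = cost, gamma = gamma, broadband = broadband,
                 bank = bank, m = m, k_pairs = k_pairs, reg = reg),
            class = "eval_spec")
}

# one filtered covariance set per analysis band of the method
.band_prep <- function(epochs, spec) {
  if (spec$method == "CSP") {
    eb <- bandpass(epochs, spec$broadband[1], spec$broadband[2])
    list(list(covmat = .trial_covmat(eb), keep = "all", band = 1L))
  } else {
    lapply(seq_len(nrow(spec$bank)), function(b) {
      eb <- bandpass(epochs, spec$bank$low[b], spec$bank$high[b])
      list(covmat = .trial_covmat(eb), keep = "first_last", band = b)
    })
  }
}

.band_features <- function(prep, labels, classes, idx_fit, idx_out, spec) {
  vals_fit <- list(); vals_out <- list(); metas <- list()
  for (p in prep) {
    s1 <- .mean_cov(p$covmat, idx_fit[labels[idx_fit] == classes[1]])
    s2 <- .mean_cov(p$covmat, idx_fit[labels[idx_fit] == classes[2]])
    dec <- .csp_decompose(s1, s2, spec$reg)
    kidx <- .keep_index(nrow(dec$W),
                        if (p$keep == "all") "all" else p$keep, spec$m)
    vals_fit[[p$band]] <- .cov_features_idx(dec$W, p$covmat, idx_fit, kidx)
    vals_out[[p$band]] <- .cov_features_idx(dec$W, p$covmat, idx_out, kidx)
    metas[[p$band]] <- data.frame(band = p$band, component = kidx,
                                  kept = seq_along(kidx),
                                  n_kept = length(kidx))
  }
  list(fit = do.call(cbind, vals_fit), out = do.call(cbind, vals_out),
       meta = do.call(rbind, metas))
}

#' Bootstrap classification accuracy
#'
#' Runs `spec$n_reps` repetitions. Each repetition draws a stratified
#' train/test split of the trials (the held-out fraction is never touched
#' during fitting), resamples the training portion with replacement within
#' class to its own size, fits the method's full pipeline on the resampled
#' training trials, and scores accuracy on the held-out trials.
#'
#' @param epochs raw (unfiltered) two-class [epoch_set()], at least 5
#'   trials per class.
#' @param spec an [eval_spec()].
#' @param return_splits attach the per-repetition train/test indices (for
#'   leakage auditing) as attribute `"splits"`.
#' @return object of class `eval_result` with `accuracies`, `mean`, `sd`,
#'   `method`.
#' @export
bootstrap_accuracy <- function(epochs, spec = eval_spec(),
                               return_splits = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(spec, "eval_spec"))
  labels <- epochs$labels
  classes <- levels(labels)
  if (length(classes) != 2) stop("need exactly two classes")
  if (min(table(labels)) < 5) stop("need at least 5 trials per class")
  prep <- .band_prep(epochs, spec)
  idx_by_class <- split(seq_along(labels), labels)
  acc <- numeric(spec$n_reps)
  splits <- if (return_splits) vector("list", spec$n_reps)

  with_seed(spec$seed, {
    for (r in seq_len(spec$n_reps)) {
      test <- integer(0); train <- integer(0)
      for (cls in classes) {
        idx <- idx_by_class[[cls]]
        n_test <- max(1L, round((1 - spec$train_frac) * length(idx)))
        te <- sample(idx, n_test)
        tr0 <- setdiff(idx, te)
        tr <- sample(tr0, length(tr0), replace = TRUE)
        test <- c(test, te); train <- c(train, tr)
      }
      bf <- .band_features(prep, labels, classes, train, test, spec)
      x_tr <- bf$fit; x_te <- bf$out
      if (spec$method == "FBCSP_MIBIF") {
        fm <- feature_matrix(x_tr, bf$meta, labels[train])
        sel <- select_pairs(mibif_rank(fm), fm, spec$k_pairs)
        x_tr <- x_tr[, sel, drop = FALSE]
        x_te <- x_te[, sel, drop = FALSE]
      }
      clf <- train_classifier(x_tr, labels[train], kernel = spec$kernel,
                              cost = spec$cost, gamma = spec$gamma)
      pred <- predict(clf, x_te)
      acc[r] <- mean(pred == labels[test])
      if (return_splits) splits[[r]] <- list(train = train, test = test)
    }
  })

  res <- structure(list(accuracies = acc, mean = mean(acc),
                        sd = stats::sd(acc), method = spec$method),
                   class = "eval_result")
  if (return_splits) attr(res, "splits") <- splits
  res
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s: %.1f%% +/- %.1f%% over %d repetitions\n",
              x$method, 100 * x$mean, 100 * x$sd, length(x$accuracies)))
  invisible(x)
}
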