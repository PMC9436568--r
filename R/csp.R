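# Common spatial patterns by generalized eigendecomposition of the two
# class-mean trial covariances, normalized log-variance features, the
# filter-bank variant, and inverse-matrix spatial patterns.

# per-trial trace-normalized covariances C = X X' / tr(X X'), stored as the
# columns of a p^2 x n_trials matrix so class means and projections are
# single BLAS calls
.trial_covmat <- function(epochs) {
  p <- dim(epochs$data)[2]
  vapply(seq_len(n_trials(epochs)), function(tr) {
    x <- epochs$data[tr, , , drop = TRUE]
    cc <- tcrossprod(x)
    as.vector(cc / sum(diag(cc)))
  }, numeric(p * p))
}

.mean_cov <- function(covmat, idx) {
  p <- as.integer(sqrt(nrow(covmat)))
  matrix(rowMeans(covmat[, idx, drop = FALSE]), p, p)
}

# log variance-share features for the kept components of W, all trials in
# `idx` at once: v[i, p] = w_p' C_i w_p over kept p, feature = log(v / sum v)
.cov_features_idx <- function(W, covmat, idx, kidx) {
  p <- ncol(W)
  k <- length(idx)
  wk <- W[kidx, , drop = FALSE]
  m <- nrow(wk)
  proj <- wk %*% matrix(covmat[, idx, drop = FALSE], p, p * k)   # m x (p k)
  e <- array(proj * wk[, rep(seq_len(p), k), drop = FALSE], c(m, p, k))
  v <- t(colSums(aperm(e, c(2, 1, 3))))                          # k x m
  # in degenerate directions (e.g. noise-free narrowband data) the
  # quadratic form can land a hair below zero; floor it at machine scale
  v <- pmax(v, .Machine$double.eps * rowSums(abs(v)))
  log(v / rowSums(v))
}

# Core decomposition on the two class-mean covariances. Whitening route:
# eigendecompose S1 + S2, whiten, eigendecompose the whitened S1. Filters
# are scaled so w' (S1 + S2) w = 1, hence lambda in [0, 1] is class-1's
# normalized variance share along each component.
.csp_decompose <- function(s1, s2, reg) {
  p <- nrow(s1)
  shrink <- function(s) s + reg * sum(diag(s)) / p * diag(p)
  s1 <- shrink(s1); s2 <- shrink(s2)
  sc <- s1 + s2
  ec <- eigen((sc + t(sc)) / 2, symmetric = TRUE)
  if (min(ec$values) <= max(ec$values) * 1e-12)
    stop("composite covariance is rank deficient; increase the `reg` ",
         "shrinkage weight or supply more/longer trials")
  wh <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)
  s1w <- wh %*% s1 %*% t(wh)
  e1 <- eigen((s1w + t(s1w)) / 2, symmetric = TRUE)
  w <- t(e1$vectors) %*% wh                     # components x channels
  lambda <- pmin(pmax(e1$values, 0), 1)         # descending by construction
  list(W = w, lambda = lambda)
}

#' Fit common spatial patterns
#'
#' Computes trace-normalized per-trial covariances `C = X X' / tr(X X')`,
#' averages them within each of the two classes, and solves the generalized
#' eigenproblem `S1 w = lambda (S1 + S2) w`. Filters are scaled so
#' `w' (S1 + S2) w = 1` and ordered by descending eigenvalue, so the first
#' components maximize the first class's variance share and the last
#' components the second's. The spatial patterns `A` are the inverse of the
#' filter matrix; their columns are the scalp projections of the extracted
#' components. With two classes the one-versus-one strategy reduces to this
#' single binary decomposition.
#'
#' @param epochs an [epoch_set()] with exactly two classes and at least two
#'   trials per class.
#' @param reg shrinkage weight toward the identity (`reg * tr(S)/p * I`)
#'   guaranteeing invertibility; default `1e-6`.
#' @param band optional band annotation (`c(low, high)` or `"broadband"`).
#' @return object of class `csp_model` with elements `W` (components x
#'   channels), `lambda`, `A` (channels x components), `class_order`,
#'   `channels`, `band`.
#' @export
fit_csp <- function(epochs, reg = 1e-6, band = "broadband") {
  stopifnot(inherits(epochs, "epoch_set"))
  classes <- levels(epochs$labels)
  if (length(classes) != 2)
    stop("CSP requires exactly 2 classes, got ", length(classes))
  if (min(table(epochs$labels)) < 2)
    stop("need at least 2 trials per class")
  covmat <- .trial_covmat(epochs)
  .fit_csp_covs(covmat, epochs$labels, classes, reg, band, epochs$channels)
}

.fit_csp_covs <- function(covmat, labels, classes, reg, band, channels) {
  s1 <- .mean_cov(covmat, which(labels == classes[1]))
  s2 <- .mean_cov(covmat, which(labels == classes[2]))
  dec <- .csp_decompose(s1, s2, reg)
  structure(list(W = dec$W, lambda = dec$lambda, A = solve(dec$W),
                 class_order = classes, channels = channels, band = band),
            class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d components (%s vs %s), band %s\n",
              nrow(x$W), x$class_order[1], x$class_order[2],
              paste(x$band, collapse = "-")))
  cat("lambda:", paste(sprintf("%.3f", utils::head(x$lambda, 6)),
                       collapse = " "),
      if (length(x$lambda) > 6) "..." else "", "\n")
  invisible(x)
}

.keep_index <- function(n_comp, keep, m) {
  if (identical(keep, "all")) return(seq_len(n_comp))
  if (m > n_comp / 2)
    stop("m = ", m, " exceeds half the component count (", n_comp, ")")
  c(seq_len(m), (n_comp - m + 1L):n_comp)
}

#' CSP log-variance features
#'
#' Projects each trial through the CSP filters and returns the logarithm of
#' each kept component's share of the projected variance,
#' `log(var_p / sum_q var_q)` over the kept components. `keep = "all"` uses
#' every component (the broadband CSP feature); `keep = "first_last"` keeps
#' the `m` first and `m` last components of the eigenvalue ordering (the
#' filter-bank feature).
#'
#' @param model a [fit_csp()] model.
#' @param epochs epochs with channels matching the model.
#' @param keep `"all"` or `"first_last"`.
#' @param m components kept from each end when `keep = "first_last"`.
#' @return object of class `feature_matrix`: `values` (trials x features),
#'   `meta` (per-feature band/component bookkeeping), `labels`.
#' @export
csp_features <- function(model, epochs, keep = c("all", "first_last"),
                         m = 2) {
  stopifnot(inherits(model, "csp_model"), inherits(epochs, "epoch_set"))
  keep <- match.arg(keep)
  if (dim(epochs$data)[2] != ncol(model$W))
    stop("epoch channel count does not match the model")
  kidx <- .keep_index(nrow(model$W), if (keep == "all") "all" else keep, m)
  covmat <- .trial_covmat(epochs)
  values <- .cov_features_idx(model$W, covmat, seq_len(n_trials(epochs)),
                              kidx)
  meta <- data.frame(band = 1L, component = kidx,
                     kept = seq_along(kidx),
                     n_kept = length(kidx))
  feature_matrix(values, meta, epochs$labels)
}

#' Construct a feature matrix
#'
#' @param values trials x features numeric matrix.
#' @param meta per-feature data.frame carrying at least `band`, `component`,
#'   `kept` (position within the band's kept ordering) and `n_kept`.
#' @param labels per-trial class labels.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, meta, labels) {
  values <- as.matrix(values)
  if (nrow(meta) != ncol(values))
    stop("meta rows must equal the feature count")
  if (length(labels) != nrow(values))
    stop("labels must match the trial count")
  if (any(!is.finite(values)))
    stop("feature values must be finite")
  structure(list(values = values, meta = meta, labels = as.factor(labels)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d trials x %d features (%d band%s)\n",
              nrow(x$values), ncol(x$values), max(x$meta$band),
              if (max(x$meta$band) > 1) "s" else ""))
  invisible(x)
}

#' Filter-bank CSP features
#'
#' Band-pass filters the epochs into each sub-band of the bank, fits one
#' CSP model per band, and concatenates the per-band `first_last` features
#' (components `1..m` and the last `m`) in band order. With the standard
#' 7-band bank and `m = 2` this yields 28 features per trial. The per-band
#' models are returned alongside the features for pattern inspection.
#'
#' @param epochs raw (broadband) [epoch_set()].
#' @param bank a [build_filter_bank()] data.frame.
#' @param m components kept from each end of every band's decomposition.
#' @param reg covariance shrinkage passed to [fit_csp()].
#' @return a `feature_matrix`; the per-band `csp_model`s are attached as
#'   attribute `"models"`.
#' @export
fbcsp_features <- function(epochs, bank, m = 2, reg = 1e-6) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!nrow(bank)) stop("`bank` must contain at least one band")
  pieces <- vector("list", nrow(bank))
  metas <- vector("list", nrow(bank))
  models <- vector("list", nrow(bank))
  for (b in seq_len(nrow(bank))) {
    eb <- tryCatch(bandpass(epochs, bank$low[b], bank$high[b]),
                   error = function(e)
                     stop("band ", bank$low[b], "-", bank$high[b], " Hz: ",
                          conditionMessage(e)))
    mod <- tryCatch(fit_csp(eb, reg = reg,
                            band = c(bank$low[b], bank$high[b])),
                    error = function(e)
                      stop("band ", bank$low[b], "-", bank$high[b], " Hz: ",
                           conditionMessage(e)))
    fm <- csp_features(mod, eb, keep = "first_last", m = m)
    pieces[[b]] <- fm$values
    metas[[b]] <- transform(fm$meta, band = b)
    models[[b]] <- mod
  }
  fm <- feature_matrix(do.call(cbind, pieces), do.call(rbind, metas),
                       epochs$labels)
  attr(fm, "models") <- models
  fm
}

#' Spatial pattern of one CSP component
#'
#' Returns the requested column of the inverse CSP filter matrix,
#' max-normalized to `[-1, 1]`, i.e. the scalp projection of that extracted
#' component for topography rendering.
#'
#' @param model a `csp_model`.
#' @param component component index (1-based, eigenvalue ordering).
#' @return named numeric vector, one weight per channel.
#' @export
csp_patterns <- function(model, component) {
  stopifnot(inherits(model, "csp_model"))
  n <- ncol(model$A)
  if (component < 1 || component > n)
    stop("component index ", component, " out of range 1..", n)
  p <- model$A[, component]
  names(p) <- model$channels
  p / max(abs(p))
}
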