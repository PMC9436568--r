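# Statistical apparatus around the classifier comparison: finite-sample
# chance level, repeated-measures method comparison with Bonferroni
# correction, and the a-priori power analysis for the paired design.

#' Adjusted chance level of a binary classifier
#'
#' The accuracy threshold that a random binary classifier only exceeds with
#' probability `alpha` given a finite test-trial count: the upper limit of
#' the adjusted Wald (Agresti-Coull) `1 - alpha` confidence interval around
#' chance, `p~ = (n/2 + 2) / (n + 4)` and
#' `p~ + z_{1 - alpha/2} * sqrt(p~ (1 - p~) / (n + 4))`. At `n = 90` trials
#' and `alpha = 0.05` this is 0.601 - well above the nominal 50%.
#'
#' @param n_test_trials number of classified trials.
#' @param alpha significance level (default 0.05).
#' @return threshold as a fraction in (0.5, 1).
#' @export
#' @examples
#' chance_level(90)    # 0.601
chance_level <- function(n_test_trials, alpha = 0.05) {
  if (n_test_trials < 1) stop("`n_test_trials` must be >= 1")
  n <- n_test_trials
  p <- (n / 2 + 2) / (n + 4)
  p + stats::qnorm(1 - alpha / 2) * sqrt(p * (1 - p) / (n + 4))
}

#' Compare feature-extraction methods across subjects
#'
#' One-way repeated-measures analysis of variance of per-subject mean
#' accuracies across methods, followed by pairwise paired t tests with
#' Bonferroni correction and paired Cohen's d (`mean(diff) / sd(diff)`).
#'
#' @param acc subjects x methods numeric matrix of mean accuracies, with
#'   method column names; each row is one subject measured under every
#'   method.
#' @param n_test_trials optional held-out trial count, used to attach the
#'   [chance_level()] threshold to the report.
#' @param alpha level for the chance threshold.
#' @return list of class `method_comparison` with `anova_F`, `anova_p`,
#'   `pairwise` (t, df, raw and Bonferroni p, Cohen's d per method pair)
#'   and `chance_threshold`.
#' @export
compare_methods <- function(acc, n_test_trials = NULL, alpha = 0.05) {
  acc <- as.matrix(acc)
  if (nrow(acc) < 2) stop("need at least 2 subjects")
  if (ncol(acc) < 2) stop("need at least 2 methods")
  if (anyNA(acc)) stop("accuracy table contains missing cells")
  methods <- colnames(acc) %||% paste0("M", seq_len(ncol(acc)))
  colnames(acc) <- methods

  long <- data.frame(
    accuracy = as.vector(acc),
    method = factor(rep(methods, each = nrow(acc)), levels = methods),
    subject = factor(rep(seq_len(nrow(acc)), ncol(acc))))
  ss_method <- nrow(acc) * sum((colMeans(acc) - mean(acc))^2)
  if (ss_method < 1e-14 * max(1, sum(acc^2))) {
    anova_F <- 0; anova_p <- 1
  } else {
    fit <- stats::aov(accuracy ~ method + Error(subject), data = long)
    tab <- summary(fit)[["Error: Within"]][[1]]
    row <- which(trimws(rownames(tab)) == "method")
    anova_F <- tab[row, "F value"]
    anova_p <- tab[row, "Pr(>F)"]
    if (!is.finite(anova_F)) { anova_F <- 0; anova_p <- 1 }
  }

  pairs <- utils::combn(methods, 2)
  n_cmp <- ncol(pairs)
  pw <- lapply(seq_len(n_cmp), function(k) {
    d <- acc[, pairs[1, k]] - acc[, pairs[2, k]]
    if (stats::sd(d) == 0) {
      if (mean(d) == 0)
        return(data.frame(method1 = pairs[1, k], method2 = pairs[2, k],
                          t = 0, df = length(d) - 1, p_raw = 1,
                          p_bonferroni = 1, cohen_d = 0))
      return(data.frame(method1 = pairs[1, k], method2 = pairs[2, k],
                        t = sign(mean(d)) * Inf, df = length(d) - 1,
                        p_raw = 0, p_bonferroni = 0,
                        cohen_d = sign(mean(d)) * Inf))
    }
    tt <- stats::t.test(d)
    data.frame(method1 = pairs[1, k], method2 = pairs[2, k],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value,
               p_bonferroni = min(1, n_cmp * tt$p.value),
               cohen_d = mean(d) / stats::sd(d))
  })
  structure(list(anova_F = anova_F, anova_p = anova_p,
                 pairwise = do.call(rbind, pw),
                 chance_threshold = if (is.null(n_test_trials)) NULL
                                    else chance_level(n_test_trials, alpha)),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("<method_comparison> repeated-measures ANOVA F = %.3f, p = %.4g\n",
              x$anova_F, x$anova_p))
  print(x$pairwise, row.names = FALSE)
  if (!is.null(x$chance_threshold))
    cat(sprintf("chance threshold: %.1f%%\n", 100 * x$chance_threshold))
  invisible(x)
}

#' A-priori sample size for a matched-pairs t test
#'
#' Smallest `n >= 2` such that a matched-pairs t test with noncentrality
#' `d * sqrt(n)` and `n - 1` degrees of freedom attains the target power at
#' level `alpha`. With `d = 1.132`, `alpha = 0.05`, power 0.8 and a
#' one-sided test this gives `n = 7`.
#'
#' @param effect_size_d standardized paired difference (> 0).
#' @param alpha significance level.
#' @param power_target required power.
#' @param sided `"one"` or `"two"`.
#' @return required sample size (integer).
#' @export
#' @examples
#' required_sample_size(1.132)   # 7
required_sample_size <- function(effect_size_d, alpha = 0.05,
                                 power_target = 0.8,
                                 sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (effect_size_d <= 0) stop("`effect_size_d` must be positive")
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must lie in (0, 1)")
  if (!(power_target > 0 && power_target < 1))
    stop("`power_target` must lie in (0, 1)")
  for (n in 2:100000) {
    df <- n - 1
    ncp <- effect_size_d * sqrt(n)
    pw <- if (sided == "one") {
      1 - stats::pt(stats::qt(1 - alpha, df), df, ncp = ncp)
    } else {
      crit <- stats::qt(1 - alpha / 2, df)
      1 - stats::pt(crit, df, ncp = ncp) + stats::pt(-crit, df, ncp = ncp)
    }
    if (pw >= power_target) return(n)
  }
  stop("no n up to 100000 reaches the target power")
}
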