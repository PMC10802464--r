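# Permutation-based empirical p-values for any feature-importance statistic,
# with BH-FDR and Bonferroni correction.

#' Permutation-based empirical p-values for feature importances
#'
#' The outcome labels are permuted uniformly at random \code{n_perm} times;
#' for each permutation the supplied statistic is recomputed (the model is
#' refitted against the permuted labels while the data stay fixed) and each
#' feature's empirical p-value is the fraction of permutations whose
#' statistic is greater than or equal to the observed one:
#' \eqn{p_j = \#\{stat^{perm}_j \ge stat^{obs}_j\} / n_{perm}}. With
#' 10,000 permutations this gives p-values at a resolution of 0.0001. The
#' estimator can return exactly 0; set \code{plus_one = TRUE} for the
#' conservative \eqn{(c+1)/(n+1)} variant.
#'
#' @param fit_fn function \code{(data, y)} returning a named numeric vector
#'   of per-feature statistics, larger meaning more important (e.g. VIP,
#'   MB-VIP, absolute loadings).
#' @param data predictor data, passed to \code{fit_fn} unchanged.
#' @param y outcome vector to permute.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @param plus_one use the (c+1)/(n+1) estimator.
#' @return An object of class \code{permutation_result}: a data frame with
#'   \code{feature}, \code{statistic}, \code{exceed} (exceedance count),
#'   \code{p} and BH-adjusted \code{p_adj}; attributes \code{n_perm} and
#'   \code{seed}.
#' @export
permutation_pvalues <- function(fit_fn, data, y, n_perm = 10000,
                                seed = NULL, plus_one = FALSE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  observed <- fit_fn(data, y)
  exceed <- numeric(length(observed))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      stat <- fit_fn(data, sample(y))
      exceed <- exceed + (stat >= observed)
    }
  })
  p <- if (plus_one) (exceed + 1) / (n_perm + 1) else exceed / n_perm
  out <- data.frame(
    feature = names(observed) %||% paste0("X", seq_along(observed)),
    statistic = unname(observed),
    exceed = unname(exceed),
    p = unname(p),
    p_adj = bh_fdr(unname(p)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, n_perm = n_perm, seed = seed,
            class = c("permutation_result", "data.frame"))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment with running-minimum enforcement,
#' clipped at 1.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return Adjusted p-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Bonferroni adjustment
#'
#' @param pvalues numeric vector in [0, 1].
#' @return \code{pmin(1, p * length(p))} in input order.
#' @export
bonferroni <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "bonferroni")
}
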