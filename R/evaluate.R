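# Benchmarking procedures: univariate pathway-vs-molecular power
# comparison, target-pathway detection scoring, leak-free cross-validated
# predictive evaluation, and superscore-metadata correlation.

#' Mann-Whitney U test (two-sided)
#'
#' Wraps the rank-sum machinery behind a two-group interface: exact
#' enumeration when both groups have at most 8 values and no ties, a normal
#' approximation with tie correction otherwise.
#'
#' @param group_a,group_b numeric vectors (each non-empty).
#' @return List with \code{statistic} (the U statistic of
#'   \code{group_a}) and \code{p.value}.
#' @export
mwu_test <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty")
  }
  use_exact <- length(group_a) <= 8L && length(group_b) <= 8L &&
    !anyDuplicated(c(group_a, group_b))
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = use_exact,
                       correct = !use_exact))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Fisher combination of molecule p-values with a majority rule
#'
#' If at least \code{majority} of the (adjusted) molecule-level p-values
#' pass the significance threshold, all of them are combined with Fisher's
#' method (\eqn{-2\sum \ln p} against a chi-square with 2m degrees of
#' freedom); otherwise the combined pathway p-value is set to 1. Zero
#' p-values are floored at the smallest positive double with a warning.
#'
#' @param pvalues numeric vector of molecule-level p-values in [0, 1].
#' @param sig_threshold significance threshold (default 0.05).
#' @param majority required fraction of significant molecules (default 0.5).
#' @return The combined p-value.
#' @export
fisher_combine_with_majority_rule <- function(pvalues, sig_threshold = 0.05,
                                              majority = 0.5) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (mean(pvalues <= sig_threshold) < majority) return(1)
  if (any(pvalues == 0)) {
    warning("zero p-value(s) floored at the smallest positive double")
    pvalues <- pmax(pvalues, .Machine$double.xmin)
  }
  stat <- -2 * sum(log(pvalues))
  stats::pchisq(stat, df = 2 * length(pvalues), lower.tail = FALSE)
}

#' Univariate power comparison: pathway-level versus molecular-level
#'
#' For each spike-in realisation, both detection arms are run on the
#' unit-variance-scaled (per realisation) multi-omics data:
#' \itemize{
#'   \item pathway arm: a Mann-Whitney U test on the target pathway's ssPA
#'     scores between case and control groups, Bonferroni-corrected over
#'     the number of retained pathways;
#'   \item molecular arm: a Mann-Whitney U test per target-pathway
#'     molecule, Bonferroni-corrected over the tested molecules, then
#'     combined by the Fisher majority rule.
#' }
#' Reported is, per effect size and arm, the proportion of realisations
#' whose final p-value is at or below \code{sig_level}.
#'
#' @param realisations list of \code{spikein_dataset}s (e.g. from
#'   \code{\link{realisation_sweep}}).
#' @param collection the \code{pathway_collection} used for scoring.
#' @param sspa_method \code{"svd"} or \code{"kpca"}.
#' @param min_coverage minimum molecules per pathway.
#' @param sig_level significance level (default 0.05).
#' @return List with \code{curve} (data frame: \code{alpha}, \code{arm},
#'   \code{prop_significant}, \code{n_realisations}) and \code{detail}
#'   (per-realisation p-values for both arms).
#' @export
univariate_power_experiment <- function(realisations, collection,
                                        sspa_method = c("svd", "kpca"),
                                        min_coverage = 2,
                                        sig_level = 0.05) {
  sspa_method <- match.arg(sspa_method)
  fitter <- if (sspa_method == "svd") sspa_svd else sspa_kpca
  rows <- lapply(realisations, function(rl) {
    stopifnot(inherits(rl, "spikein_dataset"))
    X <- uv_scale(concat_blocks(rl$blocks))
    case <- seq_len(nrow(X)) %in% rl$case_idx
    fit <- fitter(X, collection, min_coverage = min_coverage)
    n_pw <- ncol(fit$scores)
    sc <- fit$scores[, rl$target]
    p_path <- min(1, mwu_test(sc[case], sc[!case])$p.value * n_pw)
    members <- intersect(pathway_members(collection, rl$target),
                         colnames(X))
    p_mol <- vapply(members, function(m) {
      mwu_test(X[case, m], X[!case, m])$p.value
    }, numeric(1))
    p_mol_adj <- pmin(1, p_mol * length(p_mol))
    p_comb <- fisher_combine_with_majority_rule(p_mol_adj,
                                                sig_threshold = sig_level)
    data.frame(alpha = rl$alpha, target = rl$target,
               p_pathway = p_path, p_molecular = p_comb,
               stringsAsFactors = FALSE)
  })
  detail <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  curve <- do.call(rbind, lapply(split(detail, detail$alpha), function(d) {
    data.frame(
      alpha = d$alpha[1],
      arm = c("pathway", "molecular"),
      prop_significant = c(mean(d$p_pathway <= sig_level),
                           mean(d$p_molecular <= sig_level)),
      n_realisations = nrow(d),
      stringsAsFactors = FALSE)
  }))
  rownames(curve) <- NULL
  list(curve = curve, detail = detail)
}

#' Score target-pathway detection from adjusted p-values
#'
#' Confusion counts at the 0.05 level over all tested pathways: the single
#' target pathway is a true positive if its adjusted p-value is at or below
#' the threshold (else a false negative); every significant non-target is a
#' false positive (overlapping pathways deliberately count as false
#' positives), every non-significant non-target a true negative. The
#' primary score is the balanced detection rate (TPR + TNR)/2; a rank-based
#' AUC of the target against non-targets using the adjusted p-value as
#' score (ties 0.5) is reported alongside.
#'
#' @param p_adj named numeric vector of adjusted p-values per pathway.
#' @param target_id the enriched target pathway id.
#' @param sig_level threshold (default 0.05).
#' @return List with \code{tp}, \code{fp}, \code{tn}, \code{fn},
#'   \code{balanced_rate}, \code{rank_auc}, \code{target_id} and
#'   \code{sig_level}.
#' @export
detection_score <- function(p_adj, target_id, sig_level = 0.05) {
  if (!target_id %in% names(p_adj)) stop("target not among tested pathways")
  is_target <- names(p_adj) == target_id
  sig <- p_adj <= sig_level
  tp <- as.integer(sig[is_target])
  fn <- 1L - tp
  fp <- sum(sig & !is_target)
  tn <- sum(!sig & !is_target)
  tpr <- tp
  tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  others <- p_adj[!is_target]
  auc <- if (length(others)) {
    (sum(others > p_adj[is_target]) + 0.5 * sum(others == p_adj[is_target])) /
      length(others)
  } else NA_real_
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       balanced_rate = (tpr + tnr) / 2, rank_auc = auc,
       target_id = target_id, sig_level = sig_level)
}

#' Repeated stratified cross-validated AUC
#'
#' Leak-free predictive evaluation: in each of \code{repeats} x
#' \code{folds} splits the supplied builder fits the full pipeline
#' (preprocessing, ssPA, model) on the training portion only, the held-out
#' samples are scored, and the AUC of the held-out scores against the true
#' labels is recorded. Reported are the per-split AUCs, their mean, and a
#' t-based 95\% confidence interval.
#'
#' @param blocks list of (molecular or score) blocks.
#' @param y binary outcome.
#' @param model_builder function \code{(train_blocks, train_y)} returning a
#'   fitted object whose \code{predict(object, test_blocks)} yields a list
#'   with a \code{score} element (or a numeric vector of scores).
#' @param folds,repeats cross-validation layout (default 5 x 5).
#' @param seed master RNG seed.
#' @return List with \code{mean_auc}, \code{ci} (length-2), \code{aucs}
#'   (per fold x repeat) and the layout.
#' @export
crossvalidated_auc <- function(blocks, y, model_builder, folds = 5,
                               repeats = 5, seed = NULL) {
  blocks <- as_block_list(blocks)
  enc <- encode_response(y)
  if (!enc$binary) stop("crossvalidated_auc expects a binary outcome")
  ybin <- enc$Y[, 1]
  seeds <- derive_seeds(seed %||% sample.int(.Machine$integer.max, 1),
                        repeats)
  aucs <- numeric(0)
  for (rp in seq_len(repeats)) {
    fold_id <- stratified_folds(ybin, folds, seed = seeds[rp])
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      btr <- lapply(blocks, function(b) b[tr, , drop = FALSE])
      bte <- lapply(blocks, function(b) b[!tr, , drop = FALSE])
      fit <- model_builder(btr, y[tr])
      pr <- predict(fit, bte)
      sc <- if (is.list(pr)) pr$score else pr
      aucs <- c(aucs, rank_auc(sc, ybin[!tr] == 1))
    }
  }
  m <- mean(aucs)
  se <- stats::sd(aucs) / sqrt(length(aucs))
  ci <- m + c(-1, 1) * stats::qt(0.975, length(aucs) - 1) * se
  list(mean_auc = m, ci = ci, aucs = aucs, folds = folds, repeats = repeats)
}

#' Correlate multi-view superscores with clinical metadata
#'
#' Spearman correlation between each latent variable's superscores and each
#' (numeric or ordinal-coded) metadata column, with Bonferroni adjustment
#' over all tests performed; associations with \eqn{|r| \ge} the threshold
#' and adjusted p at or below 0.05 are flagged. Constant metadata columns
#' yield NA.
#'
#' @param model a fitted \code{mbpls_model}.
#' @param metadata data frame or matrix, samples (rows) aligned to the
#'   model's training samples.
#' @param r_threshold absolute-correlation threshold (default 0.3).
#' @param sig_level adjusted-p threshold for flagging (default 0.05).
#' @return Data frame with \code{lv}, \code{variable}, \code{rho},
#'   \code{p}, \code{p_adj}, \code{flagged}.
#' @export
superscore_metadata_correlation <- function(model, metadata,
                                            r_threshold = 0.3,
                                            sig_level = 0.05) {
  stopifnot(inherits(model, "mbpls_model"))
  md <- as.data.frame(metadata)
  if (nrow(md) != nrow(model$T_super)) {
    stop("metadata rows must align with the model's training samples")
  }
  res <- expand.grid(lv = seq_len(model$ncomp), variable = colnames(md),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res$rho <- NA_real_
  res$p <- NA_real_
  for (i in seq_len(nrow(res))) {
    v <- md[[res$variable[i]]]
    if (!is.numeric(v)) v <- as.numeric(as.factor(v))
    if (length(unique(v[!is.na(v)])) < 2L) next
    ct <- suppressWarnings(
      stats::cor.test(model$T_super[, res$lv[i]], v, method = "spearman"))
    res$rho[i] <- unname(ct$estimate)
    res$p[i] <- ct$p.value
  }
  tested <- !is.na(res$p)
  res$p_adj <- NA_real_
  res$p_adj[tested] <- pmin(1, res$p[tested] * sum(tested))
  res$flagged <- !is.na(res$p_adj) & abs(res$rho) >= r_threshold &
    res$p_adj <= sig_level
  res
}
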