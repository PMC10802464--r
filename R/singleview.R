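# Single-view framework: one concatenated multi-omics pathway-score matrix
# fed to a pluggable predictor with a uniform importance interface.

# Built-in predictor back-ends. Each returns list(fit, predict_scores,
# importance) closures over the fitted object. External predictors supply
# the same contract directly.
predictor_backend <- function(kind, hyper = list()) {
  switch(kind,
    pls_da = list(
      fit = function(A, y) fit_pls(A, y, ncomp = hyper$ncomp %||% 2),
      predict_scores = function(fit, A) {
        pr <- predict(fit, A)
        if (is.list(pr)) pr$score else pr
      },
      importance = function(fit) vip(fit)$importance,
      importance_kind = "vip"),
    random_forest = list(
      fit = function(A, y) {
        do.call(randomForest::randomForest,
                c(list(x = A, y = as.factor(y)), hyper))
      },
      predict_scores = function(fit, A) {
        predict(fit, A, type = "prob")[, 2]
      },
      importance = function(fit) {
        g <- randomForest::importance(fit, type = 2)[, 1]
        g / sum(g)
      },
      importance_kind = "impurity"),
    logistic = list(
      fit = function(A, y) {
        df <- data.frame(A, check.names = FALSE)
        df$.y <- as.factor(y)
        suppressWarnings(
          stats::glm(.y ~ ., data = df, family = stats::binomial()))
      },
      predict_scores = function(fit, A) {
        stats::predict(fit, data.frame(A, check.names = FALSE),
                       type = "response")
      },
      importance = function(fit) {
        abs(stats::coef(fit)[-1L])
      },
      importance_kind = "coefficient"),
    stop("unknown predictor kind: ", kind)
  )
}

#' Fit a single-view pathway model
#'
#' The single-view framework concatenates the omics blocks column-wise,
#' computes multi-omics pathway activity scores on the concatenated data
#' (so each pathway score can draw on molecules from several omics), and
#' applies a predictive model to the resulting score matrix. Any model
#' honouring a minimal contract (\code{fit(A, y)},
#' \code{predict_scores(fit, A)}, \code{importance(fit)}) can be plugged
#' in; PLS-DA (VIP importances), random forest (normalised Gini impurity)
#' and logistic regression (absolute coefficients) are built in.
#'
#' @param blocks list of molecular-level (log2-scale) omics blocks sharing
#'   samples.
#' @param y binary outcome (2-level factor or 0/1 vector).
#' @param collection a \code{pathway_collection} (multi-omics member sets).
#' @param predictor \code{"pls_da"}, \code{"random_forest"},
#'   \code{"logistic"}, or a list implementing the contract above.
#' @param sspa_method \code{"svd"} or \code{"kpca"}.
#' @param min_coverage minimum molecules per pathway.
#' @param scale_scores unit-variance scale the pathway scores before the
#'   predictor (default TRUE; harmless for scale-insensitive predictors).
#' @param hyper named list of predictor hyperparameters (e.g.
#'   \code{list(ncomp = 2)} for PLS-DA, \code{list(ntree = 500)} for the
#'   forest).
#' @param seed RNG seed (stochastic predictors such as the forest).
#' @return An object of class \code{singleview_model} with the fitted
#'   transform chain, predictor, and an \code{importance_table}.
#' @export
fit_singleview <- function(blocks, y, collection,
                           predictor = "pls_da",
                           sspa_method = c("svd", "kpca"),
                           min_coverage = 2, scale_scores = TRUE,
                           hyper = list(), seed = NULL) {
  sspa_method <- match.arg(sspa_method)
  X <- concat_blocks(blocks)
  backend <- if (is.list(predictor)) {
    if (!all(c("fit", "predict_scores", "importance") %in% names(predictor))) {
      stop("external predictor must supply fit, predict_scores, importance")
    }
    c(predictor, list(importance_kind = predictor$importance_kind %||%
                        "external"))
  } else {
    predictor_backend(match.arg(predictor,
                                c("pls_da", "random_forest", "logistic")),
                      hyper)
  }
  scaled <- uv_scale(X)
  mol_scaler <- list(center = attr(scaled, "center"),
                     scale = attr(scaled, "scale"))
  fitter <- if (sspa_method == "svd") sspa_svd else sspa_kpca
  sspa_fit <- fitter(scaled, collection, min_coverage = min_coverage)
  A <- sspa_fit$scores
  score_scaler <- NULL
  if (scale_scores) {
    As <- uv_scale(A)
    score_scaler <- list(center = attr(As, "center"),
                         scale = attr(As, "scale"))
    A <- structure(as.matrix(As), dimnames = dimnames(As))
  }
  fit <- with_seed(seed, backend$fit(A, y))
  imp <- backend$importance(fit)
  importance <- structure(
    data.frame(feature = colnames(A), block = "multiomics",
               importance = unname(imp)[seq_len(ncol(A))],
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("importance_table", "data.frame"))
  enc <- encode_response(y)
  structure(
    list(backend = backend, fit = fit, importance = importance,
         mol_scaler = mol_scaler, sspa_fit = sspa_fit,
         score_scaler = score_scaler, encoding = enc,
         predictor = if (is.list(predictor)) "external" else predictor),
    class = "singleview_model")
}

#' @export
print.singleview_model <- function(x, ...) {
  cat("Single-view pathway model (", x$predictor, "): ",
      nrow(x$importance), " pathway features\n", sep = "")
  top <- utils::head(x$importance[order(-x$importance$importance), ], 5)
  cat("  top pathways:", paste(top$feature, collapse = ", "), "\n")
  invisible(x)
}

# Transform new molecular blocks through the stored chain to score space.
singleview_scores <- function(object, newblocks) {
  X <- concat_blocks(newblocks)
  scaled <- apply_uv_scale(X, object$mol_scaler)
  A <- predict(object$sspa_fit, scaled)
  if (!is.null(object$score_scaler)) {
    A <- as.matrix(apply_uv_scale(A, object$score_scaler))
  }
  A
}

#' Predict from a fitted single-view model
#'
#' New blocks pass through the train-fitted scaling and multi-omics ssPA
#' transform, then the fitted predictor.
#'
#' @param object a \code{singleview_model}.
#' @param newblocks list of molecular blocks on the training molecule
#'   universe.
#' @param ... unused.
#' @return List with \code{score} (positive-class score) and \code{class}
#'   (labels at score 0.5 for probabilistic predictors / the encoding
#'   midpoint).
#' @export
predict.singleview_model <- function(object, newblocks, ...) {
  A <- singleview_scores(object, newblocks)
  score <- object$backend$predict_scores(object$fit, A)
  cls <- object$encoding$levels[(score >= 0.5) + 1L]
  list(score = unname(score), class = cls)
}

#' Recursive feature elimination over pathway features
#'
#' Starting from all pathway-score features, repeatedly drops the feature
#' with the lowest importance (refitted on the remaining set) while
#' tracking the stratified cross-validated AUC of the predictor at each
#' set size; returns the feature set maximising the mean CV score
#' (smallest set on ties).
#'
#' @inheritParams fit_singleview
#' @param folds number of CV folds.
#' @param seed RNG seed (folds and stochastic predictors).
#' @return List with \code{selected} (pathway ids), \code{cv_curve}
#'   (data frame of set size vs mean CV AUC), and \code{n_selected}.
#' @export
recursive_feature_elimination <- function(blocks, y, collection,
                                          predictor = "random_forest",
                                          sspa_method = c("svd", "kpca"),
                                          min_coverage = 2, folds = 5,
                                          hyper = list(), seed = NULL) {
  sspa_method <- match.arg(sspa_method)
  backend <- predictor_backend(
    match.arg(predictor, c("pls_da", "random_forest", "logistic")), hyper)
  X <- concat_blocks(blocks)
  scaled <- uv_scale(X)
  fitter <- if (sspa_method == "svd") sspa_svd else sspa_kpca
  A_full <- fitter(scaled, collection, min_coverage = min_coverage)$scores
  A_full <- as.matrix(uv_scale(A_full))
  enc <- encode_response(y)
  ybin <- enc$Y[, 1]
  seeds <- derive_seeds(seed %||% sample.int(.Machine$integer.max, 1), 2)
  fold_id <- stratified_folds(ybin, folds, seed = seeds[1])
  cv_auc <- function(feats) {
    aucs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      fit <- with_seed(seeds[2] + f,
                       backend$fit(A_full[tr, feats, drop = FALSE], y[tr]))
      pr <- backend$predict_scores(fit, A_full[!tr, feats, drop = FALSE])
      rank_auc(pr, ybin[!tr] == 1)
    }, numeric(1))
    mean(aucs)
  }
  feats <- colnames(A_full)
  sizes <- integer(0)
  scores <- numeric(0)
  sets <- list()
  while (length(feats) >= 1L) {
    sizes <- c(sizes, length(feats))
    scores <- c(scores, cv_auc(feats))
    sets[[length(sets) + 1L]] <- feats
    if (length(feats) == 1L) break
    fit <- with_seed(seeds[2],
                     backend$fit(A_full[, feats, drop = FALSE], y))
    imp <- backend$importance(fit)[seq_along(feats)]
    feats <- feats[-which.min(imp)]
  }
  best <- which(scores == max(scores))
  best <- best[which.min(sizes[best])]
  list(selected = sets[[best]], n_selected = sizes[best],
       cv_curve = data.frame(n_features = sizes, mean_auc = scores))
}
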