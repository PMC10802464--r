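# Multi-block PLS (NIPALS) on per-omics pathway-score blocks: fit, predict,
# block importances, MB-VIP, bootstrap, latent-variable selection.

# Internal: prepare the list of predictor blocks. Accepts matrices,
# omics_blocks, sspa_scores objects (their score matrix is taken) or a mix.
as_block_list <- function(blocks) {
  if (!is.list(blocks) || is.data.frame(blocks)) blocks <- list(blocks)
  out <- lapply(blocks, function(b) {
    if (inherits(b, "sspa_scores")) b$scores else as.matrix(b)
  })
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    names(out) <- paste0("block", seq_along(out))
  }
  rn <- rownames(out[[1L]])
  for (b in out[-1L]) {
    if (nrow(b) != nrow(out[[1L]]) ||
        (!is.null(rn) && !is.null(rownames(b)) && !identical(rownames(b), rn))) {
      stop("all blocks must share the same samples in the same order")
    }
  }
  out
}

#' Fit a multi-view (multi-block PLS) pathway model
#'
#' NIPALS MB-PLS with superscore deflation (Westerhuis & Coenegracht): per
#' latent variable each block gets a unit-norm weight vector and block
#' scores; the block scores are combined through unit-norm superweights into
#' a superscore, which predicts the response scores and deflates every X
#' block and Y, rendering the superscores mutually orthogonal. Per-LV block
#' importances are the squared superweights (summing to 1 across blocks),
#' measuring each omics view's contribution to the explained outcome
#' variance.
#'
#' Two input modes:
#' \itemize{
#'   \item \code{collection = NULL} (default): \code{blocks} are
#'     pathway-score (or generic feature) matrices; each block is
#'     unit-variance scaled internally (\code{scale = TRUE}) and modelled
#'     directly.
#'   \item \code{collection} supplied: \code{blocks} are molecular-level
#'     (log2-scale) omics blocks; each is unit-variance scaled, transformed
#'     to pathway scores per block with the chosen ssPA method, the score
#'     blocks scaled, then modelled. All fitted states are stored so
#'     \code{predict} applies the identical leak-free chain to new samples.
#' }
#'
#' @param blocks list of two or more matrices/\code{omics_block}s (or
#'   \code{sspa_scores} objects) sharing samples.
#' @param y outcome: 2-level factor (or 0/1 vector) or continuous numeric.
#' @param ncomp number of latent variables R.
#' @param collection optional \code{pathway_collection} switching on the
#'   molecular-input mode.
#' @param sspa_method \code{"svd"} or \code{"kpca"} (molecular mode only).
#' @param min_coverage minimum molecules per pathway (molecular mode).
#' @param scale unit-variance scale the model input blocks (recommended and
#'   default).
#' @param tol,max_iter NIPALS convergence controls.
#' @return An object of class \code{mbpls_model} with per-block weights
#'   \code{W} (unit norm per LV), superweights \code{A}, block scores
#'   \code{T_blocks}, superscores \code{T_super}, block loadings \code{V},
#'   Y weights \code{C}, Y scores \code{U}, per-LV explained sum of squares
#'   of Y \code{ssy}, block importances, and all fitted preprocessing/ssPA
#'   states.
#' @export
fit_multiview <- function(blocks, y, ncomp = 2, collection = NULL,
                          sspa_method = c("svd", "kpca"), min_coverage = 2,
                          scale = TRUE, tol = 1e-10, max_iter = 500) {
  sspa_method <- match.arg(sspa_method)
  blocks <- as_block_list(blocks)
  if (length(blocks) < 2L) {
    stop("multi-view models need at least 2 blocks; use fit_pls for one")
  }
  mol_scalers <- NULL
  sspa_fits <- NULL
  if (!is.null(collection)) {
    mol_scalers <- lapply(blocks, uv_scale)
    fitter <- if (sspa_method == "svd") sspa_svd else sspa_kpca
    sspa_fits <- lapply(mol_scalers, fitter, collection = collection,
                        min_coverage = min_coverage)
    empty <- vapply(sspa_fits, function(f) ncol(f$scores) == 0L, logical(1))
    if (any(empty)) {
      stop("no pathway reaches coverage ", min_coverage, " in block(s): ",
           paste(names(blocks)[empty], collapse = ", "))
    }
    blocks <- lapply(sspa_fits, `[[`, "scores")
    mol_scalers <- lapply(mol_scalers, function(b) {
      list(center = attr(b, "center"), scale = attr(b, "scale"))
    })
  }
  score_scalers <- NULL
  if (scale) {
    scaled <- lapply(blocks, uv_scale)
    score_scalers <- lapply(scaled, function(b) {
      list(center = attr(b, "center"), scale = attr(b, "scale"))
    })
    blocks <- lapply(scaled, function(b) {
      structure(as.matrix(b), dimnames = dimnames(b))
    })
  }
  enc <- encode_response(y)
  Y <- enc$Y
  n <- nrow(Y)
  if (any(vapply(blocks, nrow, integer(1)) != n)) {
    stop("blocks and y sizes do not match")
  }
  K <- length(blocks)
  ym <- colMeans(Y)
  F <- sweep(Y, 2, ym)
  E <- lapply(blocks, function(b) sweep(b, 2, colMeans(b)))
  x_centers <- lapply(blocks, colMeans)
  Jk <- vapply(E, ncol, integer(1))
  W <- lapply(Jk, function(j) matrix(0, j, ncomp))
  V <- lapply(Jk, function(j) matrix(0, j, ncomp))
  A <- matrix(0, K, ncomp, dimnames = list(names(blocks), NULL))
  Tb <- lapply(seq_len(K), function(k) matrix(0, n, ncomp))
  Ts <- matrix(0, n, ncomp)
  C <- matrix(0, ncol(F), ncomp)
  U <- matrix(0, n, ncomp)
  ssy <- numeric(ncomp)
  for (r in seq_len(ncomp)) {
    u <- F[, which.max(col_vars(F)), drop = TRUE]
    if (all(abs(u) < .Machine$double.eps)) u <- E[[1L]][, 1]
    ts_old <- rep(Inf, n)
    wk <- vector("list", K)
    tk <- matrix(0, n, K)
    for (it in seq_len(max_iter)) {
      for (k in seq_len(K)) {
        w <- drop(crossprod(E[[k]], u))
        w <- w / sqrt(sum(w^2))
        wk[[k]] <- w
        tk[, k] <- E[[k]] %*% w
      }
      a <- drop(crossprod(tk, u))
      a <- a / sqrt(sum(a^2))
      ts <- drop(tk %*% a)
      cc <- drop(crossprod(F, ts)) / sum(ts^2)
      u <- drop(F %*% cc) / sum(cc^2)
      if (sqrt(sum((ts - ts_old)^2)) < tol * sqrt(sum(ts^2))) {
        ts_old <- ts
        break
      }
      ts_old <- ts
    }
    ts <- ts_old
    for (k in seq_len(K)) {
      W[[k]][, r] <- wk[[k]]
      Tb[[k]][, r] <- tk[, k]
      v <- drop(crossprod(E[[k]], ts)) / sum(ts^2)
      V[[k]][, r] <- v
      E[[k]] <- E[[k]] - tcrossprod(ts, v)
    }
    A[, r] <- a
    Ts[, r] <- ts
    C[, r] <- cc
    U[, r] <- u
    ssy[r] <- sum(ts^2) * sum(cc^2)
    F <- F - tcrossprod(ts, cc)
  }
  for (k in seq_len(K)) {
    rownames(W[[k]]) <- rownames(V[[k]]) <- colnames(blocks[[k]])
  }
  names(W) <- names(V) <- names(Tb) <- names(x_centers) <- names(blocks)
  structure(
    list(W = W, A = A, V = V, C = C, T_blocks = Tb, T_super = Ts, U = U,
         ssy = ssy, ssy_cum = sum(ssy), ncomp = ncomp, n_blocks = K,
         x_centers = x_centers, y_center = ym, encoding = enc,
         features = lapply(blocks, colnames),
         score_scalers = score_scalers, mol_scalers = mol_scalers,
         sspa_fits = sspa_fits, sspa_method = sspa_method,
         residual_Y = F),
    class = "mbpls_model")
}

#' @export
print.mbpls_model <- function(x, ...) {
  cat("Multi-view MB-PLS model:", x$n_blocks, "blocks (",
      paste(vapply(x$features, length, integer(1)), collapse = " + "),
      "features ),", x$ncomp, "latent variable(s)\n")
  bi <- block_importance(x, per_lv = FALSE)
  cat("  block importance:",
      paste(sprintf("%s %.2f", bi$block, bi$importance), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.mbpls_model <- function(object, ...) {
  cat("Multi-view MB-PLS model\n")
  cat("  blocks:", paste(names(object$W), collapse = ", "), "\n")
  cat("  latent variables:", object$ncomp, "\n")
  cat("  explained SS of Y per LV (fraction of total explained):",
      paste(signif(object$ssy / object$ssy_cum, 3), collapse = " "), "\n")
  print(block_importance(object, per_lv = TRUE))
  invisible(object)
}

# Apply stored preprocessing/ssPA chain to new molecular or score blocks.
prepare_new_blocks <- function(object, newblocks) {
  nb <- as_block_list(newblocks)
  if (!is.null(object$sspa_fits)) {
    if (length(nb) != length(object$mol_scalers)) {
      stop("expected ", length(object$mol_scalers), " molecular blocks")
    }
    nb <- lapply(seq_along(nb), function(k) {
      scaled <- apply_uv_scale(nb[[k]], object$mol_scalers[[k]])
      predict(object$sspa_fits[[k]], scaled)
    })
  }
  if (!is.null(object$score_scalers)) {
    nb <- lapply(seq_along(nb), function(k) {
      as.matrix(apply_uv_scale(nb[[k]], object$score_scalers[[k]]))
    })
  }
  for (k in seq_along(nb)) {
    feats <- object$features[[k]]
    missing <- setdiff(feats, colnames(nb[[k]]))
    if (length(missing)) {
      stop("block ", k, " lacks feature(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    nb[[k]] <- nb[[k]][, feats, drop = FALSE]
  }
  nb
}

#' Predict from a fitted multi-view model
#'
#' New blocks pass through the stored (train-fitted) scaling and ssPA
#' transforms, then through the sequential MB-PLS projection: per latent
#' variable the block scores and superscore are formed with the stored
#' weights and the blocks deflated with the stored loadings, accumulating
#' the prediction \eqn{\hat Y}.
#'
#' @param object an \code{mbpls_model}.
#' @param newblocks list of new blocks matching the training input mode
#'   (molecular blocks if the model was fitted with a pathway collection,
#'   score blocks otherwise).
#' @param ncomp number of latent variables to use (defaults to all fitted).
#' @param ... unused.
#' @return List with \code{score} (continuous prediction), \code{class}
#'   (for binary outcomes, labels at the encoding midpoint) and
#'   \code{superscores} (new-sample projections, samples x ncomp).
#' @export
predict.mbpls_model <- function(object, newblocks, ncomp = object$ncomp, ...) {
  stopifnot(ncomp >= 1, ncomp <= object$ncomp)
  nb <- prepare_new_blocks(object, newblocks)
  K <- object$n_blocks
  Ek <- lapply(seq_len(K), function(k) {
    sweep(nb[[k]], 2, object$x_centers[[k]])
  })
  n <- nrow(Ek[[1L]])
  Tsn <- matrix(0, n, ncomp)
  Yhat <- matrix(rep(object$y_center, each = n), n)
  for (r in seq_len(ncomp)) {
    tk <- vapply(seq_len(K), function(k) {
      drop(Ek[[k]] %*% object$W[[k]][, r])
    }, numeric(n))
    tk <- matrix(tk, nrow = n)
    ts <- drop(tk %*% object$A[, r])
    Tsn[, r] <- ts
    for (k in seq_len(K)) {
      Ek[[k]] <- Ek[[k]] - tcrossprod(ts, object$V[[k]][, r])
    }
    Yhat <- Yhat + tcrossprod(ts, object$C[, r, drop = FALSE])
  }
  score <- drop(Yhat)
  out <- list(score = score, superscores = Tsn)
  if (object$encoding$binary) {
    out$class <- object$encoding$levels[(score >= object$encoding$midpoint) + 1L]
  }
  out
}

#' Multi-block variable importance in projection (MB-VIP)
#'
#' Extends VIP to multi-block models: for feature j of block k,
#' \deqn{MBVIP_j = \sqrt{f \sum_r (w_{krj}^2\, SSY_r)/SSY_{cum}}}
#' where f is the total number of features across blocks and the block
#' weights have unit norm within each block per LV. Under that
#' normalisation the total sum of squared MB-VIP values equals f times the
#' number of blocks.
#'
#' @param model a fitted \code{mbpls_model}.
#' @return Data frame (class \code{importance_table}) with \code{feature},
#'   \code{block} and \code{importance}, stacked across blocks.
#' @export
mb_vip <- function(model) {
  stopifnot(inherits(model, "mbpls_model"))
  f <- sum(vapply(model$W, nrow, integer(1)))
  rows <- lapply(names(model$W), function(k) {
    Wk <- model$W[[k]]
    v <- sqrt(f * drop(Wk^2 %*% model$ssy) / model$ssy_cum)
    data.frame(feature = rownames(Wk) %||% paste0(k, "_X", seq_len(nrow(Wk))),
               block = k, importance = v,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("importance_table", "data.frame"))
}

#' Contribution of each omics block to the outcome prediction
#'
#' Per latent variable, a block's importance is its squared superweight:
#' the share of the superscore direction carried by that block's scores.
#' Shares sum to 1 across blocks per LV. With \code{per_lv = FALSE} the
#' shares are aggregated across LVs weighted by each LV's explained sum of
#' squares of Y.
#'
#' @param model a fitted \code{mbpls_model}.
#' @param per_lv return per-LV shares (default) or the SSY-weighted
#'   aggregate.
#' @return Data frame with \code{block}, \code{lv} (when \code{per_lv}),
#'   and \code{importance}.
#' @export
block_importance <- function(model, per_lv = TRUE) {
  stopifnot(inherits(model, "mbpls_model"))
  shares <- model$A^2
  if (per_lv) {
    data.frame(
      block = rep(rownames(shares), model$ncomp),
      lv = rep(seq_len(model$ncomp), each = model$n_blocks),
      importance = as.vector(shares),
      stringsAsFactors = FALSE)
  } else {
    w <- model$ssy / model$ssy_cum
    data.frame(block = rownames(shares),
               importance = drop(shares %*% w),
               stringsAsFactors = FALSE)
  }
}

#' Bootstrap stability of block importances
#'
#' Resamples samples with replacement, refits the multi-view model, and
#' aggregates the per-LV block importances across replicates. Replicates
#' whose refit fails (e.g. a zero-variance column in the resample) are
#' skipped and counted.
#'
#' @param blocks,y,ncomp,... passed to \code{\link{fit_multiview}}.
#' @param n_boot number of bootstrap replicates (100 is typical).
#' @param seed RNG seed.
#' @return Data frame with \code{block}, \code{lv}, \code{mean}, \code{sd}
#'   and full-data \code{importance}; attribute \code{n_skipped}.
#' @export
bootstrap_block_importance <- function(blocks, y, ncomp = 2, n_boot = 100,
                                       seed = NULL, ...) {
  blocks <- as_block_list(blocks)
  full <- fit_multiview(blocks, y, ncomp = ncomp, ...)
  full_bi <- block_importance(full, per_lv = TRUE)
  n <- nrow(blocks[[1L]])
  reps <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, replace = TRUE)
      bb <- lapply(blocks, function(m) {
        m2 <- m[idx, , drop = FALSE]
        rownames(m2) <- paste0("b", seq_len(n))
        m2
      })
      tryCatch(
        block_importance(
          fit_multiview(bb, y[idx], ncomp = ncomp, ...), per_lv = TRUE
        )$importance,
        error = function(e) NULL)
    })
  })
  ok <- !vapply(reps, is.null, logical(1))
  n_skipped <- sum(!ok)
  if (!any(ok)) stop("all bootstrap replicates failed")
  mat <- do.call(rbind, reps[ok])
  out <- data.frame(
    block = full_bi$block, lv = full_bi$lv,
    mean = colMeans(mat), sd = apply(mat, 2, stats::sd),
    importance = full_bi$importance,
    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Select the number of latent variables by cross-validation
#'
#' Stratified k-fold cross-validation over candidate numbers of latent
#' variables: per fold the whole pipeline (scaling, optional per-block ssPA,
#' MB-PLS) is fitted on the training portion only and the held-out samples
#' are scored; the candidate with the best mean held-out AUC (binary y) or
#' R-squared (continuous y) is selected, ties going to the smallest
#' candidate. The model is fitted once per fold at the largest candidate
#' and truncated, which is exact because NIPALS components are computed
#' sequentially.
#'
#' @param blocks list of blocks (score matrices, or molecular blocks when
#'   \code{collection} is given).
#' @param y outcome.
#' @param candidates integer vector of candidate LV counts.
#' @param folds number of CV folds.
#' @param repeats number of repeated fold assignments averaged over
#'   (repetition reduces the fold-assignment noise of the selection when
#'   the CV curve is flat).
#' @param seed RNG seed for the fold assignments.
#' @param collection,sspa_method,min_coverage as in
#'   \code{\link{fit_multiview}}.
#' @return List with \code{ncomp} (selected), \code{cv_curve} (data frame
#'   of candidate vs mean and per-fold scores) and \code{metric}.
#' @export
select_n_latent <- function(blocks, y, candidates = 1:5, folds = 5,
                            repeats = 1, seed = NULL, collection = NULL,
                            sspa_method = c("svd", "kpca"),
                            min_coverage = 2) {
  sspa_method <- match.arg(sspa_method)
  stopifnot(length(candidates) >= 1L, repeats >= 1L)
  candidates <- sort(unique(as.integer(candidates)))
  blocks <- as_block_list(blocks)
  enc <- encode_response(y)
  binary <- enc$binary
  seeds <- derive_seeds(seed %||% sample.int(.Machine$integer.max, 1),
                        repeats)
  rmax <- max(candidates)
  scores <- matrix(NA_real_, folds * repeats, length(candidates),
                   dimnames = list(NULL, candidates))
  for (rp in seq_len(repeats)) {
    fold_id <- stratified_folds(if (binary) enc$Y[, 1] else
      cut(rank(enc$Y[, 1]), folds), folds, seed = seeds[rp])
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      te <- !tr
      btr <- lapply(blocks, function(b) b[tr, , drop = FALSE])
      bte <- lapply(blocks, function(b) b[te, , drop = FALSE])
      fit <- fit_multiview(btr, if (is.matrix(y)) y[tr, , drop = FALSE] else
        y[tr], ncomp = rmax, collection = collection,
        sspa_method = sspa_method, min_coverage = min_coverage)
      for (ci in seq_along(candidates)) {
        pr <- predict(fit, bte, ncomp = candidates[ci])
        obs <- enc$Y[te, 1]
        scores[(rp - 1) * folds + f, ci] <- if (binary) {
          rank_auc(pr$score, obs == 1)
        } else {
          1 - sum((obs - pr$score)^2) / sum((obs - mean(obs))^2)
        }
      }
    }
  }
  mean_score <- colMeans(scores)
  best <- candidates[which.max(mean_score)]
  list(ncomp = best,
       cv_curve = data.frame(ncomp = candidates, mean_score = mean_score,
                             t(scores), check.names = FALSE,
                             row.names = NULL),
       metric = if (binary) "auc" else "r2")
}
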