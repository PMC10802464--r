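# Single-block PLS regression via NIPALS, with variable importance in
# projection (VIP).

# Encode the response for regression-form PLS: binary outcomes become a
# single 0/1 column (second factor level / larger value = positive class),
# continuous outcomes pass through as columns. Returns the numeric matrix
# plus the encoding needed to threshold predictions.
encode_response <- function(y) {
  if (is.matrix(y)) {
    return(list(Y = y, binary = FALSE, levels = NULL, midpoint = NULL))
  }
  if (is.factor(y) || is.character(y) || is.logical(y) ||
      (is.numeric(y) && length(unique(y)) == 2L)) {
    f <- as.factor(y)
    if (nlevels(f) != 2L) stop("binary outcome must have exactly 2 levels")
    ynum <- as.numeric(f) - 1
    return(list(Y = matrix(ynum, ncol = 1), binary = TRUE,
                levels = levels(f), midpoint = 0.5))
  }
  list(Y = matrix(as.numeric(y), ncol = 1), binary = FALSE,
       levels = NULL, midpoint = NULL)
}

#' Fit a single-block PLS regression model (NIPALS)
#'
#' Decomposes centred X and Y into scores and loadings one latent variable
#' (LV) at a time: per LV the weight/score updates are iterated until the
#' X-score change falls below \code{tol}, after which X is deflated with its
#' loadings (\eqn{X_{r+1} = X_r - t_r v_r^T}) and Y with the fitted part.
#' The first latent score pair maximises the covariance between the X and Y
#' projections. Regression coefficients are \eqn{\beta = W^* C^T} with
#' \eqn{W^* = W (V^T W)^{-1}} relating weights back to the original
#' variables.
#'
#' X is expected on a common scale (typically unit-variance scaled); X and Y
#' are centred internally and the centres stored for prediction. Binary
#' outcomes are encoded as a single 0/1 column and classified at the
#' midpoint.
#'
#' @param X numeric predictor matrix (samples x features).
#' @param y response: numeric vector/matrix, or a 2-level factor.
#' @param ncomp number of latent variables R.
#' @param tol NIPALS convergence tolerance on the score vector change.
#' @param max_iter iteration cap per LV (non-convergence yields a warning
#'   and the current vectors are accepted).
#' @return An object of class \code{pls_model}: weights \code{W} (unit norm
#'   per LV), \code{Wstar}, X loadings \code{V}, Y weights \code{C}, scores
#'   \code{T_scores} and \code{U_scores}, coefficients \code{B}, per-LV
#'   explained sum of squares of Y \code{ssy} and their total
#'   \code{ssy_cum}, centres, and the response encoding.
#' @export
fit_pls <- function(X, y, ncomp = 2, tol = 1e-10, max_iter = 500) {
  X <- as.matrix(X)
  enc <- encode_response(y)
  Y <- enc$Y
  if (nrow(X) != nrow(Y)) stop("X and y sizes do not match")
  if (ncomp < 1) stop("ncomp must be >= 1")
  rk <- qr(scale(X, scale = FALSE))$rank
  if (ncomp > rk) {
    stop("ncomp (", ncomp, ") exceeds the rank of centred X (", rk, ")")
  }
  xm <- colMeans(X)
  ym <- colMeans(Y)
  E <- sweep(X, 2, xm)
  F <- sweep(Y, 2, ym)
  n <- nrow(E); J <- ncol(E); H <- ncol(F)
  W <- matrix(0, J, ncomp); V <- matrix(0, J, ncomp)
  C <- matrix(0, H, ncomp)
  Tm <- matrix(0, n, ncomp); U <- matrix(0, n, ncomp)
  ssy <- numeric(ncomp)
  for (r in seq_len(ncomp)) {
    u <- F[, which.max(col_vars(F)), drop = TRUE]
    if (all(abs(u) < .Machine$double.eps)) u <- E[, 1]
    t_old <- rep(Inf, n)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(E, u))
      w <- w / sqrt(sum(w^2))
      tt <- drop(E %*% w)
      cc <- drop(crossprod(F, tt)) / sum(tt^2)
      u <- drop(F %*% cc) / sum(cc^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) {
        converged <- TRUE
        t_old <- tt
        break
      }
      t_old <- tt
    }
    if (!converged && H > 1L) {
      warning("NIPALS did not converge for LV ", r,
              " within ", max_iter, " iterations")
    }
    tt <- t_old
    v <- drop(crossprod(E, tt)) / sum(tt^2)
    W[, r] <- w; V[, r] <- v; C[, r] <- cc
    Tm[, r] <- tt; U[, r] <- u
    ssy[r] <- sum(tt^2) * sum(cc^2)
    E <- E - tcrossprod(tt, v)
    F <- F - tcrossprod(tt, cc)
  }
  Wstar <- W %*% solve(crossprod(V, W))
  B <- Wstar %*% t(C)
  dimnames(B) <- list(colnames(X), colnames(Y))
  rownames(W) <- rownames(V) <- rownames(Wstar) <- colnames(X)
  structure(
    list(W = W, Wstar = Wstar, V = V, C = C, T_scores = Tm, U_scores = U,
         B = B, ssy = ssy, ssy_cum = sum(ssy), ncomp = ncomp,
         x_center = xm, y_center = ym, encoding = enc,
         features = colnames(X), residual_X = E, residual_Y = F),
    class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("PLS model:", length(x$features), "features,", x$ncomp,
      "latent variable(s)\n")
  cat("  explained SS of Y per LV:",
      paste(signif(x$ssy / x$ssy_cum, 3), collapse = " "), "\n")
  invisible(x)
}

#' @export
coef.pls_model <- function(object, ...) object$B

#' Predict from a fitted PLS model
#'
#' @param object a \code{pls_model}.
#' @param newdata matrix on the training scale with the training columns.
#' @param ... unused.
#' @return For continuous y, the numeric predictions. For binary y, a list
#'   with \code{score} (continuous prediction on the 0/1 encoding scale)
#'   and \code{class} (labels thresholded at the encoding midpoint).
#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$features)) {
    missing <- setdiff(object$features, colnames(X))
    if (length(missing)) {
      stop("newdata lacks feature(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    X <- X[, object$features, drop = FALSE]
  }
  Yhat <- sweep(X, 2, object$x_center) %*% object$B
  Yhat <- sweep(Yhat, 2, object$y_center, "+")
  if (object$encoding$binary) {
    score <- drop(Yhat)
    list(score = score,
         class = object$encoding$levels[(score >= object$encoding$midpoint) + 1L])
  } else if (ncol(Yhat) == 1L) drop(Yhat) else Yhat
}

#' Variable importance in projection (VIP)
#'
#' Per-feature importance combining the squared PLS weights with each latent
#' variable's share of the explained sum of squares of Y:
#' \deqn{VIP_j = \sqrt{J \sum_r (w_{rj}^2\, SSY_r) / SSY_{cum}}}
#' with J the number of features. Because the weights have unit norm per LV,
#' the mean of the squared VIP values over features is exactly 1.
#'
#' @param model a fitted \code{pls_model}.
#' @return Data frame (class \code{importance_table}) with \code{feature},
#'   \code{block} (NA for single-block models) and \code{importance}.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  J <- nrow(model$W)
  v <- sqrt(J * drop(model$W^2 %*% model$ssy) / model$ssy_cum)
  structure(
    data.frame(feature = model$features %||% paste0("X", seq_len(J)),
               block = NA_character_, importance = v,
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("importance_table", "data.frame"))
}
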