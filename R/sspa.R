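# Single-sample pathway analysis (ssPA): transform molecular-level blocks
# into pathway activity score matrices via the PLAGE/SVD method or RBF
# kernel-PCA, with leak-free application of the fitted transform to new
# samples and molecule-level loadings.

# Concatenate one block or a list of blocks column-wise after checking that
# all blocks share the same samples. Molecules appearing in more than one
# block under the same identifier are kept once (first block wins).
concat_blocks <- function(x) {
  if (!is.list(x) || is.data.frame(x)) x <- list(x)
  mats <- lapply(x, as.matrix)
  if (length(mats) > 1L) {
    rn <- rownames(mats[[1L]])
    for (m in mats[-1L]) {
      if (!identical(rownames(m), rn)) {
        stop("all blocks must share the same samples in the same order")
      }
    }
  }
  out <- do.call(cbind, mats)
  dup <- duplicated(colnames(out))
  if (any(dup)) {
    warning("molecule id(s) present in multiple blocks kept once: ",
            paste(utils::head(unique(colnames(out)[dup]), 5), collapse = ", "))
    out <- out[, !dup, drop = FALSE]
  }
  out
}

assert_uv_scaled <- function(x, what = "input") {
  mu <- colMeans(x)
  sd <- sqrt(col_vars(x))
  if (max(abs(mu)) > 1e-6 || max(abs(sd - 1)) > 1e-3) {
    stop(what, " must be unit-variance scaled (see uv_scale())")
  }
  invisible(TRUE)
}

rbf_kernel <- function(a, b, gamma) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Fit SVD (PLAGE) pathway activity scores
#'
#' For each pathway with at least \code{min_coverage} molecules in the data,
#' the sub-matrix \eqn{Z_i} of scaled abundances of its member molecules is
#' decomposed by SVD and the pathway activity score of each sample is its
#' projection on the first right singular vector, \eqn{a_i = Z_i v_1} (the
#' first principal component score). The sign of \eqn{v_1} is fixed so its
#' largest-magnitude loading is positive, making scores deterministic and
#' invariant to member ordering.
#'
#' @param x a unit-variance-scaled matrix/\code{omics_block}, or a list of
#'   such blocks sharing samples (columns are concatenated, giving
#'   multi-omics pathway scores).
#' @param collection a \code{pathway_collection}.
#' @param min_coverage minimum mapped molecules per pathway (default 2);
#'   pathways below it are dropped, not an error.
#' @return An object of class \code{c("sspa_svd", "sspa_scores")} with
#'   elements \code{scores} (samples x pathways), \code{pathways} (fitted
#'   per-pathway state), \code{dropped} (ids below coverage) and
#'   \code{method}.
#' @export
sspa_svd <- function(x, collection, min_coverage = 2) {
  X <- concat_blocks(x)
  assert_uv_scaled(X)
  flt <- filter_by_coverage(collection, colnames(X), min_coverage)
  cl <- flt$collection
  n <- nrow(X)
  fitted <- vector("list", length(cl$ids))
  scores <- matrix(0, n, length(cl$ids),
                   dimnames = list(rownames(X), cl$ids))
  for (i in seq_along(cl$ids)) {
    mem <- cl$members[[i]]
    Z <- X[, mem, drop = FALSE]
    v1 <- fix_sign(svd(Z, nu = 0, nv = 1)$v[, 1])
    names(v1) <- mem
    scores[, i] <- Z %*% v1
    fitted[[i]] <- list(id = cl$ids[i], members = mem, v1 = v1)
  }
  names(fitted) <- cl$ids
  structure(
    list(scores = scores, pathways = fitted, method = "svd",
         min_coverage = min_coverage,
         dropped = flt$report$pathway_id[!flt$report$retained]),
    class = c("sspa_svd", "sspa_scores"))
}

#' Fit RBF kernel-PCA pathway activity scores
#'
#' For each retained pathway an RBF kernel over samples is built from the
#' pathway's molecule columns, double-centred, and eigendecomposed; the
#' activity scores are the first eigenvector scaled by the square root of
#' its eigenvalue (the usual kernel-PCA principal component 1 scores), with
#' the same deterministic sign convention as \code{\link{sspa_svd}}.
#'
#' @inheritParams sspa_svd
#' @param gamma RBF bandwidth; \code{"auto"} uses \code{1/L_i} per pathway
#'   (its mapped molecule count).
#' @return An object of class \code{c("sspa_kpca", "sspa_scores")}; the
#'   fitted state keeps the training sub-matrix, gamma, kernel centring
#'   statistics and the leading eigenpair so new samples can be projected.
#' @export
sspa_kpca <- function(x, collection, gamma = "auto", min_coverage = 2) {
  X <- concat_blocks(x)
  assert_uv_scaled(X)
  if (!identical(gamma, "auto") && (!is.numeric(gamma) || gamma <= 0)) {
    stop("gamma must be a positive number or \"auto\"")
  }
  flt <- filter_by_coverage(collection, colnames(X), min_coverage)
  cl <- flt$collection
  n <- nrow(X)
  fitted <- vector("list", length(cl$ids))
  scores <- matrix(0, n, length(cl$ids),
                   dimnames = list(rownames(X), cl$ids))
  ones <- matrix(1 / n, n, n)
  for (i in seq_along(cl$ids)) {
    mem <- cl$members[[i]]
    Z <- X[, mem, drop = FALSE]
    g <- if (identical(gamma, "auto")) 1 / length(mem) else gamma
    K <- rbf_kernel(Z, Z, g)
    Kc <- K - ones %*% K - K %*% ones + ones %*% K %*% ones
    eig <- eigen(Kc, symmetric = TRUE)
    lambda <- max(eig$values[1], 0)
    alpha <- fix_sign(eig$vectors[, 1])
    scores[, i] <- alpha * sqrt(lambda)
    fitted[[i]] <- list(id = cl$ids[i], members = mem, Z = Z, gamma = g,
                        k_colmeans = colMeans(K), k_grandmean = mean(K),
                        alpha = alpha, lambda = lambda)
  }
  names(fitted) <- cl$ids
  structure(
    list(scores = scores, pathways = fitted, method = "kpca",
         min_coverage = min_coverage,
         dropped = flt$report$pathway_id[!flt$report$retained]),
    class = c("sspa_kpca", "sspa_scores"))
}

#' @export
print.sspa_scores <- function(x, ...) {
  cat("ssPA scores (", x$method, "): ", nrow(x$scores), " samples x ",
      ncol(x$scores), " pathways (", length(x$dropped),
      " below coverage ", x$min_coverage, ")\n", sep = "")
  invisible(x)
}

# Check the new data carries every molecule the fit used, and order columns.
align_new <- function(X, members) {
  missing <- setdiff(members, colnames(X))
  if (length(missing)) {
    stop("new data lacks molecule column(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  X[, members, drop = FALSE]
}

#' Project new samples onto fitted SVD pathway scores
#'
#' New samples must already be scaled with the training scaler
#' (\code{\link{apply_uv_scale}}); scores are \eqn{Z_{new} v_1} using the
#' stored loading vector, so transforming the training data reproduces the
#' training scores exactly.
#'
#' @param object a fitted \code{sspa_svd} object.
#' @param newdata matrix/\code{omics_block} or list of blocks covering the
#'   training molecule universe.
#' @param ... unused.
#' @return Score matrix for the new samples (samples x pathways).
#' @export
predict.sspa_svd <- function(object, newdata, ...) {
  X <- concat_blocks(newdata)
  out <- matrix(0, nrow(X), length(object$pathways),
                dimnames = list(rownames(X), names(object$pathways)))
  for (i in seq_along(object$pathways)) {
    p <- object$pathways[[i]]
    out[, i] <- align_new(X, p$members) %*% p$v1
  }
  out
}

#' Project new samples onto fitted kernel-PCA pathway scores
#'
#' The kernel between new and training samples is centred with the training
#' statistics and projected on the stored eigenvector; training-data
#' self-transform reproduces the training scores.
#'
#' @param object a fitted \code{sspa_kpca} object.
#' @inheritParams predict.sspa_svd
#' @return Score matrix for the new samples.
#' @export
predict.sspa_kpca <- function(object, newdata, ...) {
  X <- concat_blocks(newdata)
  out <- matrix(0, nrow(X), length(object$pathways),
                dimnames = list(rownames(X), names(object$pathways)))
  for (i in seq_along(object$pathways)) {
    p <- object$pathways[[i]]
    Zn <- align_new(X, p$members)
    Kn <- rbf_kernel(Zn, p$Z, p$gamma)
    Kc <- sweep(Kn - rowMeans(Kn), 2, p$k_colmeans) + p$k_grandmean
    proj <- if (p$lambda > 0) Kc %*% p$alpha / sqrt(p$lambda) else
      rep(0, nrow(Zn))
    out[, i] <- proj
  }
  out
}

#' Molecule loadings of a fitted SVD pathway score
#'
#' Returns the first-principal-component loading of each member molecule,
#' interpretable as the contribution of the molecule to the pathway activity
#' score (same sign convention as the scores).
#'
#' @param object a fitted \code{sspa_svd} object.
#' @param pathway_id pathway identifier.
#' @return Named numeric vector of loadings.
#' @export
molecule_loadings <- function(object, pathway_id) {
  if (!inherits(object, "sspa_svd")) {
    stop("molecule loadings are only defined for the SVD (PLAGE) method")
  }
  p <- object$pathways[[pathway_id]]
  if (is.null(p)) stop("pathway not in fitted score matrix: ", pathway_id)
  p$v1
}

#' Bootstrap stability of molecule loadings
#'
#' Resamples samples with replacement, refits the pathway's SVD
#' decomposition on the re-autoscaled resample, aligns each replicate's
#' loading vector sign to the full-data loadings (maximal dot product), and
#' reports the per-molecule mean and standard deviation across replicates.
#' Replicates where a member molecule has zero variance are skipped with a
#' warning.
#'
#' @param x scaled matrix/\code{omics_block} or list of blocks (as for
#'   \code{\link{sspa_svd}}).
#' @param collection a \code{pathway_collection}.
#' @param pathway_id pathway identifier.
#' @param n_boot number of bootstrap replicates (>= 2; 200 is typical).
#' @param seed RNG seed for reproducibility.
#' @param min_coverage minimum mapped molecules.
#' @return Data frame with \code{molecule}, \code{mean}, \code{sd},
#'   \code{loading} (full-data value); attribute \code{n_skipped} counts
#'   degenerate replicates.
#' @export
bootstrap_molecule_loadings <- function(x, collection, pathway_id,
                                        n_boot = 200, seed = NULL,
                                        min_coverage = 2) {
  if (n_boot < 2) stop("n_boot must be >= 2")
  X <- concat_blocks(x)
  fit <- sspa_svd(X, collection, min_coverage)
  ref <- molecule_loadings(fit, pathway_id)
  mem <- names(ref)
  reps <- with_seed(seed, {
    lapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(X), replace = TRUE)
      Z <- X[idx, mem, drop = FALSE]
      sds <- sqrt(col_vars(Z))
      if (any(sds <= .Machine$double.eps * 10)) return(NULL)
      Z <- scale(Z)
      v <- svd(Z, nu = 0, nv = 1)$v[, 1]
      if (sum(v * ref) < 0) v <- -v
      v
    })
  })
  ok <- !vapply(reps, is.null, logical(1))
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    warning(n_skipped, " degenerate bootstrap replicate(s) skipped")
  }
  if (!any(ok)) stop("all bootstrap replicates degenerate")
  mat <- do.call(rbind, reps[ok])
  out <- data.frame(
    molecule = mem,
    mean = colMeans(mat),
    sd = apply(mat, 2, stats::sd),
    loading = unname(ref),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}
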