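# Bring raw omics blocks to the modelling scale: log2 transform,
# unit-variance scaling (with train-fitted application to held-out samples),
# iterative low-rank imputation, low-variance filtering.

#' Construct an omics block
#'
#' An omics block is a samples-by-molecules abundance matrix for one omics
#' view (e.g. metabolomics), with unique sample ids as row names, unique
#' molecule identifiers as column names, a view label, and a record of the
#' scale the values are on (\code{"raw"}, \code{"log2"} or
#' \code{"uv_scaled"}).
#'
#' @param values numeric matrix, samples in rows and molecules in columns.
#' @param omics_label free-text view label (e.g. \code{"proteomics"}).
#' @param scale_state one of \code{"raw"}, \code{"log2"}, \code{"uv_scaled"}.
#' @return A numeric matrix of class \code{omics_block} with
#'   \code{omics_label} and \code{scale_state} attributes.
#' @export
omics_block <- function(values, omics_label = "omics", scale_state = "raw") {
  values <- as.matrix(values)
  scale_state <- match.arg(scale_state, c("raw", "log2", "uv_scaled"))
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("M", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) stop("sample ids must be unique")
  if (anyDuplicated(colnames(values))) {
    stop("molecule ids must be unique within a block")
  }
  structure(values, omics_label = omics_label, scale_state = scale_state,
            class = c("omics_block", "matrix", "array"))
}

block_state <- function(x) attr(x, "scale_state") %||% "raw"
block_label <- function(x) attr(x, "omics_label") %||% "omics"

# Rebuild an omics_block around transformed values, keeping metadata.
reblock <- function(values, template, scale_state = block_state(template)) {
  omics_block(values, omics_label = block_label(template),
              scale_state = scale_state)
}

#' @export
print.omics_block <- function(x, ...) {
  cat("Omics block '", block_label(x), "': ", nrow(x), " samples x ",
      ncol(x), " molecules (", block_state(x), ")\n", sep = "")
  invisible(x)
}

#' Log2-transform an abundance block
#'
#' @param block matrix or \code{omics_block} of positive abundances.
#' @param pseudo_count optional positive constant added before taking logs
#'   (for blocks containing zeros).
#' @return The transformed block with \code{scale_state = "log2"}.
#' @export
log2_transform <- function(block, pseudo_count = NULL) {
  x <- as.matrix(block)
  if (!is.null(pseudo_count)) x <- x + pseudo_count
  bad <- which(x <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-positive value at sample '%s', molecule '%s'; supply pseudo_count",
      rownames(x)[bad[1, 1]] %||% bad[1, 1],
      colnames(x)[bad[1, 2]] %||% bad[1, 2]))
  }
  reblock(log2(x), block, scale_state = "log2")
}

#' Unit-variance scale a block (autoscaling)
#'
#' Sets every column to mean 0 and standard deviation 1 (denominator n-1).
#' The fitted centres and scales are kept on the result so held-out samples
#' can be brought to the training scale without leakage via
#' \code{\link{apply_uv_scale}}.
#'
#' @param block matrix or \code{omics_block}.
#' @return Scaled block (\code{scale_state = "uv_scaled"}) with attributes
#'   \code{center} and \code{scale} (named per molecule).
#' @export
uv_scale <- function(block) {
  x <- as.matrix(block)
  mu <- colMeans(x)
  sd <- sqrt(col_vars(x))
  zero <- which(sd <= .Machine$double.eps * 10)
  if (length(zero)) {
    stop("zero-variance column(s): ",
         paste(utils::head(colnames(x)[zero], 5), collapse = ", "),
         if (length(zero) > 5) ", ..." else "",
         " (filter before scaling)")
  }
  out <- reblock(sweep(sweep(x, 2, mu), 2, sd, "/"), block,
                 scale_state = "uv_scaled")
  attr(out, "center") <- mu
  attr(out, "scale") <- sd
  out
}

#' Apply a fitted unit-variance scaling to new samples
#'
#' @param block new samples on the same (log2) scale and molecule universe
#'   as the training block.
#' @param fitted a block returned by \code{\link{uv_scale}}, or a list with
#'   \code{center} and \code{scale} elements.
#' @return The new block scaled with the training centres and scales.
#' @export
apply_uv_scale <- function(block, fitted) {
  mu <- attr(fitted, "center") %||% fitted$center
  sd <- attr(fitted, "scale") %||% fitted$scale
  if (is.null(mu) || is.null(sd)) stop("fitted must carry center and scale")
  x <- as.matrix(block)
  missing <- setdiff(names(mu), colnames(x))
  if (length(missing)) {
    stop("new block lacks molecule column(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  x <- x[, names(mu), drop = FALSE]
  reblock(sweep(sweep(x, 2, mu), 2, sd, "/"), block,
          scale_state = "uv_scaled")
}

#' Impute missing entries by iterative low-rank reconstruction
#'
#' Missing cells (NA) are initialised at column means, then the matrix is
#' alternately approximated by its truncated rank-\code{rank} singular value
#' decomposition and the missing cells refilled from the reconstruction,
#' until the largest relative change in imputed values drops below
#' \code{tol}. Observed entries are never altered.
#'
#' @param block matrix or \code{omics_block} with NA marking missing cells.
#' @param rank target rank (capped at \code{min(dim) - 1}).
#' @param max_iter iteration cap.
#' @param tol relative-change convergence tolerance.
#' @return The completed block (same scale state as the input).
#' @export
lowrank_impute <- function(block, rank = 10, max_iter = 100, tol = 1e-4) {
  x <- as.matrix(block)
  miss <- is.na(x)
  if (!any(miss)) return(reblock(x, block))
  if (any(colSums(!miss) == 0L)) {
    stop("column(s) entirely missing: ",
         paste(colnames(x)[colSums(!miss) == 0L], collapse = ", "))
  }
  frac <- colMeans(miss)
  if (any(frac >= 0.5)) {
    stop("column(s) with >= 50% missing values: ",
         paste(utils::head(colnames(x)[frac >= 0.5], 5), collapse = ", "))
  }
  rank <- min(rank, min(dim(x)) - 1L)
  if (rank < 1L) stop("matrix too small for low-rank imputation")
  mu <- colMeans(x, na.rm = TRUE)
  filled <- x
  filled[miss] <- mu[col(x)[miss]]
  for (it in seq_len(max_iter)) {
    s <- svd(filled, nu = rank, nv = rank)
    recon <- s$u %*% (s$d[seq_len(rank)] * t(s$v))
    new_vals <- recon[miss]
    change <- max(abs(new_vals - filled[miss])) /
      max(abs(filled[miss]), .Machine$double.eps)
    filled[miss] <- new_vals
    if (change < tol) break
  }
  reblock(filled, block)
}

#' Remove low-variance molecules
#'
#' Drops columns whose variance is strictly below the given percentile of
#' all column variances (so with all-equal variances nothing is removed).
#'
#' @param block matrix or \code{omics_block} with at least 2 samples.
#' @param percentile percentile in [0, 100); 25 reproduces the common
#'   "below 25th percentile" filter.
#' @return The block restricted to retained columns.
#' @export
filter_low_variance <- function(block, percentile = 25) {
  stopifnot(percentile >= 0, percentile < 100)
  x <- as.matrix(block)
  v <- col_vars(x)
  thr <- stats::quantile(v, percentile / 100, names = FALSE)
  reblock(x[, v >= thr, drop = FALSE], block)
}
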