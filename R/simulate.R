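# Synthetic multi-omics base data and the semi-synthetic spike-in: shuffled
# labels plus a constant log2 effect added to one target pathway's molecules
# in the new case group.

#' Configuration for the synthetic multi-omics base generator
#'
#' The generator emulates the properties the semi-synthetic benchmark relies
#' on: unit-variance log2-scale abundance blocks, within-pathway molecule
#' correlation driven by a shared latent factor per pathway
#' (\eqn{x = \sqrt{\rho} f + \sqrt{1-\rho}\,\sigma\,\epsilon}), member
#' overlap between consecutive pathways, pathway membership spanning all
#' omics blocks, and balanced binary labels assigned independently of the
#' data.
#'
#' @param n_samples number of samples (balanced two-class design).
#' @param n_pathways number of pathways.
#' @param pathway_size molecules per pathway (scalar or per-pathway vector,
#'   minimum 3).
#' @param n_blocks number of omics blocks; each pathway's own molecules are
#'   split round-robin across blocks.
#' @param overlap_frac fraction of each pathway's members borrowed from the
#'   previous pathway (membership overlap), in [0, 1).
#' @param rho within-pathway molecule correlation in [0, 1).
#' @param noise_sd standard deviation multiplier of the molecule-specific
#'   noise.
#' @param seed RNG seed for \code{\link{generate_base}}.
#' @return A list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_samples = 500, n_pathways = 40,
                             pathway_size = 20, n_blocks = 2,
                             overlap_frac = 0.1, rho = 0.5,
                             noise_sd = 1, seed = NULL) {
  sizes <- rep_len(as.integer(pathway_size), n_pathways)
  if (any(sizes < 3L)) stop("pathway sizes must be at least 3 molecules")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (overlap_frac < 0 || overlap_frac >= 1) {
    stop("overlap_frac must lie in [0, 1)")
  }
  n_borrow <- c(0L, round(overlap_frac * sizes[-1L]))
  n_fresh <- sizes - n_borrow
  if (any(n_fresh < 1L) || any(n_borrow[-1L] > n_fresh[-n_pathways])) {
    stop("infeasible layout: overlap larger than available molecules")
  }
  structure(
    list(n_samples = as.integer(n_samples), n_pathways = as.integer(n_pathways),
         sizes = sizes, n_blocks = as.integer(n_blocks),
         n_fresh = n_fresh, n_borrow = n_borrow,
         overlap_frac = overlap_frac, rho = rho, noise_sd = noise_sd,
         seed = seed),
    class = "synthetic_config")
}

#' Generate synthetic multi-omics base data
#'
#' Draws, per pathway, a latent factor over samples and per molecule a
#' weighted sum of its pathway's factor and independent noise, so that two
#' molecules of the same pathway have correlation \code{rho} in expectation
#' and molecules of unrelated pathways are uncorrelated. Values play the
#' role of log2-scale abundances. Labels are balanced and independent of
#' the data (the base data carry no outcome signal until a spike-in is
#' applied).
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return List with \code{blocks} (named list of \code{omics_block}s,
#'   \code{scale_state = "log2"}), \code{y} (0/1 integer vector) and
#'   \code{collection} (a GMT-compatible \code{pathway_collection}).
#' @export
generate_base <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    ids <- sprintf("P%02d", seq_len(config$n_pathways))
    members <- vector("list", config$n_pathways)
    fresh_sets <- vector("list", config$n_pathways)
    block_of <- character(0)
    mol_count <- integer(config$n_blocks)
    cols <- vector("list", config$n_blocks)
    vals <- vector("list", config$n_blocks)
    for (p in seq_len(config$n_pathways)) {
      f <- stats::rnorm(n)
      fresh <- character(config$n_fresh[p])
      for (m in seq_len(config$n_fresh[p])) {
        k <- ((m - 1L) %% config$n_blocks) + 1L
        mol_count[k] <- mol_count[k] + 1L
        id <- sprintf("B%d_M%04d", k, mol_count[k])
        fresh[m] <- id
        x <- sqrt(config$rho) * f +
          sqrt(1 - config$rho) * config$noise_sd * stats::rnorm(n)
        cols[[k]] <- c(cols[[k]], id)
        vals[[k]] <- c(vals[[k]], list(x))
      }
      fresh_sets[[p]] <- fresh
      borrowed <- if (config$n_borrow[p] > 0L) {
        utils::tail(fresh_sets[[p - 1L]], config$n_borrow[p])
      } else character(0)
      members[[p]] <- c(borrowed, fresh)
    }
    blocks <- lapply(seq_len(config$n_blocks), function(k) {
      m <- do.call(cbind, vals[[k]])
      dimnames(m) <- list(sprintf("S%04d", seq_len(n)), cols[[k]])
      omics_block(m, omics_label = paste0("omics", k), scale_state = "log2")
    })
    names(blocks) <- paste0("omics", seq_len(config$n_blocks))
    y <- rep(0:1, length.out = n)
    collection <- pathway_collection(
      ids, paste("synthetic pathway", seq_along(ids)), members,
      source_tag = "synthetic")
    list(blocks = blocks, y = y, collection = collection)
  })
}

#' Apply the semi-synthetic spike-in to one target pathway
#'
#' Implements the benchmark's two-step recipe: (1) shuffle the outcome
#' labels uniformly at random, preserving class sizes, which removes any
#' real outcome signal while keeping molecule covariances; (2) add the
#' constant effect size \code{alpha} (a log2 fold change, i.e. a
#' multiplicative change on the raw scale) to every mapped member molecule
#' of the target pathway, in every sample of the new case group, in every
#' block containing that molecule. All other cells are untouched.
#'
#' @param blocks named list of log2-scale omics blocks.
#' @param y outcome labels aligned to samples.
#' @param collection a \code{pathway_collection} containing the target.
#' @param target_pathway_id the pathway to enrich.
#' @param alpha effect size (log2 fold change, >= 0).
#' @param seed RNG seed for the label shuffle.
#' @return An object of class \code{spikein_dataset}: list with
#'   \code{blocks} (post-spike), \code{y} (shuffled labels),
#'   \code{target}, \code{alpha}, \code{case_idx} and \code{seed}.
#' @export
spike_in <- function(blocks, y, collection, target_pathway_id, alpha,
                     seed = NULL) {
  if (alpha < 0) stop("alpha must be >= 0")
  members <- pathway_members(collection, target_pathway_id)
  y_shuf <- with_seed(seed, sample(y))
  case_level <- if (is.factor(y_shuf)) levels(y_shuf)[2L] else max(y_shuf)
  case_idx <- which(y_shuf == case_level)
  blocks <- lapply(blocks, function(b) {
    hit <- intersect(members, colnames(b))
    if (length(hit)) b[case_idx, hit] <- b[case_idx, hit] + alpha
    b
  })
  structure(
    list(blocks = blocks, y = y_shuf, target = target_pathway_id,
         alpha = alpha, case_idx = case_idx, seed = seed),
    class = "spikein_dataset")
}

#' @export
print.spikein_dataset <- function(x, ...) {
  cat("Spike-in realisation: target", x$target, "at effect size",
      x$alpha, "(", length(x$case_idx), "case samples )\n")
  invisible(x)
}

#' Sweep of spike-in realisations over pathways and effect sizes
#'
#' Produces one realisation per (target pathway, effect size) pair. Each
#' target pathway gets its own label shuffle (derived reproducibly from the
#' master seed) which is shared across its effect sizes, so power curves
#' over alpha for one pathway differ only in the injected effect.
#'
#' @param blocks,y,collection as in \code{\link{spike_in}}.
#' @param alphas numeric vector of effect sizes (>= 0).
#' @param pathways character vector of target pathway ids, or \code{"all"}.
#' @param seed master RNG seed.
#' @return Named list of \code{spikein_dataset}s
#'   (\code{"<pathway>_a<alpha>"}), in pathway-major order.
#' @export
realisation_sweep <- function(blocks, y, collection, alphas,
                              pathways = "all", seed = NULL) {
  if (any(alphas < 0)) stop("alphas must be >= 0")
  if (identical(pathways, "all")) pathways <- collection$ids
  seeds <- derive_seeds(seed %||% sample.int(.Machine$integer.max, 1),
                        length(pathways))
  out <- list()
  for (i in seq_along(pathways)) {
    for (a in alphas) {
      out[[paste0(pathways[i], "_a", a)]] <-
        spike_in(blocks, y, collection, pathways[i], a, seed = seeds[i])
    }
  }
  out
}
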