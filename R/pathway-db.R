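# Multi-omics pathway collections in GMT format: read, write, merge, filter.

#' Construct a pathway collection
#'
#' A pathway collection is an ordered list of pathway definitions, each with a
#' unique identifier, a free-text description, and a non-empty ordered set of
#' molecule identifiers. Identifiers are opaque strings and may mix namespaces
#' (e.g. ChEBI, UniProt, ENSEMBL), which is what makes a pathway
#' "multi-omics": its members can span several measurement platforms.
#'
#' @param ids character vector of unique, non-empty pathway identifiers.
#' @param names character vector of free-text descriptions (recycled if
#'   length 1).
#' @param members list of character vectors, one per pathway; duplicates
#'   within a pathway are removed keeping first occurrence.
#' @param source_tag free-text provenance label (e.g. database name/version).
#' @return An object of class \code{pathway_collection}.
#' @export
pathway_collection <- function(ids, names = ids, members, source_tag = "") {
  ids <- as.character(ids)
  if (length(names) == 1L) names <- rep(names, length(ids))
  stopifnot(length(ids) == length(names), length(ids) == length(members))
  if (any(!nzchar(ids))) stop("pathway ids must be non-empty strings")
  if (anyDuplicated(ids)) {
    stop("duplicate pathway id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  members <- lapply(members, function(m) {
    m <- as.character(m)
    m <- m[nzchar(m)]
    m[!duplicated(m)]
  })
  if (any(lengths(members) == 0L)) stop("every pathway needs at least one member")
  structure(
    list(ids = ids, names = as.character(names), members = members,
         source_tag = source_tag),
    class = "pathway_collection")
}

#' @export
length.pathway_collection <- function(x) length(x$ids)

#' @export
print.pathway_collection <- function(x, ...) {
  cat("Pathway collection:", length(x$ids), "pathways")
  if (nzchar(x$source_tag)) cat(" [", x$source_tag, "]", sep = "")
  cat("\n")
  sz <- lengths(x$members)
  cat("  member counts: min", min(sz), "/ median", stats::median(sz),
      "/ max", max(sz), "\n")
  invisible(x)
}

#' Extract the member identifiers of one pathway
#'
#' @param collection a \code{pathway_collection}.
#' @param pathway_id pathway identifier.
#' @return Character vector of member identifiers.
#' @export
pathway_members <- function(collection, pathway_id) {
  i <- match(pathway_id, collection$ids)
  if (is.na(i)) stop("pathway not in collection: ", pathway_id)
  collection$members[[i]]
}

#' Read a pathway collection from a GMT file
#'
#' GMT (gene matrix transposed) is the tab-separated gene-set format: one
#' pathway per line with fields \code{id<TAB>description<TAB>member1<TAB>...}.
#' Strict tab separation is assumed, comment lines are not supported, and
#' empty member fields are skipped. Duplicate members within one line are
#' removed keeping the first occurrence; duplicate pathway ids across lines
#' are an error.
#'
#' @param path path to the GMT file.
#' @param source_tag optional provenance label stored on the collection
#'   (defaults to the file name).
#' @return A \code{pathway_collection} in file order.
#' @export
read_gmt <- function(path, source_tag = basename(path)) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(pathway_collection(character(), character(), list(),
                              source_tag = source_tag))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop("malformed GMT line ", bad[1L],
         ": expected at least 3 tab-separated fields, got ",
         length(fields[[bad[1L]]]))
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  nms <- vapply(fields, `[[`, character(1), 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  pathway_collection(ids, nms, members, source_tag = source_tag)
}

# pathway_collection with zero pathways needs a list() members slot; the
# constructor handles it because lapply over an empty list is empty.

#' Write a pathway collection to a GMT file
#'
#' @param collection a \code{pathway_collection}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "pathway_collection"))
  lines <- vapply(seq_along(collection$ids), function(i) {
    paste(c(collection$ids[i], collection$names[i], collection$members[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Merge pathway collections into one multi-omics collection
#'
#' Pathways sharing an identifier across collections (e.g. the metabolite and
#' protein views of the same biological pathway) have their member sets
#' unioned, merging molecules from different omics into a single multi-omics
#' pathway. Names are taken from the first occurrence; pathways present in
#' only one collection pass through unchanged. Member order is first-seen.
#'
#' @param ... two or more \code{pathway_collection} objects, or a single list
#'   of them.
#' @return A merged \code{pathway_collection}.
#' @export
merge_collections <- function(...) {
  colls <- list(...)
  if (length(colls) == 1L && !inherits(colls[[1L]], "pathway_collection")) {
    colls <- colls[[1L]]
  }
  stopifnot(length(colls) >= 1L,
            all(vapply(colls, inherits, logical(1), "pathway_collection")))
  ids <- character()
  nms <- character()
  members <- list()
  for (cl in colls) {
    for (i in seq_along(cl$ids)) {
      j <- match(cl$ids[i], ids)
      if (is.na(j)) {
        ids <- c(ids, cl$ids[i])
        nms <- c(nms, cl$names[i])
        members[[length(ids)]] <- cl$members[[i]]
      } else {
        m <- c(members[[j]], cl$members[[i]])
        members[[j]] <- m[!duplicated(m)]
      }
    }
  }
  tags <- unique(vapply(colls, `[[`, character(1), "source_tag"))
  pathway_collection(ids, nms, members,
                     source_tag = paste(tags[nzchar(tags)], collapse = "+"))
}

#' Filter a pathway collection by coverage of a molecule universe
#'
#' Pathway coverage is the number of a pathway's annotated molecules observed
#' in the data at hand. Each pathway's members are intersected with the given
#' universe; pathways whose intersection falls below \code{min_coverage}
#' (default 2 molecules per pathway) are dropped. Retained pathways keep only
#' their mapped members, in original member order.
#'
#' @param collection a \code{pathway_collection}.
#' @param universe character vector of molecule identifiers present in the
#'   data.
#' @param min_coverage minimum number of mapped molecules (integer >= 1).
#' @return A list with \code{collection} (the filtered collection, mapped
#'   members only) and \code{report}, a data frame with one row per original
#'   pathway: \code{pathway_id}, \code{n_members}, \code{n_mapped},
#'   \code{retained}, \code{min_coverage}.
#' @export
filter_by_coverage <- function(collection, universe, min_coverage = 2) {
  stopifnot(inherits(collection, "pathway_collection"))
  if (length(universe) == 0L) stop("universe must be non-empty")
  if (min_coverage < 1) stop("min_coverage must be >= 1")
  universe <- as.character(universe)
  mapped <- lapply(collection$members, function(m) m[m %in% universe])
  n_mapped <- lengths(mapped)
  keep <- n_mapped >= min_coverage
  report <- data.frame(
    pathway_id = collection$ids,
    n_members = lengths(collection$members),
    n_mapped = n_mapped,
    retained = keep,
    min_coverage = min_coverage,
    stringsAsFactors = FALSE)
  filtered <- if (any(keep)) {
    pathway_collection(collection$ids[keep], collection$names[keep],
                       mapped[keep], source_tag = collection$source_tag)
  } else {
    pathway_collection(character(), character(), list(),
                       source_tag = collection$source_tag)
  }
  list(collection = filtered, report = report)
}

#' Coverage summary across molecule universes
#'
#' Tabulates, for each pathway, how many members map into each supplied
#' universe (e.g. the molecules measured by each omics platform) and into the
#' union of all universes, mirroring the observation that multi-omics
#' pathways have greater mean coverage than single-omics ones. Per-universe
#' mean coverage and the number of pathways meeting \code{min_coverage} are
#' also reported.
#'
#' @param collection a \code{pathway_collection}.
#' @param universes named list of character vectors of molecule identifiers.
#' @param min_coverage threshold used for the retained-pathway counts.
#' @return List with \code{per_pathway} (data frame, one row per pathway,
#'   one mapped-count column per universe plus \code{union}) and
#'   \code{summary} (data frame with \code{universe}, \code{mean_coverage},
#'   \code{n_retained}).
#' @export
coverage_summary <- function(collection, universes, min_coverage = 2) {
  stopifnot(inherits(collection, "pathway_collection"),
            is.list(universes), length(universes) >= 1L)
  if (is.null(names(universes)) || any(!nzchar(names(universes)))) {
    stop("universes must be a named list")
  }
  universes <- c(universes, list(union = unique(unlist(universes))))
  counts <- sapply(universes, function(u) {
    vapply(collection$members, function(m) sum(m %in% u), integer(1))
  })
  counts <- matrix(counts, nrow = length(collection$ids),
                   dimnames = list(NULL, names(universes)))
  per_pathway <- data.frame(pathway_id = collection$ids, counts,
                            stringsAsFactors = FALSE, check.names = FALSE)
  summary <- data.frame(
    universe = names(universes),
    mean_coverage = colMeans(counts),
    n_retained = colSums(counts >= min_coverage),
    row.names = NULL, stringsAsFactors = FALSE)
  list(per_pathway = per_pathway, summary = summary)
}
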