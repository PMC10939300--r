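#' Gene set collections
#'
#' A `gene_set_collection` holds a named list of pathways (character vectors
#' of gene identifiers), optional display names, and the universe of all
#' genes appearing in any set. Gene identifiers are opaque strings; no
#' identifier mapping is performed.
#'
#' @param sets named list of character vectors (pathway id -> genes).
#' @param names optional named character vector of display names.
#' @return An object of class `gene_set_collection` with elements `sets`,
#'   `names` and `universe`.
#' @export
gene_set_collection <- function(sets, names = NULL) {
  if (length(sets) && is.null(base::names(sets)))
    stop_fmt("pathway sets must be named")
  ids <- base::names(sets)
  if (anyDuplicated(ids))
    stop_fmt("duplicate pathway id: %s", ids[duplicated(ids)][1])
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0) && length(sets))
    stop_fmt("empty pathway set: %s", ids[lengths(sets) == 0][1])
  if (is.null(names)) {
    names <- stats::setNames(ids, ids)
  } else {
    names <- stats::setNames(as.character(names)[match(ids, base::names(names))], ids)
    names[is.na(names)] <- ids[is.na(names)]
  }
  structure(
    list(sets = sets, names = names,
         universe = sort(unique(unlist(sets, use.names = FALSE)))),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, %d genes in universe\n",
              length(x$sets), length(x$universe)))
  if (length(x$sets)) {
    sz <- lengths(x$sets)
    cat(sprintf("  set sizes: min %d, median %s, max %d\n",
                min(sz), format(stats::median(sz)), max(sz)))
  }
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read gene sets in GMT format
#'
#' Parses a tab-separated GMT file (set id, description, then genes) into a
#' [gene_set_collection()]. Sets smaller than `min_size` (after removing
#' duplicate genes within a line) are dropped, following the convention of
#' keeping only pathways with at least 15 annotated genes.
#'
#' @param path path to a GMT file.
#' @param min_size minimum number of genes a set must have to be kept.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, min_size = 15L) {
  stopifnot(min_size >= 1)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warn_fmt("empty GMT file: %s", path)
    return(gene_set_collection(list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop_fmt("malformed GMT line %d (fewer than 3 fields) in %s", bad[1], path)
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop_fmt("duplicate pathway id in GMT: %s", ids[duplicated(ids)][1])
  descr <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  keep <- lengths(sets) >= min_size
  gene_set_collection(sets[keep], stats::setNames(descr, ids)[keep])
}

#' Write gene sets in GMT format
#'
#' @param collection a [gene_set_collection()].
#' @param path output file path.
#' @export
write_gmt <- function(collection, path) {
  ids <- names(collection$sets)
  lines <- vapply(ids, function(id) {
    paste(c(id, collection$names[[id]], collection$sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Jaccard index of two gene sets
#'
#' `|A intersect B| / |A union B|`, the overlap statistic used by the
#' inter-pathway overlap test.
#'
#' @param a,b character vectors of gene ids.
#' @return A fraction in \[0, 1\].
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) stop_fmt("jaccard_index: both sets are empty")
  length(intersect(a, b)) / u
}

#' Szymkiewicz-Simpson overlap coefficient
#'
#' `|A intersect B| / min(|A|, |B|)`, used for cross-dataset consistency of
#' significant pathway sets.
#'
#' @inheritParams jaccard_index
#' @return A fraction in \[0, 1\].
#' @export
overlap_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  m <- min(length(a), length(b))
  if (m == 0) stop_fmt("overlap_coefficient: an empty set has no coefficient")
  length(intersect(a, b)) / m
}
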