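#' Assemble the Disease Pathway Network
#'
#' Accepts pathway pairs whose connectivity and overlap tests both pass the
#' FDR gate (`q_conn < alpha` and `q_olap < alpha`), weights accepted edges
#' by pathway-pathway semantic similarity, and for each designated target
#' (disease) pathway keeps only its `k` highest-weight neighbours (ties
#' broken by smaller `q_conn`, then pathway id).
#'
#' @param stats a [pairwise_stats()] table.
#' @param targets character vector of target pathway ids, each present in
#'   `stats`.
#' @param alpha FDR gate on both q-values (default 0.05).
#' @param similarity a symmetric numeric matrix with pathway ids as
#'   dimnames (e.g. from [pathway_similarity()]), or a function
#'   `f(pathway_a, pathway_b)` returning a similarity in \[0, 1\].
#' @param k maximum neighbours retained per target (default 20).
#' @return An object of class `disease_pathway_network`: list with `nodes`,
#'   `edges` (data.frame `pathway_a`, `pathway_b`, `weight`, `q_conn`,
#'   `q_olap`), `targets` and `related` (named list of ordered neighbour
#'   vectors, one per target).
#' @export
build_dpn <- function(stats, targets, alpha = 0.05, similarity = NULL,
                      k = 20L) {
  all_ids <- unique(c(stats$pathway_a, stats$pathway_b))
  missing <- setdiff(targets, all_ids)
  if (length(missing))
    stop_fmt("target pathway absent from the statistics table: %s", missing[1])

  sim_fun <- make_similarity_provider(similarity)
  acc <- stats[stats$q_conn < alpha & stats$q_olap < alpha, , drop = FALSE]
  if (nrow(acc)) {
    w <- mapply(sim_fun, acc$pathway_a, acc$pathway_b)
    edges <- data.frame(pathway_a = acc$pathway_a, pathway_b = acc$pathway_b,
                        weight = as.numeric(w),
                        q_conn = acc$q_conn, q_olap = acc$q_olap,
                        stringsAsFactors = FALSE, row.names = NULL)
  } else {
    edges <- data.frame(pathway_a = character(0), pathway_b = character(0),
                        weight = numeric(0), q_conn = numeric(0),
                        q_olap = numeric(0), stringsAsFactors = FALSE)
  }

  related <- lapply(stats::setNames(targets, targets), function(tg) {
    hit <- edges$pathway_a == tg | edges$pathway_b == tg
    if (!any(hit)) return(character(0))
    e <- edges[hit, , drop = FALSE]
    nb <- ifelse(e$pathway_a == tg, e$pathway_b, e$pathway_a)
    ord <- order(-e$weight, e$q_conn, nb)
    utils::head(nb[ord], k)
  })

  structure(
    list(nodes = sort(unique(c(targets, edges$pathway_a, edges$pathway_b))),
         edges = edges, targets = targets, related = related,
         alpha = alpha, k = k),
    class = "disease_pathway_network"
  )
}

make_similarity_provider <- function(similarity) {
  if (is.null(similarity)) return(function(a, b) 1)
  if (is.function(similarity)) return(similarity)
  if (is.matrix(similarity)) {
    return(function(a, b) {
      if (!a %in% rownames(similarity) || !b %in% colnames(similarity))
        stop_fmt("similarity provider missing pair (%s, %s)", a, b)
      similarity[a, b]
    })
  }
  stop_fmt("similarity must be NULL, a function or a matrix")
}

#' @export
print.disease_pathway_network <- function(x, ...) {
  cat(sprintf("disease_pathway_network: %d pathways, %d edges, %d targets (alpha=%s, k=%d)\n",
              length(x$nodes), nrow(x$edges), length(x$targets),
              format(x$alpha), x$k))
  nrel <- lengths(x$related)
  if (length(nrel))
    cat(sprintf("  related pathways per target: min %d, max %d\n",
                min(nrel), max(nrel)))
  invisible(x)
}

#' Positive pathways for a dataset
#'
#' The benchmark's true-positive set for a dataset: its target pathway plus
#' the target's related pathways in the Disease Pathway Network.
#'
#' @param target target pathway id (must be a network target).
#' @param dpn a [build_dpn()] network.
#' @return Character vector: target first, then its related pathways.
#' @export
positives_for <- function(target, dpn) {
  if (!target %in% dpn$targets)
    stop_fmt("unknown target pathway: %s", target)
  unique(c(target, dpn$related[[target]]))
}
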