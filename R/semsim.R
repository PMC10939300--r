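#' Ontology term graphs
#'
#' A `term_graph` is a directed acyclic graph of ontology terms with
#' `is_a` / `part_of` edges from child to parent, plus gene-to-term
#' annotations. It is the substrate of the Wang graph-based semantic
#' similarity used to weight pathway-pathway edges.
#'
#' @param edges data.frame with columns `child`, `parent`, `relation`
#'   (`"is_a"` or `"part_of"`).
#' @param annotations data.frame with columns `gene`, `term`.
#' @return An object of class `term_graph` with elements `terms`, `parents`
#'   (named list of data.frames `parent`, `relation`), `annotations`
#'   (named list gene -> term vector).
#' @export
term_graph <- function(edges, annotations = NULL) {
  edges <- data.frame(child = as.character(edges$child),
                      parent = as.character(edges$parent),
                      relation = as.character(edges$relation),
                      stringsAsFactors = FALSE)
  bad <- !edges$relation %in% c("is_a", "part_of")
  if (any(bad)) stop_fmt("unknown relation type: %s", edges$relation[bad][1])
  terms <- sort(unique(c(edges$child, edges$parent)))
  # cycle check by repeated leaf stripping (Kahn)
  remaining <- edges
  left <- terms
  repeat {
    roots <- setdiff(left, remaining$child)
    if (!length(roots)) break
    left <- setdiff(left, roots)
    remaining <- remaining[!remaining$parent %in% roots, , drop = FALSE]
    if (!nrow(remaining)) break
  }
  if (nrow(remaining) && length(left)) stop_fmt("term graph contains a cycle")

  parents <- split(edges[c("parent", "relation")], edges$child)
  ann <- list()
  if (!is.null(annotations) && nrow(annotations)) {
    at <- as.character(annotations$term)
    unknown <- setdiff(at, terms)
    if (length(unknown))
      stop_fmt("annotation references unknown term: %s", unknown[1])
    ann <- lapply(split(at, as.character(annotations$gene)), unique)
  }
  structure(list(terms = terms, parents = parents, annotations = ann),
            class = "term_graph")
}

#' @export
print.term_graph <- function(x, ...) {
  cat(sprintf("term_graph: %d terms, %d annotated genes\n",
              length(x$terms), length(x$annotations)))
  invisible(x)
}

#' Read a term graph from TSV files
#'
#' @param dag_path TSV with columns `child`, `parent`, `relation`.
#' @param annotation_path optional TSV with columns `gene`, `term`.
#' @return A [term_graph()].
#' @export
read_term_graph <- function(dag_path, annotation_path = NULL) {
  dag <- utils::read.table(dag_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  ann <- if (!is.null(annotation_path))
    utils::read.table(annotation_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  term_graph(dag, ann)
}

#' Write a term graph to TSV files
#'
#' @param graph a [term_graph()].
#' @param dag_path,annotation_path output file paths.
#' @export
write_term_graph <- function(graph, dag_path, annotation_path = NULL) {
  rows <- do.call(rbind, lapply(names(graph$parents), function(ch) {
    data.frame(child = ch, parent = graph$parents[[ch]]$parent,
               relation = graph$parents[[ch]]$relation,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, dag_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(annotation_path)) {
    ann <- do.call(rbind, lapply(names(graph$annotations), function(g) {
      data.frame(gene = g, term = graph$annotations[[g]],
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(dag_path)
}

#' Wang S-values of a term's ancestors
#'
#' The semantic contribution of each ancestor `a` to term `t`:
#' `S(t) = 1`, and `S(a)` is the maximum over paths of the product of edge
#' weights (`w_is_a` for is_a, `w_part_of` for part_of) along the path from
#' `t` up to `a`. Computed by relaxation until fixpoint (weights < 1 make
#' the maximum well-defined on any DAG).
#'
#' @param t term id present in `graph`.
#' @param graph a [term_graph()].
#' @param w_is_a,w_part_of semantic contribution factors (Wang defaults
#'   0.8 and 0.6).
#' @return Named numeric vector of S-values over `t` and its ancestors.
#' @export
s_values <- function(t, graph, w_is_a = 0.8, w_part_of = 0.6) {
  if (!t %in% graph$terms) stop_fmt("term not in graph: %s", t)
  w <- c(is_a = w_is_a, part_of = w_part_of)
  s <- stats::setNames(1, t)
  frontier <- t
  while (length(frontier)) {
    nxt <- character(0)
    for (ch in frontier) {
      pr <- graph$parents[[ch]]
      if (is.null(pr)) next
      cand <- s[[ch]] * w[pr$relation]
      for (i in seq_along(pr$parent)) {
        pa <- pr$parent[i]
        if (is.na(s[pa]) || cand[i] > s[[pa]]) {
          s[pa] <- cand[i]
          nxt <- c(nxt, pa)
        }
      }
    }
    frontier <- unique(nxt)
  }
  s
}

#' Wang semantic similarity of two terms
#'
#' Shared-ancestor contributions relative to total contributions:
#' `sum over shared a of (S1(a) + S2(a)) / (sum S1 + sum S2)`.
#'
#' @param t1,t2 term ids.
#' @param graph a [term_graph()].
#' @param ... passed to [s_values()].
#' @return Similarity in \[0, 1\].
#' @export
term_similarity <- function(t1, t2, graph, ...) {
  s1 <- s_values(t1, graph, ...)
  s2 <- s_values(t2, graph, ...)
  shared <- intersect(names(s1), names(s2))
  if (!length(shared)) return(0)
  (sum(s1[shared]) + sum(s2[shared])) / (sum(s1) + sum(s2))
}

# Best-match average of a similarity matrix (rows vs columns).
bma <- function(m) {
  (sum(apply(m, 1, max)) + sum(apply(m, 2, max))) / (nrow(m) + ncol(m))
}

#' Semantic similarity of two gene sets
#'
#' Gene-gene similarity is the best-match average (BMA) over the two genes'
#' annotated term pairs; set-set similarity is the BMA over annotated gene
#' pairs. Unannotated genes are skipped.
#'
#' @param genes_a,genes_b character vectors of gene ids.
#' @param graph a [term_graph()] with annotations.
#' @param ... passed to [s_values()].
#' @return Similarity in \[0, 1\].
#' @export
set_similarity <- function(genes_a, genes_b, graph, ...) {
  ga <- intersect(unique(genes_a), names(graph$annotations))
  gb <- intersect(unique(genes_b), names(graph$annotations))
  if (!length(ga) || !length(gb))
    stop_fmt("no annotated genes on one side of set_similarity")
  terms <- unique(unlist(graph$annotations[c(ga, gb)], use.names = FALSE))
  svals <- lapply(stats::setNames(terms, terms), s_values, graph = graph, ...)
  tsim <- function(u, v) {
    s1 <- svals[[u]]; s2 <- svals[[v]]
    shared <- intersect(names(s1), names(s2))
    if (!length(shared)) return(0)
    (sum(s1[shared]) + sum(s2[shared])) / (sum(s1) + sum(s2))
  }
  gene_sim <- function(g1, g2) {
    t1 <- graph$annotations[[g1]]; t2 <- graph$annotations[[g2]]
    m <- outer(seq_along(t1), seq_along(t2),
               Vectorize(function(i, j) tsim(t1[i], t2[j])))
    bma(matrix(m, length(t1), length(t2)))
  }
  m <- outer(seq_along(ga), seq_along(gb),
             Vectorize(function(i, j) gene_sim(ga[i], gb[j])))
  bma(matrix(m, length(ga), length(gb)))
}

#' Pathway-by-pathway semantic similarity matrix
#'
#' Computes [set_similarity()] between the gene sets of every pathway pair,
#' for use as the edge-weight provider of [build_dpn()]. By default a
#' pathway maps to the terms annotated to its genes; an explicit
#' pathway-to-terms table overrides that mapping, in which case pathway
#' similarity is the best-match average over the listed term pairs.
#' Pathways with no annotated genes (or no listed terms) get `NA`
#' similarity with a warning.
#'
#' @param collection a [gene_set_collection()].
#' @param graph a [term_graph()] with annotations.
#' @param pathway_terms optional named list: pathway id -> character vector
#'   of term ids, overriding the gene-annotation mapping.
#' @param ... passed to [s_values()].
#' @return Symmetric numeric matrix with pathway ids as dimnames.
#' @export
pathway_similarity <- function(collection, graph, pathway_terms = NULL, ...) {
  ids <- names(collection$sets)
  if (is.null(pathway_terms)) {
    annotated <- vapply(collection$sets, function(g)
      any(g %in% names(graph$annotations)), logical(1))
    pair_sim <- function(i, j)
      set_similarity(collection$sets[[ids[i]]], collection$sets[[ids[j]]],
                     graph, ...)
  } else {
    annotated <- vapply(ids, function(id)
      length(pathway_terms[[id]]) > 0, logical(1))
    pair_sim <- function(i, j) {
      t1 <- pathway_terms[[ids[i]]]; t2 <- pathway_terms[[ids[j]]]
      m <- outer(t1, t2, Vectorize(function(u, v)
        term_similarity(u, v, graph, ...)))
      bma(matrix(m, length(t1), length(t2)))
    }
  }
  if (any(!annotated))
    warn_fmt("%d pathway(s) have no annotated genes; similarity set to NA",
             sum(!annotated))
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 1
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    if (annotated[i] && annotated[j])
      m[i, j] <- m[j, i] <- pair_sim(i, j)
  }
  m
}
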