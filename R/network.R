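#' Functional association networks
#'
#' A `functional_network` is an undirected, weighted gene graph: each
#' unordered gene pair is stored once, self-loops are forbidden, and a degree
#' index (link counts per gene) is kept consistent with the edge set.
#'
#' @param edges a data.frame with columns `gene1`, `gene2` and optionally
#'   `score` (confidence weight; defaults to 1).
#' @return An object of class `functional_network` with elements `nodes`
#'   (sorted character vector), `edges` (data.frame `gene1 < gene2`, `score`)
#'   and `degree` (named integer vector).
#' @export
functional_network <- function(edges) {
  if (!all(c("gene1", "gene2") %in% names(edges)))
    stop_fmt("edges must have columns gene1, gene2")
  g1 <- as.character(edges$gene1)
  g2 <- as.character(edges$gene2)
  score <- if ("score" %in% names(edges)) as.numeric(edges$score) else rep(1, length(g1))
  if (anyNA(score)) stop_fmt("non-numeric or missing edge score")
  self <- g1 == g2
  if (any(self)) {
    warn_fmt("dropping %d self-loop edge(s)", sum(self))
    g1 <- g1[!self]; g2 <- g2[!self]; score <- score[!self]
  }
  lo <- pmin(g1, g2); hi <- pmax(g1, g2)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    lo <- lo[!dup]; hi <- hi[!dup]; score <- score[!dup]
  }
  nodes <- sort(unique(c(lo, hi)))
  deg <- table(factor(c(lo, hi), levels = nodes))
  structure(
    list(nodes = nodes,
         edges = data.frame(gene1 = lo, gene2 = hi, score = score,
                            stringsAsFactors = FALSE),
         degree = stats::setNames(as.integer(deg), nodes)),
    class = "functional_network"
  )
}

#' @export
print.functional_network <- function(x, ...) {
  cat(sprintf("functional_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (length(x$degree))
    cat(sprintf("  degree: median %s, max %d\n",
                format(stats::median(x$degree)), max(x$degree)))
  invisible(x)
}

#' Network degree of a gene
#'
#' Genes absent from the network have degree 0.
#'
#' @param net a [functional_network()].
#' @param genes character vector of gene ids.
#' @return Named integer vector of link counts.
#' @export
network_degree <- function(net, genes = net$nodes) {
  d <- net$degree[genes]
  d[is.na(d)] <- 0L
  stats::setNames(as.integer(d), genes)
}

#' Read a weighted edge list, keeping the top-scoring fraction
#'
#' Reads a TSV with header columns `gene1`, `gene2`, `score` and retains only
#' the `top_fraction` highest-scoring links (as functional networks are
#' commonly thresholded to their most confident links). The filter is a
#' threshold on score, so ties at the cutoff are all retained. Degrees are
#' recomputed on the filtered graph.
#'
#' @param path path to the TSV edge list.
#' @param top_fraction fraction of highest-scoring edges to keep, in (0, 1].
#' @return A [functional_network()].
#' @export
read_edge_list <- function(path, top_fraction = 0.2) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "character"),
                          col.names = c("gene1", "gene2", "score"))
  score <- suppressWarnings(as.numeric(df$score))
  if (anyNA(score))
    stop_fmt("non-numeric score at line %d of %s", which(is.na(score))[1] + 1L, path)
  df$score <- score
  net <- functional_network(df)               # dedup + self-loop handling first
  m <- nrow(net$edges)
  if (m && top_fraction < 1) {
    keep_n <- ceiling(top_fraction * m)
    cutoff <- sort(net$edges$score, decreasing = TRUE)[keep_n]
    net <- functional_network(net$edges[net$edges$score >= cutoff, , drop = FALSE])
  }
  net
}

#' Write a network as a TSV edge list
#'
#' @param net a [functional_network()].
#' @param path output file path.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Integer-indexed view of a network restricted to a gene universe, for fast
# repeated set statistics. Genes outside `universe` that appear in the
# network are still indexed (they matter as shared neighbours).
net_index <- function(net, universe = NULL) {
  ids <- sort(unique(c(net$nodes, universe)))
  n <- length(ids)
  e1 <- match(net$edges$gene1, ids)
  e2 <- match(net$edges$gene2, ids)
  adj <- vector("list", n)
  if (length(e1)) {
    ord <- order(c(e1, e2))
    tgt <- c(e2, e1)[ord]
    src <- c(e1, e2)[ord]
    split_adj <- split(tgt, src)
    adj[as.integer(names(split_adj))] <- split_adj
  }
  list(ids = ids, n = n, e1 = e1, e2 = e2, adj = adj,
       degree = lengths(adj))
}

# Set statistics on an index: a, b are integer id vectors.
dl_idx <- function(idx, a, b) {
  ina <- inb <- logical(idx$n)
  ina[a] <- TRUE; inb[b] <- TRUE
  sum((ina[idx$e1] & inb[idx$e2]) | (inb[idx$e1] & ina[idx$e2]))
}

sn_idx <- function(idx, a, b) {
  inab <- logical(idx$n)
  inab[a] <- TRUE; inab[b] <- TRUE
  na <- unique(unlist(idx$adj[a], use.names = FALSE))
  nb <- unique(unlist(idx$adj[b], use.names = FALSE))
  cand <- intersect(na, nb)
  sum(!inab[cand])
}

#' Direct links between two gene sets
#'
#' Counts network edges with one endpoint in `a` and the other in `b`. An
#' edge between two genes lying in both sets counts once. Genes absent from
#' the network contribute nothing.
#'
#' @param a,b character vectors of gene ids.
#' @param net a [functional_network()].
#' @return Non-negative integer count.
#' @export
direct_links <- function(a, b, net) {
  idx <- net_index(net)
  dl_idx(idx, stats::na.omit(match(unique(a), idx$ids)),
         stats::na.omit(match(unique(b), idx$ids)))
}

#' Shared neighbours of two gene sets
#'
#' Counts genes outside `a` and `b` that are connected to at least one gene
#' in each set.
#'
#' @inheritParams direct_links
#' @return Non-negative integer count.
#' @export
shared_neighbors <- function(a, b, net) {
  idx <- net_index(net)
  sn_idx(idx, stats::na.omit(match(unique(a), idx$ids)),
         stats::na.omit(match(unique(b), idx$ids)))
}

#' Inter-pathway connectivity
#'
#' The connectivity statistic between two gene sets: direct links plus shared
#' neighbours, `IPC(A, B) = DL(A, B) + SN(A, B)`. Symmetric in its set
#' arguments.
#'
#' @inheritParams direct_links
#' @return Non-negative integer count.
#' @export
ipc <- function(a, b, net) {
  idx <- net_index(net)
  ai <- stats::na.omit(match(unique(a), idx$ids))
  bi <- stats::na.omit(match(unique(b), idx$ids))
  dl_idx(idx, ai, bi) + sn_idx(idx, ai, bi)
}

# igraph view, used by the network-property diagnostics.
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("gene1", "gene2")],
                                directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}
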