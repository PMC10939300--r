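#' Degree bins for degree-aware sampling
#'
#' Sorts a gene universe by network degree (genes absent from the network
#' have degree 0; ties broken by gene id for determinism) and cuts the
#' sorted order into contiguous bins of `bin_size` genes, the remainder in
#' the final bin. Random replacement sets drawn bin-by-bin then preserve the
#' degree profile of the set they replace.
#'
#' @param net a [functional_network()].
#' @param universe character vector of gene ids (non-empty).
#' @param bin_size number of genes per bin (default 100).
#' @return An object of class `degree_bins`: list with `genes` (degree-sorted),
#'   `degree`, `bin` (named integer bin index per gene) and `members`
#'   (list of gene vectors per bin).
#' @export
make_degree_bins <- function(net, universe, bin_size = 100L) {
  stopifnot(length(universe) > 0, bin_size >= 1)
  universe <- unique(as.character(universe))
  deg <- network_degree(net, universe)
  ord <- order(deg, universe)
  genes <- universe[ord]
  bin <- ((seq_along(genes) - 1L) %/% bin_size) + 1L
  structure(
    list(genes = genes, degree = deg[ord],
         bin = stats::setNames(bin, genes),
         members = split(genes, bin)),
    class = "degree_bins"
  )
}

#' @export
print.degree_bins <- function(x, ...) {
  cat(sprintf("degree_bins: %d genes in %d bins\n",
              length(x$genes), length(x$members)))
  invisible(x)
}

#' Draw a degree-matched random gene set
#'
#' Replaces each gene of `b` by a uniform draw from its degree bin, with no
#' duplicates in the result. Within a bin this is a simple random sample
#' without replacement (distributionally identical to redrawing on
#' collision, since bins are disjoint). If a bin holds fewer members than
#' needed it is widened to adjacent bins with a warning.
#'
#' @param b character vector of gene ids, all present in the bin universe.
#' @param bins a [make_degree_bins()] object.
#' @return Character vector of `length(b)` distinct gene ids.
#' @export
sample_matched <- function(b, bins) {
  bi <- bins$bin[b]
  if (anyNA(bi))
    stop_fmt("gene not in bin universe: %s", b[is.na(bi)][1])
  counts <- table(bi)
  out <- character(0)
  nb <- length(bins$members)
  for (k in names(counts)) {
    need <- counts[[k]]
    pool <- bins$members[[k]]
    width <- 0L
    while (length(pool) < need) {
      width <- width + 1L
      k0 <- as.integer(k)
      lo <- max(1L, k0 - width); hi <- min(nb, k0 + width)
      pool <- unique(unlist(bins$members[lo:hi], use.names = FALSE))
      if (lo == 1L && hi == nb) break
    }
    if (width > 0)
      warn_fmt("degree bin %s exhausted; widened by %d bin(s)", k, width)
    out <- c(out, pool[sample.int(length(pool), need)])
  }
  out
}

#' Degree-aware subsampling p-value
#'
#' One-sided empirical p-value for a pairwise pathway statistic: `a` is held
#' fixed while `b` is replaced by `n` degree-matched random sets
#' ([sample_matched()]); `p = (1 + #(null >= observed)) / (n + 1)`. The
#' pseudocount keeps p strictly positive so Fisher combination is always
#' defined.
#'
#' @param a,b character vectors of gene ids.
#' @param stat `"ipc"` (connectivity) or `"jaccard"` (gene overlap).
#' @param net a [functional_network()].
#' @param bins degree bins covering `b`'s genes.
#' @param n number of random samples (default 1000).
#' @return Empirical p-value on the `(n + 1)` grid.
#' @export
subsample_pvalue <- function(a, b, stat = c("ipc", "jaccard"), net, bins,
                             n = 1000L) {
  stat <- match.arg(stat)
  stopifnot(n >= 1)
  idx <- net_index(net, bins$genes)
  ai <- stats::na.omit(match(unique(a), idx$ids))
  stat_fun <- if (stat == "ipc") {
    function(bg) {
      bi <- match(bg, idx$ids)
      dl_idx(idx, ai, bi) + sn_idx(idx, ai, bi)
    }
  } else {
    function(bg) jaccard_index(a, bg)
  }
  obs <- stat_fun(unique(b))
  hits <- 0L
  for (i in seq_len(n))
    if (stat_fun(sample_matched(b, bins)) >= obs) hits <- hits + 1L
  (1 + hits) / (n + 1)
}

#' Combine two p-values by Fisher's method
#'
#' `X = -2 (log p1 + log p2)` referred to a chi-square distribution with 4
#' degrees of freedom. Used to merge the two directional subsampling tests
#' of a pathway pair.
#'
#' @param p1,p2 p-values in (0, 1].
#' @return Combined p-value.
#' @export
combine_fisher <- function(p1, p2) {
  if (any(c(p1, p2) <= 0) || any(c(p1, p2) > 1))
    stop_fmt("combine_fisher needs p-values in (0, 1]")
  stats::pchisq(-2 * (log(p1) + log(p2)), df = 4, lower.tail = FALSE)
}

#' Pairwise pathway statistics
#'
#' For every unordered pair of pathways in a collection: direct links,
#' shared neighbours, connectivity (IPC), Jaccard overlap, degree-aware
#' subsampling p-values in both directions for both statistics, Fisher
#' combination per statistic, and BH adjustment across all pairs (one
#' family per statistic by default, or a single joint family).
#'
#' Determinism: per-pair child seeds are derived from `seed` and the pathway
#' id pair, so results do not depend on iteration order.
#'
#' @param collection a [gene_set_collection()] (already size-filtered).
#' @param net a [functional_network()].
#' @param n_samples random samples per directional test (default 1000).
#' @param bin_size degree bin size (default 100).
#' @param seed master seed for the subsampling nulls.
#' @param fdr_family `"per_statistic"` (default) or `"joint"`.
#' @return A data.frame of class `pathway_pair_stats` with one row per
#'   unordered pair: `pathway_a`, `pathway_b`, `DL`, `SN`, `IPC`, `jaccard`,
#'   `p_conn_ab`, `p_conn_ba`, `p_conn`, `p_olap_ab`, `p_olap_ba`, `p_olap`,
#'   `q_conn`, `q_olap`.
#' @export
pairwise_stats <- function(collection, net, n_samples = 1000L,
                           bin_size = 100L, seed = 1L,
                           fdr_family = c("per_statistic", "joint")) {
  fdr_family <- match.arg(fdr_family)
  ids <- names(collection$sets)
  if (length(ids) < 2) stop_fmt("need at least two pathways")
  bins <- make_degree_bins(net, collection$universe, bin_size)
  idx <- net_index(net, collection$universe)
  iset <- lapply(collection$sets, function(g) match(g, idx$ids))

  # integer views for the inner sampling loop
  ibins <- lapply(bins$members, match, idx$ids)
  nbins <- length(ibins)
  pw_bins <- lapply(collection$sets, function(g) {
    tb <- table(bins$bin[g])
    list(bins = as.integer(names(tb)), counts = as.integer(tb))
  })
  sample_b <- function(binfo) {
    out <- integer(sum(binfo$counts))
    pos <- 0L
    for (j in seq_along(binfo$bins)) {
      k <- binfo$bins[j]; need <- binfo$counts[j]
      pool <- ibins[[k]]
      width <- 0L
      while (length(pool) < need) {
        width <- width + 1L
        lo <- max(1L, k - width); hi <- min(nbins, k + width)
        pool <- unique(unlist(ibins[lo:hi], use.names = FALSE))
        if (lo == 1L && hi == nbins) break
      }
      out[pos + seq_len(need)] <- pool[sample.int(length(pool), need)]
      pos <- pos + need
    }
    out
  }

  pairs <- utils::combn(ids, 2)
  # canonical orientation: results must not depend on collection order
  pairs <- rbind(pmin(pairs[1, ], pairs[2, ]), pmax(pairs[1, ], pairs[2, ]))
  np <- ncol(pairs)
  res <- data.frame(pathway_a = pairs[1, ], pathway_b = pairs[2, ],
                    DL = NA_integer_, SN = NA_integer_, IPC = NA_integer_,
                    jaccard = NA_real_,
                    p_conn_ab = NA_real_, p_conn_ba = NA_real_, p_conn = NA_real_,
                    p_olap_ab = NA_real_, p_olap_ba = NA_real_, p_olap = NA_real_,
                    stringsAsFactors = FALSE)

  n_nodes <- idx$n
  e1 <- idx$e1; e2 <- idx$e2; adj <- idx$adj
  dir_test <- function(afix, bvar, n) {
    # connectivity and overlap nulls share the degree-matched draws
    ai <- iset[[afix]]
    na_ <- length(ai)
    ina <- logical(n_nodes); ina[ai] <- TRUE
    nbr_a <- logical(n_nodes)
    nbr_a[unlist(adj[ai], use.names = FALSE)] <- TRUE
    # only edges touching A can contribute to DL
    touch <- ina[e1] | ina[e2]
    e1a <- e1[touch]; e2a <- e2[touch]
    stat <- function(bs) {
      inb <- logical(n_nodes); inb[bs] <- TRUE
      dl <- sum((ina[e1a] & inb[e2a]) | (inb[e1a] & ina[e2a]))
      nbr_b <- logical(n_nodes)
      nbr_b[unlist(adj[bs], use.names = FALSE)] <- TRUE
      sn <- sum(nbr_a & nbr_b & !(ina | inb))
      inter <- sum(ina[bs])
      c(dl + sn, inter / (na_ + length(bs) - inter))
    }
    obs <- stat(iset[[bvar]])
    binfo <- pw_bins[[bvar]]
    hits_ipc <- hits_j <- 0L
    for (i in seq_len(n)) {
      s <- stat(sample_b(binfo))
      if (s[1] >= obs[1]) hits_ipc <- hits_ipc + 1L
      if (s[2] >= obs[2]) hits_j <- hits_j + 1L
    }
    c(conn = (1 + hits_ipc) / (n + 1), olap = (1 + hits_j) / (n + 1))
  }

  for (r in seq_len(np)) {
    a <- pairs[1, r]; b <- pairs[2, r]
    ai <- iset[[a]]; bi <- iset[[b]]
    res$DL[r] <- dl_idx(idx, ai, bi)
    res$SN[r] <- sn_idx(idx, ai, bi)
    res$IPC[r] <- res$DL[r] + res$SN[r]
    res$jaccard[r] <- jaccard_index(collection$sets[[a]], collection$sets[[b]])
    set.seed(child_seed(seed, a, b))
    ab <- dir_test(a, b, n_samples)
    ba <- dir_test(b, a, n_samples)
    res$p_conn_ab[r] <- ab[["conn"]]; res$p_conn_ba[r] <- ba[["conn"]]
    res$p_olap_ab[r] <- ab[["olap"]]; res$p_olap_ba[r] <- ba[["olap"]]
    res$p_conn[r] <- combine_fisher(ab[["conn"]], ba[["conn"]])
    res$p_olap[r] <- combine_fisher(ab[["olap"]], ba[["olap"]])
  }

  if (fdr_family == "per_statistic") {
    res$q_conn <- bh_fdr(res$p_conn)
    res$q_olap <- bh_fdr(res$p_olap)
  } else {
    q <- bh_fdr(c(res$p_conn, res$p_olap))
    res$q_conn <- q[seq_len(np)]
    res$q_olap <- q[np + seq_len(np)]
  }
  class(res) <- c("pathway_pair_stats", "data.frame")
  res
}
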