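#' Network hubs
#'
#' The highest-connected fraction of network nodes (by convention the top
#' 20%): `ceiling(fraction * n)` nodes of highest degree, with boundary
#' degree ties broken by gene id so the hub set is deterministic.
#'
#' @param net a [functional_network()].
#' @param fraction fraction of nodes to flag, in (0, 1).
#' @return Character vector of hub gene ids.
#' @export
hubs <- function(net, fraction = 0.2) {
  stopifnot(fraction > 0, fraction < 1)
  n_hubs <- ceiling(fraction * length(net$nodes))
  ord <- order(-net$degree, names(net$degree))
  names(net$degree)[ord][seq_len(n_hubs)]
}

#' Pathway network properties
#'
#' Topological properties of one pathway's genes within a functional
#' network, the covariates of the false-positive-rate bias diagnostics:
#' pathway size; number of connected components of the induced subgraph;
#' mean local clustering coefficient of pathway genes in the full network
#' (genes with fewer than two neighbours contribute 0); median and max
#' network degree; fraction of intralinks (links staying inside the pathway
#' over all links incident to pathway genes); fraction of hubs (pathway
#' hubs over all network hubs); density of links (intralinks over possible
#' pathway pairs); density of hubs (pathway hubs over pathway size).
#'
#' @param pathway character vector of gene ids (non-empty).
#' @param net a [functional_network()].
#' @param hub_set character vector of hub gene ids (from [hubs()]).
#' @return A one-row data.frame with columns `size`, `n_components`,
#'   `mean_clustering`, `median_degree`, `max_degree`, `frac_intralinks`,
#'   `frac_hubs`, `density_links`, `density_hubs`.
#' @export
pathway_properties <- function(pathway, net, hub_set = hubs(net)) {
  pathway <- unique(pathway)
  stopifnot(length(pathway) > 0)
  n <- length(pathway)
  present <- intersect(pathway, net$nodes)
  deg <- network_degree(net, pathway)

  in_pw1 <- net$edges$gene1 %in% pathway
  in_pw2 <- net$edges$gene2 %in% pathway
  intra <- sum(in_pw1 & in_pw2)
  incident <- sum(in_pw1) + sum(in_pw2) - intra  # intra edges counted once

  if (length(present)) {
    g <- as_igraph(net)
    sub <- igraph::induced_subgraph(g, present)
    n_comp <- igraph::components(sub)$no + (n - length(present))
    cc <- igraph::transitivity(g, type = "localundirected", vids = present)
    cc[is.na(cc)] <- 0
    mean_cc <- (sum(cc) + 0 * (n - length(present))) / n
  } else {
    n_comp <- n
    mean_cc <- 0
  }

  n_hub_in <- length(intersect(pathway, hub_set))
  data.frame(
    size = n,
    n_components = n_comp,
    mean_clustering = mean_cc,
    median_degree = as.numeric(stats::median(deg)),
    max_degree = if (length(deg)) max(deg) else 0,
    frac_intralinks = if (incident > 0) intra / incident else 0,
    frac_hubs = if (length(hub_set)) n_hub_in / length(hub_set) else 0,
    density_links = if (n > 1) intra / (n * (n - 1) / 2) else 0,
    density_hubs = n_hub_in / n
  )
}

#' Pathway property table for a collection
#'
#' @param collection a [gene_set_collection()].
#' @param net a [functional_network()].
#' @param hub_fraction fraction of nodes counted as hubs (default 0.2).
#' @return data.frame with one row per pathway (`pathway` column first).
#' @export
collection_properties <- function(collection, net, hub_fraction = 0.2) {
  hub_set <- hubs(net, hub_fraction)
  rows <- lapply(names(collection$sets), function(id)
    cbind(data.frame(pathway = id, stringsAsFactors = FALSE),
          pathway_properties(collection$sets[[id]], net, hub_set)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Correlation of pathway properties with false positive rates
#'
#' Tie-corrected Spearman rank correlation of each pathway property with
#' the per-pathway FPR, with two-sided p-values. A high positive
#' correlation for a property (e.g. intralink fraction) indicates that the
#' method's null model is misspecified for pathways strong in that
#' property. Constant properties yield `NA` coefficients.
#'
#' @param props a [collection_properties()] table (with `pathway` column).
#' @param fpr named numeric vector, pathway -> FPR
#'   (from [per_pathway_fpr()]).
#' @return data.frame with columns `property`, `rho`, `p`.
#' @export
fpr_property_correlation <- function(props, fpr) {
  common <- intersect(props$pathway, names(fpr))
  if (length(common) < 3) stop_fmt("need at least 3 pathways")
  props <- props[match(common, props$pathway), , drop = FALSE]
  y <- fpr[common]
  prop_names <- setdiff(names(props), "pathway")
  rows <- lapply(prop_names, function(pn) {
    x <- props[[pn]]
    if (length(unique(x)) < 2 || length(unique(y)) < 2)
      return(data.frame(property = pn, rho = NA_real_, p = NA_real_))
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    data.frame(property = pn, rho = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
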