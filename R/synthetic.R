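#' Synthetic study specification
#'
#' Collects the parameters of the synthetic data generator: a heavy-tailed
#' functional network, a pathway collection with planted related pairs,
#' case-control expression with planted differential expression, and a toy
#' ontology. Defaults are desk-scale study conditions: a 1000-gene genome,
#' mean network degree 8 with a power-law-like tail, 20 pathways of 15-100
#' genes with 3 related pairs sharing half their genes, 3 samples per
#' condition and a 2-sigma case shift on 80% of target-pathway genes.
#'
#' @param seed master seed; all generator functions derive child seeds from
#'   it, so a spec fully determines its data.
#' @param n_genes genome size.
#' @param mean_degree target mean network degree.
#' @param degree_exponent power-law exponent of the degree tail (> 2).
#' @param heavy_tail draw degrees from the heavy-tailed law (TRUE) or
#'   Poisson (FALSE).
#' @param n_pathways number of pathways.
#' @param size_range inclusive pathway size range.
#' @param n_related number of planted related pathway pairs.
#' @param overlap_fraction fraction of genes a related pair shares, in
#'   \[0, 1).
#' @param crosslink_boost extra cross-links added per related pair, as a
#'   multiple of the mean pair size.
#' @param intralink_boost extra within-pathway links, as a multiple of
#'   pathway size; scalar or one value per pathway.
#' @param samples_per_condition case and control sample count.
#' @param effect_size case-minus-control mean shift for DE genes, in noise
#'   SD units.
#' @param noise_sd expression noise standard deviation (log scale).
#' @param frac_de_target fraction of target-pathway genes shifted in cases.
#' @param frac_de_background fraction of non-target genes shifted.
#' @param n_terms,n_layers,annotation_fraction toy ontology size, depth and
#'   fraction of genes annotated.
#' @return An object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(seed = 1L, n_genes = 1000L, mean_degree = 8,
                           degree_exponent = 2.5, heavy_tail = TRUE,
                           n_pathways = 20L, size_range = c(15L, 100L),
                           n_related = 3L, overlap_fraction = 0.5,
                           crosslink_boost = 2, intralink_boost = 0,
                           samples_per_condition = 3L, effect_size = 2,
                           noise_sd = 1, frac_de_target = 0.8,
                           frac_de_background = 0.02,
                           n_terms = 12L, n_layers = 3L,
                           annotation_fraction = 0.8) {
  stopifnot(n_genes > 0, mean_degree > 0, degree_exponent > 2,
            n_pathways > 0, size_range[1] >= 1,
            size_range[2] >= size_range[1], size_range[2] <= n_genes,
            n_related >= 0, overlap_fraction >= 0, overlap_fraction < 1,
            samples_per_condition >= 2, noise_sd > 0,
            frac_de_target >= 0, frac_de_target <= 1,
            frac_de_background >= 0, frac_de_background <= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("synthetic_spec: %d genes, %d pathways (%d related pairs), seed %d\n",
              x$n_genes, x$n_pathways, x$n_related, x$seed))
  invisible(x)
}

gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' Generate a synthetic functional network
#'
#' Configuration-model draw on a heavy-tailed (truncated discrete Pareto)
#' or Poisson degree sequence: stubs are paired uniformly at random and
#' self-loops / duplicate pairs are dropped, so realised degrees track the
#' drawn sequence closely. Edge scores are uniform confidence values.
#' Deterministic under the spec seed.
#'
#' @param spec a [synthetic_spec()].
#' @return A [functional_network()].
#' @export
make_network <- function(spec) {
  set.seed(child_seed(spec$seed, "network"))
  n <- spec$n_genes
  ids <- gene_ids(n)
  deg <- if (spec$heavy_tail) {
    dmin <- spec$mean_degree * (spec$degree_exponent - 2) /
      (spec$degree_exponent - 1)
    d <- round(dmin * stats::runif(n)^(-1 / (spec$degree_exponent - 1)))
    d <- pmin(pmax(d, 1L), floor(n / 4))
    # rescale to the target sum: truncation and rounding bias the tail low
    pmin(pmax(round(d * n * spec$mean_degree / sum(d)), 1L), floor(n / 4))
  } else {
    pmax(stats::rpois(n, spec$mean_degree), 1L)
  }
  if (sum(deg) %% 2 == 1) deg[1] <- deg[1] + 1L
  stubs <- sample(rep.int(seq_len(n), deg))
  half <- length(stubs) / 2
  e1 <- stubs[seq_len(half)]
  e2 <- stubs[half + seq_len(half)]
  keep <- e1 != e2
  e1 <- e1[keep]; e2 <- e2[keep]
  functional_network(data.frame(gene1 = ids[e1], gene2 = ids[e2],
                                score = stats::runif(length(e1)),
                                stringsAsFactors = FALSE))
}

#' Plant pathways with known related pairs into a network
#'
#' Samples pathway gene sets from the network's genome. Designated related
#' pairs share `overlap_fraction` of their genes and receive
#' `crosslink_boost` extra cross-links per gene (rewired into the network);
#' `intralink_boost` adds within-pathway links, e.g. to emulate
#' community-like pathways. Returns the collection, the ground-truth
#' related pairs and the augmented network.
#'
#' @param net a [functional_network()] (typically from [make_network()]).
#' @param spec a [synthetic_spec()].
#' @return List with `collection` ([gene_set_collection()]), `related`
#'   (data.frame `pathway_a`, `pathway_b`) and `net` (augmented network).
#' @export
plant_pathways <- function(net, spec) {
  set.seed(child_seed(spec$seed, "pathways"))
  ids <- gene_ids(spec$n_genes)
  pw_ids <- sprintf("P%02d", seq_len(spec$n_pathways))
  sizes <- sample(seq(spec$size_range[1], spec$size_range[2]),
                  spec$n_pathways, replace = TRUE)
  sets <- lapply(seq_len(spec$n_pathways),
                 function(i) sample(ids, sizes[i]))
  names(sets) <- pw_ids

  if (2 * spec$n_related > spec$n_pathways)
    stop_fmt("need at least 2 pathways per related pair")
  truth <- data.frame(pathway_a = character(0), pathway_b = character(0),
                      stringsAsFactors = FALSE)
  extra <- list()
  for (r in seq_len(spec$n_related)) {
    a <- pw_ids[2 * r - 1]; b <- pw_ids[2 * r]
    n_share <- round(spec$overlap_fraction * min(sizes[2 * r - 1], sizes[2 * r]))
    if (n_share > min(sizes[2 * r - 1], sizes[2 * r]))
      stop_fmt("overlap demand exceeds pathway size for pair %s-%s", a, b)
    shared <- sample(sets[[a]], n_share)
    sets[[b]] <- c(shared, sample(setdiff(ids, c(sets[[a]], sets[[b]])),
                                  sizes[2 * r] - n_share))
    only_a <- setdiff(sets[[a]], sets[[b]])
    only_b <- setdiff(sets[[b]], sets[[a]])
    n_cross <- round(spec$crosslink_boost *
                       mean(c(sizes[2 * r - 1], sizes[2 * r])))
    if (length(only_a) && length(only_b) && n_cross > 0)
      extra[[length(extra) + 1L]] <- data.frame(
        gene1 = sample(only_a, n_cross, replace = TRUE),
        gene2 = sample(only_b, n_cross, replace = TRUE),
        score = 1, stringsAsFactors = FALSE)
    truth <- rbind(truth, data.frame(pathway_a = a, pathway_b = b,
                                     stringsAsFactors = FALSE))
  }

  boost <- rep_len(spec$intralink_boost, spec$n_pathways)
  for (i in seq_len(spec$n_pathways)) {
    if (boost[i] <= 0) next
    g <- sets[[pw_ids[i]]]
    n_add <- round(boost[i] * length(g))
    extra[[length(extra) + 1L]] <- data.frame(
      gene1 = sample(g, n_add, replace = TRUE),
      gene2 = sample(g, n_add, replace = TRUE),
      score = 1, stringsAsFactors = FALSE)
  }

  if (length(extra)) {
    aug <- rbind(net$edges, do.call(rbind, extra))
    net <- suppressWarnings(functional_network(aug))
  }
  list(collection = gene_set_collection(sets), related = truth, net = net)
}

#' Generate a synthetic case-control expression dataset
#'
#' Gaussian noise on the log scale for all genes; in case samples, a
#' `frac_de_target` fraction of the target pathway's genes and a
#' `frac_de_background` fraction of the remaining genome are shifted by
#' `effect_size`. Deterministic under the spec seed and dataset id.
#'
#' @param spec a [synthetic_spec()].
#' @param target target pathway id (must be in `collection`), or `NA` for
#'   a signal-free dataset.
#' @param collection a [gene_set_collection()].
#' @param id dataset id (default derived from the target).
#' @param platform `"microarray"` or `"rnaseq"`.
#' @return An [expression_dataset()].
#' @export
make_expression <- function(spec, target, collection,
                            id = paste0("ds_", target),
                            platform = "microarray") {
  set.seed(child_seed(spec$seed, "expression", id))
  ids <- gene_ids(spec$n_genes)
  ns <- spec$samples_per_condition
  samples <- c(sprintf("case_%d", seq_len(ns)),
               sprintf("ctrl_%d", seq_len(ns)))
  condition <- stats::setNames(rep(c("case", "control"), each = ns), samples)
  values <- matrix(stats::rnorm(spec$n_genes * 2 * ns, sd = spec$noise_sd),
                   spec$n_genes, 2 * ns, dimnames = list(ids, samples))
  de_genes <- character(0)
  if (!is.na(target)) {
    if (!target %in% names(collection$sets))
      stop_fmt("target pathway not in collection: %s", target)
    tg <- intersect(collection$sets[[target]], ids)
    de_genes <- sample(tg, round(spec$frac_de_target * length(tg)))
  }
  bg <- setdiff(ids, if (is.na(target)) character(0) else collection$sets[[target]])
  de_genes <- c(de_genes, sample(bg, round(spec$frac_de_background * length(bg))))
  if (length(de_genes))
    values[de_genes, seq_len(ns)] <-
      values[de_genes, seq_len(ns)] + spec$effect_size
  expression_dataset(values, condition, platform = platform,
                     target_pathway = if (is.na(target)) NA_character_ else target,
                     id = id)
}

#' Generate a toy ontology term graph
#'
#' A layered random DAG: terms are arranged in `n_layers` layers under a
#' single root, every non-root term has one or two parents in the layer
#' above (relations drawn as is_a or part_of), and a random fraction of
#' genes is annotated with one to three terms. Acyclic by construction.
#'
#' @param spec a [synthetic_spec()].
#' @return A [term_graph()].
#' @export
make_term_graph <- function(spec) {
  set.seed(child_seed(spec$seed, "terms"))
  nt <- max(spec$n_terms, spec$n_layers + 1L)
  terms <- sprintf("T%03d", seq_len(nt))
  layer <- c(0L, sort(sample(rep_len(seq_len(spec$n_layers), nt - 1L))))
  edges <- list()
  for (i in which(layer > 0)) {
    above <- terms[layer == layer[i] - 1L]
    np <- min(length(above), sample(1:2, 1))
    pa <- sample(above, np)
    edges[[length(edges) + 1L]] <- data.frame(
      child = terms[i], parent = pa,
      relation = sample(c("is_a", "part_of"), np, replace = TRUE,
                        prob = c(0.7, 0.3)),
      stringsAsFactors = FALSE)
  }
  ids <- gene_ids(spec$n_genes)
  n_ann <- round(spec$annotation_fraction * spec$n_genes)
  ann_genes <- sample(ids, n_ann)
  leafy <- terms[layer > 0]
  ann <- do.call(rbind, lapply(ann_genes, function(g)
    data.frame(gene = g, term = sample(leafy, min(sample(1:3, 1), length(leafy))),
               stringsAsFactors = FALSE)))
  term_graph(do.call(rbind, edges), ann)
}
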