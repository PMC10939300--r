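#' Enrichment result matrices
#'
#' An `enrichment_matrix` is a pathways-by-datasets matrix of enrichment
#' p-values together with a tested-flag matrix; untested entries carry the
#' convention p = 1 so that every method can be ranked over the full
#' pathway panel.
#'
#' @param p numeric matrix of p-values (rownames = pathway ids, colnames =
#'   dataset ids), values in \[0, 1\].
#' @param tested logical matrix of the same shape (default: all TRUE).
#' @param method method label.
#' @return An object of class `enrichment_matrix`.
#' @export
enrichment_matrix <- function(p, tested = NULL, method = "unknown") {
  if (is.null(rownames(p)) || is.null(colnames(p)))
    stop_fmt("p-value matrix needs pathway rownames and dataset colnames")
  if (is.null(tested)) tested <- !is.na(p)
  p[!tested] <- 1
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_fmt("p-value outside [0, 1] in enrichment matrix")
  structure(list(p = p, tested = tested, method = method),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("enrichment_matrix [%s]: %d pathways x %d datasets (%d untested entries)\n",
              x$method, nrow(x$p), ncol(x$p), sum(!x$tested)))
  invisible(x)
}

#' Read an external method's p-value matrix
#'
#' Plug-in surface for enrichment methods run outside the package: a TSV
#' with pathway ids in the first column and one column per dataset. Missing
#' entries, and pathways present in the collection but absent from the
#' file, are assigned p = 1 and flagged untested (the missing-test
#' convention).
#'
#' @param path TSV file path.
#' @param collection a [gene_set_collection()] defining the full pathway
#'   panel.
#' @param method method label (default: file name).
#' @return An [enrichment_matrix()] covering every collection pathway.
#' @export
read_pvalue_matrix <- function(path, collection, method = basename(path)) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   row.names = 1, check.names = FALSE))
  storage.mode(m) <- "double"
  if (any(m < 0 | m > 1, na.rm = TRUE))
    stop_fmt("p-value outside [0, 1] in %s", path)
  ids <- names(collection$sets)
  full <- matrix(NA_real_, length(ids), ncol(m),
                 dimnames = list(ids, colnames(m)))
  common <- intersect(ids, rownames(m))
  full[common, ] <- m[common, ]
  tested <- !is.na(full)
  full[!tested] <- 1
  enrichment_matrix(full, tested, method = method)
}

#' Write a p-value matrix as TSV
#'
#' @param x an [enrichment_matrix()].
#' @param path output file path.
#' @export
write_pvalue_matrix <- function(x, path) {
  df <- data.frame(pathway = rownames(x$p), x$p, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fisher's exact test for DEG-pathway overlap
#'
#' One-sided (enrichment) hypergeometric tail probability of observing at
#' least the given overlap between the DEG list and a pathway within the
#' gene universe.
#'
#' @param degs character vector of differentially expressed genes (subset
#'   of `universe`).
#' @param pathway character vector of pathway genes.
#' @param universe character vector, the background gene universe.
#' @return One-sided p-value.
#' @export
fisher_enrichment <- function(degs, pathway, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop_fmt("empty universe")
  degs <- intersect(unique(degs), universe)
  pathway <- intersect(unique(pathway), universe)
  k <- length(intersect(degs, pathway))
  stats::phyper(k - 1, length(pathway), length(universe) - length(pathway),
                length(degs), lower.tail = FALSE)
}

#' EASE score: conservative Fisher variant
#'
#' Fisher's exact enrichment tail computed after subtracting 1 from the
#' observed overlap (floored at 0), which penalises gene sets supported by
#' a single overlapping gene.
#'
#' @inheritParams fisher_enrichment
#' @return One-sided p-value, always `>=` the Fisher p-value on the same
#'   table.
#' @export
ease_enrichment <- function(degs, pathway, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop_fmt("empty universe")
  degs <- intersect(unique(degs), universe)
  pathway <- intersect(unique(pathway), universe)
  k <- max(length(intersect(degs, pathway)) - 1L, 0L)
  stats::phyper(k - 1, length(pathway), length(universe) - length(pathway),
                length(degs), lower.tail = FALSE)
}

#' Network crosstalk enrichment test
#'
#' Tests the number of network links between a DEG set and a pathway
#' against a closed-form null. With `null = "hypergeometric"` the observed
#' crosstalk is referred to a hypergeometric distribution over edge
#' endpoints (population = total endpoint count `2m`, successes = total
#' degree of the pathway, draws = total degree of the DEG set). With
#' `null = "binomial"` the same expectation is used with a binomial tail, a
#' deliberately simpler null that ignores crosstalk overdispersion. When
#' the null expectation exceeds the observation the set is flagged
#' depleted.
#'
#' @param degs,pathway character vectors of gene ids.
#' @param net a [functional_network()].
#' @param null `"hypergeometric"` or `"binomial"`.
#' @return A list with `p` (upper-tail p-value), `depleted` (logical) and
#'   `tested` (FALSE when either side has zero total degree, with p = 1).
#' @export
crosstalk_enrichment <- function(degs, pathway, net,
                                 null = c("hypergeometric", "binomial")) {
  crosstalk_impl(degs, pathway, net, match.arg(null), net_index(net))
}

crosstalk_impl <- function(degs, pathway, net, null, idx) {
  two_m <- 2 * nrow(net$edges)
  kp <- sum(network_degree(net, unique(pathway)))
  kd <- sum(network_degree(net, unique(degs)))
  if (kp == 0 || kd == 0 || two_m == 0)
    return(list(p = 1, depleted = FALSE, tested = FALSE))
  obs <- dl_idx(idx, stats::na.omit(match(unique(degs), idx$ids)),
                stats::na.omit(match(unique(pathway), idx$ids)))
  expect <- kd * kp / two_m
  p <- if (null == "hypergeometric") {
    stats::phyper(obs - 1, kp, two_m - kp, kd, lower.tail = FALSE)
  } else {
    stats::pbinom(obs - 1, kd, kp / two_m, lower.tail = FALSE)
  }
  list(p = p, depleted = expect > obs, tested = TRUE)
}

#' Depletion-to-enrichment p-value convention
#'
#' Depletion is not treated as enrichment by the benchmark: for depleted
#' gene sets the significance of enrichment is taken as `1 - p`.
#'
#' @param p p-value in \[0, 1\].
#' @param depleted logical depletion flag.
#' @return `p` when not depleted, else `1 - p`.
#' @export
to_enrichment <- function(p, depleted) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(depleted, 1 - p, p)
}

#' Calibrated permutation reference method
#'
#' A reference enrichment test with exact finite-sample calibration: the
#' observed DEG-pathway overlap is compared with the overlaps of `n`
#' uniform random gene sets of the same size drawn from the universe, and
#' the empirical p-value `(1 + #(null >= obs)) / (n + 1)` is returned.
#'
#' The overlap count is discrete, so with `ties = "conservative"` the
#' `>=` rule makes the p-value super-uniform (valid but conservative)
#' whenever null draws tie the observation — markedly so for small
#' pathways and DEG sets. The default `ties = "randomized"` applies the
#' standard randomized Monte Carlo correction (an independent uniform
#' jitter breaks ties symmetrically), which renders the p-value exactly
#' uniform on the `(n + 1)` grid under random gene labels; that exactness
#' is what makes the method the yardstick of the negative benchmark.
#'
#' @inheritParams fisher_enrichment
#' @param n number of permutations (default 1000).
#' @param ties `"randomized"` (exactly calibrated, default) or
#'   `"conservative"` (`>=` tie counting).
#' @return Empirical p-value on the `(n + 1)` grid.
#' @export
permutation_reference <- function(degs, pathway, universe, n = 1000L,
                                  ties = c("randomized", "conservative")) {
  ties <- match.arg(ties)
  stopifnot(n >= 1)
  universe <- unique(universe)
  degs <- intersect(unique(degs), universe)
  pathway <- intersect(unique(pathway), universe)
  obs <- length(intersect(degs, pathway))
  if (ties == "randomized") obs <- obs + stats::runif(1)
  in_path <- universe %in% pathway
  nd <- length(degs)
  hits <- 0L
  for (i in seq_len(n)) {
    s <- sum(in_path[sample.int(length(universe), nd)])
    if (ties == "randomized") s <- s + stats::runif(1)
    if (s >= obs) hits <- hits + 1L
  }
  (1 + hits) / (n + 1)
}

#' Run a battery of enrichment methods
#'
#' Derives a DEG set per dataset ([moderated_t()] + [select_degs()];
#' microarray data is quantile normalised first) and evaluates each
#' requested built-in method on every pathway of the collection. A method
#' failing on a dataset (e.g. QC failure) leaves that column untested with
#' p = 1; the run continues.
#'
#' @param methods character vector among `"fisher"`, `"ease"`,
#'   `"crosstalk"`, `"crosstalk_binomial"`, `"permref"`.
#' @param datasets list of [expression_dataset()] objects.
#' @param collection a [gene_set_collection()].
#' @param net a [functional_network()] (needed by the crosstalk methods).
#' @param universe background for overlap tests: `"intersection"` (dataset
#'   genes that are in the collection universe; default), `"collection"`,
#'   or `"network"`.
#' @param n_perm permutations for `"permref"` (default 1000).
#' @param seed master seed for the permutation reference.
#' @param degs optional named list of precomputed DEG gene vectors keyed by
#'   dataset id, bypassing differential expression.
#' @return Named list of [enrichment_matrix()] objects, one per method.
#' @export
run_battery <- function(methods, datasets, collection, net = NULL,
                        universe = c("intersection", "collection", "network"),
                        n_perm = 1000L, seed = 1L, degs = NULL) {
  universe <- match.arg(universe)
  known <- c("fisher", "ease", "crosstalk", "crosstalk_binomial", "permref")
  bad <- setdiff(methods, known)
  if (length(bad)) stop_fmt("unknown method: %s", bad[1])
  needs_net <- any(grepl("crosstalk", methods))
  if (needs_net && is.null(net))
    stop_fmt("crosstalk methods need a functional network")
  idx <- if (needs_net) net_index(net)

  ids <- names(collection$sets)
  ds_ids <- vapply(datasets, `[[`, "", "id")
  if (anyDuplicated(ds_ids)) stop_fmt("duplicate dataset ids")
  out <- lapply(methods, function(m) {
    list(p = matrix(1, length(ids), length(datasets),
                    dimnames = list(ids, ds_ids)),
         tested = matrix(FALSE, length(ids), length(datasets),
                         dimnames = list(ids, ds_ids)))
  })
  names(out) <- methods

  for (j in seq_along(datasets)) {
    ds <- datasets[[j]]
    deg_genes <- if (!is.null(degs)) degs[[ds$id]] else tryCatch({
      vals <- ds$values
      if (ds$platform == "microarray" && ncol(vals) > 1)
        vals <- quantile_normalize(vals)
      ds_n <- ds; ds_n$values <- vals
      sel <- select_degs(moderated_t(ds_n))
      if (!sel$qc_pass) NULL else sel$genes
    }, error = function(e) NULL)
    if (is.null(deg_genes)) next

    uni <- switch(universe,
                  intersection = intersect(ds$genes, collection$universe),
                  collection = collection$universe,
                  network = net$nodes)
    for (m in methods) {
      for (i in seq_along(ids)) {
        pw <- collection$sets[[ids[i]]]
        res <- switch(m,
          fisher = list(p = fisher_enrichment(deg_genes, pw, uni), tested = TRUE),
          ease = list(p = ease_enrichment(deg_genes, pw, uni), tested = TRUE),
          crosstalk = {
            ct <- crosstalk_impl(deg_genes, pw, net, "hypergeometric", idx)
            list(p = to_enrichment(ct$p, ct$depleted), tested = ct$tested)
          },
          crosstalk_binomial = {
            ct <- crosstalk_impl(deg_genes, pw, net, "binomial", idx)
            list(p = to_enrichment(ct$p, ct$depleted), tested = ct$tested)
          },
          permref = {
            set.seed(child_seed(seed, ds$id, ids[i]))
            list(p = permutation_reference(deg_genes, pw, uni, n = n_perm),
                 tested = TRUE)
          })
        out[[m]]$p[i, j] <- res$p
        out[[m]]$tested[i, j] <- res$tested
      }
    }
  }
  lapply(stats::setNames(methods, methods), function(m)
    enrichment_matrix(out[[m]]$p, out[[m]]$tested, method = m))
}
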