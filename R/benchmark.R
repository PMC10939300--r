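#' Positive-benchmark confusion counts
#'
#' Counts, over all datasets, positive pathways (target or target-related)
#' called significant (`p < alpha`, strict) as TP and the rest as FN.
#'
#' @param results an [enrichment_matrix()] on real datasets.
#' @param positives named list: dataset id -> character vector of positive
#'   pathway ids.
#' @param alpha significance cutoff (default 0.05).
#' @return Named integer vector `c(TP, FN)`.
#' @export
positive_counts <- function(results, positives, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  tp <- fn <- 0L
  for (ds in intersect(colnames(results$p), names(positives))) {
    pv <- results$p[positives[[ds]], ds]
    tp <- tp + sum(pv < alpha)
    fn <- fn + sum(pv >= alpha)
  }
  c(TP = tp, FN = fn)
}

#' Randomized-label null datasets
#'
#' The negative benchmark's data: each dataset keeps its expression values
#' and design but its gene labels are replaced by a uniform random draw
#' (without replacement) from a genome label pool, `repeats` times. Because
#' per-gene statistics are label-free, DEG selection on a relabelled
#' dataset keeps its original size while the selected labels are random.
#'
#' @param datasets list of [expression_dataset()] objects.
#' @param label_pool character vector of genome gene labels, at least as
#'   large as the biggest dataset.
#' @param repeats number of relabelled copies per dataset (default 30).
#' @return List of `repeats * length(datasets)` datasets with ids
#'   `<source>__null<r>`; each carries its source id in `$source`.
#' @export
make_null_datasets <- function(datasets, label_pool, repeats = 30L) {
  stopifnot(repeats >= 1)
  label_pool <- unique(as.character(label_pool))
  out <- vector("list", length(datasets) * repeats)
  k <- 0L
  for (ds in datasets) {
    ng <- nrow(ds$values)
    if (length(label_pool) < ng)
      stop_fmt("label pool (%d) smaller than gene count (%d) of %s",
               length(label_pool), ng, ds$id)
    for (r in seq_len(repeats)) {
      nds <- ds
      labels <- label_pool[sample.int(length(label_pool), ng)]
      rownames(nds$values) <- labels
      nds$genes <- labels
      nds$id <- sprintf("%s__null%d", ds$id, r)
      nds$source <- ds$id
      k <- k + 1L
      out[[k]] <- nds
    }
  }
  out
}

#' Negative-benchmark confusion counts
#'
#' For each null dataset the evaluation is restricted to the positive
#' pathway list of its source dataset: under random gene labels those
#' pathways are true negatives, which balances the negative count against
#' the positive benchmark. Significant restricted tests count as FP, the
#' rest as TN.
#'
#' @param null_results an [enrichment_matrix()] on null datasets.
#' @param positives named list keyed by source dataset id.
#' @param alpha significance cutoff (default 0.05).
#' @param sources named character vector mapping null dataset id -> source
#'   dataset id; by default parsed from the `__null<r>` id suffix.
#' @param mode `"restrict"` (default; literal restriction to the positives
#'   list) or `"rescale"` (full-panel FPR rescaled to the positive count).
#' @return Named numeric vector `c(TN, FP)`.
#' @export
negative_counts <- function(null_results, positives, alpha = 0.05,
                            sources = NULL,
                            mode = c("restrict", "rescale")) {
  mode <- match.arg(mode)
  cols <- colnames(null_results$p)
  if (is.null(sources))
    sources <- stats::setNames(sub("__null[0-9]+$", "", cols), cols)
  tn <- fp <- 0
  for (ds in cols) {
    src <- sources[[ds]]
    pos <- positives[[src]]
    if (is.null(pos)) stop_fmt("no positives list for source dataset %s", src)
    if (mode == "restrict") {
      pv <- null_results$p[pos, ds]
      fp <- fp + sum(pv < alpha)
      tn <- tn + sum(pv >= alpha)
    } else {
      rate <- mean(null_results$p[, ds] < alpha)
      fp <- fp + rate * length(pos)
      tn <- tn + (1 - rate) * length(pos)
    }
  }
  c(TN = tn, FP = fp)
}

#' Summary metrics from confusion counts
#'
#' `TPR = TP / (TP + FN)`, `TNR = TN / (TN + FP)` and their geometric mean
#' (G-mean), the benchmark's balanced summary.
#'
#' @param counts numeric vector with named elements TP, FN, TN, FP.
#' @return List with `TPR`, `TNR`, `gmean`.
#' @export
summarize_counts <- function(counts) {
  tp <- counts[["TP"]]; fn <- counts[["FN"]]
  tn <- counts[["TN"]]; fp <- counts[["FP"]]
  if (tp + fn <= 0 || tn + fp <= 0)
    stop_fmt("summarize_counts: empty positive or negative benchmark")
  tpr <- tp / (tp + fn)
  tnr <- tn / (tn + fp)
  list(TPR = tpr, TNR = tnr, gmean = sqrt(tpr * tnr))
}

#' Tie-averaged relative ranks of positive pathways
#'
#' Per dataset, pathways are sorted by ascending p-value with tied p-values
#' receiving the mean of their rank span; the relative rank of a positive
#' pathway is `(tie-averaged rank - 1) / N` — the fraction of panel ranks
#' more significant than it. The median over all positive pathway tests is
#' the headline ranking metric (0 = always on top).
#'
#' @param results an [enrichment_matrix()] covering the full pathway panel.
#' @param positives named list: dataset id -> positive pathway ids.
#' @param denominator `"panel"` (default, divide by N) or `"panel_minus_1"`.
#' @return List with `ranks` (data.frame `dataset`, `pathway`,
#'   `relative_rank`) and `median`.
#' @export
relative_ranks <- function(results, positives,
                           denominator = c("panel", "panel_minus_1")) {
  denominator <- match.arg(denominator)
  n <- nrow(results$p)
  rows <- list()
  for (ds in intersect(colnames(results$p), names(positives))) {
    r <- rank(results$p[, ds], ties.method = "average")
    den <- if (denominator == "panel") n else n - 1
    rel <- (r[positives[[ds]]] - 1) / den
    rows[[ds]] <- data.frame(dataset = ds, pathway = positives[[ds]],
                             relative_rank = unname(rel),
                             stringsAsFactors = FALSE)
  }
  ranks <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(ranks = ranks, median = stats::median(ranks$relative_rank))
}

#' Per-pathway false positive rate
#'
#' The fraction of null-dataset tests per pathway with `p < alpha`; the
#' basis of the bias diagnostics.
#'
#' @param null_results an [enrichment_matrix()] on null datasets.
#' @param alpha significance cutoff (default 0.05).
#' @return Named numeric vector, one FPR per pathway.
#' @export
per_pathway_fpr <- function(null_results, alpha = 0.05) {
  if (!ncol(null_results$p)) stop_fmt("no null datasets")
  rowMeans(null_results$p < alpha)
}

#' Null p-value skew profile
#'
#' Classifies a method's null p-value distribution by its extreme-bin
#' masses: `m0` = fraction in \[0, 0.1\], `m1` = fraction in \[0.9, 1\].
#' Uniform when both lie in \[0.05, 0.15\]; right-skewed (toward 0,
#' false-positive prone) when only `m0` is high; left-skewed (toward 1,
#' false-negative prone) when only `m1` is high; bimodal when both are.
#'
#' @param null_results an [enrichment_matrix()] with at least 100 null
#'   p-values.
#' @return List with `class` (one of `"uniform"`, `"right-skewed"`,
#'   `"left-skewed"`, `"bimodal"`), `m0`, `m1`.
#' @export
skew_profile <- function(null_results) {
  p <- as.vector(null_results$p)
  if (length(p) < 100) stop_fmt("skew_profile needs at least 100 null p-values")
  m0 <- mean(p <= 0.1)
  m1 <- mean(p >= 0.9)
  band <- function(m) m >= 0.05 && m <= 0.15
  cls <- if (band(m0) && band(m1)) "uniform"
  else if (m0 > 0.15 && m1 > 0.15) "bimodal"
  else if (m0 > m1) "right-skewed"
  else "left-skewed"
  list(class = cls, m0 = m0, m1 = m1)
}

#' Cross-dataset consistency of significant pathway sets
#'
#' For each disease (group of datasets) compares the significant pathway
#' sets of every dataset pair by Jaccard index and Szymkiewicz-Simpson
#' overlap coefficient, returning the per-disease medians. Pairs where a
#' coefficient is undefined (an empty set) are dropped from the median.
#'
#' @param results an [enrichment_matrix()].
#' @param disease_groups named list: disease -> dataset ids (>= 2 each;
#'   smaller groups skipped with a warning).
#' @param alpha significance cutoff (default 0.05).
#' @return data.frame with columns `disease`, `median_jaccard`,
#'   `median_overlap`, `n_pairs`.
#' @export
consistency <- function(results, disease_groups, alpha = 0.05) {
  rows <- list()
  for (dz in names(disease_groups)) {
    ds <- intersect(disease_groups[[dz]], colnames(results$p))
    if (length(ds) < 2) {
      warn_fmt("disease group '%s' has fewer than 2 datasets; skipped", dz)
      next
    }
    sig <- lapply(ds, function(d) rownames(results$p)[results$p[, d] < alpha])
    jac <- ov <- numeric(0)
    for (i in seq_along(ds)) for (j in seq_len(i - 1L)) {
      a <- sig[[i]]; b <- sig[[j]]
      if (length(a) || length(b)) jac <- c(jac, jaccard_index(a, b))
      if (length(a) && length(b)) ov <- c(ov, overlap_coefficient(a, b))
    }
    rows[[dz]] <- data.frame(
      disease = dz,
      median_jaccard = if (length(jac)) stats::median(jac) else NA_real_,
      median_overlap = if (length(ov)) stats::median(ov) else NA_real_,
      n_pairs = choose(length(ds), 2), stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Benchmark one enrichment method
#'
#' Ties the positive and negative benchmarks together for a single method:
#' builds per-dataset positives from the Disease Pathway Network, counts
#' TP/FN on real results and TN/FP on null results (restricted to each
#' source dataset's positives), and summarises with TPR, TNR, G-mean,
#' median relative rank, per-pathway FPR and the skew profile. Count
#' conservation (`TP + FN` = positive tests, `TN + FP` = balanced negative
#' tests) is asserted on every run.
#'
#' @param results,null_results [enrichment_matrix()] objects on real and
#'   null datasets.
#' @param dpn a [build_dpn()] network.
#' @param targets named character vector: dataset id -> target pathway id.
#' @param alpha significance cutoff (default 0.05).
#' @param ... passed to [negative_counts()].
#' @return An object of class `ea_benchmark`.
#' @export
benchmark_method <- function(results, null_results, dpn, targets,
                             alpha = 0.05, ...) {
  positives <- lapply(targets, positives_for, dpn = dpn)
  pos <- positive_counts(results, positives, alpha)
  neg <- negative_counts(null_results, positives, alpha, ...)

  n_pos_tests <- sum(lengths(positives[intersect(colnames(results$p),
                                                 names(positives))]))
  stopifnot(pos[["TP"]] + pos[["FN"]] == n_pos_tests)
  srcs <- sub("__null[0-9]+$", "", colnames(null_results$p))
  stopifnot(isTRUE(all.equal(neg[["TN"]] + neg[["FP"]],
                             sum(lengths(positives[srcs])))))

  metrics <- summarize_counts(c(pos, neg))
  rr <- relative_ranks(results, positives)
  structure(
    list(method = results$method,
         counts = c(pos, neg), metrics = metrics,
         median_relative_rank = rr$median, relative_ranks = rr$ranks,
         fpr = per_pathway_fpr(null_results, alpha),
         skew = if (length(null_results$p) >= 100)
           skew_profile(null_results),
         alpha = alpha),
    class = "ea_benchmark"
  )
}

#' @export
print.ea_benchmark <- function(x, ...) {
  cat(sprintf("ea_benchmark [%s] at alpha = %s\n", x$method, format(x$alpha)))
  cat(sprintf("  TP %d  FN %d  TN %s  FP %s\n",
              x$counts[["TP"]], x$counts[["FN"]],
              format(x$counts[["TN"]]), format(x$counts[["FP"]])))
  cat(sprintf("  TPR %.3f  TNR %.3f  G-mean %.3f  median relative rank %.3f\n",
              x$metrics$TPR, x$metrics$TNR, x$metrics$gmean,
              x$median_relative_rank))
  if (!is.null(x$skew))
    cat(sprintf("  null p-value profile: %s (m0 %.2f, m1 %.2f)\n",
                x$skew$class, x$skew$m0, x$skew$m1))
  invisible(x)
}
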