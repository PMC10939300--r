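#' Quantile normalisation
#'
#' Forces every column of an expression matrix onto the same distribution:
#' the per-rank mean across columns. Ties within a column receive the mean
#' of the reference distribution over their rank span, and missing values
#' are left missing (ranks computed on observed values only).
#'
#' @param values numeric matrix with at least two columns.
#' @return A matrix of the same shape.
#' @export
quantile_normalize <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 2) {
    warn_fmt("quantile_normalize: single-column matrix returned unchanged")
    return(values)
  }
  if (anyNA(values))
    stop_fmt("quantile_normalize: missing values are not supported")
  sorted <- apply(values, 2, sort)
  ref <- rowMeans(sorted)
  cref <- c(0, cumsum(ref))
  out <- values
  for (j in seq_len(ncol(values))) {
    lo <- rank(values[, j], ties.method = "min")
    hi <- rank(values[, j], ties.method = "max")
    # tie groups span ranks lo..hi; assign the mean reference value there
    out[, j] <- (cref[hi + 1] - cref[lo]) / (hi - lo + 1)
  }
  out
}

# Inverse of trigamma by Newton iteration (monotone decreasing function).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

# Method-of-moments fit of the scaled inverse chi-square prior on gene-wise
# variances, via moments of log variances: if s^2 ~ s0^2 * F(df, d0), then
# z = log(s^2) has var(z) = trigamma(df/2) + trigamma(d0/2).
fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0 & is.finite(s2)
  if (sum(ok) < 2) return(list(d0 = 0, s02 = stats::median(s2[s2 > 0])))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) * (sum(ok) - 1) / sum(ok) - trigamma(df / 2)
  if (evar <= 0) {
    # observed spread no larger than chi-square sampling noise: infinite
    # shrinkage limit, all variances pulled to the common value
    return(list(d0 = Inf, s02 = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Moderated t statistics for case vs control
#'
#' Per-gene two-sample t tests with empirical-Bayes variance shrinkage: the
#' pooled sample variance of each gene is replaced by
#' `s2_tilde = (d0 * s0^2 + d * s^2) / (d0 + d)` where the prior
#' hyperparameters `(d0, s0^2)` are estimated by a closed-form
#' method-of-moments fit on the log sample variances, and p-values come from
#' a t distribution with `d0 + d` degrees of freedom. A constant prior is
#' used for both platforms (no mean-variance trend).
#'
#' @param dataset an [expression_dataset()] with at least two samples per
#'   condition.
#' @param d0,s02 optional fixed hyperparameters overriding the fit (prior
#'   degrees of freedom and prior variance).
#' @return A data.frame with columns `gene`, `t`, `p`, `q` (BH-adjusted),
#'   ordered as the dataset's genes.
#' @export
moderated_t <- function(dataset, d0 = NULL, s02 = NULL) {
  case <- dataset$condition == "case"
  n1 <- sum(case); n2 <- sum(!case)
  if (n1 < 2 || n2 < 2)
    stop_fmt("moderated_t needs at least 2 samples per condition (got %d/%d)",
             n1, n2)
  x <- dataset$values
  m1 <- rowMeans(x[, case, drop = FALSE])
  m2 <- rowMeans(x[, !case, drop = FALSE])
  v1 <- apply(x[, case, drop = FALSE], 1, stats::var)
  v2 <- apply(x[, !case, drop = FALSE], 1, stats::var)
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df

  if (is.null(d0) || is.null(s02)) {
    prior <- fit_variance_prior(s2, df)
    d0 <- d0 %||% prior$d0
    s02 <- s02 %||% prior$s02
  }
  s2_tilde <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + df * s2) / (d0 + df)
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  delta <- m1 - m2
  t <- ifelse(se == 0, ifelse(delta == 0, 0, sign(delta) * Inf), delta / se)
  df_total <- d0 + df
  p <- 2 * stats::pt(abs(t), df = df_total, lower.tail = FALSE)
  p[se == 0 & delta == 0] <- 1
  data.frame(gene = dataset$genes, t = t, p = p, q = bh_fdr(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; input order is preserved.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_fmt("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select differentially expressed genes
#'
#' Genes at FDR `q < fdr_primary`; if fewer than `floor_n`, the threshold is
#' relaxed to `fdr_fallback`; if still fewer than `floor_n` the dataset
#' fails quality control (a typed signal, not an error). When more than
#' `cap` genes qualify, the `cap` most significant are kept (smaller p,
#' then larger `|t|`, then gene id).
#'
#' @param stats a data.frame as returned by [moderated_t()].
#' @param fdr_primary,fdr_fallback FDR cutoffs (defaults 0.1 and 0.2).
#' @param floor_n minimum acceptable DEG count (default 15).
#' @param cap maximum DEG count retained (default 500).
#' @return An object of class `deg_set`: list with `genes` (most significant
#'   first), `threshold_used`, `capped`, `qc_pass`.
#' @export
select_degs <- function(stats, fdr_primary = 0.1, fdr_fallback = 0.2,
                        floor_n = 15L, cap = 500L) {
  if (!nrow(stats)) stop_fmt("select_degs: empty statistics table")
  ord <- order(stats$p, -abs(stats$t), stats$gene)
  stats <- stats[ord, ]
  pick <- function(thr) stats$gene[stats$q < thr]
  genes <- pick(fdr_primary)
  threshold <- fdr_primary
  if (length(genes) < floor_n) {
    genes <- pick(fdr_fallback)
    threshold <- fdr_fallback
  }
  qc_pass <- length(genes) >= floor_n
  capped <- length(genes) > cap
  if (capped) genes <- genes[seq_len(cap)]
  structure(list(genes = genes, threshold_used = threshold,
                 capped = capped, qc_pass = qc_pass),
            class = "deg_set")
}

#' @export
print.deg_set <- function(x, ...) {
  cat(sprintf("deg_set: %d genes (FDR < %s%s%s)\n", length(x$genes),
              format(x$threshold_used),
              if (x$capped) ", capped" else "",
              if (!x$qc_pass) ", QC FAIL" else ""))
  invisible(x)
}

#' Dataset quality control
#'
#' A dataset passes when each condition has at least `min_samples` samples
#' and DEG selection reaches the minimum DEG count at the fallback FDR.
#'
#' @param dataset an [expression_dataset()].
#' @param stats output of [moderated_t()] on `dataset`.
#' @param min_samples minimum samples per condition (default 3).
#' @param ... passed to [select_degs()].
#' @return A list with `pass` (logical) and `reasons` (character vector,
#'   subset of `"samples"`, `"degs"`).
#' @export
dataset_qc <- function(dataset, stats, min_samples = 3L, ...) {
  reasons <- character(0)
  n_case <- sum(dataset$condition == "case")
  n_ctrl <- sum(dataset$condition == "control")
  if (min(n_case, n_ctrl) < min_samples) reasons <- c(reasons, "samples")
  degs <- select_degs(stats, ...)
  if (!degs$qc_pass) reasons <- c(reasons, "degs")
  list(pass = !length(reasons), reasons = reasons)
}
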