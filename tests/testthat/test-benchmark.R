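toy_em <- function(p, method = "toy") {
  enrichment_matrix(p, method = method)
}

test_that("positives_for returns the target plus its pruned neighbours", {
  nb <- sprintf("N%02d", 1:25)
  st <- data.frame(pathway_a = "T0", pathway_b = nb,
                   DL = 0L, SN = 0L, IPC = 0L, jaccard = 0,
                   p_conn_ab = 0.001, p_conn_ba = 0.001, p_conn = 0.001,
                   p_olap_ab = 0.001, p_olap_ba = 0.001, p_olap = 0.001,
                   q_conn = 0.001, q_olap = 0.001)
  dpn <- build_dpn(st, targets = "T0", k = 20)
  pos <- positives_for("T0", dpn)
  expect_length(pos, 21)
  expect_equal(pos[1], "T0")
  expect_false(anyDuplicated(pos) > 0)

  # isolated target
  st$q_conn <- 0.9
  dpn2 <- build_dpn(st, targets = "T0")
  expect_equal(positives_for("T0", dpn2), "T0")
  expect_error(positives_for("zz", dpn2), "unknown target")
})

test_that("positive counts threshold strictly at alpha", {
  p <- matrix(c(0.01, 0.2, 0.03, 0.5), 4, 1,
              dimnames = list(paste0("P", 1:4), "d1"))
  em <- toy_em(p)
  pos <- list(d1 = c("P1", "P2", "P3"))
  expect_equal(positive_counts(em, pos, 0.05), c(TP = 2L, FN = 1L))

  # boundary p exactly at alpha is not significant
  p["P1", 1] <- 0.05
  expect_equal(positive_counts(toy_em(p), pos, 0.05), c(TP = 1L, FN = 2L))

  p[] <- 1
  expect_equal(positive_counts(toy_em(p), pos, 0.05)[["TP"]], 0L)
})

test_that("null datasets preserve shape, design and DEG count", {
  set.seed(127)
  pool <- sprintf("g%05d", 1:500)
  ds <- toy_dataset(n_genes = 120, de_genes = sprintf("t%03d", 1:40),
                    effect = 3, id = "src")
  nulls <- make_null_datasets(list(ds), pool, repeats = 3)
  expect_length(nulls, 3)
  expect_equal(vapply(nulls, `[[`, "", "id"),
               c("src__null1", "src__null2", "src__null3"))
  expect_equal(vapply(nulls, `[[`, "", "source"), rep("src", 3))
  n0 <- nulls[[1]]
  expect_equal(unname(n0$values), unname(ds$values))
  expect_equal(n0$condition, ds$condition)
  expect_true(all(n0$genes %in% pool))
  expect_false(anyDuplicated(n0$genes) > 0)
  # label-free statistics: the DEG count carries over to random labels
  expect_equal(length(select_degs(moderated_t(n0))$genes),
               length(select_degs(moderated_t(ds))$genes))

  expect_error(make_null_datasets(list(ds), pool[1:50], 2), "label pool")
})

test_that("negative counts restrict to the source dataset's positives", {
  pws <- paste0("P", 1:30)
  p <- matrix(1, 30, 2, dimnames = list(pws, c("d1__null1", "d1__null2")))
  p["P2", 1] <- 0.01
  em <- toy_em(p)
  pos <- list(d1 = paste0("P", 1:21))
  neg <- negative_counts(em, pos, alpha = 0.05)
  expect_equal(neg, c(TN = 41, FP = 1))
  # conservation: TN + FP = repeats x sum of positive list sizes
  expect_equal(sum(neg), 2 * 21)

  # significant entries outside the positives list are ignored
  p["P29", 2] <- 0.0001
  expect_equal(negative_counts(toy_em(p), pos)[["FP"]], 1)

  # perfectly conservative method
  p[] <- 1
  expect_equal(negative_counts(toy_em(p), pos)[["FP"]], 0)

  # rescale mode uses the full-panel rate
  p[] <- 1; p[1:3, 1] <- 0.01
  neg2 <- negative_counts(toy_em(p), pos, mode = "rescale")
  expect_equal(neg2[["FP"]], (3 / 30) * 21)
})

test_that("summary metrics follow the G-mean definitions", {
  m <- summarize_counts(c(TP = 5, FN = 5, TN = 72, FP = 28))
  expect_equal(m$TPR, 0.5)
  expect_equal(m$TNR, 0.72)
  expect_equal(m$gmean, 0.6)
  expect_equal(summarize_counts(c(TP = 3, FN = 0, TN = 9, FP = 0))$gmean, 1)
  expect_equal(summarize_counts(c(TP = 0, FN = 4, TN = 9, FP = 0))$gmean, 0)
  expect_error(summarize_counts(c(TP = 0, FN = 0, TN = 1, FP = 0)), "empty")

  # with a fixed TPR + TNR budget the G-mean peaks at balance
  g <- function(a, b) sqrt(a * b)
  expect_true(all(g(0.6, 0.6) >= c(g(0.5, 0.7), g(0.4, 0.8), g(0.2, 1.0))))
})

test_that("relative ranks tie-average and normalise by panel size", {
  p <- matrix(c(0.01, 0.01, 0.5), 3, 1,
              dimnames = list(c("P1", "P2", "P3"), "d1"))
  rr <- relative_ranks(toy_em(p), list(d1 = "P2"))
  expect_equal(rr$median, (1.5 - 1) / 3)

  # unique best positive has relative rank 0
  p2 <- matrix(c(0.001, 0.1, 0.2), 3, 1,
               dimnames = list(c("P1", "P2", "P3"), "d1"))
  expect_equal(relative_ranks(toy_em(p2), list(d1 = "P1"))$median, 0)

  # full tie: every pathway sits at (N - 1) / (2N)
  p3 <- matrix(0.3, 5, 1, dimnames = list(paste0("P", 1:5), "d1"))
  rr3 <- relative_ranks(toy_em(p3), list(d1 = paste0("P", 1:5)))
  expect_true(all(rr3$ranks$relative_rank == (5 - 1) / (2 * 5)))
})

test_that("relative ranks agree with the counting oracle on random vectors", {
  set.seed(131)
  for (i in 1:1000) {
    n <- sample(3:12, 1)
    # draw from a coarse grid to force ties
    p <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    pws <- paste0("P", seq_len(n))
    m <- matrix(p, n, 1, dimnames = list(pws, "d"))
    i_pos <- sample(n, 1)
    rr <- relative_ranks(toy_em(m), stats::setNames(list(pws[i_pos]), "d"))
    expect_equal(rr$median, oracle_rel_rank(p, i_pos))
  }
})

test_that("per-pathway FPR is the fraction of significant null tests", {
  set.seed(137)
  p <- matrix(stats::runif(200), 4, 50,
              dimnames = list(paste0("P", 1:4), paste0("d__null", 1:50)))
  fpr <- per_pathway_fpr(toy_em(p), 0.05)
  expect_equal(unname(fpr), unname(rowMeans(p < 0.05)))
  p[] <- 1
  expect_equal(unname(per_pathway_fpr(toy_em(p))), rep(0, 4))
})

test_that("skew profile classifies extreme-bin masses", {
  mk <- function(v) toy_em(matrix(v, length(v), 1,
                                  dimnames = list(seq_along(v), "d")))
  set.seed(139)
  expect_equal(skew_profile(mk(stats::runif(2000)))$class, "uniform")
  expect_equal(skew_profile(mk(stats::rbeta(2000, 5, 1)))$class,
               "left-skewed")
  expect_equal(skew_profile(mk(stats::rbeta(2000, 1, 5)))$class,
               "right-skewed")
  expect_equal(skew_profile(mk(c(stats::runif(1000, 0, 0.05),
                                 stats::runif(1000, 0.95, 1))))$class,
               "bimodal")
  expect_error(skew_profile(mk(stats::runif(50))), "at least 100")
})

test_that("consistency compares significant sets within disease groups", {
  pws <- paste0("P", 1:10)
  p <- matrix(1, 10, 4, dimnames = list(pws, paste0("d", 1:4)))
  p[1:4, 1] <- 0.01          # d1: P1-P4
  p[1:4, 2] <- 0.01          # d2: identical
  p[5:8, 3] <- 0.01          # d3: disjoint from d1
  p[1:2, 4] <- 0.01          # d4: subset of d1
  em <- toy_em(p)
  out <- consistency(em, list(same = c("d1", "d2"),
                              diff = c("d1", "d3"),
                              nest = c("d1", "d4")))
  expect_equal(out$median_jaccard[out$disease == "same"], 1)
  expect_equal(out$median_overlap[out$disease == "same"], 1)
  expect_equal(out$median_jaccard[out$disease == "diff"], 0)
  expect_equal(out$median_overlap[out$disease == "diff"], 0)
  expect_equal(out$median_jaccard[out$disease == "nest"], 0.5)
  expect_equal(out$median_overlap[out$disease == "nest"], 1)

  expect_warning(consistency(em, list(solo = "d1")), "fewer than 2")
})

test_that("benchmark_method conserves counts and summarises one method", {
  set.seed(149)
  pws <- paste0("P", 1:20)
  nb <- pws[2:6]
  st <- data.frame(pathway_a = "P1", pathway_b = nb,
                   DL = 0L, SN = 0L, IPC = 0L, jaccard = 0,
                   p_conn_ab = 0.001, p_conn_ba = 0.001, p_conn = 0.001,
                   p_olap_ab = 0.001, p_olap_ba = 0.001, p_olap = 0.001,
                   q_conn = 0.001, q_olap = 0.001)
  dpn <- build_dpn(st, targets = "P1", k = 20)

  real <- matrix(stats::runif(40, 0, 0.2), 20, 2,
                 dimnames = list(pws, c("d1", "d2")))
  nulls <- matrix(stats::runif(20 * 6), 20, 6,
                  dimnames = list(pws, c(paste0("d1__null", 1:3),
                                         paste0("d2__null", 1:3))))
  bm <- benchmark_method(toy_em(real, "m"), toy_em(nulls, "m"), dpn,
                         targets = c(d1 = "P1", d2 = "P1"))
  expect_s3_class(bm, "ea_benchmark")
  expect_equal(bm$counts[["TP"]] + bm$counts[["FN"]], 2 * 6)
  expect_equal(bm$counts[["TN"]] + bm$counts[["FP"]], 6 * 6)
  expect_equal(bm$metrics$gmean, sqrt(bm$metrics$TPR * bm$metrics$TNR))
  expect_true(bm$median_relative_rank >= 0 && bm$median_relative_rank <= 1)
  expect_length(bm$fpr, 20)
})
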