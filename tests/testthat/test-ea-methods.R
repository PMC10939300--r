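test_that("Fisher enrichment equals the exact hypergeometric tail", {
  uni <- sprintf("u%02d", 1:20)
  path <- uni[1:5]
  degs <- uni[1:5]
  expect_equal(fisher_enrichment(degs, path, uni), 1 / choose(20, 5))

  # zero overlap spans the whole upper tail
  expect_equal(fisher_enrichment(uni[6:10], path, uni), 1)
  # pathway covering the universe is uninformative
  expect_equal(fisher_enrichment(degs, uni, uni), 1)
  expect_error(fisher_enrichment(degs, path, character(0)), "empty")
})

test_that("Fisher enrichment matches exhaustive enumeration on small universes", {
  set.seed(89)
  for (i in 1:100) {
    n_uni <- sample(5:25, 1)
    uni <- sprintf("u%02d", seq_len(n_uni))
    path <- sample(uni, sample(1:n_uni, 1))
    degs <- sample(uni, sample(1:n_uni, 1))
    k <- length(intersect(degs, path))
    expect_equal(fisher_enrichment(degs, path, uni),
                 oracle_hyper_tail(k, length(path), n_uni, length(degs)),
                 tolerance = 1e-10)
    expect_equal(ease_enrichment(degs, path, uni),
                 oracle_hyper_tail(max(k - 1, 0), length(path), n_uni,
                                   length(degs)),
                 tolerance = 1e-10)
  }
})

test_that("EASE is conservative relative to Fisher on every table", {
  uni <- sprintf("u%02d", 1:20)
  expect_equal(ease_enrichment(uni[1:5], uni[1:5], uni), 76 / 15504)
  expect_equal(ease_enrichment(uni[6:10], uni[1:5], uni), 1)

  set.seed(97)
  for (i in 1:10000) {
    n_uni <- sample(5:30, 1)
    uni <- sprintf("u%02d", seq_len(n_uni))
    path <- sample(uni, sample(1:n_uni, 1))
    degs <- sample(uni, sample(1:n_uni, 1))
    expect_gte(ease_enrichment(degs, path, uni),
               fisher_enrichment(degs, path, uni))
  }
})

test_that("crosstalk test detects dense wiring and flags depletion", {
  # sparse 30-node background plus a hub pattern wiring degs into pathway
  set.seed(101)
  ids <- sprintf("x%02d", 1:30)
  bg <- data.frame(gene1 = ids[seq(1, 19, 2)], gene2 = ids[seq(2, 20, 2)],
                   score = 1)
  degs <- ids[21:24]; path <- ids[25:28]
  dense <- expand.grid(gene1 = degs, gene2 = path,
                       stringsAsFactors = FALSE)
  dense$score <- 1
  net <- functional_network(rbind(bg, dense))
  ct <- crosstalk_enrichment(degs, path, net)
  expect_lt(ct$p, 0.01)
  expect_false(ct$depleted)
  expect_true(ct$tested)

  # both sides wired elsewhere but not to each other: depleted
  net2 <- functional_network(data.frame(
    gene1 = c(rep("h1", 4), rep("h2", 4)),
    gene2 = c(degs, path), score = 1))
  ct2 <- crosstalk_enrichment(degs, path, net2)
  expect_true(ct2$depleted)

  # a gene set disconnected from the network is untested with p = 1
  ct3 <- crosstalk_enrichment(c("zz1", "zz2"), path, net)
  expect_false(ct3$tested)
  expect_equal(ct3$p, 1)
})

test_that("crosstalk p-values are invariant to gene relabeling", {
  set.seed(103)
  net <- random_toy_net(20, 0.3)
  degs <- sample(net$nodes, 5); path <- sample(net$nodes, 6)
  relabel <- function(x) paste0("z", x)
  net2 <- functional_network(data.frame(gene1 = relabel(net$edges$gene1),
                                        gene2 = relabel(net$edges$gene2),
                                        score = net$edges$score))
  for (nul in c("hypergeometric", "binomial")) {
    expect_equal(crosstalk_enrichment(degs, path, net, nul)$p,
                 crosstalk_enrichment(relabel(degs), relabel(path), net2,
                                      nul)$p)
  }
})

test_that("crosstalk near its expectation sits in the central p band", {
  # regular wiring so that observed equals the null expectation closely
  set.seed(107)
  sp <- synthetic_spec(seed = 13, n_genes = 300, mean_degree = 8)
  net <- make_network(sp)
  uni <- sprintf("g%05d", 1:300)
  degs <- sample(uni, 40); path <- sample(setdiff(uni, degs), 40)
  ct <- crosstalk_enrichment(degs, path, net)
  expect_gt(ct$p, 0.02)  # random sets should not look enriched
})

test_that("depletion convention flips the p-value", {
  expect_equal(to_enrichment(0.01, TRUE), 0.99)
  expect_equal(to_enrichment(0.01, FALSE), 0.01)
  expect_equal(to_enrichment(0.5, TRUE), 0.5)
  expect_equal(to_enrichment(c(0.2, 0.3), c(TRUE, FALSE)), c(0.8, 0.3))
})

test_that("permutation reference is calibrated and hits grid extremes", {
  set.seed(109)
  uni <- sprintf("u%03d", 1:200)
  path <- sample(uni, 30)

  # extreme statistic: DEG set identical to the pathway
  expect_equal(permutation_reference(path, path, uni, n = 400), 1 / 401)
  # n = 1 gives a two-point grid
  expect_true(permutation_reference(sample(uni, 20), path, uni, n = 1)
              %in% c(0.5, 1))

  # random DEG labels: the randomized-tie-break default is exactly
  # uniform on the grid
  nu <- 400; npath <- 120; ndeg <- 60; n <- 199
  uni <- sprintf("u%04d", seq_len(nu))
  path <- sample(uni, npath)
  pv <- replicate(1000, permutation_reference(sample(uni, ndeg), path, uni,
                                              n = n))
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)

  # the conservative >= variant matches the law implied by the closed-form
  # hypergeometric overlap null (two-sample check against an oracle that
  # simulates the same estimator from rhyper draws) and is valid:
  # P(p <= alpha) never exceeds alpha by more than noise
  pc <- replicate(1000, permutation_reference(sample(uni, ndeg), path, uni,
                                              n = n, ties = "conservative"))
  po <- replicate(1000, {
    x <- stats::rhyper(n + 1, npath, nu - npath, ndeg)
    (1 + sum(x[-1] >= x[1])) / (n + 1)
  })
  ks2 <- suppressWarnings(stats::ks.test(pc, po))
  expect_gt(ks2$p.value, 0.01)
  expect_lt(mean(pc <= 0.1), 0.1 + 3 * sqrt(0.1 * 0.9 / 1000))
})

test_that("run_battery produces full matrices with the missing-test convention", {
  set.seed(113)
  sp <- synthetic_spec(seed = 21, n_genes = 300, mean_degree = 8,
                       n_pathways = 10, size_range = c(15, 40),
                       n_related = 0, effect_size = 3,
                       frac_de_background = 0.1)
  net <- make_network(sp)
  pl <- plant_pathways(net, sp)
  d1 <- make_expression(sp, "P01", pl$collection, id = "d1")
  d2 <- make_expression(sp, "P02", pl$collection, id = "d2")
  # a dataset with no signal at all fails DEG QC -> untested column
  sp0 <- synthetic_spec(seed = 22, n_genes = 300, effect_size = 0,
                        frac_de_target = 0, frac_de_background = 0)
  d3 <- make_expression(sp0, NA, pl$collection, id = "d3")

  res <- run_battery(c("fisher", "ease", "crosstalk"), list(d1, d2, d3),
                     pl$collection, pl$net, seed = 2)
  expect_named(res, c("fisher", "ease", "crosstalk"))
  for (m in res) {
    expect_equal(dim(m$p), c(10, 3))
    expect_true(all(m$p[, "d3"] == 1))
    expect_false(any(m$tested[, "d3"]))
    expect_true(all(m$tested[, c("d1", "d2")]))
  }
  expect_true(all(res$ease$p >= res$fisher$p - 1e-12))

  # determinism: identical datasets give identical columns
  d2b <- d2; d2b$id <- "d2copy"
  res2 <- run_battery("fisher", list(d2, d2b), pl$collection, seed = 2)
  expect_equal(unname(res2$fisher$p[, "d2"]),
               unname(res2$fisher$p[, "d2copy"]))
})
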