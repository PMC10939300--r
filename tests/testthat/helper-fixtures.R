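# Shared fixtures, built in code at test time.

# Tiny deterministic network: two pathway-ish clusters bridged by a shared
# neighbour. Edges: a1-b1, a1-b2, a2-c, b1-c (c is outside A and B).
toy_net <- function() {
  functional_network(data.frame(
    gene1 = c("a1", "a1", "a2", "b1"),
    gene2 = c("b1", "b2", "c", "c"),
    score = c(0.9, 0.8, 0.7, 0.6)))
}

# Random Erdos-Renyi-ish toy graph on n nodes (character ids).
random_toy_net <- function(n = 12, p = 0.3) {
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(pairs)) < p
  if (!any(keep)) keep[1] <- TRUE
  functional_network(data.frame(gene1 = pairs[keep, 1],
                                gene2 = pairs[keep, 2],
                                score = stats::runif(sum(keep))))
}

# Brute-force oracles, kept independent of the package internals.
oracle_dl <- function(a, b, net) {
  cnt <- 0L
  for (i in seq_len(nrow(net$edges))) {
    x <- net$edges$gene1[i]; y <- net$edges$gene2[i]
    if ((x %in% a && y %in% b) || (x %in% b && y %in% a)) cnt <- cnt + 1L
  }
  cnt
}

oracle_sn <- function(a, b, net) {
  cnt <- 0L
  for (g in net$nodes) {
    if (g %in% a || g %in% b) next
    nb <- c(net$edges$gene2[net$edges$gene1 == g],
            net$edges$gene1[net$edges$gene2 == g])
    if (any(nb %in% a) && any(nb %in% b)) cnt <- cnt + 1L
  }
  cnt
}

oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  running <- 1
  for (i in rev(seq_len(n))) {
    running <- min(running, p[ord[i]] * n / i)
    q[ord[i]] <- running
  }
  q
}

# Tie-averaged relative rank of one element within a p-vector.
oracle_rel_rank <- function(p, i) {
  r <- sum(p < p[i]) + (sum(p == p[i]) + 1) / 2
  (r - 1) / length(p)
}

# Exhaustive hypergeometric upper tail P(X >= k).
oracle_hyper_tail <- function(k, n_path, n_uni, n_deg) {
  if (k <= 0) return(1)
  j <- k:min(n_path, n_deg)
  sum(choose(n_path, j) * choose(n_uni - n_path, n_deg - j)) /
    choose(n_uni, n_deg)
}

# Exhaustive Wang S-values by path enumeration on small DAGs.
oracle_s_values <- function(t, graph, w = c(is_a = 0.8, part_of = 0.6)) {
  s <- c(1); names(s) <- t
  walk <- function(term, value) {
    pr <- graph$parents[[term]]
    if (is.null(pr)) return()
    for (i in seq_along(pr$parent)) {
      v <- value * w[[pr$relation[i]]]
      pa <- pr$parent[i]
      if (is.na(s[pa]) || v > s[[pa]]) s[pa] <<- v
      walk(pa, v)
    }
  }
  walk(t, 1)
  s
}

# A small expression dataset with planted case shift on `de_genes`.
toy_dataset <- function(n_genes = 60, n_per = 3, de_genes = character(0),
                        effect = 2, id = "toy", target = NA_character_) {
  ids <- sprintf("t%03d", seq_len(n_genes))
  samples <- c(paste0("ca", seq_len(n_per)), paste0("co", seq_len(n_per)))
  vals <- matrix(stats::rnorm(n_genes * 2 * n_per), n_genes, 2 * n_per,
                 dimnames = list(ids, samples))
  vals[de_genes, seq_len(n_per)] <- vals[de_genes, seq_len(n_per)] + effect
  expression_dataset(vals,
                     stats::setNames(rep(c("case", "control"), each = n_per),
                                     samples),
                     target_pathway = target, id = id)
}
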