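# Fixture builders and independent oracles used across the suite.

rand_pairs <- function(n_drugs, n_genes, n_edges, seed) {
  set.seed(seed)
  all <- expand.grid(drug = sprintf("D%02d", seq_len(n_drugs)),
                     gene = sprintf("G%03d", seq_len(n_genes)),
                     stringsAsFactors = FALSE)
  all[sample(nrow(all), min(n_edges, nrow(all))), ]
}

rand_layer <- function(n_drugs, n_genes, n_edges, seed, layer = "target") {
  build_layer(rand_pairs(n_drugs, n_genes, n_edges, seed), layer)
}

# Benjamini-Hochberg by the step-up definition: adj_(i) = min_{j >= i} p_(j) * n / j.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) adj[i] <- min(pmin(1, ps[i:n] * n / (i:n)))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Two-sample KS statistic as the brute-force max ECDF gap.
oracle_ks <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  max(abs(vapply(xs, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}

# Upper-tail hypergeometric p by exhaustive enumeration of all draws of
# |query| genes from the universe.
oracle_hyper_enum <- function(universe, term, query) {
  draws <- utils::combn(universe, length(query))
  k_obs <- length(intersect(term, query))
  hits <- apply(draws, 2, function(d) length(intersect(d, term)) >= k_obs)
  mean(hits)
}

# Single-deletion fixed-point m-core oracle: delete, in randomized order, one
# violating gene (layer degree < m) at a time, then drugs left with no edge,
# until nothing violates. Independent of the bulk-peeling implementation.
oracle_mcore_peel <- function(net, m, seed) {
  set.seed(seed)
  e <- net$edges
  repeat {
    gdeg <- table(e$gene)
    viol <- names(gdeg)[as.integer(gdeg) < m]
    if (length(viol) == 0) break
    victim <- sample(viol, 1)
    e <- e[e$gene != victim, , drop = FALSE]
    if (nrow(e) == 0) break
  }
  e[order(e$layer, e$drug, e$gene), , drop = FALSE]
}

# Exhaustive m-core oracle for tiny graphs: the core's gene set is the union
# of every gene subset S such that, in the subgraph induced on S plus the
# drugs adjacent to S, every gene of S keeps degree >= m.
oracle_mcore_exhaustive <- function(net, m) {
  genes <- net$genes
  stopifnot(length(genes) <= 12)
  best <- character(0)
  for (mask in seq_len(2^length(genes)) - 1L) {
    S <- genes[bitwAnd(bitwShiftL(1L, seq_along(genes) - 1L), mask) != 0]
    if (length(S) == 0) next
    e <- net$edges[net$edges$gene %in% S, , drop = FALSE]
    deg <- table(factor(e$gene, levels = S))
    if (all(as.integer(deg) >= m)) best <- union(best, S)
  }
  sort(best)
}

expect_same_network <- function(a, b) {
  expect_setequal(a$drugs, b$drugs)
  expect_setequal(a$genes, b$genes)
  ea <- a$edges[order(ea_key(a$edges)), ]
  eb <- b$edges[order(ea_key(b$edges)), ]
  rownames(ea) <- rownames(eb) <- NULL
  expect_equal(ea, eb)
}
ea_key <- function(e) paste(e$layer, e$drug, e$gene)

tiny_spec <- function(seed = 1, mode = "clean", ...) {
  args <- list(n_drugs = 20L, n_genes = 200L, n_target_genes = 40L,
               n_sensitive_genes = 120L, overlap_fraction = 0.5,
               null_genes_per_drug = 40L, mode = mode, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synthetic_spec, args)
}
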