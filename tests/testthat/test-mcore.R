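test_that("m_core handles star graphs and argument errors", {
  star <- build_layer(data.frame(drug = "d1", gene = sprintf("g%d", 1:5)), "target")
  expect_same_network(m_core(star, 1), star)
  expect_equal(nrow(m_core(star, 2)$edges), 0)
  expect_error(m_core(star, 0), "positive integer")
  merged <- merge_layers(star, build_layer(data.frame(drug = "d2", gene = "g1"),
                                           "sensitive"))
  expect_error(m_core(merged, 1), "single-layer")
})

test_that("m_core equals the single-deletion fixed-point oracle on random graphs", {
  for (seed in 1:60) {
    net <- rand_layer(8, 15, sample(10:40, 1), seed)
    for (m in 1:3) {
      core <- m_core(net, m)
      oracle <- oracle_mcore_peel(net, m, seed * 10 + m)
      expect_equal(core$edges, oracle, ignore_attr = TRUE)
    }
  }
})

test_that("m_core equals the exhaustive gene-subset oracle on tiny graphs", {
  for (seed in 1:25) {
    net <- rand_layer(6, 9, sample(8:25, 1), seed + 500)
    for (m in 1:3) {
      expect_equal(m_core(net, m)$genes, oracle_mcore_exhaustive(net, m))
    }
  }
})

test_that("peeling is order-independent under shuffled deletion order", {
  net <- rand_layer(7, 12, 30, 77)
  ref <- m_core(net, 2)
  for (s in 1:50) {
    expect_equal(oracle_mcore_peel(net, 2, s), ref$edges, ignore_attr = TRUE)
  }
})

test_that("decomposition nests, matches independent m_core calls, profiles correctly", {
  # all genes degree 1 -> m_max 1
  star <- build_layer(data.frame(drug = "d1", gene = sprintf("g%d", 1:4)), "target")
  expect_equal(peel_decomposition(star)$m_max, 1L)

  # complete bipartite 3 x 4: every gene core number = 3
  kb <- build_layer(expand.grid(drug = sprintf("d%d", 1:3),
                                gene = sprintf("g%d", 1:4),
                                stringsAsFactors = FALSE), "target")
  dec <- peel_decomposition(kb)
  expect_equal(unname(dec$core_number), rep(3L, 4))
  expect_equal(dec$m_max, 3L)

  for (seed in 1:20) {
    net <- rand_layer(8, 15, sample(15:45, 1), seed + 900, "sensitive")
    dec <- peel_decomposition(net)
    prof <- core_profile(dec)
    expect_equal(nrow(prof), dec$m_max)
    expect_false(is.unsorted(rev(prof$n_genes)))  # nesting: non-increasing
    for (m in seq_len(dec$m_max)) {
      indep <- m_core(net, m)
      expect_setequal(dec$cores[[m]]$gene_members, indep$genes)
      if (m < dec$m_max) {
        expect_true(all(dec$cores[[m + 1]]$gene_members %in%
                          dec$cores[[m]]$gene_members))
      }
      # membership implies in-core layer degree >= m
      gdeg <- table(indep$edges$gene)
      expect_true(all(as.integer(gdeg[dec$cores[[m]]$gene_members]) >= m))
      # profile rows match direct recomputation
      expect_equal(prof$n_genes[m], length(indep$genes))
      expect_equal(prof$n_drugs[m], length(indep$drugs))
    }
    # cross-check core numbers
    for (g in names(dec$core_number)) {
      in_core <- vapply(seq_len(dec$m_max),
                        function(m) g %in% dec$cores[[m]]$gene_members, logical(1))
      expect_equal(unname(dec$core_number[g]), max(which(in_core)))
    }
  }
  expect_error(peel_decomposition(layered_network(
    data.frame(drug = character(), gene = character(), layer = character()))),
    "empty")
})

test_that("gene-constrained peeling agrees with the classical bipartite k-core", {
  # the classical (all-node) k-core is always contained in the gene-constrained
  # core; they coincide at any m where the gene-constrained core happens to
  # keep every drug at degree >= m as well
  n_equal <- 0
  for (seed in 1:10) {
    net <- rand_layer(3, 20, 35, seed + 40)
    g <- as_igraph(net)
    cn <- igraph::coreness(g)
    for (m in 1:3) {
      core <- m_core(net, m)
      classical_genes <- names(cn)[cn >= m & names(cn) %in% net$genes]
      expect_true(all(classical_genes %in% core$genes))
      drug_deg <- table(core$edges$drug)
      if (nrow(core$edges) > 0 && min(as.integer(drug_deg)) >= m) {
        expect_setequal(core$genes, classical_genes)
        n_equal <- n_equal + 1
      }
      # classical mode reproduces the off-the-shelf k-core exactly
      expect_setequal(m_core(net, m, constrain = "all")$genes, classical_genes)
    }
  }
  expect_gt(n_equal, 0)
})

test_that("strict and largest-component modes are available", {
  # two components: one K2,2 block (gene degree 2), one star (gene degree 1)
  block <- expand.grid(drug = c("d1", "d2"), gene = c("g1", "g2"),
                       stringsAsFactors = FALSE)
  star <- data.frame(drug = "d3", gene = c("g3", "g4", "g5", "g6"))
  net <- build_layer(rbind(block, star), "target")
  expect_setequal(m_core(net, 1)$genes, sprintf("g%d", 1:6))
  expect_equal(igraph::components(as_igraph(m_core(net, 1)))$no, 2)
  expect_setequal(m_core(net, 1, largest_only = TRUE)$genes,
                  c("g3", "g4", "g5", "g6"))
  # strict > m: genes need degree > 1
  expect_setequal(m_core(net, 1, strict = TRUE)$genes, c("g1", "g2"))
})
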