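test_that("build_layer creates one node per id and one edge per pair", {
  net <- build_layer(data.frame(drug = "d1", gene = "g1"), "target")
  expect_equal(length(net$drugs) + length(net$genes), 2)
  expect_equal(nrow(net$edges), 1)

  net <- build_layer(data.frame(drug = "d1", gene = c("g1", "g2", "g3")), "target")
  expect_equal(sum(net$edges$drug == "d1"), 3)

  for (seed in 1:10) {
    pairs <- rand_pairs(10, 50, 80, seed)
    net <- build_layer(pairs, "sensitive")
    expect_equal(nrow(net$edges), nrow(unique(pairs)))
  }
})

test_that("merge_layers unions nodes and keeps one typed edge per layer", {
  dtn <- build_layer(data.frame(drug = "d1", gene = "g1"), "target")
  dsn <- build_layer(data.frame(drug = "d1", gene = "g1"), "sensitive")
  m <- merge_layers(dtn, dsn)
  expect_equal(length(m$drugs) + length(m$genes), 2)
  expect_equal(nrow(m$edges), 2)
  expect_setequal(m$edges$layer, c("target", "sensitive"))

  dsn2 <- build_layer(data.frame(drug = "d9", gene = "g9"), "sensitive")
  m2 <- merge_layers(dtn, dsn2)
  expect_equal(length(m2$drugs) + length(m2$genes), 4)

  for (seed in 1:10) {
    dtn <- rand_layer(6, 20, 30, seed, "target")
    dsn <- rand_layer(6, 20, 30, seed + 50, "sensitive")
    m <- merge_layers(dtn, dsn)
    expect_equal(nrow(m$edges), nrow(dtn$edges) + nrow(dsn$edges))
  }
  expect_error(merge_layers(dsn, dtn), "target-layer")
})

test_that("gene scores are exact layer degrees with handshake identity", {
  empty <- layered_network(data.frame(drug = character(), gene = character(),
                                      layer = character()))
  expect_equal(nrow(compute_gene_scores(empty)), 0)

  net <- build_layer(data.frame(drug = c("d1", "d2", "d3"), gene = "g1"), "target")
  sc <- compute_gene_scores(net)
  expect_equal(sc$kdtn, 3L)
  expect_equal(sc$kdsn, 0L)

  for (seed in 1:20) {
    m <- merge_layers(rand_layer(8, 30, 60, seed, "target"),
                      rand_layer(8, 30, 60, seed + 99, "sensitive"))
    sc <- compute_gene_scores(m)
    expect_equal(sum(sc$kdtn), sum(m$edges$layer == "target"))
    expect_equal(sum(sc$kdsn), sum(m$edges$layer == "sensitive"))
  }
})

test_that("partition matches brute-force set comprehension and is disjoint-exhaustive", {
  sc <- gene_scores(data.frame(gene = character(), kdtn = integer(), kdsn = integer()))
  p <- partition_genes(sc)
  expect_equal(lengths(unclass(p)), c(DTG = 0L, DSG = 0L, DTSG = 0L))

  for (seed in 1:20) {
    set.seed(seed)
    sc <- gene_scores(data.frame(gene = sprintf("G%03d", 1:80),
                                 kdtn = rpois(80, 0.8), kdsn = rpois(80, 1.2)))
    p <- partition_genes(sc)
    expect_setequal(p$DTG, sc$gene[sc$kdtn >= 1 & sc$kdsn == 0])
    expect_setequal(p$DSG, sc$gene[sc$kdsn >= 1 & sc$kdtn == 0])
    expect_setequal(p$DTSG, sc$gene[sc$kdtn >= 1 & sc$kdsn >= 1])
    expect_length(intersect(p$DTG, p$DSG), 0)
    expect_length(intersect(p$DTG, p$DTSG), 0)
    expect_length(intersect(p$DSG, p$DTSG), 0)
    expect_equal(length(p$DTG) + length(p$DSG) + length(p$DTSG),
                 sum(sc$kdtn >= 1 | sc$kdsn >= 1))
  }
})

test_that("drug subnetwork sampling is seeded, induced and bounded", {
  net <- merge_layers(rand_layer(20, 60, 120, 1, "target"),
                      rand_layer(20, 60, 120, 2, "sensitive"))
  expect_same_network(sample_drug_subnetwork(net, 1.0, 5), net)
  s1 <- sample_drug_subnetwork(net, 0.25, 7)
  s2 <- sample_drug_subnetwork(net, 0.25, 7)
  expect_same_network(s1, s2)
  expect_equal(length(s1$drugs), 5)  # round(0.25 * 20)

  for (seed in 1:10) {
    s <- sample_drug_subnetwork(net, 0.3, seed)
    expect_true(all(ea_key(s$edges) %in% ea_key(net$edges)))
    gdeg <- table(s$edges$gene)
    expect_true(all(s$genes %in% names(gdeg)))  # every retained gene has an edge
  }
  # floor at one drug, round half up
  expect_equal(length(sample_drug_subnetwork(net, 0.001, 1)$drugs), 1)
  expect_error(sample_drug_subnetwork(net, 0, 1), "fraction")
  expect_error(sample_drug_subnetwork(net, 1.2, 1), "fraction")
})

test_that("merge is commutative up to attribute equality on edge sets", {
  for (seed in 1:5) {
    dtn <- rand_layer(5, 15, 25, seed, "target")
    dsn <- rand_layer(5, 15, 25, seed + 10, "sensitive")
    a <- merge_layers(dtn, dsn)
    b <- layered_network(rbind(dsn$edges, dtn$edges),
                         drugs = union(dsn$drugs, dtn$drugs),
                         genes = union(dsn$genes, dtn$genes))
    expect_same_network(a, b)
  }
})
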