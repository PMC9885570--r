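test_that("spec validation enforces feasibility", {
  expect_error(synthetic_spec(n_drugs = 10, n_genes = 50, n_target_genes = 40,
                              n_sensitive_genes = 40, overlap_fraction = 0),
               "infeasible")
  expect_error(tiny_spec(n_sensitive_genes = 10L, overlap_fraction = 1),
               "shared genes")
  expect_s3_class(tiny_spec(), "synthetic_spec")
})

test_that("planted target degrees are reproduced exactly by network scoring", {
  spec <- tiny_spec(seed = 5)
  gen <- generate_target_table(spec)
  net <- build_layer(gen$table, "target")
  sc <- compute_gene_scores(net)
  expect_equal(setNames(sc$kdtn, sc$gene)[names(gen$planted_kdtn)],
               gen$planted_kdtn)

  # one gene -> all drugs hit it
  spec1 <- synthetic_spec(n_drugs = 15, n_genes = 1, n_target_genes = 1,
                          n_sensitive_genes = 0, overlap_fraction = 0,
                          target_alpha = 1.1, seed = 2)
  gen1 <- generate_target_table(spec1)
  expect_lte(max(gen1$planted_kdtn), 15)

  # determinism: same seed twice -> identical tables
  expect_identical(generate_target_table(spec)$table$pairs, gen$table$pairs)
})

test_that("clean-mode signature tables recover planted calls exactly", {
  spec <- tiny_spec(seed = 9)
  sig <- generate_signature_tables(spec)
  calls <- call_signatures(sig$table, signature_config())
  expect_equal(calls$pairs, sig$planted_calls, ignore_attr = TRUE)
  # planted degrees reproduced through the full layer
  sc <- compute_gene_scores(build_layer(calls, "sensitive"))
  expect_equal(setNames(sc$kdsn, sc$gene)[names(sig$planted_kdsn)],
               sig$planted_kdsn)
})

test_that("overlap fraction and anti-correlation shape the planted landscape", {
  # zero overlap -> empty DTSG
  spec0 <- tiny_spec(seed = 12, overlap_fraction = 0)
  ls0 <- generate_landscape(spec0)
  expect_length(ls0$truth$partition$DTSG, 0)

  # rank-reversal coupling: strong negative Spearman on shared genes.
  # Moderate tail exponents keep degree ties rare enough for the rank
  # correlation to expose the coupling; at steeper exponents most degrees tie
  # at 1 and Spearman is bounded away from -1 regardless of the coupling.
  spec <- synthetic_spec(n_drugs = 500, n_genes = 1500, n_target_genes = 300,
                         n_sensitive_genes = 600, overlap_fraction = 0.5,
                         target_alpha = 1.5, sensitive_alpha = 1.5,
                         anti_correlation = -1, null_genes_per_drug = 10, seed = 77)
  ls <- generate_landscape(spec)
  sc <- ls$truth$scores
  shared <- sc[sc$kdtn >= 1 & sc$kdsn >= 1, ]
  expect_gte(nrow(shared), 100)
  rho <- suppressWarnings(cor(shared$kdtn, shared$kdsn, method = "spearman"))
  expect_lte(rho, -0.8)
})

test_that("generated files are byte-identical across runs with the same seed", {
  spec <- tiny_spec(seed = 4)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_landscape(generate_landscape(spec), d1)
  p2 <- write_landscape(generate_landscape(spec), d2)
  for (nm in c("target", "signature")) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
  }
  # and the manifest records the planted partition
  man <- jsonlite::read_json(p1[["manifest"]], simplifyVector = TRUE)
  ls <- generate_landscape(spec)
  expect_equal(man$planted$partition$DTSG, length(ls$truth$partition$DTSG))
})

test_that("planted annotation terms are detected; null terms are not inflated", {
  spec <- tiny_spec(seed = 15)
  universe <- sprintf("G%05d", 1:200)
  sets <- list(A = universe[1:60])
  lib <- generate_annotation_library(
    spec, universe, sets,
    planted_terms = data.frame(term_size = 50, enriched_in = "A", effect = 8),
    n_background_terms = 30, background_term_size = 25)
  res <- hypergeometric_ora(sets$A, universe, lib)
  expect_true("PLANTED001" %in% res$term[res$significant])

  expect_error(generate_annotation_library(
    spec, universe, sets,
    planted_terms = data.frame(term_size = 0, enriched_in = "A", effect = 2)),
    "sizes must be")
  expect_error(generate_annotation_library(
    spec, universe, sets,
    planted_terms = data.frame(term_size = 500, enriched_in = "A", effect = 2)),
    "impossible oversampling")
})

test_that("full-pipeline recovery: planted truth survives write -> read -> analyse", {
  spec <- tiny_spec(seed = 23)
  ls <- generate_landscape(spec)
  dir <- withr::local_tempdir()
  paths <- write_landscape(ls, dir)
  tt <- suppressMessages(read_drug_target_table(paths[["target"]]))
  st <- read_signature_table(paths[["signature"]])
  calls <- call_signatures(st, signature_config())
  merged <- merge_layers(build_layer(tt, "target"), build_layer(calls, "sensitive"))
  sc <- compute_gene_scores(merged)
  truth <- ls$truth$scores
  expect_equal(sc[match(truth$gene, sc$gene), c("kdtn", "kdsn")],
               truth[, c("kdtn", "kdsn")], ignore_attr = TRUE)
  p <- partition_genes(sc)
  expect_equal(lengths(unclass(p)), lengths(unclass(ls$truth$partition)))
})
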