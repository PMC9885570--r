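test_that("hypergeometric p equals exhaustive enumeration on small universes", {
  universe <- sprintf("G%02d", 1:20)
  term <- universe[1:5]
  query <- c(universe[1:4], universe[10])   # overlap 4
  lib <- gene_set_library("l", list(T1 = list(description = "", members = term)))
  res <- hypergeometric_ora(query, universe, lib)
  # all C(20,5) = 15504 draws enumerated: 76 have overlap >= 4
  expect_equal(res$p, 76 / 15504, tolerance = 1e-12)
  expect_equal(res$p, oracle_hyper_enum(universe, term, query), tolerance = 1e-12)

  for (seed in 1:10) {
    set.seed(seed)
    N <- sample(10:25, 1)
    universe <- sprintf("G%02d", seq_len(N))
    term <- sample(universe, sample(2:6, 1))
    query <- sample(universe, sample(3:7, 1))
    if (length(intersect(term, query)) == 0) next
    lib <- gene_set_library("l", list(T1 = list(description = "", members = term)))
    res <- hypergeometric_ora(query, universe, lib)
    expect_equal(res$p, oracle_hyper_enum(universe, term, query), tolerance = 1e-12)
  }
})

test_that("ORA reporting rules: disjoint terms absent, certain overlap p = 1, errors", {
  universe <- sprintf("G%02d", 1:20)
  lib <- gene_set_library("l", list(
    HIT = list(description = "", members = universe[1:5]),
    MISS = list(description = "", members = universe[11:15])))
  res <- hypergeometric_ora(universe[1:5], universe, lib)
  expect_equal(res$term, "HIT")

  all_lib <- gene_set_library("l", list(ALL = list(description = "", members = universe)))
  expect_equal(hypergeometric_ora(universe, universe, all_lib)$p, 1)

  expect_error(hypergeometric_ora(c("G01", "ZZ"), universe, lib), "ZZ")
  expect_error(hypergeometric_ora(character(0), universe, lib), "empty")
})

test_that("BH over terms is monotone and query growth cannot lower p", {
  set.seed(5)
  universe <- sprintf("G%03d", 1:100)
  sets <- lapply(1:12, function(i) list(description = "", members = sample(universe, 15)))
  names(sets) <- sprintf("T%02d", 1:12)
  lib <- gene_set_library("l", sets)
  query <- sample(universe, 20)
  res <- hypergeometric_ora(query, universe, lib)
  expect_false(is.unsorted(res$fdr))          # sorted by p, BH step-up smooth
  expect_true(all(res$fdr >= res$p - 1e-15))

  extra <- setdiff(universe, unique(c(query, unlist(lapply(sets, `[[`, "members")))))
  if (length(extra) > 0) {
    res2 <- hypergeometric_ora(c(query, extra[1]), universe, lib)
    both <- intersect(res$term, res2$term)
    expect_true(all(res2$p[match(both, res2$term)] >= res$p[match(both, res$term)] - 1e-15))
  }
})

test_that("term overlap accounting equals brute-force set algebra", {
  ov <- term_overlap(list(a = c("t1", "t2"), b = c("t1", "t2")))
  expect_equal(ov$n_shared, 2)
  ov <- term_overlap(list(a = c("t1", "t2"), b = c("t3")))
  expect_equal(ov$n_shared, 0)
  expect_equal(ov$n_terms, 3)

  for (seed in 1:10) {
    set.seed(seed)
    pool <- sprintf("T%02d", 1:30)
    lists <- list(x = sample(pool, 10), y = sample(pool, 8), z = sample(pool, 12))
    ov <- term_overlap(lists)
    expect_equal(ov$n_terms, length(unique(unlist(lists))))
    shared <- sum(table(unlist(lapply(lists, unique))) >= 2)
    expect_equal(ov$n_shared, shared)
    expect_equal(unname(rowSums(as.matrix(ov$table[, c("x", "y", "z")]))),
                 ov$table$n_sets)
  }
})

test_that("TF binding frequency recovers planted Poisson means", {
  # exact small case: every gene in exactly 2 TF sets
  lib <- gene_set_library("tf", list(
    TF1 = list(description = "", members = c("G1", "G2")),
    TF2 = list(description = "", members = c("G1", "G2"))))
  s <- tf_binding_frequency(c("G1", "G2"), lib)
  expect_equal(s$mean_tfs_per_gene, 2)
  s0 <- tf_binding_frequency(c("G1", "G9"), lib)
  expect_equal(unname(s0$per_gene["G9"]), 0L)
  expect_error(tf_binding_frequency(character(0), lib), "empty")

  # planted recovery: lambda 6 vs lambda 2, ratio about 3
  spec <- tiny_spec(seed = 31)
  sets <- list(DSG = sprintf("G%05d", 1:150), DTG = sprintf("G%05d", 151:300))
  gen <- generate_tf_library(spec, sets, c(DSG = 6, DTG = 2), n_tfs = 200)
  s_dsg <- tf_binding_frequency(sets$DSG, gen$library)
  s_dtg <- tf_binding_frequency(sets$DTG, gen$library)
  expect_equal(s_dsg$per_gene[names(s_dsg$per_gene)],
               gen$planted_counts[names(s_dsg$per_gene)])
  se6 <- sqrt(6 / 150); se2 <- sqrt(2 / 150)
  expect_lt(abs(s_dsg$mean_tfs_per_gene - 6), 3 * se6)
  expect_lt(abs(s_dtg$mean_tfs_per_gene - 2), 3 * se2)
  expect_lt(abs(s_dsg$mean_tfs_per_gene / s_dtg$mean_tfs_per_gene - 3), 0.5)
})
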