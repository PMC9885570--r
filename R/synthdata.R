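#' Specification of a synthetic drug-gene landscape
#'
#' Describes a DSigDB-like world with planted structure: heavy-tailed
#' gene-side degrees in both network layers, a target/sensitive gene overlap
#' small relative to the sensitive set, rank-reversal coupling between the
#' two degree sequences on shared genes (target hubs tend not to be
#' sensitive hubs), and expression tables in which the planted sensitive
#' pairs pass the calling thresholds. Defaults are the landscape the source
#' data reports: 382 drugs, 9,490 genes, 720 target genes, 9,233 sensitive
#' genes, 463 in both; degree exponents are back-derived from the printed
#' degree maxima (KDTN up to ~186, KDSN up to ~104).
#'
#' @param n_drugs Number of drugs.
#' @param n_genes Number of genes in the world.
#' @param n_target_genes Genes with at least one target edge.
#' @param n_sensitive_genes Genes with at least one sensitive edge.
#' @param overlap_fraction Fraction of target genes that are also sensitive.
#' @param target_alpha Gene-side power-law exponent of the target layer.
#' @param sensitive_alpha Gene-side exponent of the sensitive layer.
#' @param anti_correlation In \[-1, 0\]: -1 couples the two planted degree
#'   sequences on shared genes by exact rank reversal, 0 leaves them
#'   independent.
#' @param mode `"clean"`: planted pairs pass and null pairs fail the
#'   fold-change gate with certainty (logic tests are exact). `"noisy"`:
#'   margins narrowed and null fold changes may leave the (0.5, 2) window, so
#'   false calls occur at the rate of the p-value threshold.
#' @param null_genes_per_drug Null expression records emitted per drug.
#' @param seed Integer seed; identical spec + seed gives byte-identical
#'   outputs.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_drugs = 382L, n_genes = 9490L,
                           n_target_genes = 720L, n_sensitive_genes = 9233L,
                           overlap_fraction = 463 / 720,
                           target_alpha = 2.3, sensitive_alpha = 3.0,
                           anti_correlation = -1, mode = c("clean", "noisy"),
                           null_genes_per_drug = 200L, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_drugs >= 1, n_genes >= 1,
            n_target_genes >= 0, n_sensitive_genes >= 0,
            n_target_genes <= n_genes, n_sensitive_genes <= n_genes,
            overlap_fraction >= 0, overlap_fraction <= 1,
            target_alpha > 1, sensitive_alpha > 1,
            anti_correlation >= -1, anti_correlation <= 0)
  n_overlap <- as.integer(round(overlap_fraction * n_target_genes))
  if (n_overlap > min(n_target_genes, n_sensitive_genes)) {
    stop("overlap_fraction demands more shared genes than either layer holds")
  }
  if (n_target_genes + n_sensitive_genes - n_overlap > n_genes) {
    stop("infeasible: target + sensitive - overlap exceeds the gene universe")
  }
  structure(list(n_drugs = as.integer(n_drugs), n_genes = as.integer(n_genes),
                 n_target_genes = as.integer(n_target_genes),
                 n_sensitive_genes = as.integer(n_sensitive_genes),
                 overlap_fraction = overlap_fraction, n_overlap = n_overlap,
                 target_alpha = target_alpha, sensitive_alpha = sensitive_alpha,
                 anti_correlation = anti_correlation, mode = mode,
                 null_genes_per_drug = as.integer(null_genes_per_drug),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

synth_gene_ids <- function(spec) sprintf("G%05d", seq_len(spec$n_genes))
synth_drug_ids <- function(spec) sprintf("D%04d", seq_len(spec$n_drugs))

# Zeta-tailed degrees truncated at kmax (a gene cannot bind more than
# n_drugs distinct drugs in a simple bipartite graph).
rtrunc_zeta <- function(n, alpha, kmax) {
  k <- seq_len(kmax)
  sample(k, n, replace = TRUE, prob = k^(-alpha))
}

#' Generate a synthetic drug-target table with planted degrees
#'
#' Gene-side degrees are drawn from a truncated zeta(alpha) law and each
#' target gene is wired to that many distinct drugs chosen uniformly — a
#' simple bipartite realization of the planted gene-side degree sequence
#' (no multi-edges by construction).
#'
#' @param spec A `synthetic_spec`.
#' @return List with `table` (a `drug_target_table`), `planted_kdtn` (named
#'   integer vector over target genes) and `target_genes`.
#' @export
generate_target_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr_seed(spec$seed, {
    genes <- synth_gene_ids(spec)
    drugs <- synth_drug_ids(spec)
    target_genes <- sort(sample(genes, spec$n_target_genes))
    deg <- rtrunc_zeta(spec$n_target_genes, spec$target_alpha, spec$n_drugs)
    pairs <- do.call(rbind, lapply(seq_along(target_genes), function(i) {
      data.frame(drug = sample(drugs, deg[i]), gene = target_genes[i],
                 stringsAsFactors = FALSE)
    }))
    if (is.null(pairs)) pairs <- data.frame(drug = character(), gene = character())
    list(table = drug_target_table(pairs),
         planted_kdtn = setNames(as.integer(deg), target_genes),
         target_genes = target_genes)
  })
}

#' Generate synthetic signature tables with planted sensitive pairs
#'
#' A planted subset of genes (an `overlap_fraction` of the target genes plus
#' further sensitive-only genes) receives sensitive edges with truncated-zeta
#' degrees; on the shared genes the sensitive degree sequence is coupled to
#' the target one by (possibly noisy) rank reversal, emulating the observed
#' reciprocity between layers. Planted (drug, gene) records get fold changes
#' beyond the 2-fold thresholds and adjusted p below 0.05; null records stay
#' inside the fold-change window (clean mode) or may leave it (noisy mode).
#'
#' @param spec A `synthetic_spec`.
#' @param target Output of [generate_target_table()] for the same spec;
#'   generated on the fly when omitted.
#' @return List with `table` (a `signature_table`), `planted_calls`
#'   (data.frame drug/gene), `planted_kdsn` (named integer vector) and
#'   `sensitive_genes`.
#' @export
generate_signature_tables <- function(spec, target = generate_target_table(spec)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr_seed(spec$seed + 1L, {
    genes <- synth_gene_ids(spec)
    drugs <- synth_drug_ids(spec)
    n_overlap <- spec$n_overlap
    shared <- if (n_overlap > 0) sort(sample(target$target_genes, n_overlap)) else character(0)
    only_pool <- setdiff(genes, target$target_genes)
    n_only <- spec$n_sensitive_genes - n_overlap
    sens_only <- if (n_only > 0) sort(sample(only_pool, n_only)) else character(0)
    sensitive_genes <- c(shared, sens_only)

    deg <- rtrunc_zeta(length(sensitive_genes), spec$sensitive_alpha, spec$n_drugs)
    if (length(shared) > 1) {
      # rank-reversal coupling: high-KDTN shared genes get low KDSN
      kdtn_shared <- target$planted_kdtn[shared]
      ns <- length(shared)
      desc_rank <- rank(-kdtn_shared, ties.method = "random")
      blend <- abs(spec$anti_correlation) * desc_rank +
        (1 - abs(spec$anti_correlation)) * sample(ns)
      shared_deg <- sort(deg[seq_len(ns)])[rank(blend, ties.method = "random")]
      deg <- c(shared_deg, deg[-seq_len(ns)])
    }
    kdsn <- setNames(as.integer(deg), sensitive_genes)

    planted <- do.call(rbind, lapply(seq_along(sensitive_genes), function(i) {
      data.frame(drug = sample(drugs, deg[i]), gene = sensitive_genes[i],
                 stringsAsFactors = FALSE)
    }))
    if (is.null(planted)) planted <- data.frame(drug = character(), gene = character())

    np <- nrow(planted)
    noisy <- spec$mode == "noisy"
    up <- stats::runif(np) < 0.5
    fc_planted <- ifelse(up,
                         stats::runif(np, if (noisy) 2.05 else 2.2, 8),
                         stats::runif(np, 0.1, if (noisy) 0.48 else 0.45))
    padj_planted <- stats::runif(np, 0, if (noisy) 0.049 else 0.04)

    planted_by_drug <- split(planted$gene, planted$drug)
    null_rows <- do.call(rbind, lapply(drugs, function(d) {
      pool <- setdiff(genes, planted_by_drug[[d]])
      nn <- min(spec$null_genes_per_drug, length(pool))
      if (nn == 0) return(NULL)
      data.frame(drug = d, gene = sample(pool, nn), stringsAsFactors = FALSE)
    }))
    nn <- if (is.null(null_rows)) 0L else nrow(null_rows)
    fc_null <- if (noisy) stats::runif(nn, 0.3, 4) else stats::runif(nn, 0.6, 1.8)
    padj_null <- stats::runif(nn, 0, 1)

    records <- rbind(
      data.frame(drug = planted$drug, gene = planted$gene, fc = fc_planted,
                 p = NA_real_, p_adj = padj_planted, stringsAsFactors = FALSE),
      if (nn > 0) data.frame(drug = null_rows$drug, gene = null_rows$gene,
                             fc = fc_null, p = NA_real_, p_adj = padj_null,
                             stringsAsFactors = FALSE))
    records <- records[order(records$drug, records$gene), , drop = FALSE]
    calls <- planted[order(planted$drug, planted$gene), , drop = FALSE]
    rownames(calls) <- NULL
    list(table = signature_table(records),
         planted_calls = calls,
         planted_kdsn = kdsn,
         sensitive_genes = sensitive_genes)
  })
}

#' Generate an annotation library with planted enrichment
#'
#' Planted terms oversample a named gene set's members by an odds factor
#' `effect`; background terms sample the universe uniformly. `effect = 1`
#' plants nothing (null calibration).
#'
#' @param spec A `synthetic_spec` (provides the seed).
#' @param universe Character vector of gene ids to draw from.
#' @param sets Named list of gene-id vectors that planted terms can enrich.
#' @param planted_terms data.frame with columns `term_size`, `enriched_in`
#'   (a name of `sets`), `effect` (>= 1); NULL for a background-only library.
#' @param n_background_terms,background_term_size Background term layout.
#' @param seed_offset Added to `spec$seed` so several libraries per spec
#'   differ.
#' @return A `gene_set_library`; planted terms are named `PLANTED###`.
#' @export
generate_annotation_library <- function(spec, universe, sets = list(),
                                        planted_terms = NULL,
                                        n_background_terms = 50L,
                                        background_term_size = 30L,
                                        seed_offset = 2L) {
  stopifnot(inherits(spec, "synthetic_spec"), length(universe) > 0)
  withr_seed(spec$seed + seed_offset, {
    out <- list()
    if (!is.null(planted_terms)) {
      stopifnot(all(c("term_size", "enriched_in", "effect") %in% names(planted_terms)))
      for (i in seq_len(nrow(planted_terms))) {
        s <- planted_terms$term_size[i]
        if (s < 1) stop(sprintf("planted term %d has size %d; term sizes must be >= 1", i, s))
        if (s > length(universe)) stop("impossible oversampling: term size exceeds the universe")
        eff <- planted_terms$effect[i]
        stopifnot(eff >= 1)
        inset <- universe %in% sets[[planted_terms$enriched_in[i]]]
        w <- ifelse(inset, eff, 1)
        members <- sample(universe, s, prob = w)
        out[[sprintf("PLANTED%03d", i)]] <-
          list(description = sprintf("planted in %s (effect %.1f)",
                                     planted_terms$enriched_in[i], eff),
               members = sort(members))
      }
    }
    for (i in seq_len(n_background_terms)) {
      s <- min(background_term_size, length(universe))
      out[[sprintf("BG%03d", i)]] <-
        list(description = "background term", members = sort(sample(universe, s)))
    }
    gene_set_library("synthetic_annotation", out)
  })
}

#' Generate a TF library with planted per-gene binding frequencies
#'
#' For each gene of each named set, the number of distinct TFs binding it is
#' drawn Poisson(lambda) (capped at `n_tfs`); the bound TFs are a uniform
#' draw. Recovering the per-set mean with [tf_binding_frequency()] is then a
#' direct check of the planted lambdas.
#'
#' @param spec A `synthetic_spec` (provides the seed).
#' @param sets Named list of disjoint gene-id vectors.
#' @param lambdas Named numeric vector of Poisson means, same names as `sets`.
#' @param n_tfs Size of the TF pool.
#' @param seed_offset Added to `spec$seed`.
#' @return List with `library` (a `gene_set_library` of TF target sets) and
#'   `planted_counts` (named integer vector per gene).
#' @export
generate_tf_library <- function(spec, sets, lambdas, n_tfs = 150L,
                                seed_offset = 3L) {
  stopifnot(inherits(spec, "synthetic_spec"),
            setequal(names(sets), names(lambdas)))
  withr_seed(spec$seed + seed_offset, {
    tfs <- sprintf("TF%03d", seq_len(n_tfs))
    members <- setNames(vector("list", n_tfs), tfs)
    planted <- integer(0)
    for (nm in names(sets)) {
      for (g in sets[[nm]]) {
        cnt <- min(stats::rpois(1, lambdas[[nm]]), n_tfs)
        planted[[g]] <- cnt
        if (cnt > 0) {
          for (tf in sample(tfs, cnt)) members[[tf]] <- c(members[[tf]], g)
        }
      }
    }
    keep <- names(members)[lengths(members) > 0]
    gsets <- lapply(setNames(keep, keep), function(tf) {
      list(description = "TF target genes", members = sort(members[[tf]]))
    })
    list(library = gene_set_library("synthetic_tf", gsets),
         planted_counts = planted)
  })
}

#' Generate a full synthetic landscape with its planted truth
#'
#' Bundles [generate_target_table()] and [generate_signature_tables()] and
#' derives the planted truth a test harness needs: per-gene KDTN/KDSN and the
#' implied DTG/DSG/DTSG partition.
#'
#' @param spec A `synthetic_spec`.
#' @return A `synthetic_landscape`: list with `spec`, `target`, `signature`
#'   and `truth` (planted `scores` data.frame and `partition` sizes).
#' @export
generate_landscape <- function(spec) {
  target <- generate_target_table(spec)
  signature <- generate_signature_tables(spec, target)
  genes <- sort(union(target$target_genes, signature$sensitive_genes))
  kdtn <- ifelse(genes %in% names(target$planted_kdtn),
                 target$planted_kdtn[genes], 0L)
  kdsn <- ifelse(genes %in% names(signature$planted_kdsn),
                 signature$planted_kdsn[genes], 0L)
  scores <- gene_scores(data.frame(gene = genes, kdtn = as.integer(kdtn),
                                   kdsn = as.integer(kdsn),
                                   stringsAsFactors = FALSE))
  structure(list(spec = spec, target = target, signature = signature,
                 truth = list(scores = scores,
                              partition = partition_genes(scores))),
            class = "synthetic_landscape")
}

#' Write a synthetic landscape to disk
#'
#' Emits the same dialects the readers consume (two-column target TSV,
#' signature TSV) plus a JSON manifest recording the spec, the seed and the
#' planted truth summary.
#'
#' @param landscape A `synthetic_landscape`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths.
#' @export
write_landscape <- function(landscape, dir) {
  stopifnot(inherits(landscape, "synthetic_landscape"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(target = file.path(dir, "drug_target.tsv"),
             signature = file.path(dir, "signatures.tsv"),
             manifest = file.path(dir, "manifest.json"))
  write_drug_target_table(landscape$target$table, paths[["target"]])
  write_signature_table(landscape$signature$table, paths[["signature"]])
  p <- landscape$truth$partition
  manifest <- list(spec = unclass(landscape$spec),
                   planted = list(n_target_pairs = nrow(landscape$target$table$pairs),
                                  n_sensitive_pairs = nrow(landscape$signature$planted_calls),
                                  partition = list(DTG = length(p$DTG),
                                                   DSG = length(p$DSG),
                                                   DTSG = length(p$DTSG))))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE, pretty = TRUE)
  paths
}
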