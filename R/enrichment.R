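#' Hypergeometric over-representation analysis against a GMT library
#'
#' One-sided upper-tail hypergeometric test per term: with universe size N,
#' term size K (members restricted to the universe), query size n and overlap
#' k, p = P(X >= k) for X ~ Hypergeometric(N, K, n). Benjamini-Hochberg FDR
#' across all tested terms of the library (terms with >= 1 overlap); results
#' sorted by p. The universe defaults elsewhere in the pipeline to all genes
#' scored in the drug-gene network.
#'
#' @param query Non-empty set of gene ids, a subset of `universe`.
#' @param universe Background gene set.
#' @param library A `gene_set_library`.
#' @param fdr_threshold Threshold reported in the `significant` column
#'   (default 0.05); all tested terms are returned regardless.
#' @return data.frame with columns `term`, `overlap`, `set_size`,
#'   `term_size`, `universe_size`, `p`, `fdr`, `significant`.
#' @export
hypergeometric_ora <- function(query, universe, library, fdr_threshold = 0.05) {
  stopifnot(inherits(library, "gene_set_library"), length(library$sets) > 0)
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (length(query) == 0) stop("empty query gene set")
  off <- setdiff(query, universe)
  if (length(off) > 0) {
    stop(sprintf("query genes missing from the universe: %s",
                 paste(head(off, 10), collapse = ", ")))
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(names(library$sets), function(term) {
    members <- intersect(library$sets[[term]]$members, universe)
    K <- length(members)
    k <- length(intersect(members, query))
    if (k < 1) return(NULL)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, overlap = k, set_size = n, term_size = K,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    return(data.frame(term = character(), overlap = integer(), set_size = integer(),
                      term_size = integer(), universe_size = integer(),
                      p = numeric(), fdr = numeric(), significant = logical()))
  }
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$fdr < fdr_threshold
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Cross-set term-overlap accounting
#'
#' Given significant term lists for several gene sets (e.g. DTG/DSG/DTSG),
#' tabulates which sets hit each term and counts terms shared by two or more
#' sets — the exclusivity summary behind Venn-style figures.
#'
#' @param results_per_set Named list (>= 2 entries) of character vectors of
#'   term ids.
#' @return List with `table` (data.frame term x set logicals plus
#'   `n_sets`), `n_terms` (distinct terms) and `n_shared` (terms hit by
#'   >= 2 sets).
#' @export
term_overlap <- function(results_per_set) {
  stopifnot(is.list(results_per_set), length(results_per_set) >= 2,
            !is.null(names(results_per_set)))
  results_per_set <- lapply(results_per_set, function(x) unique(as.character(x)))
  terms <- sort(unique(unlist(results_per_set)))
  tab <- data.frame(term = terms, stringsAsFactors = FALSE)
  for (nm in names(results_per_set)) tab[[nm]] <- terms %in% results_per_set[[nm]]
  tab$n_sets <- rowSums(as.matrix(tab[, names(results_per_set), drop = FALSE]))
  list(table = tab,
       n_terms = length(terms),
       n_shared = sum(tab$n_sets >= 2))
}

#' Transcription-factor binding frequency of a gene set
#'
#' Given a TF library (one set per TF listing its bound target genes), counts
#' for every gene of the query set how many TFs bind it, and summarises the
#' mean TF count per gene together with the distinct TFs touching the set.
#'
#' @param gene_set Non-empty set of gene ids.
#' @param tf_library A `gene_set_library` whose terms are TFs.
#' @return A `tf_frequency_summary`: list with `mean_tfs_per_gene`,
#'   `per_gene` (named integer vector; genes bound by no TF count 0),
#'   `tf_set` (TF ids touching the set), `per_tf_coverage` (named integer
#'   vector: genes of the set each TF binds).
#' @export
tf_binding_frequency <- function(gene_set, tf_library) {
  stopifnot(inherits(tf_library, "gene_set_library"))
  gene_set <- unique(as.character(gene_set))
  if (length(gene_set) == 0) stop("empty gene set")
  counts <- setNames(rep(0L, length(gene_set)), gene_set)
  coverage <- integer(0)
  for (tf in names(tf_library$sets)) {
    hit <- intersect(tf_library$sets[[tf]]$members, gene_set)
    if (length(hit) > 0) {
      counts[hit] <- counts[hit] + 1L
      coverage[[tf]] <- length(hit)
    }
  }
  structure(list(mean_tfs_per_gene = mean(counts),
                 per_gene = counts,
                 tf_set = names(coverage),
                 per_tf_coverage = coverage),
            class = "tf_frequency_summary")
}

#' @export
print.tf_frequency_summary <- function(x, ...) {
  cat(sprintf("tf_frequency_summary: %.2f TFs/gene over %d genes; %d distinct TFs\n",
              x$mean_tfs_per_gene, length(x$per_gene), length(x$tf_set)))
  invisible(x)
}
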