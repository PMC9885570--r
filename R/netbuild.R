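#' Construct a layered bipartite drug-gene network
#'
#' The multidimensional drug-gene network is bipartite (edges only between a
#' drug and a gene) with a layer label per edge: `target` edges encode
#' physical drug-protein binding, `sensitive` edges encode a significant
#' expression change under the drug. A (drug, gene) pair present in both
#' layers contributes two distinct typed edges, so the per-gene layer degrees
#' (KDTN, KDSN) remain independent sums.
#'
#' @param edges data.frame with columns `drug`, `gene`, `layer`
#'   (values in `target`/`sensitive`). Duplicated (drug, gene, layer) rows
#'   are collapsed.
#' @param drugs,genes Optional node sets; defaults to those seen in `edges`.
#'   Isolated nodes are allowed (e.g. an empty network with declared nodes).
#' @return A `layered_network`: list with `edges`, `drugs`, `genes`.
#' @export
layered_network <- function(edges, drugs = NULL, genes = NULL) {
  stopifnot(is.data.frame(edges), all(c("drug", "gene", "layer") %in% names(edges)))
  edges <- unique(edges[, c("drug", "gene", "layer")])
  stopifnot(all(edges$layer %in% c("target", "sensitive")))
  edges <- edges[order(edges$layer, edges$drug, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  drugs <- sort(unique(c(as.character(drugs), edges$drug)))
  genes <- sort(unique(c(as.character(genes), edges$gene)))
  stopifnot(length(intersect(drugs, genes)) == 0)
  structure(list(edges = edges, drugs = drugs, genes = genes),
            class = "layered_network")
}

#' @export
print.layered_network <- function(x, ...) {
  nt <- sum(x$edges$layer == "target")
  ns <- sum(x$edges$layer == "sensitive")
  cat(sprintf("layered_network: %d drugs, %d genes, %d target + %d sensitive edges\n",
              length(x$drugs), length(x$genes), nt, ns))
  invisible(x)
}

network_layers <- function(net) unique(net$edges$layer)

#' Build one network layer from binary (drug, gene) pairs
#'
#' @param pairs data.frame with columns `drug`, `gene`, or a
#'   `drug_target_table`, or a `signature_calls` object.
#' @param layer `"target"` or `"sensitive"`.
#' @return A single-layer `layered_network`.
#' @export
build_layer <- function(pairs, layer = c("target", "sensitive")) {
  layer <- match.arg(layer)
  if (inherits(pairs, "drug_target_table")) pairs <- pairs$pairs
  if (inherits(pairs, "signature_calls")) pairs <- pairs$pairs
  stopifnot(is.data.frame(pairs), all(c("drug", "gene") %in% names(pairs)))
  if (nrow(pairs) == 0) {
    return(layered_network(data.frame(drug = character(), gene = character(),
                                      layer = character())))
  }
  layered_network(data.frame(drug = pairs$drug, gene = pairs$gene, layer = layer,
                             stringsAsFactors = FALSE))
}

#' Extract a single-layer view (DTN or DSN) from a merged network
#'
#' Nodes left without edges in the selected layer are dropped.
#'
#' @param net A `layered_network`.
#' @param layer `"target"` or `"sensitive"`.
#' @return A single-layer `layered_network`.
#' @export
layer_view <- function(net, layer = c("target", "sensitive")) {
  layer <- match.arg(layer)
  e <- net$edges[net$edges$layer == layer, , drop = FALSE]
  layered_network(e)
}

#' Merge the drug-target and drug-sensitive layers
#'
#' Node sets are unions; the edge set is the disjoint-by-layer union, so a
#' pair bound and sensitive yields two typed edges.
#'
#' @param dtn Single-layer `layered_network` with layer `target`.
#' @param dsn Single-layer `layered_network` with layer `sensitive`.
#' @return A merged `layered_network`.
#' @export
merge_layers <- function(dtn, dsn) {
  stopifnot(inherits(dtn, "layered_network"), inherits(dsn, "layered_network"))
  lt <- network_layers(dtn); ls <- network_layers(dsn)
  if (length(setdiff(lt, "target")) > 0 || length(setdiff(ls, "sensitive")) > 0) {
    stop("merge_layers() expects a target-layer network and a sensitive-layer network, in that order")
  }
  layered_network(rbind(dtn$edges, dsn$edges),
                  drugs = union(dtn$drugs, dsn$drugs),
                  genes = union(dtn$genes, dsn$genes))
}

#' Compute per-gene KDTN and KDSN degree scores
#'
#' KDTN(g) is the number of distinct drugs with a target edge to gene g (the
#' gene's degree in the drug-target network); KDSN(g) likewise over sensitive
#' edges. Genes absent from a layer score 0 there; every gene node of the
#' network gets a row.
#'
#' @param net A `layered_network`.
#' @return A `gene_scores` data.frame with columns `gene`, `kdtn`, `kdsn`.
#' @export
compute_gene_scores <- function(net) {
  stopifnot(inherits(net, "layered_network"))
  genes <- net$genes
  count_layer <- function(layer) {
    e <- net$edges[net$edges$layer == layer, , drop = FALSE]
    tab <- table(factor(e$gene, levels = genes))
    as.integer(tab)
  }
  gene_scores(data.frame(gene = genes,
                         kdtn = count_layer("target"),
                         kdsn = count_layer("sensitive"),
                         stringsAsFactors = FALSE))
}

#' Construct a gene-scores object
#'
#' @param df data.frame with columns `gene`, `kdtn`, `kdsn`.
#' @return A `gene_scores` data.frame.
#' @export
gene_scores <- function(df) {
  stopifnot(all(c("gene", "kdtn", "kdsn") %in% names(df)))
  stopifnot(!anyDuplicated(df$gene))
  df$kdtn <- as.integer(df$kdtn); df$kdsn <- as.integer(df$kdsn)
  stopifnot(all(df$kdtn >= 0), all(df$kdsn >= 0))
  df <- df[order(df$gene), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_scores", "data.frame")
  df
}

#' Partition genes into DTG / DSG / DTSG sets
#'
#' DTG: KDTN >= 1 and KDSN = 0 (target-only). DSG: KDSN >= 1 and KDTN = 0
#' (sensitive-only). DTSG: both scores >= 1. The three sets are pairwise
#' disjoint and exhaust the scored genes.
#'
#' @param scores A `gene_scores` data.frame.
#' @return A `gene_set_partition`: list with `DTG`, `DSG`, `DTSG` gene-id
#'   vectors.
#' @export
partition_genes <- function(scores) {
  stopifnot(inherits(scores, "gene_scores"))
  t1 <- scores$kdtn >= 1; s1 <- scores$kdsn >= 1
  out <- structure(list(DTG = scores$gene[t1 & !s1],
                        DSG = scores$gene[!t1 & s1],
                        DTSG = scores$gene[t1 & s1]),
                   class = "gene_set_partition")
  out
}

#' @export
print.gene_set_partition <- function(x, ...) {
  cat(sprintf("gene_set_partition: |DTG| = %d, |DSG| = %d, |DTSG| = %d\n",
              length(x$DTG), length(x$DSG), length(x$DTSG)))
  invisible(x)
}

partition_label <- function(genes, partition) {
  stopifnot(inherits(partition, "gene_set_partition"))
  lab <- rep("none", length(genes))
  lab[genes %in% partition$DTG] <- "DTG"
  lab[genes %in% partition$DSG] <- "DSG"
  lab[genes %in% partition$DTSG] <- "DTSG"
  lab
}

#' Convert a partition to a three-set GMT library
#'
#' @param partition A `gene_set_partition`.
#' @return A `gene_set_library` with terms DTG, DSG, DTSG (empty sets dropped).
#' @export
partition_as_library <- function(partition) {
  sets <- list()
  for (nm in c("DTG", "DSG", "DTSG")) {
    if (length(partition[[nm]]) > 0) {
      sets[[nm]] <- list(description = sprintf("%s gene set", nm),
                         members = sort(partition[[nm]]))
    }
  }
  gene_set_library("partition", sets)
}

#' Sample a drug-anchored subnetwork
#'
#' Selects `round(fraction * n_drugs)` drugs (round half up, floored at 1)
#' uniformly at random with the given seed and returns the subgraph induced on
#' those drugs: all their gene neighbours with all edges to the selected
#' drugs, in both layers. This is the construction used for small
#' visualisation subnetworks (the paper-scale analysis used about 5% of the
#' dual-set drugs).
#'
#' @param net A `layered_network` with at least one drug.
#' @param fraction Drug fraction in (0, 1].
#' @param seed Integer seed for the drug draw.
#' @return A `layered_network`.
#' @export
sample_drug_subnetwork <- function(net, fraction, seed) {
  stopifnot(inherits(net, "layered_network"), length(net$drugs) >= 1)
  if (!is.numeric(fraction) || length(fraction) != 1 || fraction <= 0 || fraction > 1) {
    stop("fraction must be a single number in (0, 1]")
  }
  n <- max(1L, as.integer(floor(fraction * length(net$drugs) + 0.5)))
  picked <- withr_seed(seed, sample(net$drugs, n))
  e <- net$edges[net$edges$drug %in% picked, , drop = FALSE]
  layered_network(e, drugs = picked)
}

# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Convert a layered network to an igraph graph
#'
#' @param net A `layered_network`.
#' @param partition Optional `gene_set_partition`; attaches a `set` node
#'   attribute (DTG/DSG/DTSG/none).
#' @return An igraph object with node attributes `kind`, `set` and edge
#'   attribute `layer`.
#' @export
as_igraph <- function(net, partition = NULL) {
  stopifnot(inherits(net, "layered_network"))
  nodes <- data.frame(name = c(net$drugs, net$genes),
                      kind = c(rep("drug", length(net$drugs)),
                               rep("gene", length(net$genes))),
                      stringsAsFactors = FALSE)
  nodes$set <- rep("none", nrow(nodes))
  if (!is.null(partition)) nodes$set <- partition_label(nodes$name, partition)
  el <- net$edges
  igraph::graph_from_data_frame(
    data.frame(from = el$drug, to = el$gene, layer = el$layer,
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes)
}
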