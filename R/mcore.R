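#' m-core of a single-layer drug-gene network
#'
#' Iteratively peels the bipartite layer to the maximal subgraph in which
#' every gene node keeps layer degree >= m: gene nodes below the degree
#' constraint are deleted, drug nodes left with no edges are deleted, and the
#' process repeats to a fixed point. The result is the union of the connected
#' components of the residual graph (maximality then holds per component);
#' `largest_only = TRUE` keeps only the largest component.
#'
#' By default the degree constraint applies to gene nodes only (KDTN/KDSN are
#' gene-side degrees); `constrain = "all"` applies it to drug nodes too,
#' giving the classical bipartite k-core for sensitivity analysis.
#'
#' @param net A single-layer `layered_network`.
#' @param m Positive integer core parameter.
#' @param strict If TRUE, require degree > m instead of >= m.
#' @param constrain `"genes"` (default) or `"all"`.
#' @param largest_only Keep only the largest connected component.
#' @return A `layered_network` (possibly empty).
#' @export
m_core <- function(net, m, strict = FALSE, constrain = c("genes", "all"),
                   largest_only = FALSE) {
  constrain <- match.arg(constrain)
  stopifnot(inherits(net, "layered_network"))
  if (length(network_layers(net)) > 1) stop("m_core() requires a single-layer network")
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m != round(m)) {
    stop("m must be a positive integer >= 1")
  }
  ok <- if (strict) function(d) d > m else function(d) d >= m
  e <- net$edges
  repeat {
    gdeg <- table(e$gene)
    keep_gene <- names(gdeg)[ok(as.integer(gdeg))]
    e2 <- e[e$gene %in% keep_gene, , drop = FALSE]
    if (constrain == "all") {
      ddeg <- table(e2$drug)
      keep_drug <- names(ddeg)[ok(as.integer(ddeg))]
      e2 <- e2[e2$drug %in% keep_drug, , drop = FALSE]
    }
    # drugs with no remaining edges drop out implicitly (nodes come from edges)
    if (nrow(e2) == nrow(e)) break
    e <- e2
    if (nrow(e) == 0) break
  }
  core <- layered_network(e)
  if (largest_only && nrow(core$edges) > 0) {
    g <- as_igraph(core)
    comp <- igraph::components(g)
    keep <- igraph::V(g)$name[comp$membership == which.max(comp$csize)]
    core <- layered_network(core$edges[core$edges$gene %in% keep &
                                         core$edges$drug %in% keep, , drop = FALSE])
  }
  core
}

#' Full m-core peeling decomposition of one network layer
#'
#' Computes the m-core for m = 1, 2, ... until the core empties, records the
#' gene/drug membership and component count at every m, and assigns each gene
#' its core number (the largest m whose core contains it). Cores are nested:
#' cores(m+1) is a subgraph of cores(m).
#'
#' @param net A non-empty single-layer `layered_network`.
#' @inheritParams m_core
#' @return An `mcore_decomposition`: list with `layer`, `core_number`
#'   (named integer vector over genes), `cores` (list per m with
#'   `gene_members`, `drug_members`, `n_components`), `m_max`.
#' @export
peel_decomposition <- function(net, strict = FALSE, constrain = c("genes", "all"),
                               largest_only = FALSE) {
  constrain <- match.arg(constrain)
  stopifnot(inherits(net, "layered_network"))
  if (nrow(net$edges) == 0) stop("cannot decompose an empty network")
  layer <- network_layers(net)
  if (length(layer) != 1) stop("peel_decomposition() requires a single-layer network")
  cores <- list()
  core_number <- setNames(rep(0L, length(net$genes)), net$genes)
  m <- 1L
  current <- net
  repeat {
    current <- m_core(current, m, strict = strict, constrain = constrain,
                      largest_only = largest_only)
    if (nrow(current$edges) == 0) break
    n_comp <- as.integer(igraph::components(as_igraph(current))$no)
    cores[[m]] <- list(gene_members = current$genes,
                       drug_members = current$drugs,
                       n_components = n_comp)
    core_number[current$genes] <- m
    m <- m + 1L
  }
  if (length(cores) == 0) stop("no gene satisfies the degree constraint at m = 1")
  structure(list(layer = layer, core_number = core_number, cores = cores,
                 m_max = length(cores)),
            class = "mcore_decomposition")
}

#' @export
print.mcore_decomposition <- function(x, ...) {
  cat(sprintf("mcore_decomposition (%s layer): m_max = %d, %d genes scored\n",
              x$layer, x$m_max, length(x$core_number)))
  invisible(x)
}

#' Per-m core size profile
#'
#' @param dec An `mcore_decomposition`.
#' @return data.frame with one row per m: `m`, `n_genes`, `n_drugs`,
#'   `n_components`; gene counts are non-increasing in m.
#' @export
core_profile <- function(dec) {
  stopifnot(inherits(dec, "mcore_decomposition"))
  data.frame(m = seq_len(dec$m_max),
             n_genes = vapply(dec$cores, function(c) length(c$gene_members), integer(1)),
             n_drugs = vapply(dec$cores, function(c) length(c$drug_members), integer(1)),
             n_components = vapply(dec$cores, function(c) c$n_components, integer(1)))
}

#' Export core gene memberships as a GMT library
#'
#' One set per m (`term "m=K"`), members the genes of the m-core.
#'
#' @param dec An `mcore_decomposition`.
#' @return A `gene_set_library`.
#' @export
cores_as_library <- function(dec) {
  stopifnot(inherits(dec, "mcore_decomposition"))
  sets <- list()
  for (m in seq_len(dec$m_max)) {
    sets[[sprintf("M=%d", m)]] <- list(
      description = sprintf("%s-layer %d-core genes", dec$layer, m),
      members = sort(dec$cores[[m]]$gene_members))
  }
  gene_set_library(sprintf("mcore_%s", dec$layer), sets)
}
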