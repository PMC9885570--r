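#' @importFrom stats setNames
#' @importFrom utils read.delim write.table head
NULL

# Gene/drug identifiers are opaque strings; matching is deterministic after
# trimming whitespace and uppercasing (no online ID resolution).
normalize_id <- function(x) toupper(trimws(x))

#' Read a GMT gene-set library
#'
#' GMT is the tab-separated gene-set format used by MSigDB/DSigDB-style
#' libraries: one set per line, `term <TAB> description <TAB> member...`.
#' Duplicate members within a line are collapsed; duplicate term ids across
#' lines are an error.
#'
#' @param path Path to a GMT file.
#' @param name Library name; defaults to the file name.
#' @return A `gene_set_library`: list with `name` and `sets`, where `sets` is
#'   a named list of `list(description =, members =)`.
#' @export
read_gmt <- function(path, name = basename(path)) {
  stopifnot(file.exists(path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("malformed GMT line %d in '%s': fewer than 3 tab-separated fields", i, path))
    }
    term <- normalize_id(fields[[1]])
    if (term %in% names(sets)) {
      stop(sprintf("duplicate term id '%s' at GMT line %d", term, i))
    }
    members <- unique(normalize_id(fields[-(1:2)]))
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      stop(sprintf("GMT line %d ('%s') has no non-blank members", i, term))
    }
    sets[[term]] <- list(description = fields[[2]], members = members)
  }
  gene_set_library(name = name, sets = sets)
}

#' Construct a gene-set library
#'
#' @param name Library name.
#' @param sets Named list of `list(description, members)` entries.
#' @return A `gene_set_library` object.
#' @export
gene_set_library <- function(name, sets = list()) {
  stopifnot(is.character(name), length(name) == 1)
  if (length(sets) > 0) {
    stopifnot(!is.null(names(sets)), !anyDuplicated(names(sets)))
    for (s in sets) stopifnot(length(s$members) > 0)
  }
  structure(list(name = name, sets = sets), class = "gene_set_library")
}

#' @export
print.gene_set_library <- function(x, ...) {
  cat(sprintf("gene_set_library '%s': %d sets, %d distinct members\n",
              x$name, length(x$sets),
              length(unique(unlist(lapply(x$sets, `[[`, "members"))))))
  invisible(x)
}

#' Write a gene-set library as GMT
#'
#' @param library A `gene_set_library`.
#' @param path Output path.
#' @export
write_gmt <- function(library, path) {
  stopifnot(inherits(library, "gene_set_library"))
  lines <- vapply(names(library$sets), function(term) {
    s <- library$sets[[term]]
    paste(c(term, s$description, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a drug-target membership table
#'
#' Accepts two dialects: `two-column-tsv` (rows `drug <TAB> gene`, optional
#' header) and `gmt` (one drug per line, members are its target genes).
#' Repeated (drug, gene) rows are deduplicated — the model is binary.
#' Rows with a blank gene id are rejected and counted in the
#' `n_rejected` attribute.
#'
#' @param path Input file.
#' @param dialect `"two-column-tsv"` or `"gmt"`.
#' @return A `drug_target_table`: list with `pairs` (data.frame drug/gene),
#'   `drugs`, `genes`.
#' @export
read_drug_target_table <- function(path, dialect = c("two-column-tsv", "gmt")) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  if (dialect == "gmt") {
    lib <- read_gmt(path)
    if (length(lib$sets) == 0) stop(sprintf("empty drug-target file '%s'", path))
    pairs <- do.call(rbind, lapply(names(lib$sets), function(d) {
      data.frame(drug = d, gene = lib$sets[[d]]$members, stringsAsFactors = FALSE)
    }))
    n_rejected <- 0L
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) stop(sprintf("empty drug-target file '%s'", path))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- vapply(fields, length, integer(1)) < 2
    if (any(bad)) stop(sprintf("drug-target TSV line %d has fewer than 2 fields", which(bad)[1]))
    df <- data.frame(drug = normalize_id(vapply(fields, `[[`, "", 1)),
                     gene = normalize_id(vapply(fields, `[[`, "", 2)),
                     stringsAsFactors = FALSE)
    # tolerate a header row
    if (nrow(df) > 0 && df$drug[1] %in% c("DRUG", "DRUG_ID") && df$gene[1] %in% c("GENE", "GENE_ID")) {
      df <- df[-1, , drop = FALSE]
    }
    blank <- !nzchar(df$gene) | !nzchar(df$drug)
    n_rejected <- sum(blank)
    if (n_rejected > 0) {
      warning(sprintf("%d row(s) with blank drug/gene id rejected", n_rejected))
      df <- df[!blank, , drop = FALSE]
    }
    pairs <- df
  }
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs$drug, pairs$gene), , drop = FALSE]
  rownames(pairs) <- NULL
  out <- drug_target_table(pairs)
  attr(out, "n_rejected") <- n_rejected
  message(sprintf("drug-target table: %d pairs, %d drugs, %d genes (%d rejected rows)",
                  nrow(out$pairs), length(out$drugs), length(out$genes), n_rejected))
  out
}

#' Construct a drug-target table from a pair data frame
#'
#' @param pairs data.frame with columns `drug`, `gene`.
#' @return A `drug_target_table`.
#' @export
drug_target_table <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("drug", "gene") %in% names(pairs)))
  pairs <- unique(pairs[, c("drug", "gene")])
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 drugs = sort(unique(pairs$drug)),
                 genes = sort(unique(pairs$gene))),
            class = "drug_target_table")
}

#' Write a drug-target table as two-column TSV
#'
#' @param table A `drug_target_table`.
#' @param path Output path.
#' @export
write_drug_target_table <- function(table, path) {
  stopifnot(inherits(table, "drug_target_table"))
  p <- table$pairs[order(table$pairs$drug, table$pairs$gene), ]
  write.table(p, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = c("drug", "gene"))
  invisible(path)
}

#' Read a per-drug differential-expression signature table
#'
#' Expects a TSV with a header naming at least `drug`, `gene`, `fc`
#' (fold change, linear scale) and one of `p` / `p_adj`. Rows with
#' non-numeric fold change or p-values are rejected and counted; a duplicated
#' (drug, gene) row is an error (the statistics would be ambiguous).
#'
#' @param path Input TSV.
#' @return A `signature_table`: data.frame with columns drug, gene, fc, p,
#'   p_adj (missing p columns filled with NA), plus an `n_rejected` attribute.
#' @export
read_signature_table <- function(path) {
  stopifnot(file.exists(path))
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  for (col in c("drug", "gene", "fc")) {
    if (!col %in% names(df)) stop(sprintf("signature table '%s' is missing mandatory column '%s'", path, col))
  }
  if (!any(c("p", "p_adj") %in% names(df))) {
    stop(sprintf("signature table '%s' is missing a p-value column ('p' or 'p_adj')", path))
  }
  if (!"p" %in% names(df)) df$p <- NA_real_
  if (!"p_adj" %in% names(df)) df$p_adj <- NA_real_
  df$drug <- normalize_id(df$drug)
  df$gene <- normalize_id(df$gene)
  fc <- suppressWarnings(as.numeric(df$fc))
  p <- suppressWarnings(as.numeric(df$p))
  p_adj <- suppressWarnings(as.numeric(df$p_adj))
  bad_fc <- is.na(fc) | fc <= 0
  bad_p <- (is.na(p) & is.na(p_adj))
  reject <- bad_fc | bad_p
  n_rejected <- sum(reject)
  if (any(!is.na(fc) & fc <= 0)) {
    warning("fold changes <= 0 found: fc must be on the linear scale (convert log fold changes first)")
  }
  if (n_rejected > 0) warning(sprintf("%d signature row(s) rejected (non-numeric fc/p)", n_rejected))
  out <- data.frame(drug = df$drug, gene = df$gene, fc = fc, p = p, p_adj = p_adj,
                    stringsAsFactors = FALSE)[!reject, , drop = FALSE]
  dup <- duplicated(out[, c("drug", "gene")])
  if (any(dup)) {
    d <- out[dup, ][1, ]
    stop(sprintf("duplicated (drug, gene) record in '%s': (%s, %s)", path, d$drug, d$gene))
  }
  rownames(out) <- NULL
  out <- signature_table(out)
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Construct a signature table
#'
#' @param records data.frame with columns drug, gene, fc and p and/or p_adj.
#' @return A `signature_table` (a validated data.frame).
#' @export
signature_table <- function(records) {
  stopifnot(is.data.frame(records), all(c("drug", "gene", "fc") %in% names(records)))
  if (!"p" %in% names(records)) records$p <- NA_real_
  if (!"p_adj" %in% names(records)) records$p_adj <- NA_real_
  records <- records[, c("drug", "gene", "fc", "p", "p_adj")]
  stopifnot(!any(duplicated(records[, c("drug", "gene")])))
  stopifnot(all(records$fc > 0))
  stopifnot(all(!is.na(records$p) | !is.na(records$p_adj)))
  ok_p <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
  stopifnot(ok_p(records$p), ok_p(records$p_adj))
  rownames(records) <- NULL
  class(records) <- c("signature_table", "data.frame")
  records
}

#' Write a signature table as TSV
#'
#' @param table A `signature_table`.
#' @param path Output path.
#' @export
write_signature_table <- function(table, path) {
  df <- as.data.frame(table)[order(table$drug, table$gene), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write per-gene KDTN/KDSN scores as TSV
#'
#' Columns `gene`, `kdtn`, `kdsn`, `set`; one row per gene, sorted by gene id.
#' The `set` column carries the DTG/DSG/DTSG partition label when a partition
#' is supplied, `"none"` otherwise.
#'
#' @param scores A `gene_scores` data.frame (see [compute_gene_scores()]).
#' @param path Output path.
#' @param partition Optional `gene_set_partition`.
#' @export
write_gene_scores <- function(scores, path, partition = NULL) {
  stopifnot(inherits(scores, "gene_scores"))
  df <- as.data.frame(scores)
  df$set <- if (is.null(partition)) rep("none", nrow(df)) else partition_label(df$gene, partition)
  df <- df[order(df$gene), c("gene", "kdtn", "kdsn", "set")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-score TSV written by [write_gene_scores()]
#'
#' @param path Input path.
#' @return A `gene_scores` data.frame (the `set` column is kept if present).
#' @export
read_gene_scores <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "kdtn", "kdsn") %in% names(df)))
  gene_scores(df)
}

#' Export a layered drug-gene network as GraphML
#'
#' Nodes carry attribute `kind` (`drug`/`gene`) and `set` (DTG/DSG/DTSG/none
#' when a partition is attached); edges carry `layer` (`target`/`sensitive`).
#'
#' @param network A `layered_network`.
#' @param path Output path.
#' @param partition Optional `gene_set_partition` for the `set` attribute.
#' @export
write_graphml <- function(network, path, partition = NULL) {
  g <- as_igraph(network, partition = partition)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML file written by [write_graphml()]
#'
#' @param path Input path.
#' @return A `layered_network` (node `set` attributes are not retained in the
#'   network object; they live in score tables).
#' @export
read_graphml_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::vcount(g) == 0) {
    return(layered_network(data.frame(drug = character(), gene = character(),
                                      layer = character())))
  }
  kind <- igraph::vertex_attr(g, "kind")
  name <- igraph::vertex_attr(g, "name")
  el <- igraph::as_edgelist(g, names = TRUE)
  layer <- igraph::edge_attr(g, "layer")
  is_drug <- setNames(kind == "drug", name)
  drug <- ifelse(is_drug[el[, 1]], el[, 1], el[, 2])
  gene <- ifelse(is_drug[el[, 1]], el[, 2], el[, 1])
  layered_network(data.frame(drug = drug, gene = gene, layer = layer,
                             stringsAsFactors = FALSE),
                  drugs = name[kind == "drug"], genes = name[kind == "gene"])
}
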