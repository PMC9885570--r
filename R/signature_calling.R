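#' Configuration for drug-signature calling
#'
#' A (drug, gene) pair is called drug-sensitive (s_ij = 1) when its adjusted
#' p-value is strictly below `p_threshold` AND its linear-scale fold change is
#' strictly outside `[fc_lower, fc_upper]` (upregulation FC > 2 or
#' downregulation FC < 0.5 at the defaults). All inequalities are strict, as
#' the thresholds are conventionally printed.
#'
#' @param p_threshold Adjusted p-value threshold (default 0.05).
#' @param fc_upper Upregulation fold-change threshold (default 2).
#' @param fc_lower Downregulation fold-change threshold (default 0.5).
#' @param adjust_method `"BH"` to Benjamini-Hochberg-adjust the raw `p`
#'   column, `"none"` to use the supplied `p_adj` column as-is.
#' @param adjust_scope `"per-drug"` treats each drug's profile as its own
#'   testing family (CMap-style per-compound contrasts); `"global"` adjusts
#'   across all records at once.
#' @return A `signature_config` list.
#' @export
signature_config <- function(p_threshold = 0.05, fc_upper = 2, fc_lower = 0.5,
                             adjust_method = c("none", "BH"),
                             adjust_scope = c("per-drug", "global")) {
  adjust_method <- match.arg(adjust_method)
  adjust_scope <- match.arg(adjust_scope)
  stopifnot(p_threshold > 0, p_threshold <= 1)
  stopifnot(fc_lower < 1, fc_upper > 1)
  if (abs(fc_lower - 1 / fc_upper) > 1e-8) {
    warning("fc_lower != 1/fc_upper: the up/down branches are not reciprocal")
  }
  structure(list(p_threshold = p_threshold, fc_upper = fc_upper,
                 fc_lower = fc_lower, adjust_method = adjust_method,
                 adjust_scope = adjust_scope),
            class = "signature_config")
}

#' Benjamini-Hochberg adjust a vector of p-values
#'
#' Step-up FDR adjustment; output order matches input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method Only `"BH"` is supported.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = "BH") {
  stopifnot(identical(method, "BH"))
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1] and non-missing")
  stats::p.adjust(p, method = "BH")
}

#' Call binary drug-sensitive signatures from expression statistics
#'
#' Applies the threshold rule of [signature_config()] to every record of a
#' signature table. Records never seen for a drug are simply uncalled
#' (s_ij = 0); no imputation.
#'
#' @param table A `signature_table`.
#' @param config A `signature_config`.
#' @return A `signature_calls` object: list with `pairs` (data.frame
#'   drug/gene of the called s_ij = 1 pairs), `config`, `n_tested`.
#' @export
call_signatures <- function(table, config = signature_config()) {
  stopifnot(inherits(table, "signature_table"), inherits(config, "signature_config"))
  df <- as.data.frame(table)
  if (config$adjust_method == "none") {
    missing_adj <- is.na(df$p_adj)
    if (any(missing_adj)) {
      r <- df[missing_adj, ][1, ]
      stop(sprintf("adjust_method 'none' but record (%s, %s) has no adjusted p-value",
                   r$drug, r$gene))
    }
    padj <- df$p_adj
  } else {
    if (any(is.na(df$p))) stop("adjust_method 'BH' requires a raw p-value for every record")
    padj <- if (nrow(df) == 0) numeric(0)
            else if (config$adjust_scope == "global") adjust_pvalues(df$p)
            else stats::ave(df$p, df$drug, FUN = adjust_pvalues)
  }
  called <- padj < config$p_threshold &
    (df$fc > config$fc_upper | df$fc < config$fc_lower)
  pairs <- df[called, c("drug", "gene"), drop = FALSE]
  pairs <- pairs[order(pairs$drug, pairs$gene), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, config = config, n_tested = nrow(df)),
            class = "signature_calls")
}

#' @export
print.signature_calls <- function(x, ...) {
  cat(sprintf("signature_calls: %d called pairs of %d tested (%d drugs)\n",
              nrow(x$pairs), x$n_tested, length(unique(x$pairs$drug))))
  invisible(x)
}

#' Convert signature calls to a per-drug GMT library
#'
#' @param calls A `signature_calls` object.
#' @return A `gene_set_library` with one set per drug.
#' @export
calls_as_library <- function(calls) {
  stopifnot(inherits(calls, "signature_calls"))
  sets <- lapply(split(calls$pairs$gene, calls$pairs$drug), function(g) {
    list(description = "drug-sensitive genes", members = sort(unique(g)))
  })
  gene_set_library("signature_calls", sets)
}
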