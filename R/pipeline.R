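pipeline_schema <- c(
  "target_table", "target_dialect", "signature_table",
  "libraries", "tf_library", "signature",
  "sample_fraction", "seed",
  "mcore", "ora", "out_dir", "plots"
)
signature_schema <- c("p_threshold", "fc_upper", "fc_lower",
                      "adjust_method", "adjust_scope")
mcore_schema <- c("strict", "constrain", "largest_only", "min_genes")
ora_schema <- c("fdr_threshold")

#' Validate a pipeline configuration
#'
#' Reads a YAML or JSON configuration (or takes an R list), checks it against
#' a strict schema — unknown keys are rejected, since silent typos are the
#' dominant pipeline failure mode — and reports every violation at once, not
#' just the first.
#'
#' @param config Path to a YAML/JSON file, or a named list.
#' @return A validated `pipeline_config` list with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    stopifnot(file.exists(config))
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  violations <- character(0)
  add <- function(msg) violations <<- c(violations, msg)

  unknown <- setdiff(names(config), pipeline_schema)
  if (length(unknown) > 0) {
    add(sprintf("unknown key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (is.null(config$target_table)) {
    add("missing required key 'target_table'")
  } else if (!file.exists(config$target_table)) {
    add(sprintf("target_table path does not exist: '%s'", config$target_table))
  }
  if (is.null(config$signature_table)) {
    add("missing required key 'signature_table'")
  } else if (!file.exists(config$signature_table)) {
    add(sprintf("signature_table path does not exist: '%s'", config$signature_table))
  }
  config$target_dialect <- config$target_dialect %||% "two-column-tsv"
  if (!config$target_dialect %in% c("two-column-tsv", "gmt")) {
    add(sprintf("target_dialect must be 'two-column-tsv' or 'gmt', got '%s'",
                config$target_dialect))
  }
  for (lib in c(unlist(config$libraries), config$tf_library)) {
    if (!is.null(lib) && !file.exists(lib)) add(sprintf("library path does not exist: '%s'", lib))
  }
  if (!is.null(config$sample_fraction)) {
    f <- config$sample_fraction
    if (!is.numeric(f) || f <= 0 || f > 1) {
      add(sprintf("sample_fraction must be in (0, 1], got %s", format(f)))
    }
    if (is.null(config$seed)) add("'seed' is mandatory when sample_fraction is set")
  }
  check_sub <- function(name, allowed) {
    sub <- config[[name, exact = TRUE]]
    if (!is.null(sub)) {
      bad <- setdiff(names(sub), allowed)
      if (length(bad) > 0) add(sprintf("unknown key(s) under '%s': %s", name,
                                       paste(bad, collapse = ", ")))
    }
  }
  check_sub("signature", signature_schema)
  check_sub("mcore", mcore_schema)
  check_sub("ora", ora_schema)
  if (length(violations) > 0) {
    stop(paste(c("invalid pipeline config:", paste(" -", violations)),
               collapse = "\n"), call. = FALSE)
  }
  config$out_dir <- config$out_dir %||% "landscape_run"
  config$plots <- isTRUE(config$plots)
  mc <- config$mcore %||% list()
  config$mcore <- list(strict = isTRUE(mc$strict),
                       constrain = mc$constrain %||% "genes",
                       largest_only = isTRUE(mc$largest_only),
                       min_genes = mc$min_genes %||% 50L)
  config$ora <- list(fdr_threshold = (config$ora %||% list())$fdr_threshold %||% 0.05)
  sg <- config[["signature"]] %||% list()
  config[["signature"]] <- signature_config(
    p_threshold = sg$p_threshold %||% 0.05,
    fc_upper = sg$fc_upper %||% 2,
    fc_lower = sg$fc_lower %||% 0.5,
    adjust_method = sg$adjust_method %||% "none",
    adjust_scope = sg$adjust_scope %||% "per-drug")
  structure(config, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage <- function(name, log, expr) {
  log(sprintf("[stage %s] start", name))
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full drug-gene landscape pipeline
#'
#' Orchestrates: load tables, call signatures, build and merge the DTN and
#' DSN layers, score genes (KDTN/KDSN), partition into DTG/DSG/DTSG,
#' characterise degree distributions (CCDF + discrete power-law fits +
#' two-sample KS representativeness), peel each layer into m-cores, and — if
#' annotation/TF libraries are supplied — run over-representation and
#' TF-frequency analyses. Analyses lacking inputs are skipped with a log
#' notice. All artifacts land under `out_dir`; a machine-readable run summary
#' is written as JSON and returned.
#'
#' @param config A `pipeline_config` from [validate_config()] (paths/lists
#'   are validated on the fly).
#' @param quiet Suppress stage logging.
#' @return The run summary (list), invisibly.
#' @export
run_landscape <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  log <- if (quiet) function(...) invisible() else function(msg) message(msg)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  skipped <- character(0)

  target <- stage("load", log, {
    tt <- suppressMessages(read_drug_target_table(config$target_table,
                                                  dialect = config$target_dialect))
    log(sprintf("  target table: %d pairs / %d drugs / %d genes",
                nrow(tt$pairs), length(tt$drugs), length(tt$genes)))
    tt
  })
  sig_table <- stage("load", log, read_signature_table(config$signature_table))

  calls <- stage("signature_calling", log, {
    cl <- call_signatures(sig_table, config$signature)
    log(sprintf("  %d of %d records called sensitive", nrow(cl$pairs), cl$n_tested))
    cl
  })

  res <- stage("netbuild", log, {
    dtn <- build_layer(target, "target")
    dsn <- build_layer(calls, "sensitive")
    merged <- merge_layers(dtn, dsn)
    scores <- compute_gene_scores(merged)
    partition <- partition_genes(scores)
    write_gene_scores(scores, file.path(out, "gene_scores.tsv"), partition)
    write_gmt(partition_as_library(partition), file.path(out, "partition.gmt"))
    write_graphml(merged, file.path(out, "network.graphml"), partition)
    if (!is.null(config$sample_fraction)) {
      sub <- sample_drug_subnetwork(merged, config$sample_fraction, config$seed)
      write_graphml(sub, file.path(out, "subnetwork.graphml"), partition)
    }
    list(dtn = dtn, dsn = dsn, merged = merged, scores = scores,
         partition = partition)
  })
  scores <- res$scores
  partition <- res$partition

  fits <- stage("degree_stats", log, {
    rows <- list()
    for (ly in c("kdtn", "kdsn")) {
      deg <- scores[[ly]][scores[[ly]] >= 1]
      if (length(unique(deg)) < 2) {
        skipped <- c(skipped, sprintf("degree_stats:%s", ly)); next
      }
      fit <- fit_power_law(deg, xmin = "auto")
      rc <- reverse_cumulative(deg)
      write.table(as.data.frame(rc), file.path(out, sprintf("ccdf_%s.tsv", ly)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      dual <- scores[[ly]][scores$kdtn >= 1 & scores$kdsn >= 1]
      ks <- if (length(dual) > 0) compare_distributions(dual, deg) else
        list(statistic = NA_real_, p_value = NA_real_)
      rows[[ly]] <- data.frame(score = toupper(ly), alpha = fit$alpha,
                               xmin = fit$xmin, n_tail = fit$n_tail,
                               ks_distance = fit$ks_distance,
                               dual_vs_all_ks = ks$statistic,
                               dual_vs_all_p = ks$p_value)
    }
    fits <- do.call(rbind, rows)
    if (!is.null(fits)) {
      write.table(fits, file.path(out, "power_law_fits.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    fits
  })

  mcore <- stage("mcore", log, {
    profs <- list()
    for (ly in c("target", "sensitive")) {
      net <- layer_view(res$merged, ly)
      if (length(net$genes) <= config$mcore$min_genes) {
        log(sprintf("  mcore: %s layer has <= %d genes, skipped", ly,
                    config$mcore$min_genes))
        skipped <- c(skipped, sprintf("mcore:%s", ly))
        next
      }
      dec <- peel_decomposition(net, strict = config$mcore$strict,
                                constrain = config$mcore$constrain,
                                largest_only = config$mcore$largest_only)
      prof <- core_profile(dec)
      write.table(prof, file.path(out, sprintf("mcore_profile_%s.tsv", ly)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_gmt(cores_as_library(dec), file.path(out, sprintf("mcore_%s.gmt", ly)))
      profs[[ly]] <- dec$m_max
    }
    profs
  })

  universe <- scores$gene
  sets <- list(DTG = partition$DTG, DSG = partition$DSG, DTSG = partition$DTSG)
  sets <- Filter(function(s) length(s) > 0, sets)

  if (length(config$libraries) > 0) {
    stage("enrichment", log, {
      for (lib_name in names(config$libraries)) {
        lib <- read_gmt(config$libraries[[lib_name]], name = lib_name)
        sig_terms <- list()
        for (set_name in names(sets)) {
          ora <- hypergeometric_ora(sets[[set_name]], universe, lib,
                                    fdr_threshold = config$ora$fdr_threshold)
          write.table(ora, file.path(out, sprintf("ora_%s_%s.tsv", lib_name, set_name)),
                      sep = "\t", quote = FALSE, row.names = FALSE)
          sig_terms[[set_name]] <- ora$term[ora$significant]
        }
        if (length(sig_terms) >= 2) {
          ov <- term_overlap(sig_terms)
          write.table(ov$table, file.path(out, sprintf("term_overlap_%s.tsv", lib_name)),
                      sep = "\t", quote = FALSE, row.names = FALSE)
          jsonlite::write_json(list(n_terms = ov$n_terms, n_shared = ov$n_shared),
                               file.path(out, sprintf("term_overlap_%s.json", lib_name)),
                               auto_unbox = TRUE)
        }
      }
    })
  } else {
    skipped <- c(skipped, "enrichment")
    log("  enrichment: no annotation libraries supplied, skipped")
  }

  if (!is.null(config$tf_library)) {
    stage("tf_analysis", log, {
      tf_lib <- read_gmt(config$tf_library, name = "tf")
      rows <- lapply(names(sets), function(set_name) {
        s <- tf_binding_frequency(sets[[set_name]], tf_lib)
        data.frame(set = set_name, n_genes = length(s$per_gene),
                   mean_tfs_per_gene = s$mean_tfs_per_gene,
                   n_distinct_tfs = length(s$tf_set))
      })
      write.table(do.call(rbind, rows), file.path(out, "tf_frequency.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    })
  } else {
    skipped <- c(skipped, "tf_analysis")
    log("  tf_analysis: no TF library supplied, skipped")
  }

  summary <- list(
    n_drugs = length(res$merged$drugs),
    n_genes = length(res$merged$genes),
    n_target_edges = sum(res$merged$edges$layer == "target"),
    n_sensitive_edges = sum(res$merged$edges$layer == "sensitive"),
    partition = list(DTG = length(partition$DTG), DSG = length(partition$DSG),
                     DTSG = length(partition$DTSG)),
    kdtn_range = if (any(scores$kdtn >= 1)) range(scores$kdtn[scores$kdtn >= 1]) else c(0L, 0L),
    kdsn_range = if (any(scores$kdsn >= 1)) range(scores$kdsn[scores$kdsn >= 1]) else c(0L, 0L),
    m_max = mcore,
    n_signature_records = calls$n_tested,
    n_called = nrow(calls$pairs),
    skipped = as.list(skipped),
    config = list(p_threshold = config$signature$p_threshold,
                  fc_upper = config$signature$fc_upper,
                  fc_lower = config$signature$fc_lower,
                  seed = config$seed),
    version = as.character(utils::packageVersion("druglandscape")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(summary, file.path(out, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log(sprintf("run complete: %d drugs, %d genes, partition %d/%d/%d",
              summary$n_drugs, summary$n_genes, summary$partition$DTG,
              summary$partition$DSG, summary$partition$DTSG))
  invisible(summary)
}
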