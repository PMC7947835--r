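# End-to-end orchestration: load annotated genomes, build ortholog sets,
# audit initiation codons, tabulate codon usage, compare gene orders, and
# write a deterministic report bundle.

.CONFIG_KEYS <- c("input", "format", "table_id", "extended_starts", "window",
                  "allow_novel", "include_trnas", "genes", "out_dir", "seed",
                  "log_level")

#' Build and validate a run configuration
#'
#' All fields mirror CLI flags. Unknown keys are rejected before any I/O.
#'
#' @param input Character vector of genome files, or one directory.
#' @param format `"genbank"` or `"gff3"` (GFF3 inputs are `<stem>.fasta` +
#'   `<stem>.gff3` pairs).
#' @param table_id NCBI translation table (1, 5 or 9).
#' @param extended_starts Extra start codons recognized by the audit
#'   (overrides the table default; `NULL` keeps [get_table()]'s extended
#'   set for table 9).
#' @param window Audit scan window, codons.
#' @param allow_novel Permit novel-codon calls.
#' @param include_trnas Include tRNAs in gene orders.
#' @param genes Genes to audit (default: canonical 13 PCGs).
#' @param out_dir Output directory.
#' @param seed Seed for any stochastic stage.
#' @param log_level `"info"` or `"quiet"`.
#' @param ... Unknown keys (rejected).
#' @return A validated `run_config` list.
#' @export
run_config <- function(input, format = c("genbank", "gff3"), table_id = 9L,
                       extended_starts = NULL, window = 5L,
                       allow_novel = FALSE, include_trnas = FALSE,
                       genes = NULL, out_dir = ".", seed = 1L,
                       log_level = c("info", "quiet"), ...) {
  extras <- list(...)
  if (length(extras)) {
    stop("unknown config keys: ", paste(names(extras), collapse = ","),
         call. = FALSE)
  }
  format <- match.arg(format)
  log_level <- match.arg(log_level)
  stopifnot(table_id %in% c(1L, 5L, 9L), window >= 1L)
  structure(list(input = input, format = format, table_id = as.integer(table_id),
                 extended_starts = extended_starts, window = as.integer(window),
                 allow_novel = isTRUE(allow_novel),
                 include_trnas = isTRUE(include_trnas), genes = genes,
                 out_dir = out_dir, seed = as.integer(seed),
                 log_level = log_level),
            class = "run_config")
}

#' Read a YAML run-configuration file
#'
#' Keys mirror [run_config()] arguments; unknown keys are rejected.
#' @param path YAML file.
#' @param ... Overrides applied after the file (CLI wins over file).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  bad <- setdiff(names(vals), .CONFIG_KEYS)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ","),
                        call. = FALSE)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

.load_genomes <- function(config) {
  paths <- config$input
  if (length(paths) == 1L && dir.exists(paths)) {
    ext <- if (config$format == "genbank") "\\.(gb|gbk|genbank)$" else "\\.gff3?$"
    paths <- sort(list.files(paths, pattern = ext, full.names = TRUE))
  }
  if (config$format == "genbank") {
    lapply(paths, read_genbank, table_id = config$table_id)
  } else {
    lapply(paths, function(p) {
      stem <- sub("\\.gff3?$", "", p)
      fa <- c(paste0(stem, ".fasta"), paste0(stem, ".fa"))
      fa <- fa[file.exists(fa)][1]
      if (is.na(fa)) stop("no FASTA found for ", p, call. = FALSE)
      read_fasta_gff3(fa, p, table_id = config$table_id)
    })
  }
}

#' Run the full comparative-annotation audit
#'
#' Loads >= 2 annotated genomes, pools conspecific records, builds
#' per-gene ortholog sets, audits every member's initiation codon,
#' tabulates codon usage, derives gene orders and their pairwise
#' breakpoint distances, and writes a deterministic report bundle:
#' `audit.tsv`, `usage.tsv`, `order.tsv`, `summary.json` and `run.log`
#' (no timestamps in payload files; reruns on identical inputs are
#' byte-identical). Per-gene failures are caught and reported in the
#' summary's `failures` section rather than aborting the run.
#'
#' @param config A `run_config` (or list coerced through [run_config()]).
#' @return Invisibly, a list with `calls`, `usage`, `orders`, `distances`,
#'   `summary` and the output paths.
#' @export
run_full_audit <- function(config) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    if (config$log_level == "info") message(msg)
  }
  cat("", file = log_path)  # truncate

  records <- .load_genomes(config)
  if (length(records) < 2L) stop("need >= 2 readable genomes", call. = FALSE)
  logf("loaded %d genomes", length(records))
  records <- pool_duplicates(records)
  logf("%d terminals after pooling conspecific records", length(records))

  table <- get_table(config$table_id, extended = config$table_id == 9L)
  if (!is.null(config$extended_starts)) {
    table$extended_starts <- toupper(config$extended_starts)
  }

  failures <- list()
  calls <- tryCatch(
    audit_cohort(records, table, genes = config$genes,
                 window = config$window, allow_novel = config$allow_novel),
    error = function(e) e)
  if (inherits(calls, "error")) {
    # fall back to single-pass per-gene audits so one broken gene cannot
    # sink the run; record what failed
    calls <- .empty_calls()
    osets <- suppressWarnings(build_ortholog_sets(records,
                                                  genes = config$genes))
    for (os in osets) {
      res <- tryCatch(
        audit_gene(os, records, table, window = config$window,
                   allow_novel = config$allow_novel),
        error = function(e) e)
      if (inherits(res, "error")) {
        failures[[os$gene_label]] <- conditionMessage(res)
        logf("audit failed for %s: %s", os$gene_label, conditionMessage(res))
      } else {
        calls <- rbind(calls, res)
      }
    }
  }
  usage <- codon_usage(calls)

  orders <- list()
  for (r in records) {
    res <- tryCatch(order_from_record(r, include_trnas = config$include_trnas),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[paste0("order:", r$taxon)]] <- conditionMessage(res)
    } else {
      orders[[r$taxon]] <- res
    }
  }
  distances <- if (length(orders) >= 2L) order_distance_matrix(orders) else NULL

  # ---- report bundle
  audit_path <- file.path(config$out_dir, "audit.tsv")
  write_audit_report(calls, audit_path)

  usage_path <- file.path(config$out_dir, "usage.tsv")
  um <- cbind(taxon = rownames(usage$matrix), usage$matrix)
  utils::write.table(um, usage_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  order_path <- file.path(config$out_dir, "order.tsv")
  ol <- data.frame(taxon = names(orders),
                   order = vapply(orders, format_gene_order, character(1)),
                   stringsAsFactors = FALSE)
  utils::write.table(ol[order(ol$taxon), , drop = FALSE], order_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- list(
    n_genomes = length(records),
    table_id = config$table_id,
    recognized_starts = c(table$canonical_starts, table$extended_starts),
    verdict_counts = as.list(table(calls$verdict)),
    per_gene_tallies = usage$tallies,
    pairwise_breakpoint_distances =
      if (!is.null(distances)) {
        stats::setNames(lapply(rownames(distances), function(tx)
          as.list(distances[tx, ])), rownames(distances))
      } else NULL,
    failures = failures
  )
  summary_path <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  logf("audit: %d calls (%s)", nrow(calls),
       paste(sprintf("%s=%d", names(table(calls$verdict)),
                     table(calls$verdict)), collapse = ", "))

  invisible(list(calls = calls, usage = usage, orders = orders,
                 distances = distances, summary = summary,
                 paths = c(audit = audit_path, usage = usage_path,
                           order = order_path, summary = summary_path,
                           log = log_path)))
}
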