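# Cross-taxon ortholog sets, grouped by normalized gene label. Grouping is
# annotation-driven (no homology search); partial-genome records contribute
# only full-length genes.

#' Pool conspecific records into single terminals
#'
#' Records sharing a taxon name are merged into one terminal. Records in a
#' group are ranked by completeness: fewer partial-flagged features first,
#' then longer genome, then accession (for determinism). The pooled record
#' is the top-ranked one; for each gene the copy from the most complete
#' record carrying a full-length copy wins. Winning copies that live in a
#' lesser record are attached as coordinate-free `extra_genes` (sequence
#' plus provenance), and any out-competed partial copy in the primary
#' record is dropped.
#'
#' @param records List of `mitogenome_record`.
#' @param taxon_key Optional taxon name; if given, only that taxon's
#'   records are pooled and all others pass through unchanged.
#' @return List of `mitogenome_record`, one per taxon pooled.
#' @export
pool_duplicates <- function(records, taxon_key = NULL) {
  stopifnot(length(records) >= 1L)
  taxa <- vapply(records, `[[`, character(1), "taxon")
  groups <- split(seq_along(records), taxa)
  out <- list()
  for (tx in sort(names(groups))) {
    idx <- groups[[tx]]
    if (length(idx) == 1L ||
        (!is.null(taxon_key) && tx != taxon_key)) {
      out <- c(out, records[idx])
      next
    }
    grp <- records[idx]
    n_partial <- vapply(grp, function(r)
      sum(r$features$partial_5prime | r$features$partial_3prime), integer(1))
    glen <- vapply(grp, function(r) nchar(r$sequence), integer(1))
    accs <- vapply(grp, `[[`, character(1), "accession")
    rank <- order(n_partial, -glen, accs)
    grp <- grp[rank]
    primary <- grp[[1L]]
    # per-gene best copy: first record (in completeness order) with a
    # full-length copy; else first with any copy
    labels <- unique(unlist(lapply(grp, function(r) r$features$label)))
    labels <- labels[!is.na(labels)]
    extra <- primary$extra_genes
    drop_idx <- integer(0)
    for (lb in labels) {
      hits <- lapply(grp, function(r) {
        f <- r$features[r$features$label %in% lb, , drop = FALSE]
        if (!nrow(f)) NULL else f[1L, , drop = FALSE]
      })
      have <- which(!vapply(hits, is.null, logical(1)))
      full <- have[vapply(have, function(i)
        !hits[[i]]$partial_5prime && !hits[[i]]$partial_3prime, logical(1))]
      best <- if (length(full)) full[1L] else have[1L]
      if (best != 1L) {
        extra <- rbind(extra, data.frame(
          label = lb, kind = hits[[best]]$kind,
          seq = extract_feature_seq(grp[[best]], hits[[best]]),
          accession = grp[[best]]$accession, stringsAsFactors = FALSE))
        in_primary <- which(primary$features$label %in% lb)
        drop_idx <- c(drop_idx, in_primary)
      }
    }
    if (length(drop_idx)) {
      primary$features <- primary$features[-drop_idx, , drop = FALSE]
    }
    primary["extra_genes"] <- list(extra)   # may be NULL; keep the slot
    out <- c(out, list(primary))
  }
  out
}

#' Build cross-taxon ortholog sets
#'
#' Groups genes by normalized label across records. Defaults to the 13
#' canonical PCGs. Per taxon and gene at most one member survives:
#' partial-flagged copies are excluded (reason `"partial"`), and among
#' duplicate full-length copies in one record the longest wins (ties to
#' the lowest start coordinate; losers recorded with reason `"duplicate"`).
#' Output is invariant to input record order.
#'
#' @param records List of `mitogenome_record` (>= 2).
#' @param genes Optional character vector of normalized gene labels; default
#'   the canonical 13 PCGs.
#' @return List of `ortholog_set` objects, one per requested gene, each a
#'   list with `gene_label`, `members` (data.frame: taxon, accession, seq,
#'   plus source feature columns) and `excluded` (data.frame: taxon,
#'   reason). A gene absent from every record yields an empty set with a
#'   warning.
#' @export
build_ortholog_sets <- function(records, genes = NULL) {
  stopifnot(length(records) >= 2L)
  if (is.null(genes)) genes <- pcg_labels()
  # deterministic record order
  key <- vapply(records, function(r) paste(r$taxon, r$accession), character(1))
  records <- records[order(key)]
  out <- lapply(genes, function(gl) {
    members <- NULL
    excluded <- data.frame(taxon = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
    for (r in records) {
      f <- r$features[r$features$label %in% gl, , drop = FALSE]
      extra <- r$extra_genes
      has_extra <- !is.null(extra) && any(extra$label %in% gl)
      if (!nrow(f) && !has_extra) next
      # resolve duplicates within the record: longest, then lowest start
      if (nrow(f) > 1L) {
        lens <- vapply(seq_len(nrow(f)), function(i)
          feature_length(f[i, ], nchar(r$sequence)), numeric(1))
        ord <- order(-lens, f$start)
        f <- f[ord, , drop = FALSE]
        excluded <- rbind(excluded, data.frame(
          taxon = rep(r$taxon, nrow(f) - 1L), reason = "duplicate",
          stringsAsFactors = FALSE))
        f <- f[1L, , drop = FALSE]
      }
      if (nrow(f) && (f$partial_5prime || f$partial_3prime)) {
        excluded <- rbind(excluded, data.frame(
          taxon = r$taxon, reason = "partial", stringsAsFactors = FALSE))
        f <- f[0L, , drop = FALSE]
      }
      if (nrow(f)) {
        row <- cbind(data.frame(taxon = r$taxon, accession = r$accession,
                                seq = extract_feature_seq(r, f[1L, ]),
                                stringsAsFactors = FALSE),
                     f[1L, , drop = FALSE])
        rownames(row) <- NULL
        members <- rbind(members, row)
      } else if (has_extra) {
        e <- extra[extra$label %in% gl, , drop = FALSE][1L, ]
        row <- data.frame(taxon = r$taxon, accession = e$accession,
                          seq = e$seq, label = gl, raw_name = gl,
                          kind = e$kind, start = NA_integer_,
                          end = NA_integer_, strand = "+",
                          wraps_origin = FALSE, partial_5prime = FALSE,
                          partial_3prime = FALSE, stringsAsFactors = FALSE)
        members <- rbind(members, row)
      }
    }
    if (is.null(members)) {
      warning("gene ", gl, " absent from all records", call. = FALSE)
      members <- data.frame(taxon = character(0), accession = character(0),
                            seq = character(0), stringsAsFactors = FALSE)
    }
    structure(list(gene_label = gl, members = members, excluded = excluded),
              class = "ortholog_set")
  })
  names(out) <- genes
  out
}

#' @export
print.ortholog_set <- function(x, ...) {
  cat(sprintf("<ortholog_set> %s: %d members, %d excluded\n",
              x$gene_label, nrow(x$members), nrow(x$excluded)))
  invisible(x)
}

#' Export an ortholog set as FASTA
#'
#' Headers are `taxon|accession|gene`. With `translated = TRUE` sequences
#' are translated under `table` before writing.
#'
#' @param oset An `ortholog_set`.
#' @param path Output FASTA path.
#' @param translated Write amino-acid translations instead of nucleotide.
#' @param table A `translation_table` (required when `translated`).
#' @return `path`, invisibly.
#' @export
write_ortholog_fasta <- function(oset, path, translated = FALSE, table = NULL) {
  m <- oset$members
  seqs <- m$seq
  if (translated) {
    stopifnot(inherits(table, "translation_table"))
    seqs <- vapply(seqs, function(s)
      sub("\\*$", "", translate_seq(s, table)), character(1))
  }
  hdr <- sprintf(">%s|%s|%s", m$taxon, m$accession, oset$gene_label)
  writeLines(as.vector(rbind(hdr, seqs)), path)
  invisible(path)
}
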