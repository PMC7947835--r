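# Synthetic circular mitogenomes with planted ground truth: a 37-gene
# metazoan complement (13 PCGs, 2 rRNAs, 22 tRNAs), valid ORFs under a
# chosen translation table, assigned per-gene start codons, strand
# assignments and intergenic spacers — plus perturbation operators that
# recreate the misannotation and rearrangement scenarios the audit and
# gene-order analytics are built to detect.

.DEFAULT_ORDER <- data.frame(
  label = c("COI", "trnR", "ND4L", "COII", "trnK", "ATP8", "ATP6", "COIII",
            "trnS1", "ND3", "trnQ", "ND4", "trnH", "ND5", "trnS2", "ND6",
            "CYTB", "trnF", "12S", "trnE", "trnT", "16S", "ND1", "trnL1",
            "trnL2", "ND2", "trnI", "trnA", "trnN", "trnC", "trnY", "trnM",
            "trnD", "trnG", "trnW", "trnV", "trnP"),
  sign = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L,
           1L, 1L, -1L, 1L, 1L, 1L, 1L, -1L,
           1L, -1L, 1L, -1L, 1L, 1L, 1L, 1L,
           1L, 1L, 1L, -1L, -1L, -1L, -1L, 1L,
           1L, 1L, 1L, 1L, -1L),
  stringsAsFactors = FALSE)

# Typical metazoan PCG lengths in codons (incl. the stop codon).
.DEFAULT_PCG_LEN <- c(ND1 = 324, ND2 = 356, COI = 518, COII = 230,
                      ATP8 = 55, ATP6 = 227, COIII = 261, ND3 = 116,
                      ND4L = 98, ND4 = 459, ND5 = 615, ND6 = 165, CYTB = 380)

#' Construct a synthetic genome specification
#'
#' Defines one circular mitogenome blueprint: gene order with strands,
#' PCG lengths, the planted start codon per PCG, translation table,
#' spacer and tRNA length ranges, and a seed. Defaults describe a
#' realistic compact echinoderm-like mitogenome: the full 37-gene
#' complement, typical PCG lengths, ATG starts everywhere except the two
#' genes where alternative initiation is characteristically observed in
#' asteroids (ND3 planted with ATT, ND4L with ATC).
#'
#' @param taxon Base taxon name.
#' @param order Data.frame with columns `label`, `sign` (+1/-1); kinds are
#'   derived from labels.
#' @param pcg_lengths Named integer vector, codons per PCG (>= 30, stop
#'   codon included).
#' @param start_assignment Named codon vector per PCG; must not be stop
#'   codons under `table_id`.
#' @param table_id NCBI translation table (default 9).
#' @param spacer_length_range,trna_length_range Integer pairs, nt.
#' @param rrna_lengths Named lengths for 12S/16S, nt.
#' @param seed Integer seed from which the base genome is built.
#' @return A `genome_spec` object.
#' @export
genome_spec <- function(taxon = "synthotaxon",
                        order = .DEFAULT_ORDER,
                        pcg_lengths = .DEFAULT_PCG_LEN,
                        start_assignment = c(ND3 = "ATT", ND4L = "ATC"),
                        table_id = 9L,
                        spacer_length_range = c(2L, 25L),
                        trna_length_range = c(65L, 75L),
                        rrna_lengths = c(`12S` = 900L, `16S` = 1500L),
                        seed = 1L) {
  order$kind <- gene_kind(order$label)
  pcgs <- order$label[order$kind == "PCG"]
  if (!all(pcgs %in% names(pcg_lengths))) {
    stop("missing pcg_lengths for: ",
         paste(setdiff(pcgs, names(pcg_lengths)), collapse = ","),
         call. = FALSE)
  }
  if (any(pcg_lengths < 30L)) stop("pcg_lengths must be >= 30 codons",
                                   call. = FALSE)
  starts <- stats::setNames(rep("ATG", length(pcgs)), pcgs)
  starts[names(start_assignment)] <- start_assignment
  tab <- get_table(table_id)
  if (any(starts %in% tab$stops)) {
    stop("start_assignment contains a stop codon under table ", table_id,
         call. = FALSE)
  }
  structure(
    list(taxon = taxon, order = order,
         pcg_lengths = pcg_lengths[pcgs],
         start_assignment = starts, table_id = as.integer(table_id),
         spacer_length_range = as.integer(spacer_length_range),
         trna_length_range = as.integer(trna_length_range),
         rrna_lengths = rrna_lengths, seed = as.integer(seed),
         rearrangements = list()),
    class = "genome_spec")
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

.rand_pcg <- function(label, len, start_codon, table) {
  nonstop <- setdiff(names(table$codon_to_aa), table$stops)
  body <- sample(nonstop, len - 2L, replace = TRUE)
  stopc <- sample(table$stops, 1L)
  paste(c(start_codon, body, stopc), collapse = "")
}

#' Build the base genome of a specification
#'
#' Deterministic given `spec$seed`. Genes are laid out in the spec's
#' order, separated by random intergenic spacers; minus-strand genes are
#' stored reverse-complemented in the genome. Every PCG begins with its
#' assigned start codon and ends with a full stop codon, with no internal
#' stops under the spec's table.
#'
#' @param spec A `genome_spec`.
#' @return List with `record` (a `mitogenome_record`) and `truth` (list
#'   with `genes` data.frame of true coordinates/strands/start codons,
#'   plus empty `perturbations` and the spec's `rearrangements`).
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  table <- get_table(spec$table_id)
  withr::with_seed(spec$seed, {
    pieces <- character(0)
    feats <- .empty_features()
    pos <- 0L
    for (i in seq_len(nrow(spec$order))) {
      sp_len <- sample(spec$spacer_length_range[1]:spec$spacer_length_range[2], 1L)
      pieces <- c(pieces, .rand_dna(sp_len))
      pos <- pos + sp_len
      lb <- spec$order$label[i]; kind <- spec$order$kind[i]
      gseq <- switch(kind,
        PCG = .rand_pcg(lb, spec$pcg_lengths[[lb]],
                        spec$start_assignment[[lb]], table),
        rRNA = .rand_dna(spec$rrna_lengths[[lb]]),
        tRNA = .rand_dna(sample(spec$trna_length_range[1]:spec$trna_length_range[2], 1L)),
        .rand_dna(60L))
      glen <- nchar(gseq)
      strand <- if (spec$order$sign[i] < 0L) "-" else "+"
      pieces <- c(pieces, if (strand == "-") revcomp(gseq) else gseq)
      feats <- rbind(feats, data.frame(
        label = lb, raw_name = lb, kind = kind,
        start = pos, end = pos + glen, strand = strand,
        wraps_origin = FALSE, partial_5prime = FALSE, partial_3prime = FALSE,
        stringsAsFactors = FALSE))
      pos <- pos + glen
    }
    record <- mitogenome_record(
      taxon = spec$taxon, sequence = paste(pieces, collapse = ""),
      features = feats, circular = TRUE, accession = "SYN000000",
      table_id = spec$table_id)
  })
  truth_genes <- record$features[, c("label", "kind", "start", "end", "strand")]
  truth_genes$start_codon <- NA_character_
  is_pcg <- truth_genes$kind == "PCG"
  truth_genes$start_codon[is_pcg] <-
    unname(spec$start_assignment[truth_genes$label[is_pcg]])
  list(record = record,
       truth = list(genes = truth_genes,
                    perturbations = data.frame(
                      taxon = character(0), gene = character(0),
                      type = character(0), magnitude = integer(0),
                      stringsAsFactors = FALSE),
                    rearrangements = spec$rearrangements))
}

# Mutate one genome under a site-uniform model, rejecting changes that
# destroy a planted start codon, a terminal stop, or create an internal
# stop in a PCG. Returns the mutated sequence and the substitution count.
.mutate_genome <- function(sequence, truth_genes, divergence, table) {
  n <- nchar(sequence)
  bases <- strsplit(sequence, "")[[1]]
  pcg <- truth_genes[truth_genes$kind == "PCG", , drop = FALSE]
  # protected sites: start and stop codons of every PCG (genome coords)
  site_gene <- rep(0L, n)       # which PCG row covers each site
  protected <- rep(FALSE, n)
  for (k in seq_len(nrow(pcg))) {
    span <- (pcg$start[k] + 1L):pcg$end[k]
    site_gene[span] <- k
    if (pcg$strand[k] == "+") {
      protected[pcg$start[k] + 1:3] <- TRUE
      protected[(pcg$end[k] - 2L):pcg$end[k]] <- TRUE
    } else {
      protected[(pcg$end[k] - 2L):pcg$end[k]] <- TRUE
      protected[pcg$start[k] + 1:3] <- TRUE
    }
  }
  hit <- which(stats::runif(n) < divergence & !protected)
  n_sub <- 0L
  for (p in hit) {
    cur <- bases[p]
    alts <- setdiff(c("A", "C", "G", "T"), cur)
    k <- site_gene[p]
    if (k > 0L) {
      # keep the codon containing p non-stop in gene orientation
      g <- pcg[k, ]
      local <- if (g$strand == "+") p - 1L - g$start else g$end - p
      cstart_local <- (local %/% 3L) * 3L
      codon_sites <- if (g$strand == "+") {
        g$start + cstart_local + 1:3            # ascending genome order
      } else {
        g$end - cstart_local - (2:0)            # ascending genome order
      }
      ok <- vapply(alts, function(b) {
        tmp <- bases
        tmp[p] <- b
        cod <- paste(tmp[codon_sites], collapse = "")
        if (g$strand == "-") cod <- revcomp(cod)
        !cod %in% table$stops
      }, logical(1))
      alts <- alts[ok]
      if (!length(alts)) next
    }
    bases[p] <- if (length(alts) == 1L) alts else sample(alts, 1L)
    n_sub <- n_sub + 1L
  }
  list(sequence = paste(bases, collapse = ""), n_sub = n_sub)
}

#' Simulate a cohort of diverged genomes from one specification
#'
#' A star cohort: each taxon is the spec's base genome with independent
#' point substitutions at per-site probability `divergence`, drawn under a
#' site-uniform model that re-draws (or skips) any change that would
#' destroy a planted start codon, a terminal stop codon, or create an
#' internal stop in a PCG. Deterministic given `seed` (per-taxon streams
#' are derived from it at fixed offsets).
#'
#' Per-taxon overrides emulate genuine 5'-length variation: `trim_5prime`
#' removes leading codons of a gene for one taxon (the gene then genuinely
#' starts downstream of the cohort), and `start_override` changes that
#' taxon's planted start codon.
#'
#' @param base A `genome_spec`.
#' @param n_taxa Number of taxa (>= 1).
#' @param divergence Per-site substitution probability in `[0, 0.3]`.
#' @param seed Integer seed.
#' @param trim_5prime Named list: taxon name -> named integer vector
#'   (gene -> codons trimmed from the 5' end).
#' @param start_override Named list: taxon name -> named codon vector.
#' @return List of per-taxon entries, each `list(record, truth)`.
#' @export
simulate_cohort <- function(base, n_taxa, divergence = 0.05, seed = 1L,
                            trim_5prime = list(), start_override = list()) {
  stopifnot(inherits(base, "genome_spec"), n_taxa >= 1L,
            divergence >= 0, divergence <= 0.3)
  table <- get_table(base$table_id)
  g0 <- build_genome(base)   # one shared ancestor: cross-taxon homology
  out <- vector("list", n_taxa)
  for (i in seq_len(n_taxa)) {
    tx <- sprintf("%s_%02d", base$taxon, i)
    g <- g0
    g$record$taxon <- tx
    g$record$accession <- sprintf("SYN%06d", i)
    tr <- trim_5prime[[tx]]
    if (!is.null(tr)) {
      for (gl in names(tr)) g <- .trim_gene_5prime(g, gl, tr[[gl]])
    }
    so <- start_override[[tx]]
    if (!is.null(so)) {
      for (gl in names(so)) g <- .set_start_codon(g, gl, so[[gl]], table)
    }
    if (divergence > 0) {
      mseed <- (seed + 7919L * i) %% 2147483647L
      withr::with_seed(mseed, {
        mut <- .mutate_genome(g$record$sequence, g$truth$genes,
                              divergence, table)
      })
      g$record$sequence <- mut$sequence
      g$truth$n_substitutions <- mut$n_sub
    } else {
      g$truth$n_substitutions <- 0L
    }
    out[[i]] <- g
  }
  out
}

# Overwrite the planted start codon of one gene in place (strand-aware).
.set_start_codon <- function(g, gene, codon, table) {
  codon <- normalize_seq(codon)
  if (codon %in% table$stops) stop("start override is a stop codon",
                                   call. = FALSE)
  fi <- which(g$record$features$label == gene)
  if (!length(fi)) stop("gene not found: ", gene, call. = FALSE)
  f <- g$record$features[fi[1L], ]
  s <- g$record$sequence
  if (f$strand == "+") {
    substr(s, f$start + 1L, f$start + 3L) <- codon
  } else {
    substr(s, f$end - 2L, f$end) <- revcomp(codon)
  }
  g$record$sequence <- s
  g$truth$genes$start_codon[g$truth$genes$label == gene] <- codon
  g
}

# Remove k leading codons of one gene from the genome (the gene genuinely
# starts k codons downstream of the cohort); the planted start codon is
# re-imposed on the new first codon. Downstream feature coordinates shift.
.trim_gene_5prime <- function(g, gene, k) {
  fi <- which(g$record$features$label == gene)
  if (!length(fi)) stop("gene not found: ", gene, call. = FALSE)
  f <- g$record$features[fi[1L], ]
  del <- 3L * as.integer(k)
  s <- g$record$sequence
  d0 <- if (f$strand == "+") f$start else f$end - del  # 0-based deletion start
  g$record$sequence <- paste0(substr(s, 1L, d0), substr(s, d0 + del + 1L, nchar(s)))
  adj <- function(df) {
    move <- df$start >= d0 + del
    df$start[move] <- df$start[move] - del
    df$end[df$end >= d0 + del] <- df$end[df$end >= d0 + del] - del
    df
  }
  # the gene itself: keep its start, shrink its end
  own_end <- f$end - del
  g$record$features <- adj(g$record$features)
  g$record$features$end[fi[1L]] <- own_end
  g$record$features$start[fi[1L]] <- f$start
  g$truth$genes <- adj(g$truth$genes)
  ti <- which(g$truth$genes$label == gene)
  g$truth$genes$end[ti] <- own_end
  g$truth$genes$start[ti] <- f$start
  # re-impose the planted start codon on the new first codon
  codon <- g$truth$genes$start_codon[ti]
  s <- g$record$sequence
  if (f$strand == "+") {
    substr(s, f$start + 1L, f$start + 3L) <- codon
  } else {
    substr(s, own_end - 2L, own_end) <- revcomp(codon)
  }
  g$record$sequence <- s
  g
}

#' Shift annotated start coordinates without touching the sequence
#'
#' Recreates start-codon misannotation: a chosen fraction of the cohort's
#' PCG annotations get their start coordinate shifted by whole codons
#' (downstream positive), never past a neighboring feature. The truth
#' sidecar records every applied shift; genes with no room are skipped
#' with a note.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param shift_fraction Fraction of (taxon, PCG) annotations to perturb.
#' @param shift_range Maximum absolute shift in codons (shifts are drawn
#'   uniformly from `{-shift_range..-1, 1..shift_range}`).
#' @param seed Integer seed.
#' @return The cohort with perturbed records and updated truth.
#' @export
perturb_annotations <- function(cohort, shift_fraction = 0.25,
                                shift_range = 3L, seed = 1L) {
  stopifnot(shift_fraction >= 0, shift_fraction <= 1, shift_range >= 1L)
  if (shift_fraction == 0) return(cohort)
  pairs <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    f <- cohort[[i]]$record$features
    idx <- which(f$kind == "PCG")
    if (!length(idx)) return(NULL)
    data.frame(entry = i, fidx = idx, stringsAsFactors = FALSE)
  }))
  n_pick <- round(shift_fraction * nrow(pairs))
  if (!n_pick) return(cohort)
  withr::with_seed(seed, {
    picked <- pairs[sample.int(nrow(pairs), n_pick), , drop = FALSE]
    shifts <- sample(c(-(shift_range:1), 1:shift_range), n_pick, TRUE)
  })
  for (k in seq_len(n_pick)) {
    i <- picked$entry[k]; fi <- picked$fidx[k]; s <- shifts[k]
    rec <- cohort[[i]]$record
    n <- nchar(rec$sequence)
    feat <- rec$features[fi, ]
    ok_dir <- function(s) {
      f2 <- .shifted_feature(feat, s, n, rec$circular)
      if (is.null(f2)) return(FALSE)
      if (s < 0L) {
        if (feat$strand == "+") { qs <- feat$start + 3L * s; qe <- feat$start }
        else { qs <- feat$end; qe <- feat$end - 3L * s }
        if (qs < 0L) { qs <- qs + n; qe <- qe + n }
        if (.crosses_other_feature(rec, fi, qs, qe)) return(FALSE)
      }
      TRUE
    }
    if (!ok_dir(s)) s <- -s
    if (!ok_dir(s)) next  # no room either way: skipped
    cohort[[i]]$record$features[fi, ] <-
      .shifted_feature(feat, s, n, rec$circular)
    cohort[[i]]$truth$perturbations <- rbind(
      cohort[[i]]$truth$perturbations,
      data.frame(taxon = rec$taxon, gene = feat$label, type = "start_shift",
                 magnitude = s, stringsAsFactors = FALSE))
  }
  cohort
}

#' Apply a rearrangement operator to a genome specification
#'
#' Operates on the spec's gene order: `transpose_block` moves a contiguous
#' block elsewhere, `invert_block` reverses a block in place flipping its
#' strands, and `interchange` swaps the positions of two disjoint
#' contiguous blocks (each keeping its internal order and orientation).
#'
#' @param spec A `genome_spec`.
#' @param op One of `"transpose_block"`, `"invert_block"`, `"interchange"`.
#' @param params List: for transpose, `block` (labels) and `insert_after`
#'   (a label, or `""` for the front); for invert, `block`; for
#'   interchange, `block1` and `block2`.
#' @return A new `genome_spec` with the rearranged order; the operation is
#'   appended to `spec$rearrangements`.
#' @export
apply_rearrangement <- function(spec, op = c("transpose_block",
                                             "invert_block", "interchange"),
                                params = list()) {
  op <- match.arg(op)
  stopifnot(inherits(spec, "genome_spec"))
  ord <- spec$order
  block_idx <- function(labels) {
    idx <- match(labels, ord$label)
    if (anyNA(idx)) stop("unknown gene(s): ",
                         paste(labels[is.na(idx)], collapse = ","), call. = FALSE)
    idx <- sort(idx)
    if (length(idx) > 1L && any(diff(idx) != 1L)) {
      stop("block is not contiguous: ", paste(labels, collapse = ","),
           call. = FALSE)
    }
    idx
  }
  if (op == "invert_block") {
    idx <- block_idx(params$block)
    ord[idx, ] <- ord[rev(idx), ]
    ord$sign[idx] <- -ord$sign[idx]
  } else if (op == "transpose_block") {
    idx <- block_idx(params$block)
    rest <- ord[-idx, , drop = FALSE]
    at <- if (identical(params$insert_after, "")) 0L else
      match(params$insert_after, rest$label)
    if (is.na(at)) stop("insert_after gene not found (or inside the block)",
                        call. = FALSE)
    ord <- rbind(rest[seq_len(at), , drop = FALSE],
                 ord[idx, , drop = FALSE],
                 if (at < nrow(rest)) rest[(at + 1L):nrow(rest), , drop = FALSE])
  } else {
    i1 <- block_idx(params$block1); i2 <- block_idx(params$block2)
    if (length(intersect(i1, i2))) stop("overlapping blocks", call. = FALSE)
    if (min(i2) < min(i1)) { tmp <- i1; i1 <- i2; i2 <- tmp }
    if (max(i1) >= min(i2)) stop("overlapping blocks", call. = FALSE)
    pre <- if (min(i1) > 1L) ord[seq_len(min(i1) - 1L), , drop = FALSE]
    mid <- if (max(i1) + 1L <= min(i2) - 1L)
      ord[(max(i1) + 1L):(min(i2) - 1L), , drop = FALSE]
    post <- if (max(i2) < nrow(ord)) ord[(max(i2) + 1L):nrow(ord), , drop = FALSE]
    ord <- rbind(pre, ord[i2, , drop = FALSE], mid, ord[i1, , drop = FALSE],
                 post)
  }
  rownames(ord) <- NULL
  spec$order <- ord
  spec$rearrangements <- c(spec$rearrangements,
                           list(c(list(op = op), params)))
  spec
}

#' Write a simulated cohort to GenBank files with truth sidecars
#'
#' One GenBank flat file and one JSON truth sidecar per taxon.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Character vector of GenBank paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(cohort, function(entry) {
    gb <- file.path(dir, paste0(entry$record$taxon, ".gb"))
    write_genbank(entry$record, gb)
    jsonlite::write_json(
      entry$truth, file.path(dir, paste0(entry$record$taxon, ".truth.json")),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    gb
  }, character(1))
  invisible(paths)
}
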