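# Codon-aware audit of annotated initiation codons. The procedure
# formalizes comparative visual inspection: translate each annotated CDS,
# build a cross-taxon protein alignment per gene, measure each taxon's
# 5'-end offset against the cohort consensus, then scan a window of
# in-frame candidate starts around the annotated coordinate and pick the
# best-supported one.

.START_PREFERENCE <- c("ATG", "GTG", "ATT", "ATC", "TTG")

.default_aln_params <- function() {
  list(substitution_matrix = "BLOSUM62", gap_open = 10, gap_ext = 1)
}

.get_submat <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Center-star multiple alignment of a protein ortholog set
#'
#' Global multiple alignment by the center-star heuristic: every sequence
#' is aligned pairwise (Needleman-Wunsch, affine gaps, BLOSUM62) to the
#' center — the member maximizing the summed pairwise alignment scores —
#' and the pairwise alignments are merged under "once a gap, always a
#' gap". Members are sorted by taxon name first, so the result is
#' invariant to input order; score ties for the center go to the
#' alphabetically first taxon. Adequate and fully deterministic for the
#' highly conserved mitochondrial PCGs this package audits.
#'
#' @param seqs Named character vector of amino-acid sequences (names are
#'   taxa; internal stops as `*` are tolerated).
#' @param gene_label Label stored on the result.
#' @param params List with `substitution_matrix` (a matrix name in
#'   Biostrings), `gap_open`, `gap_ext` (positive penalties).
#' @return A `gene_alignment`: list with `gene_label`, `taxa`, `aligned`
#'   (named character vector, gap symbol `-`), `backmap` (per row, aligned
#'   column to 1-based codon index or NA), `consensus_start_col`, `params`.
#' @export
align_protein_set <- function(seqs, gene_label = "", params = .default_aln_params()) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)), all(nchar(seqs) > 0L))
  ord <- order(names(seqs))
  seqs <- seqs[ord]
  if (length(seqs) == 1L) {
    warning("single sequence: trivial alignment", call. = FALSE)
    aln <- seqs
  } else {
    submat <- .get_submat(params$substitution_matrix)
    aas <- Biostrings::AAStringSet(unname(seqs))
    n <- length(seqs)
    scores <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      sc <- Biostrings::pairwiseAlignment(
        rep(aas[i], n - i), aas[(i + 1L):n], type = "global",
        substitutionMatrix = submat, gapOpening = params$gap_open,
        gapExtension = params$gap_ext, scoreOnly = TRUE)
      scores[i, (i + 1L):n] <- sc
      scores[(i + 1L):n, i] <- sc
    }
    center <- which.max(rowSums(scores))  # ties -> first (alphabetical taxon)
    others <- setdiff(seq_len(n), center)
    master <- strsplit(as.character(seqs[[center]]), "")[[1]]
    rows <- list()
    for (k in others) {
      pa <- Biostrings::pairwiseAlignment(
        aas[center], aas[k], type = "global", substitutionMatrix = submat,
        gapOpening = params$gap_open, gapExtension = params$gap_ext)
      pc <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
      ps <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
      merged <- .merge_into_star(master, rows, pc, ps)
      master <- merged$master
      rows <- merged$rows
    }
    aln_chr <- character(n)
    aln_chr[center] <- paste(master, collapse = "")
    for (idx in seq_along(others)) {
      aln_chr[others[idx]] <- paste(rows[[idx]], collapse = "")
    }
    aln <- stats::setNames(aln_chr, names(seqs))
  }
  backmap <- lapply(aln, function(a) {
    ch <- strsplit(a, "")[[1]]
    idx <- cumsum(ch != "-")
    idx[ch == "-"] <- NA_integer_
    as.integer(idx)
  })
  out <- structure(
    list(gene_label = gene_label, taxa = names(aln), aligned = aln,
         backmap = backmap, consensus_start_col = NA_integer_,
         params = params),
    class = "gene_alignment")
  if (length(aln) >= 2L) {
    cs <- locate_consensus_start(out)
    out$consensus_start_col <- cs$consensus_start_col
  }
  out
}

# Merge one pairwise alignment (pc = center row, ps = new row) into the
# running star alignment under "once a gap, always a gap".
.merge_into_star <- function(master, rows, pc, ps) {
  lm <- length(master); lp <- length(pc)
  new_master <- character(0); new_ps <- character(0)
  take_master <- integer(0)  # per output column: master col index or NA
  i <- 1L; j <- 1L
  while (i <= lm || j <= lp) {
    if (i <= lm && master[i] == "-" && (j > lp || pc[j] != "-")) {
      new_master <- c(new_master, master[i]); take_master <- c(take_master, i)
      new_ps <- c(new_ps, "-"); i <- i + 1L
    } else if (j <= lp && pc[j] == "-") {
      new_master <- c(new_master, "-"); take_master <- c(take_master, NA_integer_)
      new_ps <- c(new_ps, ps[j]); j <- j + 1L
    } else if (i <= lm && j <= lp) {
      new_master <- c(new_master, master[i]); take_master <- c(take_master, i)
      new_ps <- c(new_ps, ps[j]); i <- i + 1L; j <- j + 1L
    } else {
      stop("alignment merge out of sync", call. = FALSE)  # defensive
    }
  }
  new_rows <- lapply(rows, function(r) {
    ifelse(is.na(take_master), "-", r[pmax(take_master, 1L)])
  })
  list(master = new_master, rows = c(new_rows, list(new_ps)))
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("<gene_alignment> %s: %d rows x %d cols, consensus start col %s\n",
              x$gene_label, length(x$aligned),
              if (length(x$aligned)) nchar(x$aligned[[1]]) else 0L,
              x$consensus_start_col))
  invisible(x)
}

#' Locate the consensus 5' start column of an alignment
#'
#' The consensus start column is the modal first non-gap column across
#' rows (ties broken toward the smallest column, i.e. the longer 5' end).
#' Each row's 5' offset — positive when the row starts downstream of the
#' cohort, i.e. has a shorter 5' end — is measured at an anchor column
#' (the first column where every row has a residue, so gap-placement
#' ambiguity in the ragged 5' region cannot bias it): the modal residue
#' count reaching the anchor minus the row's own count. When no fully
#' occupied column exists the offsets fall back to first non-gap columns.
#'
#' @param aln A `gene_alignment` with >= 2 rows.
#' @return List with `consensus_start_col` (1-based) and `offsets` (named
#'   integer vector per taxon, in codons).
#' @export
locate_consensus_start <- function(aln) {
  stopifnot(inherits(aln, "gene_alignment"), length(aln$aligned) >= 2L)
  chars <- lapply(aln$aligned, function(a) strsplit(a, "")[[1]])
  first_col <- vapply(chars, function(ch) which(ch != "-")[1L], integer(1))
  tab <- table(first_col)
  modal <- as.integer(names(tab)[tab == max(tab)])
  consensus <- min(modal)
  gapmat <- vapply(chars, `==`, logical(length(chars[[1]])), "-")
  full <- !apply(gapmat, 1L, any)    # per alignment column: no row gapped
  if (any(full)) {
    # anchor on the first sustained run of fully occupied columns: isolated
    # occupied columns inside the ragged 5' region (a stray residue aligned
    # just before a gap) must not serve as the anchor
    r <- rle(full)
    run_start <- cumsum(r$lengths) - r$lengths + 1L
    need <- min(10L, max(r$lengths[r$values]))
    k <- which(r$values & r$lengths >= need)[1L]
    anchor <- run_start[k]
    b <- vapply(aln$backmap, `[[`, integer(1), anchor)
    tb <- table(b)
    bmodal <- as.integer(names(tb)[tb == max(tb)])
    bmode <- max(bmodal)   # ties toward the longer 5' end
    offsets <- bmode - b
  } else {
    offsets <- first_col - consensus
  }
  names(offsets) <- names(aln$aligned)
  list(consensus_start_col = consensus, offsets = offsets)
}

## ---- candidate geometry ----------------------------------------------------

# Shift a feature's biological start by s codons (downstream positive),
# wrap-aware. Returns NULL when the shift is infeasible (runs past the 3'
# end, or off a linear genome).
.shifted_feature <- function(feature, s, genome_length, circular) {
  n <- genome_length
  us <- feature$start
  ue <- if (isTRUE(feature$wraps_origin)) feature$end + n else feature$end
  if (feature$strand == "+") us <- us + 3L * s else ue <- ue - 3L * s
  if (ue - us < 3L) return(NULL)
  if (!circular && (us < 0L || ue > n)) return(NULL)
  if (us < 0L) { us <- us + n; ue <- ue + n }
  if (us >= n) { us <- us - n; ue <- ue - n }
  if (us < 0L || ue - us > n) return(NULL)
  f <- feature
  f$start <- us
  f$wraps_origin <- ue > n
  f$end <- if (ue > n) ue - n else ue
  f
}

# Does genome interval [qs, qe) (unwrapped circular coords) overlap any
# feature other than row `exclude` of kinds PCG/rRNA/tRNA?
.crosses_other_feature <- function(record, exclude, qs, qe) {
  n <- nchar(record$sequence)
  feats <- record$features
  for (i in seq_len(nrow(feats))) {
    if (i == exclude) next
    if (!feats$kind[i] %in% c("PCG", "rRNA", "tRNA")) next
    fs <- feats$start[i]
    fe <- if (feats$wraps_origin[i]) feats$end[i] + n else feats$end[i]
    for (sh in c(-n, 0L, n)) {
      if (max(qs, fs + sh) < min(qe, fe + sh)) return(TRUE)
    }
  }
  FALSE
}

# Strip a clean terminal stop from a translation (for alignment input).
.strip_terminal_stop <- function(aa) sub("\\*$", "", aa)

# TRUE when the CDS has a stop codon anywhere except a clean terminal one.
.has_internal_stop <- function(cds, table) {
  aa <- translate_seq(cds, table, stop_policy = "annotate")
  ch <- strsplit(aa, "")[[1]]
  if (nchar(cds) %% 3L == 0L && length(ch)) ch <- ch[-length(ch)]
  any(ch == "*")
}

## ---- the audit -------------------------------------------------------------

.empty_calls <- function() {
  data.frame(taxon = character(0), accession = character(0),
             gene_label = character(0), annotated_codon = character(0),
             verdict = character(0), shift_codons = integer(0),
             final_codon = character(0), classification = character(0),
             five_prime_offset = integer(0), notes = character(0),
             stringsAsFactors = FALSE)
}

#' Audit the annotated initiation codons of one ortholog set
#'
#' For every member: (a) translate the annotated CDS; (b) align the set's
#' translations; (c) measure each row's 5' offset against the consensus
#' start column; (d) enumerate in-frame candidate start codons at shifts
#' `s` in `[-window, window]` codons from the annotated start (negative =
#' upstream, retrieved with circular wrap; candidates whose upstream
#' extension crosses another PCG/rRNA/tRNA feature, whose codon is a stop,
#' or whose resulting ORF contains an internal stop are discarded);
#' (e) rank candidates lexicographically — predicted 5' offset of zero
#' first, then start-set membership (canonical, canonical alternative,
#' extended alternative), then the fixed codon preference ATG > GTG > ATT >
#' ATC > TTG, then smallest `|s|`, then smallest `s`; (f) call a verdict:
#' `confirmed` when the winner is the annotated start and a recognized
#' start codon; `corrected` when a different recognized-start candidate
#' wins; `novel_candidate` when `allow_novel` is set and no recognized
#' codon attains offset zero but some non-stop codon does; otherwise
#' `unresolved`.
#'
#' @param oset An `ortholog_set`.
#' @param records List of `mitogenome_record` the members came from.
#' @param table A `translation_table` (its extended start set defines what
#'   counts as a recognized start).
#' @param window Scan window in codons (default 5).
#' @param allow_novel Permit positional-evidence novel-codon calls.
#' @param params Alignment parameters (see [align_protein_set()]).
#' @return Data.frame of start-codon calls, one row per member: `taxon`,
#'   `accession`, `gene_label`, `annotated_codon`, `verdict`,
#'   `shift_codons` (downstream positive), `final_codon`,
#'   `classification`, `five_prime_offset`, `notes`.
#' @export
audit_gene <- function(oset, records, table, window = 5L,
                       allow_novel = FALSE, params = .default_aln_params()) {
  stopifnot(inherits(oset, "ortholog_set"), window >= 1L)
  m <- oset$members
  if (!nrow(m)) return(.empty_calls())
  rec_key <- vapply(records, function(r) paste0(r$taxon, "\r", r$accession),
                    character(1))
  m <- m[order(m$taxon), , drop = FALSE]

  aa <- vapply(m$seq, function(s)
    .strip_terminal_stop(translate_seq(s, table, stop_policy = "annotate")),
    character(1), USE.NAMES = FALSE)
  names(aa) <- m$taxon
  if (nrow(m) >= 2L) {
    aln <- align_protein_set(aa, gene_label = oset$gene_label, params = params)
    offs <- locate_consensus_start(aln)$offsets
  } else {
    offs <- stats::setNames(0L, m$taxon)
  }

  calls <- .empty_calls()
  for (i in seq_len(nrow(m))) {
    mem <- m[i, ]
    d <- unname(offs[[mem$taxon]])
    annotated_codon <- substr(mem$seq, 1L, 3L)
    note <- character(0)

    ri <- which(rec_key == paste0(mem$taxon, "\r", mem$accession))
    cands <- NULL
    if (length(ri) && !is.na(mem$start)) {
      record <- records[[ri[1L]]]
      n <- nchar(record$sequence)
      fidx <- which(record$features$label %in% mem$label &
                      record$features$start == mem$start &
                      record$features$strand == mem$strand)
      fidx <- if (length(fidx)) fidx[1L] else 0L
      feat <- mem[, c("label", "raw_name", "kind", "start", "end", "strand",
                      "wraps_origin", "partial_5prime", "partial_3prime")]
      clipped <- FALSE
      for (s in seq.int(-window, window)) {
        f2 <- .shifted_feature(feat, s, n, record$circular)
        if (is.null(f2)) { clipped <- TRUE; next }
        if (s < 0L) {
          # upstream extension region in unwrapped + coords
          if (feat$strand == "+") {
            qs <- feat$start + 3L * s; qe <- feat$start
          } else {
            qe0 <- if (feat$wraps_origin) feat$end + n else feat$end
            qs <- qe0; qe <- qe0 - 3L * s
          }
          if (qs < 0L) { qs <- qs + n; qe <- qe + n }
          if (.crosses_other_feature(record, fidx, qs, qe)) next
        }
        cds <- extract_feature_seq(record, f2)
        codon <- substr(cds, 1L, 3L)
        if (!grepl("^[ACGT]{3}$", codon)) next
        if (codon %in% table$stops) next
        if (.has_internal_stop(cds, table)) next
        cands <- rbind(cands, data.frame(
          s = s, codon = codon, stringsAsFactors = FALSE))
      }
      if (clipped) note <- c(note, "window clipped")
    } else {
      # no genome context (pooled extra gene): only the annotated start
      note <- c(note, "no genome context")
      if (grepl("^[ACGT]{3}$", annotated_codon) &&
          !annotated_codon %in% table$stops &&
          !.has_internal_stop(mem$seq, table)) {
        cands <- data.frame(s = 0L, codon = annotated_codon,
                            stringsAsFactors = FALSE)
      }
    }

    if (is.null(cands) || !nrow(cands)) {
      calls <- rbind(calls, data.frame(
        taxon = mem$taxon, accession = mem$accession,
        gene_label = oset$gene_label, annotated_codon = annotated_codon,
        verdict = "unresolved", shift_codons = 0L,
        final_codon = annotated_codon,
        classification = classify_start(annotated_codon, table),
        five_prime_offset = d,
        notes = paste(c(note, "no viable candidates"), collapse = "; "),
        stringsAsFactors = FALSE))
      next
    }

    cands$class <- vapply(cands$codon, classify_start, character(1),
                          table = table)
    cands$pred_off <- d + cands$s
    recog <- cands$class %in% c("canonical", "canonical_alternative",
                                "extended_alternative")
    r0 <- cands[recog & cands$pred_off == 0L, , drop = FALSE]
    ann <- cands[cands$s == 0L, , drop = FALSE]
    if (nrow(r0)) {
      # a recognized start attains the cohort's consensus 5' offset: the
      # annotation is confirmed there, or corrected onto it
      rank_member <- match(r0$class, c("canonical", "canonical_alternative",
                                       "extended_alternative"))
      rank_pref <- match(r0$codon, .START_PREFERENCE)
      rank_pref[is.na(rank_pref)] <- length(.START_PREFERENCE) + 1L
      w <- r0[order(rank_member, rank_pref, abs(r0$s), r0$s)[1L], ]
      if (w$s == 0L) {
        verdict <- "confirmed"; shift <- 0L; final <- annotated_codon
        cls <- w$class
      } else {
        verdict <- "corrected"; shift <- w$s; final <- w$codon; cls <- w$class
        note <- c(note, sprintf("shifted %+d codons to reach %s", shift, final))
      }
    } else if (isTRUE(allow_novel) && nrow(ann) &&
               !ann$class[1L] %in% c("canonical", "canonical_alternative",
                                     "extended_alternative") &&
               ann$pred_off[1L] == 0L) {
      # the annotated codon itself sits at the consensus offset but is not a
      # recognized start: flag it; never propose shifting onto a non-start
      verdict <- "novel_candidate"; shift <- 0L; final <- annotated_codon
      cls <- "novel_candidate"
      note <- c(note, "positional evidence: annotated codon at consensus 5' offset 0")
    } else if (nrow(ann) &&
               ann$class[1L] %in% c("canonical", "canonical_alternative",
                                    "extended_alternative")) {
      # no start attains offset 0, but the annotation is a recognized start
      # (e.g. a gene genuinely one codon shorter at the 5' end): keep it
      verdict <- "confirmed"; shift <- 0L; final <- annotated_codon
      cls <- ann$class[1L]
      if (d != 0L) note <- c(note, sprintf("5' offset %+d vs consensus", d))
    } else {
      verdict <- "unresolved"; shift <- 0L; final <- annotated_codon
      cls <- classify_start(annotated_codon, table)
    }
    calls <- rbind(calls, data.frame(
      taxon = mem$taxon, accession = mem$accession,
      gene_label = oset$gene_label, annotated_codon = annotated_codon,
      verdict = verdict, shift_codons = shift, final_codon = final,
      classification = cls, five_prime_offset = d,
      notes = paste(note, collapse = "; "), stringsAsFactors = FALSE))
  }
  rownames(calls) <- NULL
  calls
}

#' Iteratively audit a whole cohort until annotations settle
#'
#' Runs [audit_gene()] over every requested gene, applies the corrections,
#' and re-audits, until a pass proposes no further correction (or
#' `max_passes` is reached). A single pass can leave a gene unresolved
#' when its upstream candidate scan is blocked by a neighboring gene's own
#' misannotation (two 5' ends facing each other across a spacer, one
#' annotation extended over the other's true start); correcting the
#' neighbor first unblocks it, which is exactly what iterating does. The
#' returned calls are expressed against the original annotations:
#' `annotated_codon` is the codon as first annotated and `shift_codons`
#' the cumulative proposed shift.
#'
#' @inheritParams audit_gene
#' @param records List of `mitogenome_record`.
#' @param genes Gene labels to audit (default the canonical 13 PCGs).
#' @param max_passes Maximum audit passes (the facing-5'-ends geometry
#'   settles in 2; the default leaves margin).
#' @return Data.frame of start-codon calls as in [audit_gene()].
#' @export
audit_cohort <- function(records, table, genes = NULL, window = 5L,
                         allow_novel = FALSE, max_passes = 3L,
                         params = .default_aln_params()) {
  work <- records
  cum <- list()      # taxon|gene -> cumulative shift applied in prior passes
  orig_codon <- list()
  orig_off <- list()
  calls <- NULL
  for (pass in seq_len(max_passes)) {
    osets <- suppressWarnings(build_ortholog_sets(work, genes = genes))
    calls <- do.call(rbind, lapply(osets, audit_gene, records = work,
                                   table = table, window = window,
                                   allow_novel = allow_novel,
                                   params = params))
    rownames(calls) <- NULL
    if (pass == 1L) {
      for (i in seq_len(nrow(calls))) {
        key <- paste0(calls$taxon[i], "\r", calls$gene_label[i])
        orig_codon[[key]] <- calls$annotated_codon[i]
        orig_off[[key]] <- calls$five_prime_offset[i]
      }
    }
    corr <- calls[calls$verdict == "corrected" & calls$shift_codons != 0L, ,
                  drop = FALSE]
    if (!nrow(corr) || pass == max_passes) break
    for (i in seq_len(nrow(corr))) {
      key <- paste0(corr$taxon[i], "\r", corr$gene_label[i])
      cum[[key]] <- (if (is.null(cum[[key]])) 0L else cum[[key]]) +
        corr$shift_codons[i]
    }
    work <- apply_audit_corrections(work, corr)
  }
  # express calls against the original annotations
  for (i in seq_len(nrow(calls))) {
    key <- paste0(calls$taxon[i], "\r", calls$gene_label[i])
    prior <- if (is.null(cum[[key]])) 0L else cum[[key]]
    total <- prior + calls$shift_codons[i]
    calls$shift_codons[i] <- total
    calls$annotated_codon[i] <- orig_codon[[key]]
    calls$five_prime_offset[i] <- orig_off[[key]]
    if (total != 0L && calls$verdict[i] == "confirmed") {
      calls$verdict[i] <- "corrected"
    }
  }
  calls
}

#' Apply corrected start coordinates back to records
#'
#' Shifts the annotated start of each feature with a `corrected` (or,
#' optionally, `novel_candidate`) call by the proposed number of codons,
#' so a re-audit sees the corrected annotation.
#'
#' @param records List of `mitogenome_record`.
#' @param calls Audit calls data.frame.
#' @param include_novel Also apply `novel_candidate` shifts.
#' @return The updated list of records.
#' @export
apply_audit_corrections <- function(records, calls, include_novel = FALSE) {
  verdicts <- c("corrected", if (include_novel) "novel_candidate")
  todo <- calls[calls$verdict %in% verdicts & calls$shift_codons != 0L, ,
                drop = FALSE]
  for (k in seq_len(nrow(todo))) {
    cl <- todo[k, ]
    for (ri in seq_along(records)) {
      r <- records[[ri]]
      if (r$taxon != cl$taxon || r$accession != cl$accession) next
      fi <- which(r$features$label %in% cl$gene_label)
      if (!length(fi)) next
      f2 <- .shifted_feature(r$features[fi[1L], ], cl$shift_codons,
                             nchar(r$sequence), r$circular)
      if (is.null(f2)) next
      records[[ri]]$features[fi[1L], ] <- f2
    }
  }
  records
}

#' Tabulate final initiation codons across taxa and genes
#'
#' Builds the taxa-by-genes matrix of final codons (genes in canonical
#' genome-complement order) and per-gene codon frequency tallies.
#'
#' @param calls Audit calls data.frame.
#' @return A `codon_usage_matrix`: list with `matrix` (data.frame, rows =
#'   taxa, cols = genes, entries = final codon or NA) and `tallies` (named
#'   list per gene of codon counts).
#' @export
codon_usage <- function(calls) {
  if (!nrow(calls)) {
    return(structure(list(matrix = data.frame(), tallies = list()),
                     class = "codon_usage_matrix"))
  }
  genes <- intersect(c(pcg_labels(), rrna_labels()), unique(calls$gene_label))
  genes <- c(genes, setdiff(unique(calls$gene_label), genes))
  taxa <- sort(unique(calls$taxon))
  mat <- matrix(NA_character_, length(taxa), length(genes),
                dimnames = list(taxa, genes))
  for (k in seq_len(nrow(calls))) {
    mat[calls$taxon[k], calls$gene_label[k]] <- calls$final_codon[k]
  }
  tallies <- lapply(genes, function(g) {
    v <- mat[, g]
    as.list(table(v[!is.na(v)]))
  })
  names(tallies) <- genes
  structure(list(matrix = as.data.frame(mat, stringsAsFactors = FALSE),
                 tallies = tallies),
            class = "codon_usage_matrix")
}

#' @export
print.codon_usage_matrix <- function(x, ...) {
  cat("<codon_usage_matrix>", nrow(x$matrix), "taxa x",
      ncol(x$matrix), "genes\n")
  for (g in names(x$tallies)) {
    t <- x$tallies[[g]]
    if (length(t)) {
      cat(sprintf("  %-5s %s\n", g,
                  paste(sprintf("%s:%d", names(t), unlist(t)), collapse = " ")))
    }
  }
  invisible(x)
}
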