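# Uniform record model for annotated mitogenomes, plus GenBank flat-file and
# FASTA+GFF3 ingestion. Internal coordinates are 0-based half-open on the
# plus strand; GenBank's 1-based inclusive coordinates are converted at the
# boundary. A feature spanning the circular origin keeps start near the end
# of the sequence and end <= start, with wraps_origin set.

.PCG_LABELS <- c("ND1", "ND2", "COI", "COII", "ATP8", "ATP6", "COIII",
                 "ND3", "ND4L", "ND4", "ND5", "ND6", "CYTB")
.RRNA_LABELS <- c("12S", "16S")

#' Canonical metazoan mitochondrial protein-coding gene labels
#'
#' The 13 protein-coding genes of the canonical metazoan mitogenome, in
#' conventional naming: ND1-ND6 and ND4L (NADH dehydrogenase subunits),
#' COI-COIII (cytochrome c oxidase), ATP6/ATP8, and CYTB.
#' @return Character vector of length 13.
#' @export
pcg_labels <- function() .PCG_LABELS

#' @rdname pcg_labels
#' @export
rrna_labels <- function() .RRNA_LABELS

# Synonym table: heterogeneous GenBank/MITOS names -> normalized label.
.GENE_SYNONYMS <- local({
  syn <- list(
    COI  = c("COI", "COX1", "CO1", "COXI", "MT-CO1"),
    COII = c("COII", "COX2", "CO2", "COXII", "MT-CO2"),
    COIII = c("COIII", "COX3", "CO3", "COXIII", "MT-CO3"),
    CYTB = c("CYTB", "COB", "CYB", "MT-CYB"),
    ATP6 = c("ATP6", "ATPASE6", "ATPASE 6", "ATP SYNTHASE 6", "MT-ATP6"),
    ATP8 = c("ATP8", "ATPASE8", "ATPASE 8", "ATP SYNTHASE 8", "MT-ATP8"),
    ND1 = c("ND1", "NAD1", "NADH1", "MT-ND1"),
    ND2 = c("ND2", "NAD2", "NADH2", "MT-ND2"),
    ND3 = c("ND3", "NAD3", "NADH3", "MT-ND3"),
    ND4 = c("ND4", "NAD4", "NADH4", "MT-ND4"),
    ND4L = c("ND4L", "NAD4L", "NADH4L", "MT-ND4L"),
    ND5 = c("ND5", "NAD5", "NADH5", "MT-ND5"),
    ND6 = c("ND6", "NAD6", "NADH6", "MT-ND6"),
    `16S` = c("16S", "RRNL", "L-RRNA", "LSU", "16S RRNA", "RRN16", "LRRNA"),
    `12S` = c("12S", "RRNS", "S-RRNA", "SSU", "12S RRNA", "RRN12", "SRRNA")
  )
  out <- stats::setNames(rep(names(syn), lengths(syn)), toupper(unlist(syn)))
  out
})

#' Normalize a gene name
#'
#' Maps heterogeneous annotation names (COX1, NAD1, rrnL, ...) onto the
#' canonical labels used throughout the package (COI, ND1, 16S, ...).
#' tRNA names (trnX / tRNA-Xxx) are normalized to `trnX` form. Unknown
#' names pass through unchanged.
#'
#' @param name Character vector of as-annotated gene names.
#' @return Character vector of normalized labels.
#' @export
normalize_gene_name <- function(name) {
  vapply(name, function(nm) {
    if (is.na(nm) || !nzchar(nm)) return(NA_character_)
    key <- toupper(trimws(nm))
    if (!is.na(.GENE_SYNONYMS[key])) return(unname(.GENE_SYNONYMS[key]))
    # tRNAs: trnA, trnL1, tRNA-Leu, TRNL ...
    if (grepl("^TRNA[-_ ]", key)) {
      aa3 <- sub("^TRNA[-_ ]", "", key)
      one <- .AA3_TO_1[substr(aa3, 1, 3)]
      if (!is.na(one)) return(paste0("trn", unname(one)))
    }
    if (grepl("^TRN", key)) {
      return(paste0("trn", sub("^TRN[-_ ]?", "", key)))
    }
    nm
  }, character(1), USE.NAMES = FALSE)
}

.AA3_TO_1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
               GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
               LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
               SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Classify a normalized gene label into a feature kind
#' @param label Character vector of normalized labels.
#' @return Character vector: `"PCG"`, `"rRNA"`, `"tRNA"` or `"other"`.
#' @export
gene_kind <- function(label) {
  ifelse(label %in% .PCG_LABELS, "PCG",
         ifelse(label %in% .RRNA_LABELS, "rRNA",
                ifelse(grepl("^trn", label), "tRNA", "other")))
}

.empty_features <- function() {
  data.frame(label = character(0), raw_name = character(0),
             kind = character(0), start = integer(0), end = integer(0),
             strand = character(0), wraps_origin = logical(0),
             partial_5prime = logical(0), partial_3prime = logical(0),
             stringsAsFactors = FALSE)
}

#' Construct a mitogenome record
#'
#' The uniform in-memory model: one genome's sequence with its feature
#' table. Feature coordinates are 0-based half-open on the plus strand;
#' `end <= start` is only legal for features wrapping the circular origin.
#'
#' @param taxon Taxon name.
#' @param sequence Nucleotide string.
#' @param features Feature data.frame with columns `label`, `raw_name`,
#'   `kind`, `start`, `end`, `strand`, `wraps_origin`, `partial_5prime`,
#'   `partial_3prime`.
#' @param circular Logical; complete circular genome.
#' @param accession Accession string (may be empty).
#' @param table_id NCBI translation-table id used for this genome's PCGs.
#' @param extra_genes Optional data.frame of coordinate-free gene copies
#'   (columns `label`, `kind`, `seq`, `accession`), used when conspecific
#'   records are pooled into one terminal.
#' @return A `mitogenome_record` object.
#' @export
mitogenome_record <- function(taxon, sequence, features = .empty_features(),
                              circular = TRUE, accession = "", table_id = 9L,
                              extra_genes = NULL) {
  sequence <- normalize_seq(sequence)
  n <- nchar(sequence)
  if (nrow(features)) {
    bad <- features$start < 0 | features$start >= n |
      features$end < 0 | features$end > n
    if (any(bad)) stop("feature coordinates out of bounds for ",
                       paste(features$label[bad], collapse = ","), call. = FALSE)
    if (any(features$end <= features$start & !features$wraps_origin)) {
      stop("end <= start only permitted for origin-wrapping features",
           call. = FALSE)
    }
  }
  structure(
    list(taxon = taxon, accession = accession, sequence = sequence,
         circular = isTRUE(circular), features = features,
         table_id = as.integer(table_id), extra_genes = extra_genes),
    class = "mitogenome_record"
  )
}

#' @export
print.mitogenome_record <- function(x, ...) {
  cat(sprintf("<mitogenome_record> %s %s: %d nt (%s), %d features\n",
              x$taxon, x$accession, nchar(x$sequence),
              if (x$circular) "circular" else "linear", nrow(x$features)))
  tab <- table(x$features$kind)
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Length of a feature in nucleotides (wrap-aware)
#' @param feature One-row feature data.frame (or list with start/end/...).
#' @param genome_length Genome length in nt.
#' @return Integer length.
#' @export
feature_length <- function(feature, genome_length) {
  if (isTRUE(feature$wraps_origin)) {
    (genome_length - feature$start) + feature$end
  } else {
    feature$end - feature$start
  }
}

#' Extract a feature's 5'-to-3' nucleotide sequence
#'
#' Concatenates across the circular origin for wrapping features and
#' reverse-complements minus-strand features.
#'
#' @param record A `mitogenome_record`.
#' @param feature One row of `record$features` (data.frame row or list).
#' @return Nucleotide string, 5' to 3' in gene orientation.
#' @export
extract_feature_seq <- function(record, feature) {
  n <- nchar(record$sequence)
  s <- feature$start; e <- feature$end
  if (s < 0 || s >= n || e < 0 || e > n) stop("feature out of bounds", call. = FALSE)
  seq <- if (isTRUE(feature$wraps_origin)) {
    paste0(substr(record$sequence, s + 1L, n), substr(record$sequence, 1L, e))
  } else {
    substr(record$sequence, s + 1L, e)
  }
  if (feature$strand == "-") seq <- revcomp(seq)
  seq
}

#' Reverse-complement a DNA string
#' @param seq Nucleotide string.
#' @return Reverse complement.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## ---- GenBank flat-file I/O -------------------------------------------------

.parse_gb_location <- function(loc) {
  out <- list(strand = "+", wraps_origin = FALSE,
              partial_5prime = FALSE, partial_3prime = FALSE)
  loc <- gsub("[[:space:]]", "", loc)
  if (grepl("^complement\\(", loc)) {
    out$strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  segs_txt <- if (grepl("^join\\(", loc)) {
    strsplit(sub("^join\\((.*)\\)$", "\\1", loc), ",", fixed = TRUE)[[1]]
  } else loc
  segs <- lapply(segs_txt, function(s) {
    p5 <- grepl("<", s); p3 <- grepl(">", s)
    s <- gsub("[<>]", "", s)
    ends <- as.numeric(strsplit(s, "..", fixed = TRUE)[[1]])
    if (any(is.na(ends))) stop("unparseable location segment: ", s, call. = FALSE)
    if (length(ends) == 1L) ends <- c(ends, ends)
    list(from = ends[1], to = ends[2], p5 = p5, p3 = p3)
  })
  first <- segs[[1]]; last <- segs[[length(segs)]]
  if (out$strand == "+") {
    out$partial_5prime <- first$p5; out$partial_3prime <- last$p3
  } else {
    # complement(): biological 5' end is the high-coordinate side
    out$partial_5prime <- last$p3; out$partial_3prime <- first$p5
  }
  if (length(segs) > 1L && last$to < first$from) {
    out$wraps_origin <- TRUE
    out$start <- as.integer(first$from - 1L)
    out$end <- as.integer(last$to)
  } else {
    out$start <- as.integer(first$from - 1L)
    out$end <- as.integer(last$to)
  }
  out
}

#' Read a GenBank flat file into a mitogenome record
#'
#' Parses LOCUS (length, circular/linear), ACCESSION, ORGANISM, the feature
#' table (CDS, rRNA, tRNA) and ORIGIN sequence. GenBank 1-based inclusive
#' coordinates become 0-based half-open; `join()` locations spanning the
#' origin of a circular genome set `wraps_origin`; `complement()` sets the
#' minus strand; `<`/`>` markers set partial flags. `/gene` (falling back to
#' `/product`) supplies the raw name, which is normalized via
#' [normalize_gene_name()].
#'
#' @param path Path to a GenBank flat file.
#' @param table_id Translation table recorded on the result (a
#'   `/transl_table` qualifier in the file takes precedence).
#' @return A `mitogenome_record`.
#' @export
read_genbank <- function(path, table_id = 9L) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1])) {
    stop("not a GenBank flat file (missing LOCUS): ", path, call. = FALSE)
  }
  circular <- grepl("circular", lines[1], ignore.case = TRUE)
  acc <- ""
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc_line)) acc <- trimws(sub("^ACCESSION", "", acc_line[1]))
  taxon <- ""
  org_line <- grep("^[[:space:]]+ORGANISM", lines, value = TRUE)
  if (length(org_line)) taxon <- trimws(sub("^[[:space:]]+ORGANISM", "", org_line[1]))
  if (!nzchar(taxon)) {
    src <- grep("^SOURCE", lines, value = TRUE)
    if (length(src)) taxon <- trimws(sub("^SOURCE", "", src[1]))
  }

  ft_start <- grep("^FEATURES", lines)
  or_start <- grep("^ORIGIN", lines)
  if (!length(or_start)) stop("missing ORIGIN sequence in ", path, call. = FALSE)
  seq_lines <- lines[(or_start[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("record without sequence: ", path, call. = FALSE)

  feats <- .empty_features()
  tbl_id <- table_id
  if (length(ft_start)) {
    block <- lines[(ft_start[1] + 1L):(or_start[1] - 1L)]
    # feature headers start at column 6; qualifiers/continuations at column 22
    hdr_idx <- grep("^ {5}[A-Za-z]", block)
    for (k in seq_along(hdr_idx)) {
      i <- hdr_idx[k]
      j <- if (k < length(hdr_idx)) hdr_idx[k + 1L] - 1L else length(block)
      key <- trimws(substr(block[i], 1, 20))
      if (!key %in% c("CDS", "rRNA", "tRNA")) next
      body <- trimws(substr(block[i:j], 22, nchar(block[i:j])))
      # location may continue over lines until the first qualifier
      qual_at <- grep("^/", body)
      loc_end <- if (length(qual_at)) qual_at[1L] - 1L else length(body)
      loc <- paste(body[seq_len(loc_end)], collapse = "")
      quals <- body[qual_at]
      getq <- function(nm) {
        hit <- grep(paste0("^/", nm, "="), quals, value = TRUE)
        if (!length(hit)) return(NA_character_)
        gsub('^"|"$', "", sub(paste0("^/", nm, "="), "", hit[1]))
      }
      raw_name <- getq("gene")
      if (is.na(raw_name)) raw_name <- getq("product")
      tt <- getq("transl_table")
      if (!is.na(tt)) tbl_id <- as.integer(tt)
      pl <- tryCatch(.parse_gb_location(loc), error = function(e)
        stop("unparseable location near line ", ft_start[1] + i, " of ", path,
             ": ", conditionMessage(e), call. = FALSE))
      label <- normalize_gene_name(raw_name)
      feats <- rbind(feats, data.frame(
        label = label, raw_name = raw_name,
        kind = if (key == "CDS") "PCG"
               else if (key == "rRNA") "rRNA" else "tRNA",
        start = pl$start, end = pl$end, strand = pl$strand,
        wraps_origin = pl$wraps_origin,
        partial_5prime = pl$partial_5prime, partial_3prime = pl$partial_3prime,
        stringsAsFactors = FALSE))
    }
    # unknown CDS names pass through as kind=other (excluded from PCG audits)
    if (nrow(feats)) {
      feats$kind[feats$kind == "PCG" & !feats$label %in% .PCG_LABELS] <- "other"
    }
  }
  mitogenome_record(taxon = taxon, sequence = sequence, features = feats,
                    circular = circular, accession = acc, table_id = tbl_id)
}

.format_gb_location <- function(f, n) {
  if (isTRUE(f$wraps_origin)) {
    core <- sprintf("join(%d..%d,1..%d)", f$start + 1L, n, f$end)
  } else {
    lhs <- if (isTRUE(f$strand == "+") && isTRUE(f$partial_5prime)) "<" else
      if (f$strand == "-" && isTRUE(f$partial_3prime)) "<" else ""
    rhs <- if (f$strand == "+" && isTRUE(f$partial_3prime)) ">" else
      if (f$strand == "-" && isTRUE(f$partial_5prime)) ">" else ""
    core <- sprintf("%s%d..%s%d", lhs, f$start + 1L, rhs, f$end)
  }
  if (f$strand == "-") core <- sprintf("complement(%s)", core) else core
}

#' Write a mitogenome record as a GenBank flat file
#'
#' Emits LOCUS, ACCESSION, SOURCE/ORGANISM, a feature table (CDS/rRNA/tRNA
#' with `/gene` qualifiers and `/transl_table` on CDS) and the ORIGIN block.
#' Round-trips through [read_genbank()] bit-exactly for coordinates,
#' strands and labels.
#'
#' @param record A `mitogenome_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  n <- nchar(record$sequence)
  topo <- if (record$circular) "circular" else "linear"
  out <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     %s MIT %s",
            ifelse(nzchar(record$accession), record$accession, "UNNAMED"),
            n, topo, format(as.Date("2020-01-01"), "%d-%b-%Y")),
    sprintf("DEFINITION  %s mitochondrion.", record$taxon),
    sprintf("ACCESSION   %s", record$accession),
    sprintf("SOURCE      %s", record$taxon),
    sprintf("  ORGANISM  %s", record$taxon),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n)
  )
  if (nrow(record$features)) {
    for (i in seq_len(nrow(record$features))) {
      f <- record$features[i, ]
      key <- switch(f$kind, PCG = "CDS", rRNA = "rRNA", tRNA = "tRNA", "misc_feature")
      out <- c(out,
               sprintf("     %-15s %s", key, .format_gb_location(f, n)),
               sprintf('                     /gene="%s"', f$raw_name))
      if (key == "CDS") {
        out <- c(out, sprintf("                     /transl_table=%d",
                              record$table_id))
      }
    }
  }
  out <- c(out, "ORIGIN")
  pos <- seq(1L, n, by = 60L)
  for (p in pos) {
    chunk <- substr(record$sequence, p, min(p + 59L, n))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, tolower(paste(tens, collapse = " "))))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

## ---- FASTA + GFF3 ----------------------------------------------------------

#' Read a FASTA + GFF3 pair into a mitogenome record
#'
#' The GFF3 `seqid` must match the FASTA header token before the first
#' whitespace. `gene=` or `Name=` attributes supply the raw gene name.
#' CDS/mRNA types become PCG features; rRNA and tRNA types map directly.
#'
#' @param fasta_path FASTA file with one genome sequence.
#' @param gff_path GFF3 annotation file.
#' @param taxon Taxon name (defaults to the FASTA header token).
#' @param circular Logical topology flag.
#' @param table_id Translation-table id.
#' @return A `mitogenome_record`.
#' @export
read_fasta_gff3 <- function(fasta_path, gff_path, taxon = NULL,
                            circular = TRUE, table_id = 9L) {
  dna <- Biostrings::readDNAStringSet(fasta_path)
  if (!length(dna)) stop("no sequence in ", fasta_path, call. = FALSE)
  seqid <- strsplit(names(dna)[1], "[[:space:]]")[[1]][1]
  if (is.null(taxon)) taxon <- seqid
  gff <- rtracklayer::import.gff3(gff_path)
  gff <- gff[as.character(GenomicRanges::seqnames(gff)) == seqid]
  type <- as.character(gff$type)
  keep <- type %in% c("CDS", "rRNA", "tRNA")
  gff <- gff[keep]; type <- type[keep]
  nm <- rep(NA_character_, length(gff))
  if (!is.null(gff$gene)) nm <- ifelse(!is.na(gff$gene), gff$gene, nm)
  if (!is.null(gff$Name)) nm <- ifelse(is.na(nm) & !is.na(gff$Name), gff$Name, nm)
  label <- normalize_gene_name(nm)
  feats <- data.frame(
    label = label, raw_name = nm,
    kind = ifelse(type == "CDS", "PCG", type),
    start = GenomicRanges::start(gff) - 1L,
    end = GenomicRanges::end(gff),
    strand = ifelse(as.character(GenomicRanges::strand(gff)) == "-", "-", "+"),
    wraps_origin = FALSE, partial_5prime = FALSE, partial_3prime = FALSE,
    stringsAsFactors = FALSE)
  mitogenome_record(taxon = taxon, sequence = as.character(dna[[1]]),
                    features = feats, circular = circular, table_id = table_id)
}

## ---- reports ---------------------------------------------------------------

#' Write an initiation-codon audit report as TSV
#'
#' One row per (taxon, gene), ordered deterministically: taxa
#' alphabetically, genes in the canonical 13-PCG order.
#'
#' @param calls Data.frame of start-codon calls, as produced by
#'   [audit_gene()] / [run_full_audit()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_audit_report <- function(calls, path) {
  ord <- order(match(calls$gene_label, c(.PCG_LABELS, .RRNA_LABELS)),
               calls$taxon)
  calls <- calls[ord, , drop = FALSE]
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
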