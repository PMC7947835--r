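# GenBank / FASTA+GFF3 ingestion, coordinate semantics, extraction.

make_gb_text <- function(loc_lines, seq, circular = TRUE) {
  n <- nchar(seq)
  c(sprintf("LOCUS       TEST             %d bp    DNA     %s MIT 01-JAN-2020",
            n, if (circular) "circular" else "linear"),
    "DEFINITION  test record.",
    "ACCESSION   TEST01",
    "SOURCE      Testa taxa",
    "  ORGANISM  Testa taxa",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", n),
    loc_lines,
    "ORIGIN",
    sprintf("%9d %s", 1, tolower(seq)),
    "//")
}

test_that("GenBank coordinates convert to 0-based half-open", {
  seq <- paste(rep("ACGTACGTAC", 10), collapse = "")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(make_gb_text(c(
    "     CDS             1..9",
    '                     /gene="ND3"'), seq), path)
  rec <- read_genbank(path)
  f <- rec$features[1, ]
  expect_identical(f$start, 0L)
  expect_identical(f$end, 9L)
  expect_identical(f$strand, "+")
  expect_false(f$wraps_origin)
  expect_identical(rec$taxon, "Testa taxa")
  expect_identical(rec$accession, "TEST01")
  expect_true(rec$circular)
})

test_that("origin-spanning complement locations parse with wrap and strand", {
  seq <- paste(rep("ACGTACGTAC", 10), collapse = "")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(make_gb_text(c(
    "     CDS             complement(join(95..100,1..10))",
    '                     /gene="ND5"'), seq), path)
  rec <- read_genbank(path)
  f <- rec$features[1, ]
  expect_identical(f$strand, "-")
  expect_true(f$wraps_origin)
  expect_identical(f$start, 94L)
  expect_identical(f$end, 10L)
  expect_equal(feature_length(f, 100L), 16L)
})

test_that("partial markers set partial flags", {
  seq <- paste(rep("ACGTACGTAC", 10), collapse = "")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(make_gb_text(c(
    "     CDS             <5..20",
    '                     /gene="COI"',
    "     CDS             complement(30..>50)",
    '                     /gene="ND6"'), seq, circular = FALSE), path)
  rec <- read_genbank(path)
  expect_true(rec$features$partial_5prime[1])
  expect_false(rec$features$partial_3prime[1])
  # on the minus strand the high-coordinate '>' marker is the biological 5'
  expect_true(rec$features$partial_5prime[2])
  expect_false(rec$features$partial_3prime[2])
  expect_false(rec$circular)
})

test_that("malformed or sequence-less files raise format errors", {
  p1 <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("not a genbank file"), p1)
  expect_error(read_genbank(p1), "LOCUS")
  p2 <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X 10 bp DNA circular", "FEATURES", "//"), p2)
  expect_error(read_genbank(p2), "ORIGIN")
})

test_that("feature extraction honours strand and circular wrap", {
  rec <- mitogenome_record("t", "ATGAAATTTCATCCC", data.frame(
    label = c("g1", "g2"), raw_name = c("g1", "g2"), kind = "other",
    start = c(0L, 6L), end = c(6L, 12L), strand = c("+", "-"),
    wraps_origin = FALSE, partial_5prime = FALSE, partial_3prime = FALSE,
    stringsAsFactors = FALSE))
  expect_identical(extract_feature_seq(rec, rec$features[1, ]), "ATGAAA")
  # minus strand: reverse complement of TTTCAT is ATGAAA
  expect_identical(extract_feature_seq(rec, rec$features[2, ]), "ATGAAA")
})

test_that("wrap-around extraction matches the doubled-sequence oracle", {
  withr::with_seed(7, {
    n <- 60L
    seq <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    doubled <- paste0(seq, seq)
    for (rep in 1:25) {
      start <- sample(30:59, 1)
      len <- sample(5:25, 1)
      end <- (start + len) %% n
      if (start + len <= n) next   # only wrap cases are interesting here
      f <- data.frame(label = "g", raw_name = "g", kind = "other",
                      start = start, end = end, strand = "+",
                      wraps_origin = TRUE, partial_5prime = FALSE,
                      partial_3prime = FALSE, stringsAsFactors = FALSE)
      rec <- mitogenome_record("t", seq, f)
      want <- substr(doubled, start + 1, start + len)
      expect_identical(extract_feature_seq(rec, f), want)
      f$strand <- "-"
      expect_identical(extract_feature_seq(rec, f), revcomp(want))
    }
  })
})

test_that("GenBank write-read round-trips generated genomes bit-exactly", {
  g <- build_genome(tiny_spec(seed = 5))
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g$record, path)
  back <- read_genbank(path)
  expect_identical(back$sequence, g$record$sequence)
  expect_identical(back$features, g$record$features)
  expect_identical(back$circular, g$record$circular)
  expect_identical(back$accession, g$record$accession)
  expect_identical(back$table_id, g$record$table_id)
  # minus-strand extraction equals reverse complement of plus extraction
  for (i in seq_len(nrow(back$features))) {
    f <- back$features[i, ]
    fwd <- f; fwd$strand <- "+"
    expect_identical(
      extract_feature_seq(back, f),
      if (f$strand == "-") revcomp(extract_feature_seq(back, fwd))
      else extract_feature_seq(back, fwd))
  }
})

test_that("gene names normalize through the synonym table", {
  expect_identical(normalize_gene_name(c("COX1", "CO1", "COI")),
                   rep("COI", 3))
  expect_identical(normalize_gene_name(c("NAD1", "nad4l", "CYB", "cob")),
                   c("ND1", "ND4L", "CYTB", "CYTB"))
  expect_identical(normalize_gene_name(c("rrnL", "l-rRNA", "16S")),
                   rep("16S", 3))
  expect_identical(normalize_gene_name(c("rrnS", "12S rRNA")), rep("12S", 2))
  expect_identical(normalize_gene_name("tRNA-Leu"), "trnL")
  expect_identical(normalize_gene_name("trnK"), "trnK")
  # unknown names pass through; their kind is 'other'
  expect_identical(normalize_gene_name("ORF314"), "ORF314")
  expect_identical(gene_kind(c("COI", "16S", "trnF", "ORF314")),
                   c("PCG", "rRNA", "tRNA", "other"))
})

test_that("FASTA+GFF3 pairs load with seqid matching and gene attributes", {
  g <- build_genome(tiny_spec(seed = 2))
  r <- g$record
  fa <- withr::local_tempfile(fileext = ".fasta")
  gf <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(sprintf(">%s synthetic mitogenome", r$taxon), r$sequence), fa)
  rows <- vapply(seq_len(nrow(r$features)), function(i) {
    f <- r$features[i, ]
    type <- c(PCG = "CDS", rRNA = "rRNA", tRNA = "tRNA")[[f$kind]]
    sprintf("%s\tsynth\t%s\t%d\t%d\t.\t%s\t.\tID=f%d;gene=%s",
            r$taxon, type, f$start + 1, f$end, f$strand, i, f$raw_name)
  }, character(1))
  writeLines(c("##gff-version 3", rows), gf)
  back <- read_fasta_gff3(fa, gf)
  expect_identical(back$sequence, r$sequence)
  expect_identical(back$taxon, r$taxon)
  ord <- order(back$features$start)
  expect_identical(back$features$label[ord], r$features$label)
  expect_identical(back$features$start[ord], r$features$start)
  expect_identical(back$features$strand[ord], r$features$strand)
})

test_that("audit reports are written in canonical gene-then-taxon order", {
  calls <- data.frame(
    taxon = c("b", "a", "a"), accession = "x",
    gene_label = c("ND1", "COI", "ND1"), annotated_codon = "ATG",
    verdict = "confirmed", shift_codons = 0L, final_codon = "ATG",
    classification = "canonical", five_prime_offset = 0L, notes = "",
    stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_audit_report(calls, path)
  got <- utils::read.delim(path)
  expect_identical(got$gene_label, c("ND1", "ND1", "COI"))
  expect_identical(got$taxon, c("a", "b", "a"))
})
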