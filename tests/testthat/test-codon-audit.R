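# Center-star alignment, consensus-start location, and the initiation-codon
# audit itself.

test_that("identical sequences align gap-free", {
  aln <- align_protein_set(c(a = "MKLV", b = "MKLV", c = "MKLV"))
  expect_true(all(aln$aligned == "MKLV"))
  expect_identical(aln$consensus_start_col, 1L)
})

test_that("a prefix sequence gets a suffix gap block only", {
  aln <- align_protein_set(c(a = "MKLVWYHH", b = "MKLV"))
  expect_identical(unname(aln$aligned[["b"]]), "MKLV----")
})

test_that("rows degap to their inputs and back-maps increase strictly", {
  withr::with_seed(31, {
    aas <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
    for (rep in 1:8) {
      n <- sample(3:6, 1)
      seqs <- vapply(seq_len(n), function(i)
        paste(sample(aas, sample(8:25, 1), TRUE), collapse = ""), character(1))
      names(seqs) <- paste0("t", seq_len(n))
      aln <- align_protein_set(seqs)
      expect_identical(unique(nchar(aln$aligned)), nchar(aln$aligned[[1]]))
      for (tx in names(seqs)) {
        expect_identical(gsub("-", "", aln$aligned[[tx]]),
                         unname(seqs[[tx]]))
        bm <- aln$backmap[[tx]]
        expect_true(all(diff(bm[!is.na(bm)]) > 0))
      }
    }
  })
})

test_that("pairwise star scores match an independent Gotoh dynamic program", {
  subm <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    get("BLOSUM62", envir = e)
  })
  withr::with_seed(17, {
    aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (rep in 1:10) {
      a <- paste(sample(aas, sample(4:8, 1), TRUE), collapse = "")
      b <- paste(sample(aas, sample(4:8, 1), TRUE), collapse = "")
      ours <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
        substitutionMatrix = subm, gapOpening = 10, gapExtension = 1,
        scoreOnly = TRUE)
      expect_equal(ours, gotoh_score(a, b, subm), tolerance = 1e-9)
    }
  })
})

test_that("the chosen center maximizes the summed pairwise score", {
  subm <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    get("BLOSUM62", envir = e)
  })
  seqs <- c(t1 = "MKLVWY", t2 = "MKIVWY", t3 = "MRLVW", t4 = "AKLVWY")
  sums <- vapply(names(seqs), function(ci) {
    sum(vapply(setdiff(names(seqs), ci), function(o)
      gotoh_score(seqs[[ci]], seqs[[o]], subm), numeric(1)))
  }, numeric(1))
  best <- names(which.max(sums))
  aln <- align_protein_set(seqs)
  # the center row is the one that stays gap-free here
  center_row <- names(aln$aligned)[!grepl("-", aln$aligned)]
  expect_true(best %in% center_row)
})

test_that("consensus start column follows the mode with ties to the 5' side", {
  a1 <- align_protein_set(c(a = "MKLVW", b = "MKLVW", c = "MKLVW"))
  cs <- locate_consensus_start(a1)
  expect_identical(cs$consensus_start_col, 1L)
  expect_true(all(cs$offsets == 0L))
  # one row one codon short at the 5' end: offset +1
  seqs <- c(vapply(1:16, function(i) "MKLVWYHAKL", character(1)),
            short = "KLVWYHAKL")
  names(seqs)[1:16] <- sprintf("t%02d", 1:16)
  cs2 <- locate_consensus_start(align_protein_set(seqs))
  expect_identical(unname(cs2$offsets[["short"]]), 1L)
  expect_true(all(cs2$offsets[sprintf("t%02d", 1:16)] == 0L))
  # 2-2 tie resolves toward the longer 5' end (smaller column)
  seqs3 <- c(a = "MKLVWYHAKL", b = "MKLVWYHAKL",
             c = "KLVWYHAKL", d = "KLVWYHAKL")
  cs3 <- locate_consensus_start(align_protein_set(seqs3))
  expect_identical(cs3$consensus_start_col, 1L)
  expect_identical(unname(cs3$offsets[c("a", "b", "c", "d")]),
                   c(0L, 0L, 1L, 1L))
})

# A controlled audit cohort: identical genomes except where stated, so every
# verdict is forced by construction.
audit_fixture <- function(n = 6, gene_start = "ATG", upstream = "CCTCCT",
                          shift_taxon = NULL, shift_by = 0L) {
  tab <- get_table(9)
  withr::with_seed(99, {
    body <- sample(setdiff(names(tab$codon_to_aa), tab$stops), 30, TRUE)
  })
  gene <- paste(c(gene_start, body, "TAA"), collapse = "")
  trna <- paste(rep("ACGT", 5), collapse = "")
  recs <- lapply(seq_len(n), function(i) {
    hand_record(sprintf("tax%02d", i),
                list(list(label = "trnV", seq = trna),
                     list(label = "ND3", seq = gene),
                     list(label = "trnW", seq = trna)),
                list("AAAA", upstream, "GGGG", "TTTT"),
                accession = sprintf("F%02d", i))
  })
  if (!is.null(shift_taxon)) {
    for (i in shift_taxon) {
      f <- recs[[i]]$features
      k <- which(f$label == "ND3")
      f$start[k] <- f$start[k] + 3L * shift_by
      recs[[i]]$features <- f
    }
  }
  recs
}

test_that("a start annotated downstream of the cohort is corrected upstream", {
  # codon 2 of the true gene becomes the annotated codon after a +1 shift
  recs <- audit_fixture(n = 6, shift_taxon = 3, shift_by = 1L)
  sets <- build_ortholog_sets(recs, genes = "ND3")
  calls <- audit_gene(sets$ND3, recs, get_table(9, extended = TRUE))
  bad <- calls[calls$taxon == "tax03", ]
  good <- calls[calls$taxon != "tax03", ]
  expect_identical(bad$verdict, "corrected")
  expect_identical(bad$shift_codons, -1L)
  expect_identical(bad$final_codon, "ATG")
  expect_identical(bad$five_prime_offset, 1L)
  expect_true(all(good$verdict == "confirmed"))
  expect_true(all(good$shift_codons == 0L))
})

test_that("an upstream-shifted annotation is corrected back downstream", {
  recs <- audit_fixture(n = 6, shift_taxon = 2, shift_by = -2L)
  sets <- build_ortholog_sets(recs, genes = "ND3")
  calls <- audit_gene(sets$ND3, recs, get_table(9, extended = TRUE))
  bad <- calls[calls$taxon == "tax02", ]
  expect_identical(bad$verdict, "corrected")
  expect_identical(bad$shift_codons, 2L)
  expect_identical(bad$final_codon, "ATG")
})

test_that("a planted extended-alternative start is confirmed, not corrected", {
  recs <- audit_fixture(n = 6, gene_start = "ATC")
  sets <- build_ortholog_sets(recs, genes = "ND3")
  calls <- audit_gene(sets$ND3, recs, get_table(9, extended = TRUE))
  expect_true(all(calls$verdict == "confirmed"))
  expect_true(all(calls$classification == "extended_alternative"))
})

test_that("unrecognized codons at the consensus offset are flagged, never shifted onto", {
  # all taxa initiate with TTG; the in-frame codon upstream reads AAT
  recs <- audit_fixture(n = 6, gene_start = "TTG", upstream = "CCTAAT")
  sets <- build_ortholog_sets(recs, genes = "ND3")
  tab <- get_table(9, extended = TRUE)
  tab$extended_starts <- c("ATT", "ATC")          # TTG not admitted
  calls <- audit_gene(sets$ND3, recs, tab, allow_novel = TRUE)
  expect_true(all(calls$verdict == "novel_candidate"))
  expect_true(all(calls$final_codon == "TTG"))
  expect_true(all(calls$shift_codons == 0L))
  expect_false(any(calls$final_codon == "AAT"))
  # without allow_novel the same members are unresolved
  calls2 <- audit_gene(sets$ND3, recs, tab, allow_novel = FALSE)
  expect_true(all(calls2$verdict == "unresolved"))
  # admitting TTG to the extended set confirms them instead
  calls3 <- audit_gene(sets$ND3, recs, get_table(9, extended = TRUE))
  expect_true(all(calls3$verdict == "confirmed"))
  expect_true(all(calls3$classification == "extended_alternative"))
})

test_that("plant-and-recover holds on a diverged cohort with shifted annotations", {
  spec <- tiny_spec(seed = 21)
  cohort <- simulate_cohort(spec, 8, divergence = 0.05, seed = 4)
  pert <- perturb_annotations(cohort, shift_fraction = 0.25,
                              shift_range = 3L, seed = 6)
  recs <- lapply(pert, `[[`, "record")
  tab <- get_table(9, extended = TRUE)
  calls <- audit_cohort(recs, tab)
  perturbed <- do.call(rbind, lapply(pert, function(e) e$truth$perturbations))
  expect_gt(nrow(perturbed), 10L)
  for (k in seq_len(nrow(perturbed))) {
    p <- perturbed[k, ]
    cl <- calls[calls$taxon == p$taxon & calls$gene_label == p$gene, ]
    truth <- pert[[match(p$taxon, vapply(pert, function(e) e$record$taxon,
                                         character(1)))]]$truth$genes
    expect_identical(cl$verdict, "corrected",
                     label = paste(p$taxon, p$gene))
    expect_identical(cl$shift_codons, -p$magnitude)
    expect_identical(cl$final_codon,
                     truth$start_codon[truth$label == p$gene])
  }
  # unperturbed members stay confirmed
  keys <- paste(perturbed$taxon, perturbed$gene)
  rest <- calls[!paste(calls$taxon, calls$gene_label) %in% keys, ]
  expect_true(all(rest$verdict == "confirmed"))
  # no call ever proposes a stop codon
  expect_false(any(calls$final_codon %in% get_table(9)$stops))
})

test_that("audit output is invariant to member input order", {
  recs <- audit_fixture(n = 5, shift_taxon = 4, shift_by = 2L)
  sets1 <- build_ortholog_sets(recs, genes = "ND3")
  sets2 <- build_ortholog_sets(rev(recs), genes = "ND3")
  tab <- get_table(9, extended = TRUE)
  c1 <- audit_gene(sets1$ND3, recs, tab)
  c2 <- audit_gene(sets2$ND3, rev(recs), tab)
  expect_identical(c1, c2)
})

test_that("applying corrections makes a re-audit confirm everything", {
  recs <- audit_fixture(n = 6, shift_taxon = c(2, 5), shift_by = 1L)
  tab <- get_table(9, extended = TRUE)
  sets <- build_ortholog_sets(recs, genes = "ND3")
  calls <- audit_gene(sets$ND3, recs, tab)
  expect_identical(sum(calls$verdict == "corrected"), 2L)
  fixed <- apply_audit_corrections(recs, calls)
  sets2 <- build_ortholog_sets(fixed, genes = "ND3")
  calls2 <- audit_gene(sets2$ND3, fixed, tab)
  expect_true(all(calls2$verdict == "confirmed"))
  expect_true(all(calls2$shift_codons == 0L))
})

test_that("upstream candidates never cross a neighboring feature", {
  # spacer of 2 nt between tRNA and gene: upstream shifts would cross trnV
  recs <- audit_fixture(n = 4, upstream = "CC", shift_taxon = 1,
                        shift_by = 1L)
  sets <- build_ortholog_sets(recs, genes = "ND3")
  calls <- audit_gene(sets$ND3, recs, get_table(9, extended = TRUE))
  # the shifted member is still recovered: its correction target lies
  # within its own (true) gene span, not across the tRNA
  expect_identical(calls$verdict[calls$taxon == "tax01"], "corrected")
  # nobody is ever shifted upstream into the tRNA
  expect_true(all(calls$shift_codons >= -1L))
})

test_that("iterating the audit untangles interlocked neighbor misannotations", {
  # ND6(-) and CYTB(+) with facing 5' ends across a short spacer; in one
  # taxon ND6's annotation is extended over CYTB's true start while CYTB's
  # is shifted downstream: CYTB's upstream scan is blocked until the ND6
  # correction is applied
  tab <- get_table(9)
  withr::with_seed(55, {
    nonstop <- setdiff(names(tab$codon_to_aa), tab$stops)
    nd6 <- paste(c("ATG", sample(nonstop, 40, TRUE), "TAA"), collapse = "")
    cytb <- paste(c("ATG", sample(nonstop, 44, TRUE), "TAA"), collapse = "")
  })
  recs <- lapply(1:5, function(i) {
    hand_record(sprintf("tax%02d", i),
                list(list(label = "ND6", seq = nd6, strand = "-"),
                     list(label = "CYTB", seq = cytb)),
                list("AAAACC", "CCTT", "GGGA"),
                accession = sprintf("I%02d", i))
  })
  f <- recs[[2]]$features
  f$end[f$label == "ND6"] <- f$end[f$label == "ND6"] + 6L    # -2 codons, 5'
  f$start[f$label == "CYTB"] <- f$start[f$label == "CYTB"] + 3L
  recs[[2]]$features <- f
  tab9 <- get_table(9, extended = TRUE)
  # single pass: CYTB's upstream candidate crosses the inflated ND6
  sets <- build_ortholog_sets(recs, genes = c("ND6", "CYTB"))
  single <- audit_gene(sets$CYTB, recs, tab9)
  expect_identical(single$verdict[single$taxon == "tax02"], "unresolved")
  # iterated: both genes come back corrected to their planted starts
  calls <- audit_cohort(recs, tab9, genes = c("ND6", "CYTB"))
  bad <- calls[calls$taxon == "tax02", ]
  expect_setequal(bad$verdict, "corrected")
  expect_identical(bad$shift_codons[bad$gene_label == "ND6"], 2L)
  expect_identical(bad$shift_codons[bad$gene_label == "CYTB"], -1L)
  expect_true(all(bad$final_codon == "ATG"))
  expect_true(all(calls$verdict[calls$taxon != "tax02"] == "confirmed"))
})

test_that("codon usage tallies final codons per gene", {
  calls <- data.frame(
    taxon = c("a", "b", "c"), accession = "",
    gene_label = "ND3", annotated_codon = c("ATT", "ATT", "ATG"),
    verdict = "confirmed", shift_codons = 0L,
    final_codon = c("ATT", "ATT", "ATG"),
    classification = "extended_alternative", five_prime_offset = 0L,
    notes = "", stringsAsFactors = FALSE)
  u <- codon_usage(calls)
  expect_identical(u$tallies$ND3$ATT, 2L)
  expect_identical(u$tallies$ND3$ATG, 1L)
  expect_identical(u$matrix["a", "ND3"], "ATT")
  empty <- codon_usage(calls[0, ])
  expect_identical(nrow(empty$matrix), 0L)
  expect_length(empty$tallies, 0L)
})
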