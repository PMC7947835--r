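# Mitochondrial genetic-code variants (NCBI translation tables 1, 5, 9).
#
# The 64-codon assignments and initiation-codon sets below are transcribed
# from the NCBI genetic-code specification (the "gc.prt" release): codons
# enumerated with bases in T, C, A, G order, first base slowest.

.GC_BASES <- c("T", "C", "A", "G")

.gc_codons <- function() {
  g <- expand.grid(b3 = .GC_BASES, b2 = .GC_BASES, b1 = .GC_BASES,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

# NCBI amino-acid strings, codon order TTT, TTC, TTA, TTG, TCT, ...
.GC_AA_STRINGS <- list(
  "1" = "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  "5" = "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSSSSVVVVAAAADDEEGGGG",
  "9" = "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIIMTTTTNNNKSSSSVVVVAAAADDEEGGGG"
)

.GC_STARTS <- list(
  "1" = c("TTG", "CTG", "ATG"),
  "5" = c("TTG", "ATT", "ATC", "ATA", "ATG", "GTG"),
  "9" = c("ATG", "GTG")
)

.GC_NAMES <- list(
  "1" = "Standard",
  "5" = "Invertebrate Mitochondrial",
  "9" = "Echinoderm and Flatworm Mitochondrial"
)

#' Retrieve a mitochondrial translation table
#'
#' Builds the full NCBI definition of a genetic-code variant: the 64-entry
#' codon to amino-acid map, the stop codons, and the initiation-codon sets.
#' Table 1 is the standard code, table 5 the invertebrate mitochondrial code
#' (six initiation codons), and table 9 the echinoderm/flatworm mitochondrial
#' code, whose only NCBI-accepted starts are ATG and the alternative GTG.
#'
#' With `extended = TRUE` on table 9 the table additionally carries the
#' extended echinoderm start set `{ATT, ATC, TTG}`: codons that comparative
#' alignment evidence supports as initiation codons in asteroid mitogenomes
#' (ATT and ATC unambiguously; TTG as a preliminary fourth candidate) even
#' though the NCBI definition does not list them. ATA is deliberately absent
#' from the extended set, so ATA-initiated annotations remain audit targets
#' for correction. Tables 1 and 5 always have an empty extended set.
#'
#' @param table_id Integer NCBI code number; one of 1, 5, 9.
#' @param extended Logical; attach the extended echinoderm start set
#'   (meaningful for table 9 only).
#' @return A `translation_table` object: a list with elements `table_id`,
#'   `name`, `codon_to_aa` (named character vector of length 64, stop codons
#'   mapped to `"*"`), `canonical_starts`, `extended_starts`, `stops`.
#' @examples
#' tab9 <- get_table(9, extended = TRUE)
#' tab9$codon_to_aa[["AGA"]]   # "S"
#' tab9$canonical_starts       # ATG, GTG
#' @export
get_table <- function(table_id, extended = FALSE) {
  key <- as.character(table_id)
  if (length(table_id) != 1L || !key %in% names(.GC_AA_STRINGS)) {
    stop("unsupported translation table: ", paste(table_id, collapse = ","),
         " (supported: 1, 5, 9)", call. = FALSE)
  }
  aas <- strsplit(.GC_AA_STRINGS[[key]], "")[[1]]
  codon_to_aa <- stats::setNames(aas, .gc_codons())
  stops <- names(codon_to_aa)[codon_to_aa == "*"]
  ext <- character(0)
  if (isTRUE(extended) && key == "9") ext <- c("ATT", "ATC", "TTG")
  structure(
    list(
      table_id = as.integer(table_id),
      name = .GC_NAMES[[key]],
      codon_to_aa = codon_to_aa,
      canonical_starts = .GC_STARTS[[key]],
      extended_starts = ext,
      stops = stops
    ),
    class = "translation_table"
  )
}

#' @export
print.translation_table <- function(x, ...) {
  cat(sprintf("NCBI translation table %d (%s)\n", x$table_id, x$name))
  cat("  stops:            ", paste(x$stops, collapse = " "), "\n")
  cat("  canonical starts: ", paste(x$canonical_starts, collapse = " "), "\n")
  if (length(x$extended_starts)) {
    cat("  extended starts:  ", paste(x$extended_starts, collapse = " "), "\n")
  }
  invisible(x)
}

#' Normalize a nucleotide string to the internal DNA alphabet
#'
#' Uppercases and converts U to T. All internal sequence handling assumes
#' this representation.
#' @param seq Character scalar.
#' @return Normalized character scalar.
#' @export
normalize_seq <- function(seq) {
  chartr("u", "T", chartr("U", "T", toupper(seq)))
}

#' Translate a nucleotide sequence under a mitochondrial code
#'
#' Translates successive codons starting at `frame`; a trailing 1-2 nt
#' remainder is ignored. Codons containing ambiguity codes (anything outside
#' ACGT) translate to `X` and never match start or stop sets.
#'
#' @param seq Nucleotide string (U tolerated, normalized to T).
#' @param table A `translation_table` from [get_table()].
#' @param frame Offset 0, 1 or 2 into `seq`.
#' @param stop_policy How internal stop codons are handled: `"annotate"`
#'   keeps them as `"*"`, `"truncate"` cuts the translation at the first
#'   stop (the stop itself is dropped), `"error"` raises an error for any
#'   stop before the final codon.
#' @return Amino-acid string.
#' @export
translate_seq <- function(seq, table,
                          frame = 0,
                          stop_policy = c("annotate", "truncate", "error")) {
  stop_policy <- match.arg(stop_policy)
  stopifnot(inherits(table, "translation_table"), frame %in% 0:2)
  if (length(seq) != 1L || is.na(seq) || nchar(seq) == 0L) {
    stop("empty input sequence", call. = FALSE)
  }
  seq <- normalize_seq(seq)
  body <- substr(seq, frame + 1L, nchar(seq))
  n_codons <- nchar(body) %/% 3L
  if (n_codons == 0L) stop("sequence shorter than one codon after frame offset",
                           call. = FALSE)
  starts <- 3L * (seq_len(n_codons) - 1L) + 1L
  codons <- substring(body, starts, starts + 2L)
  aa <- unname(table$codon_to_aa[codons])
  aa[is.na(aa)] <- "X"  # ambiguity codes
  if (stop_policy == "truncate") {
    hit <- which(aa == "*")
    if (length(hit)) aa <- aa[seq_len(hit[1L] - 1L)]
  } else if (stop_policy == "error") {
    internal <- which(aa == "*")
    internal <- internal[internal < length(aa)]
    if (length(internal)) {
      stop("internal stop codon at codon ", internal[1L], call. = FALSE)
    }
  }
  paste(aa, collapse = "")
}

#' Classify a codon against a table's initiation-codon sets
#'
#' Pure set membership: `ATG` is `canonical`; other members of the table's
#' canonical start set are `canonical_alternative`; members of the extended
#' set are `extended_alternative`. Any other codon returns `non_start` —
#' `novel_candidate` is never assigned here (positional evidence belongs to
#' the audit) unless `allow_novel = TRUE` explicitly requests that non-stop
#' non-start codons be labelled as candidates. Stop codons and codons with
#' ambiguity characters are always `non_start`.
#'
#' @param codon Trinucleotide, uppercase.
#' @param table A `translation_table`.
#' @param allow_novel Logical; label non-stop, non-start codons
#'   `novel_candidate` instead of `non_start`.
#' @return One of `"canonical"`, `"canonical_alternative"`,
#'   `"extended_alternative"`, `"novel_candidate"`, `"non_start"`.
#' @export
classify_start <- function(codon, table, allow_novel = FALSE) {
  stopifnot(inherits(table, "translation_table"))
  if (length(codon) != 1L || is.na(codon) || nchar(codon) != 3L) {
    stop("malformed codon: ", paste(codon, collapse = ","), call. = FALSE)
  }
  codon <- normalize_seq(codon)
  if (!grepl("^[ACGT]{3}$", codon)) return("non_start")
  if (codon %in% table$stops) return("non_start")
  if (codon == "ATG" && "ATG" %in% table$canonical_starts) return("canonical")
  if (codon %in% table$canonical_starts) return("canonical_alternative")
  if (codon %in% table$extended_starts) return("extended_alternative")
  if (isTRUE(allow_novel)) return("novel_candidate")
  "non_start"
}

#' Export a translation table as JSON
#'
#' Writes the table id, name, 64-entry codon map and start sets so the code
#' definition can be reused outside R.
#'
#' @param table A `translation_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
table_to_json <- function(table, path) {
  stopifnot(inherits(table, "translation_table"))
  jsonlite::write_json(
    list(
      table_id = table$table_id,
      name = table$name,
      codon_to_aa = as.list(table$codon_to_aa),
      canonical_starts = table$canonical_starts,
      extended_starts = table$extended_starts,
      stops = table$stops
    ),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
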