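# Independent oracles and fixture builders shared across tests. Everything
# here is deliberately written without reusing package internals, so the
# implementations under test are checked against a second route.

# --- Gotoh global alignment score (affine gaps), plain-R dynamic program.
gotoh_score <- function(a, b, submat, open = 10, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - ext * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -open - ext * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# --- Circular signed-adjacency conservation by linear scan (no canonical
# string representation; direction handled explicitly).
adj_conserved <- function(la, sa, i, lb, sb) {
  n <- length(la); m <- length(lb)
  j <- i %% n + 1
  for (k in seq_len(m)) {
    l <- k %% m + 1
    if (lb[k] == la[i] && sb[k] == sa[i] && lb[l] == la[j] && sb[l] == sa[j])
      return(TRUE)
    if (lb[k] == la[j] && sb[k] == -sa[j] && lb[l] == la[i] && sb[l] == -sa[i])
      return(TRUE)
  }
  FALSE
}

oracle_breakpoints <- function(la, sa, lb, sb) {
  sum(!vapply(seq_along(la), adj_conserved, logical(1),
              la = la, sa = sa, lb = lb, sb = sb))
}

# Conserved blocks by cutting the circle of `a` at every non-conserved
# adjacency and walking the pieces.
oracle_blocks <- function(la, sa, lb, sb) {
  n <- length(la)
  kept <- vapply(seq_len(n), adj_conserved, logical(1),
                 la = la, sa = sa, lb = lb, sb = sb)
  if (all(kept)) return(list(la))
  cut_after <- which(!kept)            # adjacency i joins i and i %% n + 1
  pieces <- list()
  start <- cut_after[length(cut_after)] %% n + 1
  walk <- ((start - 1 + 0:(n - 1)) %% n) + 1
  cur <- c()
  for (p in walk) {
    cur <- c(cur, p)
    if (p %in% cut_after) { pieces[[length(pieces) + 1]] <- la[cur]; cur <- c() }
  }
  if (length(cur)) pieces[[length(pieces) + 1]] <- la[cur]
  pieces
}

# Canonical form for comparing block partitions regardless of list order or
# reading direction (a conserved run is the same block read either way).
block_key <- function(blocks) {
  sort(vapply(blocks, function(b) {
    fwd <- paste(b, collapse = " ")
    rev_ <- paste(rev(b), collapse = " ")
    if (fwd < rev_) fwd else rev_
  }, character(1)))
}

# --- Small fast genome spec for unit tests (short PCGs, full complement).
tiny_spec <- function(seed = 1L, starts = c(ND3 = "ATT", ND4L = "ATC")) {
  lens <- c(ND1 = 60, ND2 = 62, COI = 80, COII = 55, ATP8 = 40, ATP6 = 58,
            COIII = 64, ND3 = 50, ND4L = 42, ND4 = 70, ND5 = 85, ND6 = 48,
            CYTB = 66)
  genome_spec(taxon = "tiny", pcg_lengths = lens, start_assignment = starts,
              rrna_lengths = c(`12S` = 200L, `16S` = 300L),
              spacer_length_range = c(8L, 20L), seed = seed)
}

# --- Build a minimal annotated record from explicit gene sequences.
# genes: list of list(label, seq (5'->3'), strand); laid out in order with
# the given spacer sequences between (length(spacers) == length(genes) + 1).
hand_record <- function(taxon, genes, spacers, circular = TRUE,
                        accession = "HAND01") {
  stopifnot(length(spacers) == length(genes) + 1)
  seq <- spacers[[1]]
  feats <- NULL
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    strand <- if (is.null(g$strand)) "+" else g$strand
    body <- if (strand == "-") revcomp(g$seq) else g$seq
    start <- nchar(seq)
    seq <- paste0(seq, body)
    feats <- rbind(feats, data.frame(
      label = g$label, raw_name = g$label, kind = gene_kind(g$label),
      start = start, end = nchar(seq), strand = strand,
      wraps_origin = FALSE, partial_5prime = isTRUE(g$partial_5prime),
      partial_3prime = isTRUE(g$partial_3prime), stringsAsFactors = FALSE))
    seq <- paste0(seq, spacers[[i + 1]])
  }
  mitogenome_record(taxon = taxon, sequence = seq, features = feats,
                    circular = circular, accession = accession)
}

# --- Genome-level transformations for invariance tests.
rotate_record <- function(record, k) {
  n <- nchar(record$sequence)
  k <- k %% n
  s <- paste0(substr(record$sequence, k + 1, n), substr(record$sequence, 1, k))
  f <- record$features
  lens <- vapply(seq_len(nrow(f)), function(i) feature_length(f[i, ], n),
                 numeric(1))
  ns <- (f$start - k) %% n
  ne <- ns + lens
  f$start <- as.integer(ns)
  f$wraps_origin <- ne > n
  f$end <- as.integer(ifelse(ne > n, ne - n, ne))
  mitogenome_record(record$taxon, s, f, circular = record$circular,
                    accession = record$accession, table_id = record$table_id)
}

reflect_record <- function(record) {
  n <- nchar(record$sequence)
  f <- record$features
  stopifnot(!any(f$wraps_origin))   # sufficient for generated fixtures
  ns <- n - f$end
  ne <- n - f$start
  f$start <- as.integer(ns); f$end <- as.integer(ne)
  f$strand <- ifelse(f$strand == "+", "-", "+")
  mitogenome_record(record$taxon, revcomp(record$sequence), f,
                    circular = record$circular, accession = record$accession,
                    table_id = record$table_id)
}

# All signed circular permutations of n labels, reduced: first element fixed
# in place with + sign (rotation/reflection representatives).
all_signed_perms <- function(n) {
  labs <- LETTERS[seq_len(n)]
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  signs_of <- function(m) {
    g <- as.matrix(expand.grid(rep(list(c(1L, -1L)), m)))
    lapply(seq_len(nrow(g)), function(i) unname(g[i, ]))
  }
  out <- list()
  for (p in perms(labs[-1])) {
    for (s in signs_of(n - 1)) {
      out[[length(out) + 1]] <- list(labels = c(labs[1], p),
                                     signs = c(1L, s))
    }
  }
  out
}
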