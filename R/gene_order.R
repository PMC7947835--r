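# Gene arrangements as normalized signed circular permutations, and
# conservation analytics: shared oriented adjacencies (breakpoint
# distance), maximal conserved blocks, and detection of a single two-block
# interchange. Full rearrangement-distance inference (sorting by
# inversions/transpositions) is deliberately out of scope.

#' Construct a signed circular gene order
#'
#' @param labels Character vector of gene labels (unique).
#' @param signs Integer vector of +1/-1 orientations (or character "+"/"-").
#' @param taxon Taxon name.
#' @param circular Logical topology flag.
#' @param include_trnas Whether tRNAs were included when deriving the order.
#' @param normalize Normalize on construction (rotate COI first, reflect so
#'   COI is +).
#' @return A `gene_order` object.
#' @export
gene_order <- function(labels, signs = rep(1L, length(labels)), taxon = "",
                       circular = TRUE, include_trnas = FALSE,
                       normalize = TRUE) {
  if (is.character(signs)) signs <- ifelse(signs == "-", -1L, 1L)
  stopifnot(length(labels) == length(signs), all(signs %in% c(-1L, 1L)))
  if (anyDuplicated(labels)) {
    stop("duplicate gene labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ","),
         call. = FALSE)
  }
  x <- structure(
    list(taxon = taxon, labels = labels, signs = as.integer(signs),
         circular = isTRUE(circular), include_trnas = isTRUE(include_trnas)),
    class = "gene_order")
  if (normalize) normalize_gene_order(x) else x
}

#' Normalize a circular gene order
#'
#' Pure function: the order is rotated so the anchor gene (COI, falling
#' back to the lexicographically smallest label when COI is absent, with a
#' note attribute) comes first, and reflected (sequence reversed, all signs
#' flipped) beforehand if needed so the anchor carries a + sign. Two
#' arrangements that differ only by rotation and/or reading direction
#' therefore normalize identically.
#'
#' @param x A `gene_order`.
#' @return The normalized `gene_order`.
#' @export
normalize_gene_order <- function(x) {
  stopifnot(inherits(x, "gene_order"))
  anchor <- if ("COI" %in% x$labels) "COI" else {
    attr(x, "anchor_note") <- "COI absent; anchored on smallest label"
    sort(x$labels)[1L]
  }
  i <- match(anchor, x$labels)
  if (x$signs[i] < 0L) {
    x$labels <- rev(x$labels)
    x$signs <- rev(-x$signs)
    i <- match(anchor, x$labels)
  }
  if (i > 1L) {
    rot <- c(i:length(x$labels), seq_len(i - 1L))
    x$labels <- x$labels[rot]
    x$signs <- x$signs[rot]
  }
  x
}

#' @export
print.gene_order <- function(x, ...) {
  cat(sprintf("<gene_order> %s (%s, %d genes)\n", x$taxon,
              if (x$circular) "circular" else "linear", length(x$labels)))
  cat(" ", format_gene_order(x), "\n")
  invisible(x)
}

#' One-line signed label string for a gene order
#' @param x A `gene_order`.
#' @return Character scalar like `"+COI +ND4L ... -ND6"`.
#' @export
format_gene_order <- function(x) {
  paste(paste0(ifelse(x$signs > 0L, "+", "-"), x$labels), collapse = " ")
}

#' Derive a gene order from an annotated record
#'
#' Filters features to PCG+rRNA (plus tRNA when `include_trnas`), sorts
#' them around the circle by midpoint in unwrapped circular coordinates,
#' signs them by strand, and normalizes.
#'
#' @param record A `mitogenome_record`.
#' @param include_trnas Include tRNA features.
#' @return A normalized `gene_order`.
#' @export
order_from_record <- function(record, include_trnas = FALSE) {
  kinds <- c("PCG", "rRNA", if (include_trnas) "tRNA")
  f <- record$features[record$features$kind %in% kinds, , drop = FALSE]
  if (nrow(f) < 2L) stop("fewer than 2 features after filtering", call. = FALSE)
  if (anyDuplicated(f$label)) {
    stop("duplicate gene in record ", record$taxon, ": ",
         paste(unique(f$label[duplicated(f$label)]), collapse = ","),
         call. = FALSE)
  }
  n <- nchar(record$sequence)
  mid <- (f$start + ifelse(f$wraps_origin, f$end + n, f$end)) / 2
  mid <- mid %% n
  f <- f[order(mid), , drop = FALSE]
  gene_order(f$label, ifelse(f$strand == "-", -1L, 1L), taxon = record$taxon,
             circular = record$circular, include_trnas = include_trnas)
}

# Signed oriented adjacencies of a circular order, as canonical strings.
# The adjacency (a, b) read in the opposite direction is (-b, -a); both
# spellings denote the same junction, so the lexicographically smaller
# spelling is kept.
.adjacency_set <- function(x) {
  n <- length(x$labels)
  s <- ifelse(x$signs > 0L, "+", "-")
  flip <- ifelse(x$signs > 0L, "-", "+")
  lab <- x$labels
  idx2 <- c(2:n, 1L)
  fwd <- paste0(s, lab, "|", s[idx2], lab[idx2])
  rev_ <- paste0(flip[idx2], lab[idx2], "|", flip, lab)
  pmin(fwd, rev_)
}

.check_comparable <- function(a, b) {
  stopifnot(inherits(a, "gene_order"), inherits(b, "gene_order"))
  if (!length(intersect(a$labels, b$labels))) {
    stop("incomparable orders: disjoint label sets", call. = FALSE)
  }
  if (!setequal(a$labels, b$labels)) {
    shared <- intersect(a$labels, b$labels)
    a <- .restrict_order(a, shared)
    b <- .restrict_order(b, shared)
    attr(a, "restricted") <- attr(b, "restricted") <- TRUE
  }
  list(a = a, b = b)
}

.restrict_order <- function(x, labels) {
  keep <- x$labels %in% labels
  gene_order(x$labels[keep], x$signs[keep], taxon = x$taxon,
             circular = x$circular, include_trnas = x$include_trnas)
}

#' Breakpoint distance between two circular gene orders
#'
#' Counts the oriented adjacencies of `a` that are absent from `b`,
#' on the normalized circular signed sequences. Symmetric, zero iff the
#' normalized orders are identical; a single-gene transposition yields 3.
#' Orders with unequal label sets are first restricted to the shared
#' labels (an error if disjoint).
#'
#' @param a,b `gene_order` objects.
#' @return Integer breakpoint count.
#' @export
breakpoint_distance <- function(a, b) {
  ab <- .check_comparable(a, b)
  sa <- .adjacency_set(normalize_gene_order(ab$a))
  sb <- .adjacency_set(normalize_gene_order(ab$b))
  sum(!sa %in% sb)
}

#' Maximal conserved blocks between two circular gene orders
#'
#' Maximal runs of consecutive elements that appear consecutively with the
#' same labels and relative orientation in both circular orders (a run is
#' also conserved when it appears whole in the opposite reading direction
#' of `b`). Identical orders yield one block covering every gene.
#'
#' @param a,b Comparable `gene_order` objects.
#' @return List of character vectors, each a block's labels in `a`'s
#'   normalized reading order.
#' @export
conserved_blocks <- function(a, b) {
  ab <- .check_comparable(a, b)
  a <- normalize_gene_order(ab$a); b <- normalize_gene_order(ab$b)
  n <- length(a$labels)
  sb <- .adjacency_set(b)
  sa_all <- .adjacency_set(a)          # adjacency i joins element i and i+1
  kept <- sa_all %in% sb
  if (all(kept)) {
    return(list(a$labels))
  }
  # blocks are maximal runs of elements joined by kept adjacencies,
  # circularly: cut at every broken adjacency (adjacency i joins elements
  # i and i %% n + 1)
  broken <- which(!kept)
  nb <- length(broken)
  blocks <- vector("list", nb)
  for (k in seq_len(nb)) {
    from <- broken[k] %% n + 1L
    to <- broken[if (k < nb) k + 1L else 1L]
    idx <- if (from <= to) from:to else c(from:n, seq_len(to))
    blocks[[k]] <- a$labels[idx]
  }
  # deterministic order: by position of first element
  firsts <- vapply(blocks, function(bl) match(bl[1L], a$labels), integer(1))
  blocks[order(firsts)]
}

#' Detect a single two-block interchange between two orders
#'
#' Tests whether `b` equals `a` after swapping the positions of exactly
#' two disjoint contiguous blocks (each block keeping its internal order
#' and orientation). Returns the smallest such pair of blocks (by summed
#' length, then larger-block length, then labels) or `NULL` when the
#' orders are identical or differ by anything other than one interchange.
#'
#' @param a,b Comparable `gene_order` objects.
#' @return `NULL`, or a list with `block1` and `block2` label vectors.
#' @export
detect_interchange <- function(a, b) {
  ab <- .check_comparable(a, b)
  a <- normalize_gene_order(ab$a); b <- normalize_gene_order(ab$b)
  n <- length(a$labels)
  if (identical(a$labels, b$labels) && identical(a$signs, b$signs)) {
    return(NULL)
  }
  # Rotate a so some element outside both putative blocks leads; align b by
  # the same leading element. The mismatch span [i1..j2] between the two
  # linearizations must then be exactly [start of block1 .. end of block2],
  # and because labels are unique the block boundaries are forced: block2
  # must start with b's element at i1 and block1 must end with b's element
  # at j2. One O(n) verification per rotation.
  cands <- list()
  for (r in seq_len(n)) {
    rot <- c(r:n, seq_len(r - 1L))
    la <- a$labels[rot]; sa <- a$signs[rot]
    q <- match(la[1L], b$labels)
    rotb <- c(q:n, seq_len(q - 1L))
    lb <- b$labels[rotb]; sb <- b$signs[rotb]
    if (sa[1L] != sb[1L]) next        # leading element changed orientation
    diff <- which(la != lb | sa != sb)
    if (!length(diff)) next           # equal under this rotation: no interchange
    i1 <- diff[1L]; j2 <- diff[length(diff)]
    if (i1 == 1L) next                # leading element must sit outside the blocks
    i2 <- match(lb[i1], la)
    j1 <- match(lb[j2], la)
    if (is.na(i2) || is.na(j1)) next
    if (!(i1 <= j1 && j1 < i2 && i2 <= j2)) next
    mid <- if (j1 + 1L <= i2 - 1L) (j1 + 1L):(i2 - 1L) else integer(0)
    idx <- c(i2:j2, mid, i1:j1)
    if (!identical(la[idx], lb[i1:j2]) || !identical(sa[idx], sb[i1:j2])) next
    cands[[length(cands) + 1L]] <- list(
      block1 = la[i1:j1], block2 = la[i2:j2],
      len = (j1 - i1 + 1L) + (j2 - i2 + 1L))
  }
  if (!length(cands)) return(NULL)
  lens <- vapply(cands, `[[`, integer(1), "len")
  maxb <- vapply(cands, function(cc)
    max(length(cc$block1), length(cc$block2)), integer(1))
  keys <- vapply(cands, function(cc)
    paste(c(cc$block1, cc$block2), collapse = " "), character(1))
  best <- cands[[order(lens, maxb, keys)[1L]]]
  bl <- list(block1 = best$block1, block2 = best$block2)
  # deterministic presentation: block containing the earlier label (in a's
  # normalized order) first
  if (min(match(bl$block2, a$labels)) < min(match(bl$block1, a$labels))) {
    bl <- list(block1 = bl$block2, block2 = bl$block1)
  }
  bl
}

#' Pairwise breakpoint-distance matrix
#'
#' @param orders List of comparable `gene_order` objects.
#' @return Symmetric integer matrix with zero diagonal, dimnames = taxa.
#' @export
order_distance_matrix <- function(orders) {
  stopifnot(length(orders) >= 2L)
  taxa <- vapply(orders, `[[`, character(1), "taxon")
  n <- length(orders)
  d <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- breakpoint_distance(orders[[i]], orders[[j]])
  }
  d
}
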