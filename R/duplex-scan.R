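# The four-criterion duplex scan over a collapsed count table:
#   (1) read counts strictly greater than `min_count` on both strands,
#   (2) 2-nt 3' overhangs on both termini (fixed register),
#   (3) at most `max_mismatches` mismatched positions,
#   (4) G:U wobble counts as paired.

#' Filter a count table by read count
#'
#' Retains exactly the species with `count > min_count` (strict inequality:
#' a count of 31 passes the default threshold of 30, a count of 30 does not).
#'
#' @param table Count tibble (`sequence`, `count`).
#' @param min_count Exclusive lower bound on counts (default 30).
#' @return The filtered tibble.
#' @export
filter_by_count <- function(table, min_count = 30) {
  stopifnot(all(c("sequence", "count") %in% names(table)), min_count >= 0)
  dplyr::filter(table, .data$count > min_count)
}

# Purine/pyrimidine skeleton of a sequence: A,G -> R; C,U -> Y.
.ry_pattern <- function(x) chartr("AGCU", "RRYY", x)

# R/Y pattern a duplex partner must carry over its own paired region
# (positions 1..Lp), given strand a: reverse and flip R<->Y.
.partner_ry <- function(ry_paired) {
  vapply(strsplit(chartr("RY", "YR", ry_paired), "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# Contiguous seed blocks: split 1..n into k nearly-equal pieces.
.seed_blocks <- function(n, k) {
  sizes <- diff(round(seq(0, n, length.out = k + 1)))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  Map(c, starts, ends)
}

.canonical_calls <- function(calls) {
  if (!nrow(calls)) return(calls)
  swap <- calls$seq_a > calls$seq_b
  if (any(swap)) {
    tmp_s <- calls$seq_a[swap]; tmp_c <- calls$count_a[swap]
    calls$seq_a[swap] <- calls$seq_b[swap]
    calls$count_a[swap] <- calls$count_b[swap]
    calls$seq_b[swap] <- tmp_s
    calls$count_b[swap] <- tmp_c
    # mismatch positions are re-derived on the canonical orientation below
  }
  dplyr::arrange(dplyr::distinct(calls, .data$seq_a, .data$seq_b,
                                 .keep_all = TRUE),
                 .data$seq_a, .data$seq_b)
}

.call_row <- function(seq_a, count_a, seq_b, count_b, dx) {
  tibble::tibble(
    seq_a = seq_a, count_a = count_a,
    seq_b = seq_b, count_b = count_b,
    mismatches = dx$mismatch_count,
    mismatch_positions = paste(dx$mismatch_positions, collapse = ","),
    self_pair = seq_a == seq_b
  )
}

#' Find all duplex pairs satisfying the four pairing criteria
#'
#' Scans a collapsed count table for unordered pairs of species whose strands
#' assemble into a gapless antiparallel duplex with `overhang`-nt 3' overhangs
#' on both termini and at most `max_mismatches` mismatches (wobble pairs count
#' as paired), with both read counts strictly above `min_count`. One species
#' may appear in several calls; near-palindromic species may (optionally) pair
#' with themselves.
#'
#' Two strategies produce identical output: `"brute"` examines every unordered
#' pair, and `"seeded"` exploits the fact that every paired (Watson-Crick or
#' wobble) position joins a purine to a pyrimidine, so a partner within
#' `max_mismatches` mismatches must agree with the expected purine/pyrimidine
#' pattern everywhere except at its mismatch positions. Splitting that pattern
#' into `max_mismatches + 1` contiguous blocks guarantees (pigeonhole) that at
#' least one block matches exactly, so candidates come from hash lookups and
#' are then verified with [assemble_duplex()]. `"brute"` is retained as the
#' reference oracle.
#'
#' @param table Count tibble (`sequence`, `count`).
#' @param min_count Exclusive count threshold, criterion (1); default 30.
#' @param max_mismatches Maximum mismatches, criterion (3); default 3
#'   ("less than four").
#' @param overhang 3' overhang length, criterion (2); default 2.
#' @param allow_self_pairs Allow a species to pair with itself (default TRUE).
#' @param strategy `"seeded"` (default) or `"brute"`.
#' @return Tibble of calls in canonical order (`seq_a <= seq_b`, rows sorted
#'   lexicographically): `seq_a`, `count_a`, `seq_b`, `count_b`, `mismatches`,
#'   `mismatch_positions` (comma-joined 1-based `seq_a` positions),
#'   `self_pair`.
#' @examples
#' tbl <- tibble::tibble(
#'   sequence = c("CGUACGCGGAAUACUUCGAUU", "UCGAAGUAUUCCGCGUACGUU"),
#'   count = c(40L, 45L))
#' find_duplex_pairs(tbl)
#' @export
find_duplex_pairs <- function(table, min_count = 30, max_mismatches = 3,
                              overhang = 2, allow_self_pairs = TRUE,
                              strategy = c("seeded", "brute")) {
  strategy <- match.arg(strategy)
  stopifnot(max_mismatches >= 0, overhang >= 0)
  tbl <- filter_by_count(table, min_count)
  empty <- tibble::tibble(
    seq_a = character(), count_a = integer(),
    seq_b = character(), count_b = integer(),
    mismatches = integer(), mismatch_positions = character(),
    self_pair = logical())
  if (nrow(tbl) < 1L) return(empty)

  seqs <- tbl$sequence
  counts <- tbl$count
  rows <- list()
  add_pair <- function(i, j) {
    # canonical orientation first so mismatch positions refer to seq_a
    a <- seqs[i]; b <- seqs[j]; ca <- counts[i]; cb <- counts[j]
    if (a > b) {
      tmp <- a; a <- b; b <- tmp
      tmp <- ca; ca <- cb; cb <- tmp
    }
    dx <- assemble_duplex(a, b, overhang)
    if (!is.null(dx) && dx$mismatch_count <= max_mismatches) {
      rows[[length(rows) + 1L]] <<- .call_row(a, ca, b, cb, dx)
    }
  }

  if (strategy == "brute") {
    n <- length(seqs)
    for (i in seq_len(n)) {
      j0 <- if (allow_self_pairs) i else i + 1L
      for (j in seq.int(j0, n)) {
        if (j > n) break
        if (nchar(seqs[i]) == nchar(seqs[j])) add_pair(i, j)
      }
    }
  } else {
    for (L in unique(nchar(seqs))) {
      if (L <= 2 * overhang) next
      idx <- which(nchar(seqs) == L)
      Lp <- L - overhang
      own <- substr(.ry_pattern(seqs[idx]), 1L, Lp)
      want <- .partner_ry(own)
      blocks <- .seed_blocks(Lp, max_mismatches + 1L)
      # hash: block id + own-pattern substring -> member indices (into idx)
      index <- new.env(parent = emptyenv())
      for (bi in seq_along(blocks)) {
        s <- blocks[[bi]][1]; e <- blocks[[bi]][2]
        if (e < s) next
        keys <- paste0(bi, ":", substr(own, s, e))
        for (k in seq_along(idx)) {
          index[[keys[k]]] <- c(index[[keys[k]]], k)
        }
      }
      seen <- new.env(parent = emptyenv())
      for (k in seq_along(idx)) {
        cand <- integer(0)
        for (bi in seq_along(blocks)) {
          s <- blocks[[bi]][1]; e <- blocks[[bi]][2]
          if (e < s) next
          hit <- index[[paste0(bi, ":", substr(want[k], s, e))]]
          if (!is.null(hit)) cand <- c(cand, hit)
        }
        for (m in unique(cand)) {
          if (m == k && !allow_self_pairs) next
          key <- paste(min(k, m), max(k, m), sep = "-")
          if (!is.null(seen[[key]])) next
          seen[[key]] <- TRUE
          add_pair(idx[k], idx[m])
        }
      }
    }
  }
  if (!length(rows)) return(empty)
  .canonical_calls(dplyr::bind_rows(rows))
}
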