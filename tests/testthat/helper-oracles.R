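# Shared helpers: random sequences and brute-force oracles that stay
# independent of the implementation paths they check.

rand_rna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# a strand that pairs perfectly (zero mismatches) with `a` at the given
# 3' overhang, by construction
perfect_partner <- function(a, overhang = 2) {
  L <- nchar(a)
  paste0(rna_reverse_complement(substr(a, 1, L - overhang)),
         rand_rna(1, overhang))
}

# independent position-wise mismatch count for the fixed 3'-overhang register
oracle_mismatches <- function(a, b, overhang = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  L <- length(av)
  ok_pairs <- c("AU", "UA", "GC", "CG", "GU", "UG")
  pos <- integer(0)
  for (i in seq_len(L - overhang)) {
    if (!paste0(av[i], bv[L - overhang + 1 - i]) %in% ok_pairs) {
      pos <- c(pos, i)
    }
  }
  pos
}

# brute-force enumeration of all non-crossing structures: maximum number of
# (WC + wobble) pairs in s[i..j] with hairpin loops of >= min_loop unpaired nt
oracle_max_pairs <- function(seq, min_loop = 3) {
  s <- strsplit(seq, "")[[1]]
  ok_pairs <- c("AU", "UA", "GC", "CG", "GU", "UG")
  rec <- function(i, j) {
    if (i >= j) return(0L)
    best <- rec(i + 1L, j)           # leave i unpaired
    for (k in seq.int(i + 1L, j)) {  # or pair i with k
      if (k - i <= min_loop) next
      if (!paste0(s[i], s[k]) %in% ok_pairs) next
      cand <- 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j)
      if (cand > best) best <- cand
    }
    best
  }
  rec(1L, length(s))
}

# a random count table of 21-mers with counts above the scan threshold
rand_table <- function(n, len = 21, counts = 31:100) {
  tibble::tibble(sequence = unique(rand_rna(n, len))) |>
    dplyr::mutate(count = sample(counts, dplyr::n(), replace = TRUE))
}

# positive / re-oriented negative strand of the synthesized perfect duplex
POS_STRAND <- "CGUACGCGGAAUACUUCGAUU"
NEG_STRAND <- "UCGAAGUAUUCCGCGUACGUU"
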