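# Reference-based cleaning and pre-miRNA hairpin support.
#
# A called pair is supported as a miRNA/miRNA* duplex when both reads map to
# the same contig (same strand, within a window), and in the folded spanning
# region each read sits on one arm of a stem: most of its bases are paired,
# and most of those partners fall inside the other read's interval.

#' Filter reads by exact reference match
#'
#' Retains a read iff its sequence, or its reverse complement, occurs as an
#' exact substring of some contig. This is the error-cleaning step: reads
#' carrying sequencing errors (absent from the genome) are removed; counts of
#' surviving species are unchanged. Both orientations are accepted because
#' sRNAs derive from transcripts of either genomic strand.
#'
#' @param table Count tibble (`sequence`, `count`).
#' @param contigs Contig tibble (`name`, `sequence`), RNA alphabet.
#' @return The filtered count tibble.
#' @export
filter_by_reference <- function(table, contigs) {
  stopifnot(nrow(contigs) > 0)
  if (!nrow(table)) return(table)
  ref <- contigs$sequence
  hit <- vapply(table$sequence, function(s) {
    any(stringr::str_detect(ref, stringr::fixed(s))) ||
      any(stringr::str_detect(ref, stringr::fixed(rna_reverse_complement(s))))
  }, logical(1), USE.NAMES = FALSE)
  table[hit, , drop = FALSE]
}

#' Locate all exact occurrences of a read in a contig
#'
#' @param seq RNA sequence, 5'->3'.
#' @param contig_seq Contig sequence (RNA alphabet).
#' @return Tibble with `start` (1-based) and `strand` (`"+"` for the sequence
#'   itself, `"-"` for its reverse complement), starts ascending within
#'   strand; zero rows if absent.
#' @export
locate_read <- function(seq, contig_seq) {
  check_rna(seq, "seq")
  fwd <- stringr::str_locate_all(contig_seq, stringr::fixed(seq))[[1]][, 1]
  rev <- stringr::str_locate_all(
    contig_seq, stringr::fixed(rna_reverse_complement(seq)))[[1]][, 1]
  tibble::tibble(
    start = as.integer(c(fwd, rev)),
    strand = rep(c("+", "-"), c(length(fwd), length(rev)))
  )
}

.pairable <- function(a, b) .is_paired_class(pair_class(a, b))

#' Fold an RNA sequence by base-pair maximisation
#'
#' Nussinov-style dynamic programme maximising the number of paired positions
#' (Watson-Crick plus G:U wobble) over all pseudoknot-free structures, with a
#' minimum hairpin loop of `min_loop` unpaired bases (no pair between
#' positions closer than `min_loop + 1`). The traceback is deterministic:
#' whenever pairing the 5'-most open base attains the optimum, it is paired,
#' with the 5'-most partner that attains it.
#'
#' This is a structural stand-in for thermodynamic folding: it finds stems
#' reliably but knows nothing about stacking energies. Externally computed
#' dot-bracket structures can be supplied to [hairpin_support()] instead.
#'
#' @param seq RNA sequence.
#' @param min_loop Minimum hairpin loop length in nt (default 3).
#' @return An object of class `rna_structure`: list with `sequence`,
#'   `dotbracket`, `pair_table` (integer vector, `pair_table[i]` is the
#'   partner of position `i`, 0 if unpaired) and `n_pairs`.
#' @examples
#' nussinov_fold("GGGAAAACCC")$dotbracket
#' @export
nussinov_fold <- function(seq, min_loop = 3) {
  check_rna(seq, "seq")
  stopifnot(length(seq) == 1L, min_loop >= 0)
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(s)
  pt <- integer(n)
  if (n >= min_loop + 2) {
    # N[i,j]: max pairs in s[i..j]
    N <- matrix(0L, n, n)
    for (span in (min_loop + 1):(n - 1)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- N[i + 1, j]  # i unpaired
        ks <- (i + min_loop + 1):j
        for (k in ks) {
          if (.pairable(s[i], s[k])) {
            inner <- if (k - i >= 2) N[i + 1, k - 1] else 0L
            outer <- if (k < j) N[k + 1, j] else 0L
            cand <- 1L + inner + outer
            if (cand > best) best <- cand
          }
        }
        N[i, j] <- best
      }
    }
    # deterministic traceback, 5'-most pairing preferred
    stack <- list(c(1L, n))
    while (length(stack)) {
      ij <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i <- ij[1]; j <- ij[2]
      if (i >= j || j - i <= min_loop) next
      target <- N[i, j]
      if (target == 0L) next
      paired <- FALSE
      for (k in (i + min_loop + 1):j) {
        if (!.pairable(s[i], s[k])) next
        inner <- if (k - i >= 2) N[i + 1, k - 1] else 0L
        outer <- if (k < j) N[k + 1, j] else 0L
        if (1L + inner + outer == target) {
          pt[i] <- k; pt[k] <- i
          if (k - i >= 2) stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
          if (k < j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
          paired <- TRUE
          break
        }
      }
      if (!paired) stack[[length(stack) + 1L]] <- c(i + 1L, j)
    }
  }
  db <- rep(".", n)
  db[pt > seq_len(n)] <- "("
  db[pt > 0 & pt < seq_len(n)] <- ")"
  structure(
    list(sequence = seq, dotbracket = paste(db, collapse = ""),
         pair_table = pt, n_pairs = sum(pt > 0) %/% 2L),
    class = "rna_structure"
  )
}

#' Parse a dot-bracket string into an `rna_structure`
#'
#' @param seq RNA sequence.
#' @param dotbracket Dot-bracket string over `(`, `)`, `.`, same length
#'   as `seq`.
#' @return An `rna_structure` (see [nussinov_fold()]).
#' @export
parse_dotbracket <- function(seq, dotbracket) {
  check_rna(seq, "seq")
  if (nchar(dotbracket) != nchar(seq)) {
    stop("dot-bracket length differs from sequence length", call. = FALSE)
  }
  ch <- strsplit(dotbracket, "", fixed = TRUE)[[1]]
  if (any(!ch %in% c("(", ")", "."))) {
    stop("dot-bracket may contain only '(', ')', '.'", call. = FALSE)
  }
  pt <- integer(length(ch))
  open <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") open <- c(open, i)
    else if (ch[i] == ")") {
      if (!length(open)) stop("unbalanced dot-bracket", call. = FALSE)
      j <- open[length(open)]
      open <- open[-length(open)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(open)) stop("unbalanced dot-bracket", call. = FALSE)
  structure(
    list(sequence = seq, dotbracket = dotbracket, pair_table = pt,
         n_pairs = sum(pt > 0) %/% 2L),
    class = "rna_structure"
  )
}

#' @export
print.rna_structure <- function(x, ...) {
  cat("<rna_structure>", x$n_pairs, "pairs\n")
  cat(x$sequence, "\n")
  cat(x$dotbracket, "\n")
  invisible(x)
}

# stem-arm statistics for one read interval against a pair table
.arm_stats <- function(pt, iv_self, iv_other) {
  partners <- pt[iv_self[1]:iv_self[2]]
  paired <- partners > 0
  pf <- mean(paired)
  cf <- if (any(paired)) {
    mean(partners[paired] >= iv_other[1] & partners[paired] <= iv_other[2])
  } else 0
  c(paired_fraction = pf, cross_fraction = cf)
}

#' Assess pre-miRNA hairpin support for duplex calls
#'
#' For each called pair, both reads are located in the reference; the pair is
#' supported when some contig carries both reads on the same strand within
#' `window` nt, and in the folded region spanning both reads (plus `flank` nt
#' on each side) each read has at least `min_paired_fraction` of its bases
#' paired, with at least `min_cross_fraction` of those partners falling inside
#' the other read's interval — i.e. the two reads occupy opposite arms of one
#' stem. Folding uses [nussinov_fold()] unless an external dot-bracket
#' structure for the contig is supplied via `structures` (a named list of
#' `rna_structure` objects keyed by contig name, e.g. from
#' [read_structure_file()]); external structures are used for plus-strand
#' placements and must name a contig present in `contigs`.
#'
#' @param calls Call tibble from [find_duplex_pairs()].
#' @param contigs Contig tibble (`name`, `sequence`).
#' @param window Maximum separation between read starts in nt (default 300,
#'   plant pre-miRNA scale).
#' @param min_paired_fraction Minimum fraction of each read's bases paired
#'   (default 0.6).
#' @param min_cross_fraction Minimum fraction of a read's paired bases whose
#'   partner lies in the other read's interval (default 0.5).
#' @param flank Flanking nt added to the folded region (default 10).
#' @param structures Optional named list of external `rna_structure`s,
#'   keyed by contig name.
#' @param min_loop Passed to [nussinov_fold()].
#' @return `calls` with audit columns appended: `contig`, `strand`,
#'   `start_a`, `start_b`, `paired_fraction_a`, `paired_fraction_b`,
#'   `cross_fraction_a`, `cross_fraction_b`, `supported`.
#' @export
hairpin_support <- function(calls, contigs, window = 300,
                            min_paired_fraction = 0.6,
                            min_cross_fraction = 0.5,
                            flank = 10, structures = NULL, min_loop = 3) {
  if (!is.null(structures) && length(structures)) {
    missing_ctg <- setdiff(names(structures), contigs$name)
    if (length(missing_ctg)) {
      stop("external structure(s) name contig(s) absent from the reference: ",
           paste(missing_ctg, collapse = ", "), call. = FALSE)
    }
  }
  n <- nrow(calls)
  out <- tibble::tibble(
    contig = rep(NA_character_, n), strand = rep(NA_character_, n),
    start_a = rep(NA_integer_, n), start_b = rep(NA_integer_, n),
    paired_fraction_a = rep(NA_real_, n), paired_fraction_b = rep(NA_real_, n),
    cross_fraction_a = rep(NA_real_, n), cross_fraction_b = rep(NA_real_, n),
    supported = rep(FALSE, n))
  for (r in seq_len(n)) {
    res <- .support_one(calls$seq_a[r], calls$seq_b[r], contigs, window,
                        min_paired_fraction, min_cross_fraction, flank,
                        structures, min_loop)
    if (!is.null(res)) out[r, ] <- res
  }
  dplyr::bind_cols(calls, out)
}

.support_one <- function(seq_a, seq_b, contigs, window, min_pf, min_cf,
                         flank, structures, min_loop) {
  best <- NULL
  for (ci in seq_len(nrow(contigs))) {
    ctg <- contigs$sequence[ci]
    loc_a <- locate_read(seq_a, ctg)
    if (!nrow(loc_a)) next
    loc_b <- locate_read(seq_b, ctg)
    if (!nrow(loc_b)) next
    for (sa in seq_len(nrow(loc_a))) for (sb in seq_len(nrow(loc_b))) {
      if (loc_a$strand[sa] != loc_b$strand[sb]) next
      if (abs(loc_a$start[sa] - loc_b$start[sb]) > window) next
      strand <- loc_a$strand[sa]
      iv_a <- c(loc_a$start[sa], loc_a$start[sa] + nchar(seq_a) - 1L)
      iv_b <- c(loc_b$start[sb], loc_b$start[sb] + nchar(seq_b) - 1L)
      lo <- max(1L, min(iv_a[1], iv_b[1]) - flank)
      hi <- min(nchar(ctg), max(iv_a[2], iv_b[2]) + flank)
      ext <- !is.null(structures) &&
        contigs$name[ci] %in% names(structures) && strand == "+"
      if (ext) {
        st <- structures[[contigs$name[ci]]]
        if (nchar(st$sequence) != nchar(ctg)) {
          stop("external structure for contig '", contigs$name[ci],
               "' has a different length than the contig", call. = FALSE)
        }
        pt <- st$pair_table
        ia <- iv_a; ib <- iv_b
      } else {
        region <- substr(ctg, lo, hi)
        if (strand == "-") region <- rna_reverse_complement(region)
        st <- nussinov_fold(region, min_loop)
        pt_local <- st$pair_table
        if (strand == "+") {
          # local coords: pos - lo + 1; partners back in local frame
          ia <- iv_a - lo + 1L; ib <- iv_b - lo + 1L
        } else {
          # reverse-complemented frame: genomic pos p -> hi - p + 1
          ia <- sort(hi - iv_a + 1L); ib <- sort(hi - iv_b + 1L)
        }
        pt <- pt_local
      }
      st_a <- .arm_stats(pt, ia, ib)
      st_b <- .arm_stats(pt, ib, ia)
      ok <- st_a["paired_fraction"] >= min_pf &&
        st_b["paired_fraction"] >= min_pf &&
        st_a["cross_fraction"] >= min_cf &&
        st_b["cross_fraction"] >= min_cf
      row <- tibble::tibble(
        contig = contigs$name[ci], strand = strand,
        start_a = iv_a[1], start_b = iv_b[1],
        paired_fraction_a = unname(st_a["paired_fraction"]),
        paired_fraction_b = unname(st_b["paired_fraction"]),
        cross_fraction_a = unname(st_a["cross_fraction"]),
        cross_fraction_b = unname(st_b["cross_fraction"]),
        supported = ok)
      if (ok) return(row)
      if (is.null(best)) best <- row
    }
  }
  best
}

#' Read a two-line structure file (sequence, dot-bracket)
#'
#' Plain-text dialect for supplying externally computed secondary structures:
#' records of a `>name` header line, the sequence, and its dot-bracket.
#'
#' @param path File path.
#' @return Named list of `rna_structure` objects.
#' @export
read_structure_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads) || any(diff(heads) != 3)) {
    if (length(lines) %% 3 != 0 || !all(grepl("^>", lines[seq(1, length(lines), 3)]))) {
      stop("structure file must be records of: >name, sequence, dot-bracket",
           call. = FALSE)
    }
  }
  out <- list()
  for (i in seq(1, length(lines), by = 3)) {
    nm <- sub("^>\\s*", "", lines[i])
    nm <- sub("\\s.*$", "", nm)
    out[[nm]] <- parse_dotbracket(.transliterate_rna(lines[i + 1]),
                                  lines[i + 2])
  }
  out
}
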