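# RNA sequence algebra and duplex geometry.
#
# All sequences are plain character strings over {A,C,G,U}, read 5'->3',
# 1-based positions. DNA input (T) is transliterated to U at ingest by the
# I/O layer; these functions reject anything outside the RNA alphabet.

RNA_BASES <- c("A", "C", "G", "U")
.RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")
.PURINES <- c("A", "G")

#' Validate RNA sequences
#'
#' Checks that every element of `x` is a non-empty string over the RNA
#' alphabet `{A, C, G, U}`.
#'
#' @param x Character vector of candidate sequences (5'->3').
#' @param arg Name used in error messages.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @examples
#' check_rna("ACGU")
#' @export
check_rna <- function(x, arg = "sequence") {
  if (!is.character(x) || length(x) == 0 || anyNA(x)) {
    stop(sprintf("`%s` must be a character vector of RNA sequences", arg),
         call. = FALSE)
  }
  bad <- grepl("[^ACGU]", x) | nchar(x) == 0L
  if (any(bad)) {
    stop(sprintf(
      "`%s` contains %d sequence(s) with symbols outside {A,C,G,U} (or empty)",
      arg, sum(bad)), call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement of RNA sequences
#'
#' Watson-Crick reverse complement, returned 5'->3'. Vectorised.
#'
#' @param x Character vector of RNA sequences (5'->3').
#' @return Character vector of the same length.
#' @examples
#' rna_reverse_complement("CGUACGCGGAAUACUUCGAUU")
#' @export
rna_reverse_complement <- function(x) {
  check_rna(x)
  comp <- chartr("ACGU", "UGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Classify one base pair
#'
#' Classifies opposing bases of an antiparallel duplex: Watson-Crick
#' (`A:U`, `U:A`, `G:C`, `C:G`), wobble (`G:U`, `U:G`) or mismatch
#' (everything else). Wobble pairs count as paired throughout the package,
#' never as mismatches. Vectorised and symmetric in its arguments.
#'
#' @param base_a,base_b Character vectors of single RNA bases.
#' @return Character vector with values `"watson_crick"`, `"wobble"` or
#'   `"mismatch"`.
#' @examples
#' pair_class("G", "U")
#' @export
pair_class <- function(base_a, base_b) {
  check_rna(base_a, "base_a")
  check_rna(base_b, "base_b")
  if (any(nchar(base_a) != 1L) || any(nchar(base_b) != 1L)) {
    stop("`pair_class()` expects single bases", call. = FALSE)
  }
  key <- paste0(base_a, base_b)
  out <- rep("mismatch", length(key))
  out[key %in% c("AU", "UA", "GC", "CG")] <- "watson_crick"
  out[key %in% c("GU", "UG")] <- "wobble"
  out
}

.is_paired_class <- function(cls) cls != "mismatch"

#' Assemble a fixed-register RNA duplex with 3' overhangs
#'
#' Places two equal-length strands (both given 5'->3') in the unique gapless
#' antiparallel register that leaves exactly `overhang` unpaired nucleotides
#' at each 3' terminus: position `i` of `strand_a` faces position
#' `L - overhang + 1 - i` of `strand_b` over the paired region
#' `i = 1 .. L - overhang`. Overhang bases are never counted as mismatches.
#'
#' Strands of unequal length, or too short to leave the requested overhangs
#' (`L <= 2 * overhang`), admit no such register and are *rejected*:
#' the function returns `NULL`, which is distinguishable from a valid
#' high-mismatch duplex.
#'
#' @param strand_a,strand_b RNA sequences, 5'->3'.
#' @param overhang Unpaired nucleotides left at each 3' terminus
#'   (default 2, the Dicer-product geometry that p19 recognises).
#' @return An object of class `rna_duplex` (list with `strand_a`, `strand_b`,
#'   `overhang`, `pair_classes` indexed by `strand_a` position over the paired
#'   region, `mismatch_count`, `mismatch_positions`), or `NULL` on rejection.
#' @examples
#' dx <- assemble_duplex("CGUACGCGGAAUACUUCGAUU", "UCGAAGUAUUCCGCGUACGUU")
#' dx$mismatch_count
#' @export
assemble_duplex <- function(strand_a, strand_b, overhang = 2L) {
  check_rna(strand_a, "strand_a")
  check_rna(strand_b, "strand_b")
  stopifnot(length(strand_a) == 1L, length(strand_b) == 1L)
  overhang <- as.integer(overhang)
  if (is.na(overhang) || overhang < 0L) {
    stop("`overhang` must be a non-negative integer", call. = FALSE)
  }
  L <- nchar(strand_a)
  if (nchar(strand_b) != L || L <= 2L * overhang) {
    return(NULL)  # no gapless register with equal 3' overhangs exists
  }
  n_paired <- L - overhang
  a <- strsplit(strand_a, "", fixed = TRUE)[[1]]
  b <- strsplit(strand_b, "", fixed = TRUE)[[1]]
  i <- seq_len(n_paired)
  cls <- pair_class(a[i], b[L - overhang + 1L - i])
  mm_pos <- which(cls == "mismatch")
  structure(
    list(
      strand_a = strand_a,
      strand_b = strand_b,
      overhang = overhang,
      pair_classes = cls,
      mismatch_count = length(mm_pos),
      mismatch_positions = as.integer(mm_pos)
    ),
    class = "rna_duplex"
  )
}

#' @export
print.rna_duplex <- function(x, ...) {
  cat(sprintf(
    "<rna_duplex> %d nt strands, %d paired positions, %d-nt 3' overhangs\n",
    nchar(x$strand_a), length(x$pair_classes), x$overhang))
  cat("  5'-", x$strand_a, "-3'\n", sep = "")
  cat("  3'-", paste(rev(strsplit(x$strand_b, "")[[1]]), collapse = ""),
      "-5'\n", sep = "")
  if (x$mismatch_count == 0) {
    cat("  perfectly paired (wobble permitted)\n")
  } else {
    cat(sprintf("  %d mismatch(es) at strand-a position(s) %s\n",
                x$mismatch_count,
                paste(x$mismatch_positions, collapse = ", ")))
  }
  invisible(x)
}

#' Tidy a duplex into a per-position table
#'
#' @param x An `rna_duplex`.
#' @param ... Unused.
#' @return A tibble with one row per paired position: `pos_a`, `pos_b`,
#'   `base_a`, `base_b`, `class`.
#' @export
tidy.rna_duplex <- function(x, ...) {
  L <- nchar(x$strand_a)
  i <- seq_along(x$pair_classes)
  a <- strsplit(x$strand_a, "", fixed = TRUE)[[1]]
  b <- strsplit(x$strand_b, "", fixed = TRUE)[[1]]
  j <- L - x$overhang + 1L - i
  tibble::tibble(
    pos_a = i, pos_b = j,
    base_a = a[i], base_b = b[j],
    class = x$pair_classes
  )
}
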