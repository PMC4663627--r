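# Reading sRNA libraries and references; collapsed count tables.

.transliterate_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' Load and collapse a small-RNA read library
#'
#' Reads a FASTA or FASTQ file (gzip transparently handled), upper-cases and
#' transliterates `T -> U`, drops reads outside `length_range` or containing
#' symbols outside `{A, C, G, U, T}` (IUPAC ambiguity codes such as `N` are
#' dropped, never randomly resolved), and collapses identical sequences into a
#' count table. FASTA headers of the collapsed-library form `name_xN` are
#' honoured as pre-collapsed counts of `N`; any other record counts 1.
#' Quality values in FASTQ are ignored.
#'
#' @param path Path to the reads file.
#' @param format `"fasta"` or `"fastq"`; default guessed from the file
#'   extension (`.fq`/`.fastq` with optional `.gz` means FASTQ).
#' @param length_range Two-element numeric, inclusive bounds on read length in
#'   nt; default `c(18, 30)`, the small-RNA scale.
#' @return A tibble with columns `sequence` (RNA, 5'->3') and `count`,
#'   sorted by descending count then sequence. Attributes `n_records`,
#'   `n_dropped_length`, `n_dropped_alphabet` summarise the ingest log.
#'   An empty file yields an empty (zero-row) table.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "ACGTACGTACGTACGTACGTA", ">r2_x5", "ACGUACGUACGUACGUACGUA"), fa)
#' load_reads(fa)
#' @export
load_reads <- function(path, format = NULL, length_range = c(18, 30)) {
  if (!file.exists(path)) stop("reads file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path)) "fastq" else "fasta"
  }
  format <- match.arg(format, c("fasta", "fastq"))
  set <- Biostrings::readBStringSet(path, format = format)
  seqs <- unname(.transliterate_rna(as.character(set)))
  ids <- names(set)
  counts <- rep(1L, length(seqs))
  if (format == "fasta" && length(ids)) {
    tok <- sub("\\s.*$", "", ids)  # count suffix lives on the id token
    has <- grepl("_x[0-9]+$", tok)
    counts[has] <- as.integer(sub("^.*_x", "", tok[has]))
  }
  bad_alpha <- grepl("[^ACGU]", seqs)
  len <- nchar(seqs)
  bad_len <- !bad_alpha & (len < length_range[1] | len > length_range[2])
  keep <- !bad_alpha & !bad_len
  tbl <- tibble::tibble(sequence = seqs[keep], count = counts[keep]) |>
    dplyr::group_by(.data$sequence) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$sequence)
  attr(tbl, "n_records") <- length(seqs)
  attr(tbl, "n_dropped_length") <- sum(bad_len)
  attr(tbl, "n_dropped_alphabet") <- sum(bad_alpha)
  tbl
}

#' Write a collapsed count table
#'
#' Tab-separated, header `sequence\tcount`, rows sorted by descending count
#' then lexicographic sequence, so write -> read -> write round-trips to a
#' byte-identical file.
#'
#' @param table Tibble with `sequence` and `count` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  stopifnot(all(c("sequence", "count") %in% names(table)))
  out <- table |>
    dplyr::arrange(dplyr::desc(.data$count), .data$sequence) |>
    dplyr::select("sequence", "count")
  readr::write_tsv(out, path, eol = "\n", progress = FALSE)
  invisible(path)
}

#' Read a count table written by [write_count_table()]
#'
#' @param path Path to the TSV file.
#' @return A tibble with `sequence` and `count`, in canonical order.
#' @export
read_count_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sequence = readr::col_character(),
    count = readr::col_integer()
  ), progress = FALSE) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$sequence)
}

#' Load reference contigs from FASTA
#'
#' Contig sequences are transliterated to the RNA alphabet (`T -> U`) so that
#' reads and reference live in one alphabet; names are the first whitespace-
#' delimited token of each header and must be unique.
#'
#' @param path FASTA path (gzip accepted).
#' @return A tibble with columns `name` and `sequence`.
#' @export
load_contigs <- function(path) {
  set <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) stop("duplicate contig names in ", path, call. = FALSE)
  tibble::tibble(name = nm, sequence = .transliterate_rna(as.character(set)))
}

#' Write contigs or reads to FASTA
#'
#' @param x Tibble with `name`/`sequence` (contigs) or `sequence`/`count`
#'   (collapsed reads; headers become `s<i>_x<count>`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (all(c("name", "sequence") %in% names(x))) {
    headers <- x$name
  } else if (all(c("sequence", "count") %in% names(x))) {
    headers <- sprintf("s%d_x%d", seq_len(nrow(x)), x$count)
  } else {
    stop("`x` must have name/sequence or sequence/count columns", call. = FALSE)
  }
  lines <- character(0)
  if (nrow(x)) {
    lines <- as.vector(rbind(paste0(">", headers), x$sequence))
  }
  writeLines(lines, path)
  invisible(path)
}
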