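# Library-level descriptive statistics: power-of-2 count spectra, relative
# abundances, and input-vs-eluted duplex enrichment summaries.

#' Power-of-2 read-count spectrum
#'
#' Assigns each species to the count bin `[2^k, 2^(k+1) - 1]` and reports the
#' fraction of distinct species per bin (normalised by species, not by total
#' reads). Two headline summaries ride along as attributes:
#' `singleton_fraction` (species with count 1) and `tail_fraction_ge16`
#' (species with count >= 16).
#'
#' @param table Count tibble (`sequence`, `count`).
#' @return A tibble of class `count_spectrum` with `bin_lower`, `bin_upper`,
#'   `n_species`, `species_fraction` (summing to 1), plus the attributes
#'   above and `total_species`/`total_reads`. An empty table yields a
#'   zero-row spectrum with `NA` summaries.
#' @examples
#' bin_counts_pow2(tibble::tibble(sequence = letters[1:8],
#'                                count = c(1, 1, 1, 1, 3, 2, 16, 20)))
#' @export
bin_counts_pow2 <- function(table) {
  stopifnot(all(c("sequence", "count") %in% names(table)))
  if (!nrow(table)) {
    out <- tibble::tibble(bin_lower = integer(), bin_upper = integer(),
                          n_species = integer(), species_fraction = numeric())
    attr(out, "singleton_fraction") <- NA_real_
    attr(out, "tail_fraction_ge16") <- NA_real_
    attr(out, "total_species") <- 0L
    attr(out, "total_reads") <- 0L
    class(out) <- c("count_spectrum", class(out))
    return(out)
  }
  stopifnot(all(table$count >= 1))
  k <- floor(log2(table$count))
  out <- tibble::tibble(k = k) |>
    dplyr::count(.data$k, name = "n_species") |>
    dplyr::arrange(.data$k) |>
    dplyr::mutate(
      bin_lower = 2L^.data$k,
      bin_upper = 2L^(.data$k + 1L) - 1L,
      species_fraction = .data$n_species / nrow(table)) |>
    dplyr::select("bin_lower", "bin_upper", "n_species", "species_fraction")
  attr(out, "singleton_fraction") <- mean(table$count == 1)
  attr(out, "tail_fraction_ge16") <- mean(table$count >= 16)
  attr(out, "total_species") <- nrow(table)
  attr(out, "total_reads") <- sum(table$count)
  class(out) <- c("count_spectrum", class(out))
  out
}

#' Plot a count spectrum
#'
#' @param object A `count_spectrum` from [bin_counts_pow2()].
#' @param ... Unused.
#' @return A ggplot bar chart of species fraction per power-of-2 bin.
#' @export
autoplot.count_spectrum <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$bin <- factor(sprintf("%d-%d", df$bin_lower, df$bin_upper),
                   levels = sprintf("%d-%d", df$bin_lower, df$bin_upper))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$species_fraction)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "read-count bin", y = "fraction of species") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Relative abundance normalised to a reference species
#'
#' `percent = 100 * value / value(reference)`; the reference maps to exactly
#' 100. Applies to read counts and qPCR-derived amounts alike, and is
#' invariant under rescaling all quantities by a constant.
#'
#' @param values Data frame with columns `name` and `value`, or a named
#'   numeric vector.
#' @param reference Reference name (must be present, with value > 0).
#' @return Tibble with `name`, `value`, `percent`.
#' @examples
#' relative_abundance(c(miR168 = 2040, `miR168*` = 100), "miR168")
#' @export
relative_abundance <- function(values, reference) {
  if (!is.data.frame(values)) {
    values <- tibble::tibble(name = names(values), value = unname(values))
  }
  tbl <- tibble::tibble(name = values$name, value = as.numeric(values$value))
  if (!reference %in% tbl$name) {
    stop("reference '", reference, "' not present", call. = FALSE)
  }
  ref <- tbl$value[tbl$name == reference][1]
  if (!is.finite(ref) || ref <= 0) {
    stop("reference value must be positive", call. = FALSE)
  }
  tbl$percent <- 100 * tbl$value / ref
  tbl$percent[tbl$name == reference] <- 100
  tbl
}

#' Compare an input library against a p19-enriched (eluted) library
#'
#' Bundles per-library count spectra with duplex-call bookkeeping: number of
#' calls, distinct species involved in calls, the duplex fraction
#' (`calls / total_species`), and the enrichment ratio
#' (`eluted fraction / input fraction`). A zero input fraction with a
#' non-zero eluted fraction yields an infinite ratio, flagged rather than
#' erroring.
#'
#' @param input,eluted Count tibbles.
#' @param calls_input,calls_eluted Call tibbles from [find_duplex_pairs()].
#' @return Object of class `library_comparison` (list with `input`, `eluted`
#'   sub-reports and `enrichment_ratio`); see `glance()` for the one-row
#'   summary.
#' @export
compare_libraries <- function(input, eluted, calls_input, calls_eluted) {
  one <- function(tbl, calls) {
    n_species <- nrow(tbl)
    n_calls <- nrow(calls)
    list(
      spectrum = bin_counts_pow2(tbl),
      total_species = n_species,
      total_reads = if (n_species) sum(tbl$count) else 0L,
      n_calls = n_calls,
      n_call_species = length(unique(c(calls$seq_a, calls$seq_b))),
      duplex_fraction = if (n_species > 0) n_calls / n_species else NA_real_
    )
  }
  inp <- one(input, calls_input)
  elu <- one(eluted, calls_eluted)
  ratio <- if (is.na(inp$duplex_fraction) || is.na(elu$duplex_fraction)) {
    NA_real_
  } else if (inp$duplex_fraction == 0) {
    if (elu$duplex_fraction == 0) NA_real_ else Inf
  } else {
    elu$duplex_fraction / inp$duplex_fraction
  }
  structure(list(input = inp, eluted = elu, enrichment_ratio = ratio),
            class = "library_comparison")
}

#' @rdname compare_libraries
#' @param x A `library_comparison`.
#' @param ... Unused.
#' @export
glance.library_comparison <- function(x, ...) {
  tibble::tibble(
    input_species = x$input$total_species,
    input_reads = x$input$total_reads,
    input_calls = x$input$n_calls,
    input_duplex_fraction = x$input$duplex_fraction,
    eluted_species = x$eluted$total_species,
    eluted_reads = x$eluted$total_reads,
    eluted_calls = x$eluted$n_calls,
    eluted_duplex_fraction = x$eluted$duplex_fraction,
    enrichment_ratio = x$enrichment_ratio
  )
}

#' @export
print.library_comparison <- function(x, ...) {
  g <- glance(x)
  cat("<library_comparison>\n")
  cat(sprintf("  input : %d species, %d reads, %d calls (fraction %.3g)\n",
              g$input_species, g$input_reads, g$input_calls,
              g$input_duplex_fraction))
  cat(sprintf("  eluted: %d species, %d reads, %d calls (fraction %.3g)\n",
              g$eluted_species, g$eluted_reads, g$eluted_calls,
              g$eluted_duplex_fraction))
  cat(sprintf("  enrichment ratio: %s\n", format(g$enrichment_ratio)))
  invisible(x)
}
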