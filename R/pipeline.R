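# Orchestration: load -> (reference filter) -> count filter -> duplex scan
# -> (hairpin support) -> spectrum statistics, with a reproducibility
# manifest.

#' Build a pipeline configuration
#'
#' Validates and completes a configuration list for [run_scan_pipeline()].
#' Unknown keys are rejected with a message naming them.
#'
#' @param reads Path to the reads file (FASTA/FASTQ), or a count tibble.
#' @param reference Optional path to a contig FASTA (or contig tibble);
#'   enables the reference filter and hairpin support.
#' @param output_dir Optional directory for TSV/JSON outputs.
#' @param min_count,max_mismatches,overhang,allow_self_pairs,strategy Scan
#'   parameters, see [find_duplex_pairs()].
#' @param length_range Read-length window for ingest (default c(18, 30)).
#' @param window,min_paired_fraction,min_cross_fraction Hairpin-support
#'   thresholds, see [hairpin_support()].
#' @param structures Optional path to an external structure file
#'   (see [read_structure_file()]).
#' @param seed Seed recorded in the manifest (the scan itself is
#'   deterministic).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(reads, reference = NULL, output_dir = NULL,
                            min_count = 30, max_mismatches = 3, overhang = 2,
                            allow_self_pairs = TRUE,
                            strategy = "seeded",
                            length_range = c(18, 30),
                            window = 300, min_paired_fraction = 0.6,
                            min_cross_fraction = 0.5,
                            structures = NULL, seed = 1L) {
  cfg <- list(reads = reads, reference = reference, output_dir = output_dir,
              min_count = min_count, max_mismatches = max_mismatches,
              overhang = overhang, allow_self_pairs = allow_self_pairs,
              strategy = match.arg(strategy, c("seeded", "brute")),
              length_range = length_range, window = window,
              min_paired_fraction = min_paired_fraction,
              min_cross_fraction = min_cross_fraction,
              structures = structures, seed = as.integer(seed))
  stopifnot(cfg$min_count >= 0, cfg$max_mismatches >= 0, cfg$overhang >= 0,
            length(cfg$length_range) == 2L)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are
#' rejected with a message.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

#' Run the duplex-discovery pipeline
#'
#' Executes the full analysis path: read loading and collapsing, optional
#' exact-match reference cleaning, the strict `> min_count` filter, the
#' four-criterion duplex scan, optional hairpin-stem support against the
#' reference, and the power-of-2 count spectrum. When `config$output_dir` is
#' set, writes `counts.tsv`, `calls.tsv`, `spectrum.json` and
#' `manifest.json` (parameters, seed, package version, input checksums), so
#' identical configurations produce byte-identical outputs.
#'
#' @param config A [pipeline_config()] (or a list coerced through it).
#' @return A list of class `scan_pipeline_report`: `table` (post-filter
#'   counts), `n_species_loaded`, `calls` (with support columns when a
#'   reference is given), `spectrum`, `manifest`.
#' @export
run_scan_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  checksums <- list()
  if (is.character(config$reads)) {
    if (!file.exists(config$reads)) {
      stop("reads file not found: ", config$reads, call. = FALSE)
    }
    checksums$reads <- unname(tools::md5sum(config$reads))
    table <- load_reads(config$reads, length_range = config$length_range)
  } else {
    table <- tibble::as_tibble(config$reads)
  }
  n_loaded <- nrow(table)
  contigs <- NULL
  if (!is.null(config$reference)) {
    contigs <- if (is.character(config$reference)) {
      checksums$reference <- unname(tools::md5sum(config$reference))
      load_contigs(config$reference)
    } else tibble::as_tibble(config$reference)
    table <- filter_by_reference(table, contigs)
  }
  filtered <- filter_by_count(table, config$min_count)
  calls <- find_duplex_pairs(
    filtered, min_count = config$min_count,
    max_mismatches = config$max_mismatches, overhang = config$overhang,
    allow_self_pairs = config$allow_self_pairs, strategy = config$strategy)
  if (!is.null(contigs)) {
    structures <- if (!is.null(config$structures)) {
      read_structure_file(config$structures)
    } else NULL
    calls <- hairpin_support(
      calls, contigs, window = config$window,
      min_paired_fraction = config$min_paired_fraction,
      min_cross_fraction = config$min_cross_fraction,
      structures = structures)
  }
  spectrum <- bin_counts_pow2(table)
  manifest <- list(
    package = "srnaduplex",
    version = as.character(utils::packageVersion("srnaduplex")),
    parameters = config[setdiff(names(config), c("reads", "reference",
                                                 "output_dir"))],
    seed = config$seed,
    checksums = checksums,
    n_species_loaded = n_loaded,
    n_species_scanned = nrow(filtered),
    n_calls = nrow(calls))
  report <- structure(
    list(table = table, n_species_loaded = n_loaded, calls = calls,
         spectrum = spectrum, manifest = manifest),
    class = "scan_pipeline_report")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_count_table(table, file.path(config$output_dir, "counts.tsv"))
    readr::write_tsv(calls, file.path(config$output_dir, "calls.tsv"),
                     eol = "\n", progress = FALSE)
    jsonlite::write_json(
      list(spectrum = tibble::as_tibble(spectrum),
           singleton_fraction = attr(spectrum, "singleton_fraction"),
           tail_fraction_ge16 = attr(spectrum, "tail_fraction_ge16")),
      file.path(config$output_dir, "spectrum.json"),
      auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(config$output_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}

#' @export
print.scan_pipeline_report <- function(x, ...) {
  cat("<scan_pipeline_report>\n")
  cat(sprintf("  species loaded:   %d\n", x$n_species_loaded))
  cat(sprintf("  species scanned:  %d\n", x$manifest$n_species_scanned))
  cat(sprintf("  duplex calls:     %d\n", nrow(x$calls)))
  if ("supported" %in% names(x$calls)) {
    cat(sprintf("  hairpin-supported: %d\n", sum(x$calls$supported)))
  }
  invisible(x)
}

#' Recipe for the full-scale library reproduction
#'
#' The published input/eluted pair counts (459 and 3,752) and the library
#' spectra (80% singletons of 4,653,979 input species; 39% singletons and
#' >50% at count >= 16 of 199,001 eluted species) require the deposited
#' libraries SRR1555764 (input) and SRR1555765 (eluted) plus the
#' *N. benthamiana* genome v0.4.4 contigs, none of which this package
#' downloads; the exact read-cleaning details behind those libraries are
#' also not fully specified. This function returns the documented recipe
#' (shell commands) for users who fetch the data themselves.
#'
#' @return Tibble with `step` and `command` columns.
#' @export
full_scale_recipe <- function() {
  tibble::tibble(
    step = c(
      "fetch input library",
      "fetch eluted library",
      "fetch reference contigs",
      "run input scan",
      "run eluted scan"),
    command = c(
      "prefetch SRR1555764 && fasterq-dump SRR1555764",
      "prefetch SRR1555765 && fasterq-dump SRR1555765",
      paste0("download Niben.genome.v0.4.4.contig.fasta ",
             "(N. benthamiana genome v0.4.4) from the Sol Genomics Network"),
      paste0("Rscript inst/cli/srnaduplex.R scan --reads SRR1555764.fastq ",
             "--reference Niben.genome.v0.4.4.contig.fasta --out input_run"),
      paste0("Rscript inst/cli/srnaduplex.R scan --reads SRR1555765.fastq ",
             "--reference Niben.genome.v0.4.4.contig.fasta --out eluted_run"))
  )
}
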