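# Synthetic-data generator: pre-miRNA hairpins planted in random contigs, a
# collapsed sRNA library with a heavy singleton background and strand-
# asymmetric degradation of the star strand, and a p19 sequestration step
# that captures duplexes according to Langmuir occupancy.

# sample() semantics without the scalar-x surprise
.sample1 <- function(x, prob = NULL) x[sample.int(length(x), 1, prob = prob)]
.sample_n <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]

# Run code under a given RNG seed without disturbing global RNG state.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.random_rna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(RNA_BASES, length, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulation parameters for the p19 sequestration generator
#'
#' Bundles every knob of the generator with defaults matching the study
#' conditions this package emulates: ~80% of distinct input species are
#' singletons, the star strand survives at ~5% of the guide strand, planted
#' guide counts are 31-500 so planted duplexes pass the `> 30` count
#' criterion, and duplex capture follows Langmuir occupancy with the
#' dissociation-constant ladder measured for 0-3 mismatch duplexes
#' (16, 55, 227, 1138 nM) at an effective p19 concentration of 100 nM.
#'
#' @param seed Integer seed; every random draw in the generator flows from
#'   it (stage offsets 0/1/2 for hairpins/library/sequestration).
#' @param n_hairpins Number of planted pre-miRNA hairpins (default 5).
#' @param arm_length Read/arm length in nt (default 21).
#' @param mismatch_spectrum Probabilities over 0-3 mismatches for planted
#'   duplexes (default uniform).
#' @param loop_length Two-element range of hairpin loop lengths in nt
#'   (default 8-15).
#' @param contig_length Length of each background contig (default 500 nt).
#' @param n_background Number of background (non-pairing) species
#'   (default 1000).
#' @param background_singleton_fraction Fraction of background species at
#'   count 1 (default 0.8).
#' @param star_survival Binomial survival probability of each star-strand
#'   copy in the input library (default 0.05).
#' @param planted_count_range Inclusive range of planted guide-strand counts
#'   (default c(31, 500)).
#' @param p19_concentration Effective p19 concentration during capture, nM
#'   (default 100).
#' @param kd_by_class Named numeric, dissociation constant (nM) per mismatch
#'   class `"0"..."3"` (default c(16, 55, 227, 1138)).
#' @param nonspecific_capture_prob Retention probability for single-stranded
#'   copies and background reads (default 0.01).
#' @param eluted_total_reads Sequencing depth of the eluted library; `NULL`
#'   (default) re-sequences the captured pool to the input library's total
#'   read count, `NA` disables depth re-scaling (pure thinning).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(seed,
                       n_hairpins = 5L,
                       arm_length = 21L,
                       mismatch_spectrum = c(`0` = 0.25, `1` = 0.25,
                                             `2` = 0.25, `3` = 0.25),
                       loop_length = c(8L, 15L),
                       contig_length = 500L,
                       n_background = 1000L,
                       background_singleton_fraction = 0.8,
                       star_survival = 0.05,
                       planted_count_range = c(31L, 500L),
                       p19_concentration = 100,
                       kd_by_class = c(`0` = 16, `1` = 55,
                                       `2` = 227, `3` = 1138),
                       nonspecific_capture_prob = 0.01,
                       eluted_total_reads = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (arm_length <= 4) stop("`arm_length` must exceed 4 nt", call. = FALSE)
  stopifnot(
    n_hairpins >= 0, length(loop_length) == 2L,
    loop_length[1] >= 4, loop_length[2] >= loop_length[1],
    contig_length >= arm_length * 2 + loop_length[2],
    n_background >= 0,
    background_singleton_fraction >= 0, background_singleton_fraction <= 1,
    star_survival >= 0, star_survival <= 1,
    length(planted_count_range) == 2L,
    planted_count_range[1] >= 1,
    planted_count_range[2] >= planted_count_range[1],
    p19_concentration > 0,
    all(kd_by_class > 0),
    nonspecific_capture_prob >= 0, nonspecific_capture_prob <= 1
  )
  if (abs(sum(mismatch_spectrum) - 1) > 1e-9 || any(mismatch_spectrum < 0)) {
    stop("`mismatch_spectrum` must be a probability vector", call. = FALSE)
  }
  if (is.null(names(mismatch_spectrum))) {
    names(mismatch_spectrum) <- as.character(seq_along(mismatch_spectrum) - 1L)
  }
  structure(list(
    seed = as.integer(seed), n_hairpins = as.integer(n_hairpins),
    arm_length = as.integer(arm_length),
    mismatch_spectrum = mismatch_spectrum,
    loop_length = as.integer(loop_length),
    contig_length = as.integer(contig_length),
    n_background = as.integer(n_background),
    background_singleton_fraction = background_singleton_fraction,
    star_survival = star_survival,
    planted_count_range = as.integer(planted_count_range),
    p19_concentration = p19_concentration,
    kd_by_class = kd_by_class,
    nonspecific_capture_prob = nonspecific_capture_prob,
    eluted_total_reads = eluted_total_reads
  ), class = "sim_params")
}

# substitute star positions so that the facing pair becomes a mismatch
.inject_mismatches <- function(mirna, star, n_mm, overhang = 2L) {
  if (n_mm == 0) return(list(star = star, positions = integer(0)))
  L <- nchar(mirna)
  Lp <- L - overhang
  a <- strsplit(mirna, "", fixed = TRUE)[[1]]
  b <- strsplit(star, "", fixed = TRUE)[[1]]
  pos_a <- sort(sample(seq_len(Lp), n_mm))
  for (i in pos_a) {
    j <- Lp + 1L - i  # partner position on the star strand
    opts <- RNA_BASES[pair_class(rep(a[i], 4), RNA_BASES) == "mismatch"]
    b[j] <- .sample1(opts)
  }
  list(star = paste(b, collapse = ""), positions = pos_a)
}

#' Generate pre-miRNA hairpins embedded in background contigs
#'
#' Each hairpin is `guide + loop + star` where the star arm is the reverse
#' complement of the guide's first `arm_length - 2` nt (so the two arms
#' assemble into a duplex with 2-nt 3' overhangs by construction) extended by
#' 2 random 3' nt, with the requested number of mismatch substitutions
#' injected into the star arm. Hairpins are embedded at random positions in
#' random-sequence contigs. Deterministic given `params$seed`.
#'
#' @param params A [sim_params()] object.
#' @return List with `contigs` (tibble `name`, `sequence`) and `truths`
#'   (tibble: `hairpin`, `contig`, `mirna_start`, `star_start`, `mirna`,
#'   `star`, `mismatches`, `class`).
#' @export
generate_premirna_set <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  .with_seed(params$seed, {
    p <- params
    L <- p$arm_length
    rows <- vector("list", p$n_hairpins)
    contigs <- character(p$n_hairpins)
    mm_levels <- as.integer(names(p$mismatch_spectrum))
    for (h in seq_len(p$n_hairpins)) {
      guide <- .random_rna(1, L)
      star0 <- paste0(rna_reverse_complement(substr(guide, 1L, L - 2L)),
                      .random_rna(1, 2))
      n_mm <- .sample1(mm_levels, prob = p$mismatch_spectrum)
      inj <- .inject_mismatches(guide, star0, n_mm)
      loop <- .random_rna(1, .sample1(seq(p$loop_length[1], p$loop_length[2])))
      hairpin <- paste0(guide, loop, inj$star)
      pad <- p$contig_length - nchar(hairpin)
      at <- sample.int(pad + 1L, 1)  # hairpin start within contig
      bg <- .random_rna(1, p$contig_length)
      contig <- paste0(substr(bg, 1, at - 1L), hairpin,
                       substr(bg, at + nchar(hairpin), p$contig_length))
      contigs[h] <- contig
      rows[[h]] <- tibble::tibble(
        hairpin = sprintf("hp%02d", h),
        contig = sprintf("contig%02d", h),
        mirna_start = at,
        star_start = at + L + nchar(loop),
        mirna = guide, star = inj$star,
        mismatches = n_mm,
        class = as.character(n_mm))
    }
    truths <- if (p$n_hairpins) dplyr::bind_rows(rows) else
      tibble::tibble(hairpin = character(), contig = character(),
                     mirna_start = integer(), star_start = integer(),
                     mirna = character(), star = character(),
                     mismatches = integer(), class = character())
    list(
      contigs = tibble::tibble(
        name = sprintf("contig%02d", seq_len(p$n_hairpins)),
        sequence = contigs),
      truths = truths
    )
  })
}

# does candidate background read form a valid duplex with any planted read?
.pairs_with_any <- function(seq, planted, max_mismatches = 3L, overhang = 2L) {
  same_len <- planted[nchar(planted) == nchar(seq)]
  for (pl in same_len) {
    dx <- assemble_duplex(seq, pl, overhang)
    if (!is.null(dx) && dx$mismatch_count <= max_mismatches) return(TRUE)
  }
  FALSE
}

#' Generate the input sRNA library
#'
#' Planted guide counts are drawn uniformly from `planted_count_range`; star
#' counts are `Binomial(guide count, star_survival)`, emulating the rapid
#' in-vivo degradation of the passenger strand. Background species are random
#' 20-24 nt sequences, rejection-sampled so none forms a valid (<= 3
#' mismatch, 2-nt overhang) duplex with a planted read, with counts designed
#' so that about `background_singleton_fraction` of species are singletons.
#' Deterministic given `params$seed`.
#'
#' @param contigs,truths Output of [generate_premirna_set()].
#' @param params A [sim_params()] object.
#' @return Count tibble (`sequence`, `count`) in canonical order.
#' @export
generate_library <- function(contigs, truths, params) {
  stopifnot(inherits(params, "sim_params"))
  .with_seed(params$seed + 1L, {
    p <- params
    planted <- c(truths$mirna, truths$star)
    rows <- list()
    if (nrow(truths)) {
      g_counts <- .sample_n(seq(p$planted_count_range[1],
                                p$planted_count_range[2]),
                            nrow(truths))
      s_counts <- stats::rbinom(nrow(truths), g_counts, p$star_survival)
      rows[[1]] <- tibble::tibble(sequence = truths$mirna, count = g_counts)
      keep <- s_counts > 0
      rows[[2]] <- tibble::tibble(sequence = truths$star[keep],
                                  count = s_counts[keep])
    }
    if (p$n_background > 0) {
      bg <- character(p$n_background)
      i <- 1L
      while (i <= p$n_background) {
        cand <- .random_rna(1, .sample1(20:24))
        if (!.pairs_with_any(cand, planted)) {
          bg[i] <- cand
          i <- i + 1L
        }
      }
      singleton <- stats::runif(p$n_background) < p$background_singleton_fraction
      counts <- ifelse(singleton, 1L,
                       2L + stats::rgeom(p$n_background, prob = 0.15))
      rows[[length(rows) + 1L]] <- tibble::tibble(sequence = bg,
                                                  count = as.integer(counts))
    }
    dplyr::bind_rows(rows) |>
      dplyr::group_by(.data$sequence) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$count), .data$sequence)
  })
}

#' Simulate p19 sequestration (capture and elution)
#'
#' p19 binds the duplex, not the strands: for each planted pair, the paired
#' copies `min(count_guide, count_star)` are eligible for specific capture,
#' each retained with the Langmuir occupancy
#' `p19_concentration / (p19_concentration + K_d(class))`; guide and star
#' copies of a captured duplex are captured together, so captured strand
#' counts are exactly equal. Leftover single-stranded copies and all
#' background reads are retained with `nonspecific_capture_prob`.
#'
#' The captured pool is then *sequenced*: counts are re-scaled
#' deterministically to the eluted library's depth (`eluted_total_reads`;
#' default the input library's total), mirroring that a real eluted library
#' is an independently sequenced sample, not a subsample of the input
#' library's reads. The uniform scaling preserves exact strand balance of
#' captured duplexes. Deterministic given `params$seed`.
#'
#' @param library Input count tibble from [generate_library()].
#' @param truths Truth tibble from [generate_premirna_set()].
#' @param params A [sim_params()] object.
#' @return Eluted count tibble (`sequence`, `count`), zero-count species
#'   dropped, canonical order.
#' @export
simulate_sequestration <- function(library, truths, params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  if (nrow(truths)) {
    unknown <- setdiff(truths$class, names(p$kd_by_class))
    if (length(unknown)) {
      stop("no K_d configured for duplex class(es): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  .with_seed(p$seed + 2L, {
    cnt <- stats::setNames(library$count, library$sequence)
    get_count <- function(s) if (s %in% names(cnt)) unname(cnt[s]) else 0L
    eluted <- stats::setNames(integer(0), character(0))
    add <- function(seq, n) {
      if (n > 0) eluted[seq] <<- (if (seq %in% names(eluted))
        eluted[seq] else 0L) + n
    }
    specific <- character(0)
    if (nrow(truths)) {
      for (r in seq_len(nrow(truths))) {
        cg <- get_count(truths$mirna[r])
        cs <- get_count(truths$star[r])
        paired <- min(cg, cs)
        kd <- p$kd_by_class[[truths$class[r]]]
        occ <- p$p19_concentration / (p$p19_concentration + kd)
        cap <- if (paired > 0) stats::rbinom(1, paired, occ) else 0L
        add(truths$mirna[r], cap)
        add(truths$star[r], cap)
        add(truths$mirna[r], stats::rbinom(1, cg - cap,
                                           p$nonspecific_capture_prob))
        add(truths$star[r], stats::rbinom(1, cs - cap,
                                          p$nonspecific_capture_prob))
        specific <- c(specific, truths$mirna[r], truths$star[r])
      }
    }
    bg <- setdiff(names(cnt), specific)
    for (s in bg) add(s, stats::rbinom(1, cnt[[s]], p$nonspecific_capture_prob))
    out <- tibble::tibble(sequence = names(eluted),
                          count = as.integer(unname(eluted)))
    out <- out[out$count > 0, , drop = FALSE]
    target <- p$eluted_total_reads
    if (is.null(target)) target <- sum(library$count)
    if (!is.na(target) && nrow(out) && sum(out$count) > 0) {
      f <- target / sum(out$count)
      out$count <- as.integer(round(out$count * f))
      out <- out[out$count > 0, , drop = FALSE]
    }
    dplyr::arrange(out, dplyr::desc(.data$count), .data$sequence)
  })
}

#' Run the full synthetic experiment
#'
#' Convenience wrapper: [generate_premirna_set()], [generate_library()] and
#' [simulate_sequestration()] in sequence.
#'
#' @param params A [sim_params()] object.
#' @return List with `contigs`, `truths`, `input`, `eluted`.
#' @examples
#' sim <- simulate_srna_experiment(sim_params(seed = 1, n_hairpins = 2,
#'                                            n_background = 20))
#' nrow(sim$input)
#' @export
simulate_srna_experiment <- function(params) {
  hp <- generate_premirna_set(params)
  input <- generate_library(hp$contigs, hp$truths, params)
  eluted <- simulate_sequestration(input, hp$truths, params)
  list(contigs = hp$contigs, truths = hp$truths,
       input = input, eluted = eluted)
}
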