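small_params <- function(seed = 1, ...) {
  sim_params(seed = seed, n_hairpins = 3L, n_background = 60L,
             contig_length = 300L, ...)
}

test_that("generated hairpins honour the duplex geometry by construction", {
  hp <- generate_premirna_set(small_params())
  expect_equal(nrow(hp$truths), 3)
  for (r in seq_len(nrow(hp$truths))) {
    dx <- assemble_duplex(hp$truths$mirna[r], hp$truths$star[r], overhang = 2)
    expect_equal(dx$mismatch_count, hp$truths$mismatches[r])
    # both arms are exact substrings of the named contig at the stated starts
    ctg <- hp$contigs$sequence[hp$contigs$name == hp$truths$contig[r]]
    expect_equal(substr(ctg, hp$truths$mirna_start[r],
                        hp$truths$mirna_start[r] + 20),
                 hp$truths$mirna[r])
    expect_equal(substr(ctg, hp$truths$star_start[r],
                        hp$truths$star_start[r] + 20),
                 hp$truths$star[r])
  }
})

test_that("perfect planted hairpins fold with arm-to-arm support; shuffled arms do not", {
  p <- small_params(seed = 2, mismatch_spectrum = c(`0` = 1))
  hp <- generate_premirna_set(p)
  calls <- tibble::tibble(seq_a = hp$truths$mirna, seq_b = hp$truths$star)
  sup <- hairpin_support(calls, hp$contigs)
  expect_true(all(sup$supported))
  # shuffled-arm control: a random read in place of the star arm
  set.seed(9)
  fake <- tibble::tibble(seq_a = hp$truths$mirna[1], seq_b = rand_rna(1, 21))
  expect_false(hairpin_support(fake, hp$contigs)$supported)
})

test_that("the generator is deterministic given the seed", {
  a <- simulate_srna_experiment(small_params(seed = 7))
  b <- simulate_srna_experiment(small_params(seed = 7))
  expect_identical(a, b)
  c <- simulate_srna_experiment(small_params(seed = 8))
  expect_false(identical(a$input, c$input))
})

test_that("the background is dominated by singletons at the configured rate", {
  p <- sim_params(seed = 3, n_hairpins = 5L, n_background = 1000L)
  sim <- generate_premirna_set(p)
  lib <- generate_library(sim$contigs, sim$truths, p)
  expect_equal(mean(lib$count == 1), 0.8, tolerance = 0.05)
})

test_that("a fully degraded star strand leaves no duplex calls among planted pairs", {
  p <- small_params(seed = 4, star_survival = 0)
  sim <- simulate_srna_experiment(p)
  expect_false(any(sim$truths$star %in% sim$input$sequence))
  calls <- find_duplex_pairs(sim$input)
  key <- paste(pmin(sim$truths$mirna, sim$truths$star),
               pmax(sim$truths$mirna, sim$truths$star))
  expect_false(any(key %in% paste(calls$seq_a, calls$seq_b)))
})

test_that("surviving stars with zero mismatches make every planted pair callable", {
  p <- small_params(seed = 5, star_survival = 1,
                    mismatch_spectrum = c(`0` = 1))
  sim <- simulate_srna_experiment(p)
  calls <- find_duplex_pairs(sim$input)
  key <- paste(pmin(sim$truths$mirna, sim$truths$star),
               pmax(sim$truths$mirna, sim$truths$star))
  expect_true(all(key %in% paste(calls$seq_a, calls$seq_b)))
})

test_that("three-mismatch duplexes are called at the bound and missed below it", {
  p <- small_params(seed = 6, star_survival = 1,
                    mismatch_spectrum = c(`0` = 0, `1` = 0, `2` = 0, `3` = 1))
  sim <- simulate_srna_experiment(p)
  expect_true(all(sim$truths$mismatches == 3))
  key <- paste(pmin(sim$truths$mirna, sim$truths$star),
               pmax(sim$truths$mirna, sim$truths$star))
  at3 <- find_duplex_pairs(sim$input, max_mismatches = 3)
  at2 <- find_duplex_pairs(sim$input, max_mismatches = 2)
  expect_true(all(key %in% paste(at3$seq_a, at3$seq_b)))
  expect_false(any(key %in% paste(at2$seq_a, at2$seq_b)))
})

test_that("capture probability is Langmuir occupancy of the duplex", {
  # at p19 concentration == K_d, each paired copy is captured w.p. 1/2;
  # disable non-specific capture and depth re-scaling to observe it directly
  p <- sim_params(seed = 10, n_hairpins = 40L, n_background = 0L,
                  star_survival = 1, mismatch_spectrum = c(`0` = 1),
                  p19_concentration = 16, kd_by_class = c(`0` = 16),
                  nonspecific_capture_prob = 0, eluted_total_reads = NA)
  sim <- simulate_srna_experiment(p)
  paired_total <- sum(sim$input$count[sim$input$sequence %in%
                                        sim$truths$star])
  captured <- sum(sim$eluted$count) / 2  # both strands counted
  phat <- captured / paired_total
  se <- sqrt(0.5 * 0.5 / paired_total)
  expect_lt(abs(phat - 0.5), 4 * se)
})

test_that("the measured affinity ladder orders capture as expected", {
  kd <- c(ds0 = 16, ds1 = 55, ds2 = 227, ds3 = 1138, ds4 = 117, ds5 = 722)
  occ <- langmuir_response(100, 1, kd)
  expect_equal(names(sort(occ, decreasing = TRUE)),
               c("ds0", "ds1", "ds4", "ds2", "ds5", "ds3"))
})

test_that("pure duplex capture leaves guide and star exactly balanced", {
  p <- small_params(seed = 11, nonspecific_capture_prob = 0)
  sim <- simulate_srna_experiment(p)
  cnt <- stats::setNames(sim$eluted$count, sim$eluted$sequence)
  lookup <- function(s) if (s %in% names(cnt)) unname(cnt[[s]]) else 0L
  for (r in seq_len(nrow(sim$truths))) {
    expect_identical(lookup(sim$truths$mirna[r]), lookup(sim$truths$star[r]))
  }
})

test_that("an unknown duplex class is a configuration error", {
  p <- small_params(seed = 12, kd_by_class = c(`9` = 16))
  hp <- generate_premirna_set(p)
  lib <- generate_library(hp$contigs, hp$truths, p)
  expect_error(simulate_sequestration(lib, hp$truths, p), "no K_d configured")
})
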