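test_that("reference filtering keeps exact matches on either strand only", {
  set.seed(50)
  ctg <- paste(rand_rna(1, 200), collapse = "")
  contigs <- tibble::tibble(name = "c1", sequence = ctg)
  inside <- substr(ctg, 31, 51)
  mutated <- inside
  substr(mutated, 11, 11) <- setdiff(c("A", "C", "G", "U"),
                                     substr(inside, 11, 11))[1]
  while (grepl(mutated, ctg, fixed = TRUE) ||
         grepl(rna_reverse_complement(mutated), ctg, fixed = TRUE)) {
    substr(mutated, 12, 12) <- "A"
  }
  tbl <- tibble::tibble(
    sequence = c(inside, rna_reverse_complement(inside), mutated),
    count = c(5L, 7L, 9L))
  kept <- filter_by_reference(tbl, contigs)
  expect_setequal(kept$sequence, c(inside, rna_reverse_complement(inside)))
  expect_equal(kept$count[kept$sequence == inside], 5L)  # counts unchanged
  expect_lte(nrow(kept), nrow(tbl))
})

test_that("locate_read reports all occurrences with strand and ascending starts", {
  seq <- "ACGUACGUACGUACGUACGUA"
  ctg <- paste0(strrep("G", 10), seq, strrep("C", 5), seq, strrep("G", 4))
  loc <- locate_read(seq, ctg)
  expect_equal(loc$start[loc$strand == "+"], c(11L, 37L))
  expect_equal(nrow(locate_read("UUUUUUUUUUUUUUUUUUUUU", ctg)), 0)
  rc <- rna_reverse_complement(seq)
  loc2 <- locate_read(rc, ctg)
  expect_equal(loc2$start[loc2$strand == "-"], c(11L, 37L))
})

test_that("base-pair maximisation matches known folds", {
  f <- nussinov_fold("GGGAAAACCC")
  expect_equal(f$dotbracket, "(((....)))")
  expect_equal(f$n_pairs, 3)
  expect_equal(nussinov_fold("AAAAAA")$dotbracket, "......")
  # pair table is symmetric and consistent with the dot-bracket
  expect_equal(f$pair_table[f$pair_table > 0][1:3], c(10L, 9L, 8L))
  expect_equal(parse_dotbracket(f$sequence, f$dotbracket)$pair_table,
               f$pair_table)
})

test_that("fold pair counts equal exhaustive enumeration on random sequences", {
  set.seed(51)
  for (rep in 1:30) {
    s <- rand_rna(1, 12)
    expect_equal(nussinov_fold(s)$n_pairs, oracle_max_pairs(s),
                 info = s)
  }
})

test_that("no pair violates the minimum loop separation", {
  set.seed(52)
  for (ml in c(0, 3, 5)) {
    s <- rand_rna(1, 30)
    pt <- nussinov_fold(s, min_loop = ml)$pair_table
    idx <- which(pt > 0)
    expect_true(all(abs(pt[idx] - idx) > ml))
  }
})

test_that("malformed dot-brackets are rejected", {
  expect_error(parse_dotbracket("ACGU", "(()"), "length")
  expect_error(parse_dotbracket("ACGUA", "(()))"), "unbalanced")
  expect_error(parse_dotbracket("ACGUA", "((().("), "length")
})

test_that("reads on opposite arms of a planted stem are supported", {
  # arm of G only: the all-A loop cannot pair with anything, so the fold
  # must pair arm to arm and every partner falls in the other read
  arm <- strrep("G", 21)
  ctg <- paste0(arm, strrep("A", 8), rna_reverse_complement(arm))
  contigs <- tibble::tibble(name = "hp", sequence = ctg)
  calls <- tibble::tibble(seq_a = arm, seq_b = rna_reverse_complement(arm))
  sup <- hairpin_support(calls, contigs)
  expect_true(sup$supported)
  expect_equal(sup$cross_fraction_a, 1.0)
  expect_equal(sup$cross_fraction_b, 1.0)
  expect_equal(sup$contig, "hp")
  # a random-sequence stem is still supported even when the maximising fold
  # recruits the odd loop base
  set.seed(53)
  arm <- rand_rna(1, 21)
  ctg <- paste0(arm, rand_rna(1, 8), rna_reverse_complement(arm))
  sup2 <- hairpin_support(
    tibble::tibble(seq_a = arm, seq_b = rna_reverse_complement(arm)),
    tibble::tibble(name = "hp", sequence = ctg))
  expect_true(sup2$supported)
  expect_gte(sup2$cross_fraction_a, 0.5)
})

test_that("reads in different contigs, or loop-only reads, are not supported", {
  set.seed(54)
  arm <- rand_rna(1, 21)
  loop <- rand_rna(1, 10)
  hair <- paste0(arm, loop, rna_reverse_complement(arm))
  split_contigs <- tibble::tibble(
    name = c("c1", "c2"),
    sequence = c(paste0(rand_rna(1, 30), arm, rand_rna(1, 30)),
                 paste0(rand_rna(1, 30), rna_reverse_complement(arm),
                        rand_rna(1, 30))))
  calls <- tibble::tibble(seq_a = arm, seq_b = rna_reverse_complement(arm))
  expect_false(hairpin_support(calls, split_contigs)$supported)
  # a read sitting wholly in the loop is not on the opposite arm: too few of
  # the stem read's partners fall inside it
  loop_read <- substr(hair, 23, 30)
  sup <- hairpin_support(
    tibble::tibble(seq_a = arm, seq_b = loop_read),
    tibble::tibble(name = "hp", sequence = hair))
  expect_false(sup$supported)
  expect_lt(sup$cross_fraction_a, 0.5)
})

test_that("a hairpin transcribed from the minus strand is still supported", {
  set.seed(55)
  arm <- rand_rna(1, 21)
  star <- perfect_partner(arm)  # rc of first 19 nt plus a 2-nt 3' extension
  hair <- paste0(arm, rand_rna(1, 9), star)
  contigs <- tibble::tibble(
    name = "rc", sequence = rna_reverse_complement(hair))
  calls <- tibble::tibble(seq_a = arm, seq_b = star)
  sup <- hairpin_support(calls, contigs)
  expect_true(sup$supported)
  expect_equal(sup$strand, "-")
})

test_that("external dot-bracket structures are used and validated", {
  set.seed(56)
  arm <- rand_rna(1, 21)
  loop <- rand_rna(1, 8)
  ctg <- paste0(arm, loop, rna_reverse_complement(arm))
  contigs <- tibble::tibble(name = "hp", sequence = ctg)
  db <- paste0(strrep("(", 21), strrep(".", 8), strrep(")", 21))
  structs <- list(hp = parse_dotbracket(ctg, db))
  calls <- tibble::tibble(seq_a = arm, seq_b = rna_reverse_complement(arm))
  sup <- hairpin_support(calls, contigs, structures = structs)
  expect_true(sup$supported)
  expect_equal(sup$paired_fraction_a, 1.0)  # external structure pairs all 21
  expect_error(
    hairpin_support(calls, contigs,
                    structures = stats::setNames(structs, "missing")),
    "absent from the reference")
})

test_that("structure files round-trip through the two-line dialect", {
  p <- tempfile(fileext = ".txt")
  writeLines(c(">hp1", "GGGAAAACCC", "(((....)))",
               ">hp2", "ACGUACGU", "........"), p)
  st <- read_structure_file(p)
  expect_named(st, c("hp1", "hp2"))
  expect_equal(st$hp1$n_pairs, 3)
  expect_equal(st$hp2$n_pairs, 0)
})
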