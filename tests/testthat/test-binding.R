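DESIGN_C <- c(1, 5, 10, 25, 50, 100, 200, 400)

test_that("the isotherm obeys its limiting identities", {
  expect_equal(langmuir_response(16, 2, 16), 1)        # C = K_d -> half max
  expect_equal(langmuir_response(0, 2, 16), 0)
  expect_equal(langmuir_response(1e9, 2, 16), 2, tolerance = 1e-6)
  expect_true(all(diff(langmuir_response(DESIGN_C, 2, 16)) > 0))
  expect_error(langmuir_response(10, 2, 0), "positive")
  expect_error(langmuir_response(-1, 2, 16), "non-negative")
})

test_that("noiseless curves are recovered to machine precision", {
  crv <- data.frame(concentration = DESIGN_C,
                    response = langmuir_response(DESIGN_C, 2, 16))
  fit <- fit_langmuir(crv, fix_dG_max = FALSE)
  expect_true(fit$converged)
  expect_lt(abs(fit$kd - 16) / 16, 1e-6)
  expect_lt(abs(fit$dg_max - 2) / 2, 1e-6)
  td <- tidy(fit)
  expect_equal(td$term, c("K_d", "dG_max"))
  expect_equal(glance(fit)$n_obs, 8)
})

test_that("fixed-saturation mode pins dG_max to the saturation mean", {
  C <- c(1, 5, 10, 25, 50, 100, 200, 5000, 10000)
  crv <- data.frame(concentration = C,
                    response = langmuir_response(C, 2, 16))
  fit <- fit_langmuir(crv, fix_dG_max = TRUE, saturation_threshold = 1000)
  expect_true(fit$dg_max_fixed)
  expect_equal(fit$dg_max, mean(crv$response[C >= 1000]))
  expect_lt(abs(fit$kd - 16) / 16, 0.05)
  # falls back to a free dG_max when nothing reaches the threshold
  low <- crv[C < 200, ]
  fit2 <- fit_langmuir(low, fix_dG_max = TRUE, saturation_threshold = 200)
  expect_false(fit2$dg_max_fixed)
})

test_that("the fit is scale-equivariant in the response", {
  set.seed(60)
  y <- langmuir_response(DESIGN_C, 2, 55) * (1 + 0.03 * rnorm(8))
  f1 <- fit_langmuir(data.frame(concentration = DESIGN_C, response = y),
                     fix_dG_max = FALSE)
  f5 <- fit_langmuir(data.frame(concentration = DESIGN_C, response = 5 * y),
                     fix_dG_max = FALSE)
  expect_equal(f5$kd, f1$kd, tolerance = 1e-6)
  expect_equal(f5$dg_max, 5 * f1$dg_max, tolerance = 1e-6)
})

test_that("noisy replicates recover the dissociation constant on average", {
  set.seed(61)
  kds <- replicate(30, {
    y <- langmuir_response(DESIGN_C, 2, 16) * (1 + 0.05 * rnorm(8))
    fit_langmuir(data.frame(concentration = DESIGN_C, response = y),
                 fix_dG_max = FALSE)$kd
  })
  expect_lt(abs(mean(kds) - 16), 2 * stats::sd(kds) / sqrt(30) + 0.5)
})

test_that("degenerate curves return a diagnosable failure, not a crash", {
  flat <- data.frame(concentration = DESIGN_C, response = rep(0, 8))
  fit <- fit_langmuir(flat)
  expect_false(fit$converged)
  expect_type(fit$diagnostics, "character")
  expect_error(fit_langmuir(data.frame(concentration = c(1, 1, 1),
                                       response = c(1, 2, 3))),
               "distinct")
})

test_that("relative affinities normalise to the reference", {
  rel <- relative_kd(data.frame(name = c("ds0", "ds3"), kd = c(16, 1138)),
                     "ds0")
  expect_equal(rel$k_rel[rel$name == "ds0"], 1)
  expect_equal(rel$k_rel[rel$name == "ds3"], 71.125)
  expect_equal(relative_kd(data.frame(name = "x", kd = 42), "x")$k_rel, 1)
  scaled <- relative_kd(data.frame(name = c("ds0", "ds3"),
                                   kd = 7 * c(16, 1138)), "ds0")
  expect_equal(scaled$k_rel, rel$k_rel)
  expect_error(relative_kd(data.frame(name = "a", kd = 1), "b"),
               "not present")
})

test_that("ionic strength follows the half-sum of c z^2", {
  expect_equal(ionic_strength(phosphate_solution_0.1x()), 2.52e-3)
  salt <- tibble::tibble(species = c("Na+", "Cl-"), conc = c(0.1, 0.1),
                         charge = c(1L, -1L))
  expect_equal(ionic_strength(salt), 0.1)
  expect_equal(ionic_strength(phosphate_solution_0.1x()[0, ]), 0)
  bad <- tibble::tibble(species = "X", conc = -1, charge = 1L)
  expect_error(ionic_strength(bad), ">= 0")
  unbal <- tibble::tibble(species = "Na+", conc = 0.1, charge = 1L)
  expect_warning(ionic_strength(unbal), "electroneutral")
})

test_that("the screening length matches its closed form and scaling law", {
  expect_equal(signif(debye_length(2.52e-3), 2), 6.1)
  expect_equal(debye_length(1), 0.304, tolerance = 0.005)
  expect_equal(debye_length(0.05) / debye_length(0.1), sqrt(2),
               tolerance = 1e-9)
  expect_error(debye_length(0), "positive")
  # full-strength PBS screens far harder than the 0.1x phosphate solution
  l_pbs <- debye_length(ionic_strength(pbs_1x()))
  l_ps <- debye_length(ionic_strength(phosphate_solution_0.1x()))
  expect_lt(l_pbs, 1)
  expect_lt(l_pbs, l_ps)
})

test_that("buffer YAML definitions load into buffer tables", {
  p <- system.file("extdata", "buffers.yml", package = "srnaduplex")
  bufs <- read_buffers(p)
  expect_named(bufs, c("phosphate_solution_0.1x", "pbs_1x"))
  expect_equal(ionic_strength(bufs$phosphate_solution_0.1x),
               ionic_strength(phosphate_solution_0.1x()))
})
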