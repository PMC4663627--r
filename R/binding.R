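# Langmuir-isotherm binding analytics and electrolyte screening.
#
# The sensor response to a duplex at concentration C follows the Langmuir
# adsorption isotherm  dG(C) = dG_max * C / (K_d + C): independent, identical
# binding sites at fractional occupancy C / (K_d + C).

# physical constants (SI, 2019 redefinition)
.EPS0 <- 8.8541878128e-12   # F/m
.KB <- 1.380649e-23         # J/K
.NA <- 6.02214076e23        # 1/mol
.EC <- 1.602176634e-19      # C

#' Langmuir isotherm response
#'
#' @param C Analyte concentration(s), nM, `>= 0`.
#' @param dG_max Saturated response (same units as the response, e.g. % of
#'   baseline conductance).
#' @param K_d Dissociation constant, nM, `> 0`.
#' @return `dG_max * C / (K_d + C)`; 0 at `C = 0`, `dG_max / 2` at
#'   `C = K_d`, monotone in `C` and bounded by `dG_max`.
#' @export
langmuir_response <- function(C, dG_max, K_d) {
  if (any(K_d <= 0)) stop("`K_d` must be positive", call. = FALSE)
  if (any(C < 0)) stop("`C` must be non-negative", call. = FALSE)
  dG_max * C / (K_d + C)
}

#' Fit the Langmuir isotherm to a binding curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) of response against
#' concentration. `K_d` is fitted on the log scale, which enforces positivity;
#' its standard error is mapped back by the delta method. With
#' `fix_dG_max = TRUE` (the default) the saturated response is pinned to the
#' mean observed response at `C >= saturation_threshold` and only `K_d` is
#' free; if no observation reaches the threshold the fit silently falls back
#' to a free `dG_max`.
#'
#' Starting values: `dG_max` at the maximum observed response, `K_d` at the
#' concentration whose response is nearest to half of that, so fits are
#' reproducible.
#'
#' @param curve Data frame with columns `concentration` (nM) and `response`
#'   (e.g. normalized conductance change, %). At least 3 distinct
#'   concentrations are required.
#' @param fix_dG_max Pin `dG_max` to the saturation mean (default TRUE).
#' @param saturation_threshold Concentration (nM) defining saturation
#'   (default 200).
#' @return Object of class `langmuir_fit`: list with `kd`, `kd_stderr`,
#'   `dg_max`, `dg_max_stderr` (`NA` when fixed), `dg_max_fixed`,
#'   `residual_ss`, `n_obs`, `converged`, `curve`. On numerical failure a
#'   `langmuir_fit` with `converged = FALSE` and a `diagnostics` message is
#'   returned rather than an error.
#' @examples
#' crv <- data.frame(concentration = c(1, 5, 10, 25, 50, 100, 200, 400))
#' crv$response <- langmuir_response(crv$concentration, 2, 16)
#' fit_langmuir(crv)
#' @export
fit_langmuir <- function(curve, fix_dG_max = TRUE, saturation_threshold = 200) {
  stopifnot(all(c("concentration", "response") %in% names(curve)))
  C <- as.numeric(curve$concentration)
  y <- as.numeric(curve$response)
  if (any(C < 0)) stop("concentrations must be non-negative", call. = FALSE)
  if (length(unique(C)) < 3) {
    stop("need at least 3 distinct concentrations to fit", call. = FALSE)
  }
  dat <- data.frame(C = C, y = y)
  dg0 <- max(y)
  fail <- function(msg) {
    structure(list(kd = NA_real_, kd_stderr = NA_real_, dg_max = NA_real_,
                   dg_max_stderr = NA_real_, dg_max_fixed = fix_dG_max,
                   residual_ss = NA_real_, n_obs = length(y),
                   converged = FALSE, diagnostics = msg,
                   curve = tibble::as_tibble(dat)),
              class = "langmuir_fit")
  }
  if (dg0 <= 0 || all(y == 0)) return(fail("all responses are non-positive"))
  kd0 <- C[C > 0][which.min(abs(y[C > 0] - dg0 / 2))]
  if (!length(kd0) || kd0 <= 0) kd0 <- stats::median(C[C > 0])
  fixed <- fix_dG_max && any(C >= saturation_threshold)
  res <- tryCatch({
    if (fixed) {
      dg_fix <- mean(y[C >= saturation_threshold])
      fit <- minpack.lm::nlsLM(
        y ~ dg_fix * C / (exp(lkd) + C), data = dat,
        start = list(lkd = log(kd0)),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      co <- summary(fit)$coefficients
      list(fit = fit, lkd = co["lkd", 1], lkd_se = co["lkd", 2],
           dg = dg_fix, dg_se = NA_real_)
    } else {
      fit <- minpack.lm::nlsLM(
        y ~ dg * C / (exp(lkd) + C), data = dat,
        start = list(dg = dg0, lkd = log(kd0)),
        control = minpack.lm::nls.lm.control(maxiter = 200))
      co <- summary(fit)$coefficients
      list(fit = fit, lkd = co["lkd", 1], lkd_se = co["lkd", 2],
           dg = co["dg", 1], dg_se = co["dg", 2])
    }
  }, error = function(e) e)
  if (inherits(res, "error")) return(fail(conditionMessage(res)))
  kd <- exp(res$lkd)
  structure(
    list(kd = kd, kd_stderr = kd * res$lkd_se,  # delta method
         dg_max = res$dg, dg_max_stderr = res$dg_se,
         dg_max_fixed = fixed,
         residual_ss = sum(stats::residuals(res$fit)^2),
         n_obs = length(y), converged = TRUE, diagnostics = NULL,
         curve = tibble::as_tibble(dat)),
    class = "langmuir_fit")
}

#' @export
print.langmuir_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<langmuir_fit> FAILED:", x$diagnostics, "\n")
    return(invisible(x))
  }
  cat(sprintf("<langmuir_fit> K_d = %.3g +/- %.2g nM; dG_max = %.3g%s (n = %d)\n",
              x$kd, x$kd_stderr, x$dg_max,
              if (x$dg_max_fixed) " [fixed from saturation]" else "",
              x$n_obs))
  invisible(x)
}

#' @rdname fit_langmuir
#' @param x A `langmuir_fit`.
#' @param ... Unused.
#' @export
tidy.langmuir_fit <- function(x, ...) {
  tibble::tibble(
    term = c("K_d", "dG_max"),
    estimate = c(x$kd, x$dg_max),
    std.error = c(x$kd_stderr, x$dg_max_stderr)
  )
}

#' @rdname fit_langmuir
#' @export
glance.langmuir_fit <- function(x, ...) {
  tibble::tibble(
    kd = x$kd, kd_stderr = x$kd_stderr,
    dg_max = x$dg_max, dg_max_fixed = x$dg_max_fixed,
    residual_ss = x$residual_ss, n_obs = x$n_obs, converged = x$converged
  )
}

#' Plot a fitted binding curve
#'
#' @param object A `langmuir_fit`.
#' @param ... Unused.
#' @return A ggplot: observed responses and the fitted isotherm.
#' @export
autoplot.langmuir_fit <- function(object, ...) {
  stopifnot(object$converged)
  grid <- tibble::tibble(
    C = seq(0, max(object$curve$C), length.out = 200))
  grid$y <- langmuir_response(grid$C, object$dg_max, object$kd)
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$C, y = .data$y)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "concentration (nM)",
                  y = "response",
                  title = sprintf("Langmuir fit: K_d = %.3g nM", object$kd)) +
    ggplot2::theme_minimal()
}

#' Relative affinities from a set of Langmuir fits
#'
#' Normalises each dissociation constant to a reference species:
#' `K_rel = K_d / K_d(reference)`, so the reference maps to exactly 1 and the
#' result is invariant under rescaling all `K_d` by a constant.
#'
#' @param fits Either a named list of `langmuir_fit` objects or a data frame
#'   with columns `name` and `kd`.
#' @param reference Name of the reference species.
#' @return Tibble with `name`, `kd`, `k_rel`.
#' @examples
#' relative_kd(data.frame(name = c("ds0", "ds3"), kd = c(16, 1138)), "ds0")
#' @export
relative_kd <- function(fits, reference) {
  if (is.data.frame(fits)) {
    tbl <- tibble::tibble(name = fits$name, kd = fits$kd)
  } else {
    tbl <- tibble::tibble(
      name = names(fits),
      kd = vapply(fits, function(f) f$kd, numeric(1)))
  }
  if (!reference %in% tbl$name) {
    stop("reference '", reference, "' not present", call. = FALSE)
  }
  ref_kd <- tbl$kd[tbl$name == reference][1]
  tbl$k_rel <- tbl$kd / ref_kd
  tbl$k_rel[tbl$name == reference] <- 1
  tbl
}

#' Ionic strength of a buffer
#'
#' `I = 1/2 * sum(c_i * z_i^2)` over the explicitly listed ionic species.
#' Speciation is *not* derived from pH; the caller supplies the ions. A
#' buffer far from electroneutrality triggers a warning, not an error.
#'
#' @param buffer Data frame with columns `species`, `conc` (mol/L) and
#'   `charge` (signed integer).
#' @return Ionic strength in mol/L (0 for an empty species list).
#' @examples
#' ionic_strength(phosphate_solution_0.1x())
#' @export
ionic_strength <- function(buffer) {
  stopifnot(all(c("conc", "charge") %in% names(buffer)))
  if (!nrow(buffer)) return(0)
  if (any(buffer$conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  net <- sum(buffer$conc * buffer$charge)
  scale <- sum(abs(buffer$conc * buffer$charge))
  if (scale > 0 && abs(net) > 1e-6 * max(scale, 1e-12) + 1e-9) {
    warning(sprintf("buffer is not electroneutral (net charge %.3g mol/L)",
                    net), call. = FALSE)
  }
  0.5 * sum(buffer$conc * buffer$charge^2)
}

#' Debye-Hueckel screening length
#'
#' `lambda_D = sqrt(eps_r * eps0 * kB * T / (2 * N_A * e^2 * I))`, reported
#' in nm. In water at 298 K this reduces to about `0.304 nm / sqrt(I [mol/L])`.
#'
#' @param I Ionic strength, mol/L, `> 0`.
#' @param temperature Kelvin (default 298.15).
#' @param relative_permittivity Dimensionless (default 78.5, water at 25 C).
#' @return Screening length in nm; strictly decreasing in `I`.
#' @examples
#' debye_length(ionic_strength(phosphate_solution_0.1x()))
#' @export
debye_length <- function(I, temperature = 298.15, relative_permittivity = 78.5) {
  if (any(I <= 0)) stop("`I` must be positive", call. = FALSE)
  lam_m <- sqrt(relative_permittivity * .EPS0 * .KB * temperature /
                  (2 * .NA * .EC^2 * (I * 1000)))  # I mol/L -> mol/m^3
  lam_m * 1e9
}

#' Built-in measurement buffers
#'
#' `phosphate_solution_0.1x()` is the 0.1x phosphate measurement solution
#' (240 uM NaH2PO4 + 760 uM Na2HPO4): Na+ 1.76 mM, H2PO4- 0.24 mM,
#' HPO4(2-) 0.76 mM. `pbs_1x()` is standard 1x PBS (138 mM NaCl, 2.7 mM KCl,
#' 8 mM Na2HPO4, 1.5 mM KH2PO4) expanded to its ions. Concentrations in
#' mol/L.
#'
#' @return A buffer tibble (`species`, `conc`, `charge`).
#' @export
phosphate_solution_0.1x <- function() {
  tibble::tibble(
    species = c("Na+", "H2PO4-", "HPO4(2-)"),
    conc = c(1.76e-3, 0.24e-3, 0.76e-3),
    charge = c(1L, -1L, -2L)
  )
}

#' @rdname phosphate_solution_0.1x
#' @export
pbs_1x <- function() {
  tibble::tibble(
    species = c("Na+", "K+", "Cl-", "HPO4(2-)", "H2PO4-"),
    conc = c(138e-3 + 2 * 8e-3, 2.7e-3 + 1.5e-3, 138e-3 + 2.7e-3,
             8e-3, 1.5e-3),
    charge = c(1L, 1L, -1L, -2L, -1L)
  )
}

#' Read buffer definitions from a YAML file
#'
#' Expected layout: a top-level mapping of buffer names, each a list of
#' species entries with `species`, `conc` (mol/L) and `charge`. A shipped
#' example lives at `system.file("extdata", "buffers.yml",
#' package = "srnaduplex")`.
#'
#' @param path YAML file path.
#' @return Named list of buffer tibbles.
#' @export
read_buffers <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(b) {
    tibble::tibble(
      species = vapply(b, `[[`, character(1), "species"),
      conc = vapply(b, function(s) as.numeric(s$conc), numeric(1)),
      charge = vapply(b, function(s) as.integer(s$charge), integer(1))
    )
  })
}
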