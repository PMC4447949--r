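# Equilibrium DNA-binding analysis from EMSA-style isotherms: a specific
# one-site binding model with Hill slope,
#   f(c) = bmax * c^h / (kd^h + c^h),
# simulated titrations, multi-start nonlinear least-squares fitting in
# log10(Kd) space, fold-inhibition ratios, and a two-species redox (monomer/
# dimer) mixture curve. The pipeline starts from fraction-bound tables; gel
# imaging and densitometry are out of scope.

#' Default titration grid
#'
#' Log-spaced protein concentrations covering the standard titration range.
#'
#' @param from,to concentration range (molar).
#' @param n number of points.
#' @return numeric vector (molar), increasing.
#' @export
titration_grid <- function(from = 1e-14, to = 1e-6, n = 12) {
  10^seq(log10(from), log10(to), length.out = n)
}

#' Simulate a binding isotherm
#'
#' Evaluates the one-site-with-Hill-slope model on a concentration grid and
#' adds i.i.d. Gaussian noise; seed-reproducible.
#'
#' @param kd dissociation constant (molar, > 0).
#' @param hill Hill slope.
#' @param bmax saturating bound fraction.
#' @param conc protein concentration grid (molar).
#' @param noise_sd Gaussian noise SD on fraction bound.
#' @param seed integer seed.
#' @param label isotherm label.
#' @return tibble of class `ets_isotherm`: `conc` (M), `fraction_bound`,
#'   `valid` (inside the noise-tolerant range [-0.1, 1.1]), `label`.
#' @export
simulate_isotherm <- function(kd, hill = 1, bmax = 1, conc = titration_grid(),
                              noise_sd = 0, seed = 1L, label = "simulated") {
  if (kd <= 0) abort("kd must be > 0")
  if (any(conc <= 0)) abort("concentrations must be positive")
  conc <- sort(conc)
  f <- hill_model(conc, kd, hill, bmax)
  if (noise_sd > 0) {
    set.seed(seed)
    f <- f + rnorm(length(f), sd = noise_sd)
  }
  out <- tibble::tibble(conc = conc, fraction_bound = f,
                        valid = f >= -0.1 & f <= 1.1, label = label)
  class(out) <- c("ets_isotherm", class(out))
  attr(out, "truth") <- list(kd = kd, hill = hill, bmax = bmax,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' One-site binding model with Hill slope
#' @param conc concentrations (M).
#' @param kd dissociation constant (M).
#' @param hill Hill slope.
#' @param bmax saturating fraction.
#' @return fraction bound.
#' @export
hill_model <- function(conc, kd, hill = 1, bmax = 1) {
  bmax * conc^hill / (kd^hill + conc^hill)
}

#' Fit the Hill model to an isotherm
#'
#' Nonlinear least squares (Levenberg-Marquardt) on parameters log10(Kd),
#' Hill slope and Bmax, with multi-start initialization (Kd started at every
#' decade of the concentration grid). Parameter standard errors come from the
#' Jacobian-based covariance. Flat or empty responses are flagged
#' non-binding (converged = FALSE) rather than raising an error.
#'
#' @param isotherm data frame with columns `conc` (M) and `fraction_bound`.
#' @param bounds named list with elements `hill` and `bmax`, each `c(lo, hi)`.
#' @param nonbinding_threshold top-concentration fraction bound below which
#'   the curve is declared undetectable binding.
#' @return object of class `ets_fit`: `kd`, `hill`, `bmax`, `se` (named), `rss`,
#'   `converged`, `nonbinding`, `n`, and the data.
#' @export
fit_isotherm <- function(isotherm,
                         bounds = list(hill = c(0.2, 5), bmax = c(0.05, 1.2)),
                         nonbinding_threshold = 0.05) {
  df <- tibble::as_tibble(isotherm)
  stopifnot(all(c("conc", "fraction_bound") %in% names(df)))
  df <- df[order(df$conc), ]
  n <- nrow(df)
  out <- list(kd = NA_real_, hill = NA_real_, bmax = NA_real_,
              se = c(kd = NA_real_, hill = NA_real_, bmax = NA_real_),
              rss = NA_real_, converged = FALSE, nonbinding = FALSE,
              n = n, data = df)
  class(out) <- "ets_fit"
  if (n < 5) {
    warn("fewer than 5 points; not fitting")
    return(out)
  }
  top <- mean(df$fraction_bound[df$conc >= sort(df$conc, decreasing = TRUE)[2]])
  if (is.finite(top) && top < nonbinding_threshold) {
    out$nonbinding <- TRUE
    return(out)
  }
  starts <- unique(round(log10(df$conc)))
  best <- NULL
  for (lk0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        fraction_bound ~ bmax * conc^hill / ((10^lkd)^hill + conc^hill),
        data = df,
        start = list(lkd = lk0, hill = 1, bmax = max(df$fraction_bound)),
        lower = c(lkd = log10(min(df$conc)) - 2, hill = bounds$hill[1],
                  bmax = bounds$bmax[1]),
        upper = c(lkd = log10(max(df$conc)) + 2, hill = bounds$hill[2],
                  bmax = bounds$bmax[2]),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) return(out)
  cf <- coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) c(lkd = NA, hill = NA, bmax = NA))
  kd <- 10^cf[["lkd"]]
  out$kd <- kd
  out$hill <- cf[["hill"]]
  out$bmax <- cf[["bmax"]]
  # delta-method SE for Kd from the SE of log10(Kd)
  out$se <- c(kd = unname(se["lkd"]) * log(10) * kd,
              hill = unname(se["hill"]), bmax = unname(se["bmax"]))
  out$rss <- best$rss
  out$converged <- TRUE
  out
}

#' @export
print.ets_fit <- function(x, ...) {
  if (x$nonbinding) {
    cat("<binding fit>  undetectable binding (NA)\n")
  } else if (!x$converged) {
    cat("<binding fit>  did not converge\n")
  } else {
    cat(sprintf("<binding fit>  Kd %.3g M (se %.2g), Hill %.2f, Bmax %.2f, rss %.2g, n %d\n",
                x$kd, x$se["kd"], x$hill, x$bmax, x$rss, x$n))
  }
  invisible(x)
}

#' @method tidy ets_fit
#' @export
tidy.ets_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kd", "hill", "bmax"),
    estimate = c(x$kd, x$hill, x$bmax),
    std.error = unname(x$se[c("kd", "hill", "bmax")])
  )
}

#' @method glance ets_fit
#' @export
glance.ets_fit <- function(x, ...) {
  tibble::tibble(kd = x$kd, hill = x$hill, bmax = x$bmax, rss = x$rss,
                 converged = x$converged, nonbinding = x$nonbinding, n = x$n)
}

#' Fold inhibition between two binding fits
#'
#' Ratio of the test fit's Kd to the reference (wild-type) fit's Kd -- the
#' fold increase in Kd relative to the reference.
#'
#' @param fit_test,fit_ref converged `ets_fit` objects (or bare Kd values).
#' @param label_test,label_ref labels for the report.
#' @return one-row tibble of class `ets_foldchange`: `ratio`, labels, both Kds.
#' @export
fold_inhibition <- function(fit_test, fit_ref, label_test = "test",
                            label_ref = "reference") {
  kd_of <- function(f, what) {
    if (inherits(f, "ets_fit")) {
      if (!f$converged) abort(paste0(what, " fit did not converge"))
      f$kd
    } else {
      as.numeric(f)
    }
  }
  kt <- kd_of(fit_test, "test")
  kr <- kd_of(fit_ref, "reference")
  out <- tibble::tibble(ratio = kt / kr, label_test = label_test,
                        label_ref = label_ref, kd_test = kt, kd_ref = kr)
  class(out) <- c("ets_foldchange", class(out))
  out
}

#' Two-species (monomer/dimer) binding mixture
#'
#' Additive binding curve of a monomer/dimer population mixture, weighting
#' each species' one-site curve by its fraction -- a qualitative emulation of
#' redox (glutathione) titration series in which dimer dissociation restores
#' binding.
#'
#' @param frac_dimer dimer fraction in [0, 1].
#' @param kd_monomer,kd_dimer species dissociation constants (M).
#' @param conc concentration grid (M).
#' @param hill,bmax shared Hill slope and plateau.
#' @param noise_sd,seed optional Gaussian noise.
#' @return an `ets_isotherm` tibble.
#' @export
redox_mixture_model <- function(frac_dimer, kd_monomer, kd_dimer,
                                conc = titration_grid(), hill = 1, bmax = 1,
                                noise_sd = 0, seed = 1L) {
  if (frac_dimer < 0 || frac_dimer > 1) abort("frac_dimer must be in [0, 1]")
  if (kd_monomer <= 0 || kd_dimer <= 0) abort("kds must be > 0")
  conc <- sort(conc)
  f <- (1 - frac_dimer) * hill_model(conc, kd_monomer, hill, bmax) +
    frac_dimer * hill_model(conc, kd_dimer, hill, bmax)
  if (noise_sd > 0) {
    set.seed(seed)
    f <- f + rnorm(length(f), sd = noise_sd)
  }
  out <- tibble::tibble(conc = conc, fraction_bound = f,
                        valid = f >= -0.1 & f <= 1.1,
                        label = sprintf("mixture %.0f%% dimer", 100 * frac_dimer))
  class(out) <- c("ets_isotherm", class(out))
  out
}

#' Median fold-inhibition recovery over seeded replicate simulations
#'
#' Simulates noisy isotherm pairs at two Kd values over many seeds, fits both
#' members of each pair, and reports the median ratio of fitted Kds --
#' the parameter-recovery experiment for a mutant-vs-wild-type fold change.
#'
#' @param kd_test,kd_ref generating Kds (M).
#' @param n_seeds number of replicate pairs.
#' @param noise_sd noise SD.
#' @param conc concentration grid.
#' @param hill,bmax generator parameters.
#' @param base_seed offset added to the per-replicate seeds.
#' @return list: `median_ratio`, `ratios` (per-seed), `n_converged`.
#' @export
fold_recovery <- function(kd_test, kd_ref, n_seeds = 100, noise_sd = 0.02,
                          conc = titration_grid(), hill = 1, bmax = 1,
                          base_seed = 0L) {
  ratios <- rep(NA_real_, n_seeds)
  for (s in seq_len(n_seeds)) {
    iso_t <- simulate_isotherm(kd_test, hill, bmax, conc, noise_sd,
                               seed = base_seed + 2L * s)
    iso_r <- simulate_isotherm(kd_ref, hill, bmax, conc, noise_sd,
                               seed = base_seed + 2L * s + 1L)
    ft <- fit_isotherm(iso_t)
    fr <- fit_isotherm(iso_r)
    if (ft$converged && fr$converged) ratios[s] <- ft$kd / fr$kd
  }
  list(median_ratio = median(ratios, na.rm = TRUE), ratios = ratios,
       n_converged = sum(!is.na(ratios)))
}
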