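# Hill-model isotherm simulation, fitting, and fold-inhibition statistics.

test_that("the model obeys the half-saturation identity and the asymptote", {
  for (h in c(0.7, 1, 2.3)) {
    expect_equal(hill_model(2.7e-10, kd = 2.7e-10, hill = h, bmax = 0.9),
                 0.45, tolerance = 1e-12)
  }
  expect_equal(hill_model(1e3, kd = 1e-10, hill = 1, bmax = 0.8), 0.8,
               tolerance = 1e-9)
  iso <- simulate_isotherm(1e-10, conc = c(1e-10), noise_sd = 0)
  expect_equal(iso$fraction_bound, 0.5)
})

test_that("simulated noise has the stated standard deviation", {
  f <- vapply(1:1000, function(s) {
    simulate_isotherm(1e-10, conc = 1e-8, noise_sd = 0.02,
                      seed = s)$fraction_bound
  }, numeric(1))
  expect_equal(sd(f), 0.02, tolerance = 0.1)
})

test_that("simulation is seed-reproducible and validates parameters", {
  a <- simulate_isotherm(1e-10, noise_sd = 0.05, seed = 3)
  b <- simulate_isotherm(1e-10, noise_sd = 0.05, seed = 3)
  expect_identical(a$fraction_bound, b$fraction_bound)
  expect_error(simulate_isotherm(-1e-10), "kd")
})

test_that("noiseless isotherms recover the generator Kd to better than 0.1%", {
  for (kd in c(1e-12, 2.7e-10, 5e-9, 1e-7)) {
    fit <- fit_isotherm(simulate_isotherm(kd, hill = 1, bmax = 1, noise_sd = 0))
    expect_true(fit$converged)
    expect_lt(abs(fit$kd - kd) / kd, 1e-3)
    expect_equal(fit$hill, 1, tolerance = 1e-3)
    expect_equal(fit$bmax, 1, tolerance = 1e-3)
  }
})

test_that("the optimizer is at least as good as a grid-search oracle", {
  iso <- simulate_isotherm(2.7e-10, noise_sd = 0.02, seed = 41)
  fit <- fit_isotherm(iso)
  lkd <- seq(-13, -7, length.out = 61)
  hills <- seq(0.4, 2.5, length.out = 22)
  bmaxs <- seq(0.6, 1.2, length.out = 13)
  best <- Inf
  for (h in hills) {
    ch <- outer(iso$conc^h, 10^(lkd * h), function(c_h, kd_h) c_h / (kd_h + c_h))
    for (bm in bmaxs) {
      rss <- colSums((bm * ch - iso$fraction_bound)^2)
      best <- min(best, min(rss))
    }
  }
  expect_lte(fit$rss, best + 1e-10)
})

test_that("median log-Kd recovery error stays under 0.05 at 2% noise", {
  errs <- vapply(1:100, function(s) {
    fit <- fit_isotherm(simulate_isotherm(2.7e-10, noise_sd = 0.02, seed = s))
    if (fit$converged) abs(log10(fit$kd / 2.7e-10)) else NA_real_
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.05)
})

test_that("flat responses are flagged as undetectable binding", {
  flat <- tibble::tibble(conc = titration_grid(), fraction_bound = 0.01)
  fit <- fit_isotherm(flat)
  expect_true(fit$nonbinding)
  expect_false(fit$converged)
  expect_error(fold_inhibition(fit, fit), "converge")
})

test_that("fold inhibition is the Kd ratio, identically one on self", {
  fit <- fit_isotherm(simulate_isotherm(2.7e-10, noise_sd = 0))
  expect_equal(fold_inhibition(fit, fit)$ratio, 1)
  # the printed affinity table is internally consistent: Kd ratios reproduce
  # the printed fold columns within rounding
  kd1 <- c(WT = 2.7, Y329S = 2.5, D387A = 1.7, R391A = 118, R394A = 2757,
           Y395F = 2.3, Y396F = 26390, S334E = 8.9, phosWT = 521, C416S = 4.6,
           dimer = 195, dimer_tcep = 11.2)
  fold1 <- c(WT = 1, Y329S = 0.9, D387A = 0.6, R391A = 43.7, R394A = 1021,
             Y395F = 0.9, Y396F = 9774.1, S334E = 3.3, phosWT = 193,
             C416S = 1.7, dimer = 72.2, dimer_tcep = 4.1)
  for (nm in names(kd1)) {
    r <- fold_inhibition(kd1[[nm]] * 1e-10, 2.7e-10)$ratio
    expect_lt(abs(r - fold1[[nm]]) / fold1[[nm]], 0.06) # printed-value rounding
  }
})

test_that("the redox mixture interpolates between monomer and dimer curves", {
  mono <- redox_mixture_model(0, 2.6e-10, 802e-10)
  pure <- simulate_isotherm(2.6e-10, noise_sd = 0)
  expect_equal(mono$fraction_bound, pure$fraction_bound, tolerance = 1e-12)
  dim <- redox_mixture_model(1, 2.6e-10, 802e-10)
  pure_d <- simulate_isotherm(802e-10, noise_sd = 0)
  expect_equal(dim$fraction_bound, pure_d$fraction_bound, tolerance = 1e-12)
  half <- redox_mixture_model(0.5, 2.6e-10, 802e-10)
  fit <- fit_isotherm(half)
  expect_true(fit$converged)
  expect_gt(fit$kd, 2.6e-10)
  expect_lt(fit$kd, 802e-10)
  expect_error(redox_mixture_model(1.5, 1e-10, 1e-9), "frac_dimer")
})

test_that("tidy and glance expose the fit in broom form", {
  fit <- fit_isotherm(simulate_isotherm(1e-9, noise_sd = 0))
  td <- tidy(fit)
  expect_equal(td$term, c("kd", "hill", "bmax"))
  expect_equal(td$estimate[1], fit$kd)
  gl <- glance(fit)
  expect_true(gl$converged)
})
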