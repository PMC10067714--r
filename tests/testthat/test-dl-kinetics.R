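test_that("gu_intensity identities and limits", {
  m1 <- gu_model(A = 1, B = 10, C = asinh(1))
  expect_equal(gu_intensity(0, m1), 1)  # sinh C = 1
  expect_error(gu_intensity(-1, m1), class = "biophoton_validation_error")

  # strictly decreasing and vanishing at long times
  m <- ref_model()
  tt <- seq(0, 300, by = 1)
  expect_true(all(diff(gu_intensity(tt, m)) < 0))
  expect_lt(gu_intensity(20 * m$B, m), 1e-6 * initial_intensity(m$A, m$C))
})

test_that("initial_intensity matches its closed form", {
  expect_equal(initial_intensity(0, 1), 0)
  expect_equal(initial_intensity(1, asinh(1)), 1)
  # independent high-precision arithmetic: sinh(5) = (e^5 - e^-5)/2
  sinh5 <- (exp(5) - exp(-5)) / 2
  expect_equal(initial_intensity(2.5, 5), 2.5 / sinh5^2, tolerance = 1e-12)
  expect_equal(initial_intensity(2.5, 5), 4.540405e-4, tolerance = 1e-6)
  expect_error(initial_intensity(1, 0), class = "biophoton_validation_error")
})

test_that("coherence_time matches the arcsinh identity and its limits", {
  expect_identical(coherence_time(1, 0.7, m = 1), 0)
  expect_identical(coherence_time(5, 2.3, m = 1), 0)
  # independent evaluation via logs: asinh(x) = log(x + sqrt(x^2 + 1))
  expect_equal(coherence_time(1, asinh(1), 3),
               log(3 + sqrt(10)) - log(1 + sqrt(2)), tolerance = 1e-12)
  expect_equal(coherence_time(1, asinh(1), 3), 0.93708, tolerance = 1e-5)
  expect_equal(coherence_time(2, 0.8), 2 * coherence_time(1, 0.8))
  # strictly increasing in m
  expect_true(all(diff(coherence_time(1, 0.8, m = c(1, 2, 3, 5, 10))) > 0))
  expect_error(coherence_time(1, 0.8, m = 0.5), class = "biophoton_validation_error")
})

test_that("decay law, I0 and T are mutually consistent on random models", {
  withr::local_seed(42)
  for (i in 1:100) {
    m <- random_model()
    I0 <- initial_intensity(m$A, m$C)
    Tm <- coherence_time(m$B, m$C, m$m)
    expect_equal(gu_intensity(0, m), I0, tolerance = 1e-12)
    expect_equal(gu_intensity(Tm, m), I0 / m$m^2, tolerance = 1e-9)
    # I0 strictly decreasing in C at fixed A
    expect_lt(initial_intensity(m$A, m$C * 1.1), I0)
  }
})

test_that("fit recovers exact parameters from noise-free curves", {
  truth <- ref_model()
  fit <- fit_dl_curve(noise_free_dl(truth), offset = 5)
  expect_true(fit$converged)
  expect_lt(abs(fit$model$A / truth$A - 1), 1e-4)
  expect_lt(abs(fit$model$B / truth$B - 1), 1e-4)
  expect_lt(abs(fit$model$C / truth$C - 1), 1e-4)
  # derived quantities obey the exact identities
  expect_equal(fit$I0, initial_intensity(fit$model$A, fit$model$C))
  expect_equal(fit$T, coherence_time(fit$model$B, fit$model$C, 3))
  expect_equal(gu_intensity(fit$T, fit$model), fit$I0 / 9, tolerance = 1e-9)
})

test_that("wls loss also recovers noise-free parameters", {
  truth <- ref_model()
  fit <- fit_dl_curve(noise_free_dl(truth), offset = 5, loss = "wls")
  expect_lt(abs(fit$model$B / truth$B - 1), 1e-3)
  expect_lt(abs(fit$I0 / initial_intensity(truth$A, truth$C) - 1), 1e-3)
})

test_that("flat series raises a non-decaying-signal error", {
  expect_error(fit_dl_curve(flat_series(5, 300, run_kind = "dl"), offset = 5),
               class = "biophoton_nondecaying_signal")
  expect_error(fit_dl_curve(flat_series(5, 10, run_kind = "dl"), offset = 0),
               class = "biophoton_validation_error")  # too few bins
})

test_that("scaling counts by k scales A and I0 by k, leaves B, C, T unchanged", {
  truth <- ref_model()
  mu <- expected_dl_bin_counts(truth, 5, 300, 1)
  s1 <- photon_series(round(mu), run_kind = "dl")
  s3 <- photon_series(round(mu) * 3, run_kind = "dl")
  f1 <- fit_dl_curve(s1, offset = 5)
  f3 <- fit_dl_curve(s3, offset = 15)
  expect_equal(f3$model$A / f1$model$A, 3, tolerance = 1e-3)
  expect_equal(f3$I0 / f1$I0, 3, tolerance = 1e-3)
  expect_equal(f3$model$B, f1$model$B, tolerance = 1e-3)
  expect_equal(f3$model$C, f1$model$C, tolerance = 1e-3)
  expect_equal(f3$T, f1$T, tolerance = 1e-3)
})

test_that("discarding initial bins and fitted offset are supported", {
  truth <- ref_model()
  dl <- simulate_dl_run(truth, 55, 300, seed = 9)
  f <- fit_dl_curve(dl, offset = 55, discard_initial_bins = 5)
  expect_equal(f$n_bins_used, 295)
  expect_lt(abs(f$I0 / initial_intensity(truth$A, truth$C) - 1), 0.1)
  ffree <- fit_dl_curve(dl, offset = 55, offset_mode = "fitted")
  expect_equal(ffree$offset_mode, "fitted")
  expect_lt(abs(ffree$offset / 55 - 1), 0.2)
})

test_that("grid oracle is deterministic, flags boundary optima, beats nothing", {
  dl <- simulate_dl_run(ref_model(), 55, 300, seed = 13)
  g1 <- grid_fit_oracle(dl, 55, B_grid = seq(20, 120, 10), C_grid = seq(0.3, 2, 0.1))
  g2 <- grid_fit_oracle(dl, 55, B_grid = seq(20, 120, 10), C_grid = seq(0.3, 2, 0.1))
  expect_identical(tidy(g1), tidy(g2))
  expect_false(g1$on_boundary)
  # grid excluding the truth region ends on the boundary and says so
  g3 <- grid_fit_oracle(dl, 55, B_grid = c(200, 300, 400), C_grid = c(4, 6, 8))
  expect_true(g3$on_boundary)
  expect_error(grid_fit_oracle(dl, 55, B_grid = numeric(0), C_grid = 1),
               class = "biophoton_validation_error")
})

test_that("likelihood fit is at least as good as the coarse grid oracle", {
  withr::local_seed(99)
  for (i in 1:5) {
    m <- random_model()
    dl <- simulate_dl_run(m, 30, 300, seed = 1000 + i)
    fit <- fit_dl_curve(dl, 30)
    orc <- grid_fit_oracle(dl, 30, B_grid = seq(15, 250, length.out = 20),
                           C_grid = seq(0.2, 3.5, length.out = 15))
    expect_lte(fit$loss_value, orc$loss_value)
  }
})

test_that("replicate summaries average converged fits only", {
  fake <- function(I0, T, conv = TRUE) {
    structure(list(I0 = I0, T = T, converged = conv), class = "dl_fit")
  }
  same <- summarize_replicates(list(fake(10, 50), fake(10, 50), fake(10, 50)))
  expect_equal(same$I0_mean, 10)
  expect_equal(same$I0_sd, 0)

  spread <- summarize_replicates(list(fake(10, 40), fake(12, 50), fake(14, 60)))
  expect_equal(spread$I0_mean, 12)
  expect_equal(spread$I0_sd, 2)
  expect_equal(spread$T_mean, 50)

  expect_warning(part <- summarize_replicates(list(fake(10, 40), fake(12, 50),
                                                   fake(99, 99, FALSE))),
                 "did not converge")
  expect_equal(part$I0_mean, 11)
  expect_equal(part$n_nonconverged, 1)
  expect_error(summarize_replicates(list(fake(1, 1, FALSE))),
               class = "biophoton_validation_error")
})

test_that("tidy and glance expose the fitted quantities", {
  fit <- fit_dl_curve(noise_free_dl(), offset = 5)
  td <- tidy(fit)
  expect_setequal(td$term, c("A", "B", "C", "offset", "I0", "T"))
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$loss, "poisson")
  expect_s3_class(autoplot(fit), "ggplot")
})
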