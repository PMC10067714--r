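test_that("student's t-test matches the pooled-variance closed form", {
  tt <- students_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)  # -3.674
  expect_equal(tt$df, 4)
  expect_equal(tt$p_value, 0.0213, tolerance = 1e-2)
  expect_true(tt$significant)

  # swapping groups negates t, p unchanged
  rev <- students_t_test(c(4, 5, 6), c(1, 2, 3))
  expect_equal(rev$statistic, -tt$statistic)
  expect_equal(rev$p_value, tt$p_value)

  same <- students_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  expect_error(students_t_test(c(1, 1), c(2, 2)),
               class = "biophoton_validation_error")
  expect_error(students_t_test(1, c(1, 2)), class = "biophoton_validation_error")
})

test_that("t and Pearson p-values agree with stats:: reference to 1e-10", {
  withr::local_seed(23)
  for (i in 1:50) {
    n1 <- sample(3:50, 1); n2 <- sample(3:50, 1)
    x <- rnorm(n1); y <- rnorm(n2, mean = runif(1, -1, 1))
    ours <- students_t_test(x, y)
    ref <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)

    w <- students_t_test(x, y, var_equal = FALSE)
    refw <- stats::t.test(x, y)
    expect_equal(w$p_value, refw$p.value, tolerance = 1e-10)
    expect_equal(w$df, unname(refw$parameter), tolerance = 1e-10)

    n <- sample(3:50, 1)
    a <- rnorm(n); b <- 0.5 * a + rnorm(n)
    pc <- pearson_correlation(a, b)
    refc <- stats::cor.test(a, b)
    expect_equal(pc$r, unname(refc$estimate), tolerance = 1e-10)
    expect_equal(pc$p_value, refc$p.value, tolerance = 1e-10)
  }
})

test_that("pearson correlation handles exact and degenerate cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  expect_equal(pearson_correlation(x, c(2, 1, 4, 3))$r, 0.6)
  expect_error(pearson_correlation(c(1, 2), c(1, 2)),
               class = "biophoton_validation_error")
  expect_error(pearson_correlation(x, rep(1, 4)),
               class = "biophoton_validation_error")
})

test_that("stage_trend detects a built-in decreasing trend", {
  withr::local_seed(5)
  n <- 10; stages <- 1:5
  dat <- tidyr::expand_grid(stage = stages, rep = 1:n) |>
    dplyr::mutate(I0 = 100 * 0.8^(stage - 1) * exp(rnorm(dplyr::n(), 0, 0.05)))
  tr <- stage_trend(dat, I0)
  expect_equal(tr$stage_means$stage, stages)
  expect_true(all(tr$adjacent_tests$delta < 0))
  expect_true(all(tr$adjacent_tests$significant))
  expect_equal(tr$frac_decreasing, 1)
})

test_that("stage_trend under the null rejects at roughly the nominal rate", {
  withr::local_seed(17)
  rejections <- vapply(1:200, function(i) {
    dat <- tibble::tibble(stage = rep(1:2, each = 10), y = rnorm(20))
    stage_trend(dat, y)$adjacent_tests$significant
  }, logical(1))
  expect_gt(mean(rejections), 0.005)
  expect_lt(mean(rejections), 0.12)
})

test_that("stage_trend degenerate inputs", {
  expect_error(stage_trend(tibble::tibble(stage = 1, y = 1:3), y),
               class = "biophoton_validation_error")
  singles <- tibble::tibble(stage = c(1, 2), y = c(5, 3))
  expect_warning(tr <- stage_trend(singles, y), "skipped")
  expect_equal(tr$stage_means$mean, c(5, 3))
  expect_true(is.na(tr$adjacent_tests$p_value))
})

test_that("correlation_matrix reports each pair and survives bad columns", {
  withr::local_seed(41)
  n <- 40
  z <- rnorm(n)
  dat <- tibble::tibble(
    I0 = exp(z), T = exp(-0.6 * z + rnorm(n, 0, 0.8)),
    content = exp(0.9 * z + rnorm(n, 0, 0.45)),
    const = 1
  )
  cm <- correlation_matrix(dat, c("I0", "T"), c("content", "const"))
  expect_equal(nrow(cm), 4)
  r_i0 <- cm$r[cm$biophoton == "I0" & cm$content == "content"]
  r_T <- cm$r[cm$biophoton == "T" & cm$content == "content"]
  expect_gt(r_i0, 0)
  expect_lt(r_T, 0)
  expect_false(any(cm$computable[cm$content == "const"]))
  expect_equal(attr(cm, "n_tests"), 2)

  # joint row permutation leaves r unchanged
  perm <- sample(n)
  cm2 <- correlation_matrix(dat[perm, ], "I0", "content")
  expect_equal(cm2$r, r_i0, tolerance = 1e-12)
  expect_error(correlation_matrix(dat, "nope", "content"),
               class = "biophoton_validation_error")
  expect_s3_class(plot_correlation_matrix(cm), "ggplot")
})

test_that("observed r lies in the Fisher-z band of the generating correlation", {
  withr::local_seed(77)
  n <- 40; rho <- 0.9
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  r <- pearson_correlation(x, y)$r
  expect_lt(abs(atanh(r) - atanh(rho)), 1.96 / sqrt(n - 3))
})

test_that("pharmacopoeia compliance thresholds, boundary inclusive", {
  expect_true(compliance_check(1.2, "hsya"))
  expect_false(compliance_check(0.8, "hsya"))
  expect_true(compliance_check(1.0, "hsya"))
  expect_true(compliance_check(0.05, "kaempferol"))
  expect_false(compliance_check(0.049, "kaempferol"))
  expect_equal(compliance_check(c(0.8, 1.2), "hsya"), c(FALSE, TRUE))
  # configurable thresholds
  expect_true(compliance_check(0.5, "hsya", thresholds = c(hsya = 0.4)))
})

test_that("build_report writes a re-parsable, deterministic bundle", {
  des <- cohort_design(n_per_cell = 2, spe_duration = 120,
                       background_duration = 120, dl_duration = 60)
  co <- simulate_cohort(des, seed = 2)
  ct <- cohort_table(co$session, co$content_table)
  tests <- tidy(students_t_test(ct$I0[ct$group == "healthy"],
                                ct$I0[ct$group == "poor"]))
  cors <- correlation_matrix(ct, c("cps_normalized", "I0", "T"), "content_mg_g")
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- build_report(ct, tests, cors, d1)
  expect_true(all(file.exists(p1)))
  back <- read.csv(p1[["cohort"]])
  expect_equal(nrow(back), nrow(ct))
  expect_equal(back$I0, ct$I0, tolerance = 1e-12)
  # determinism at fixed formatting
  p2 <- build_report(ct, tests, cors, d2)
  expect_identical(readLines(p1[["cohort"]]), readLines(p2[["cohort"]]))
  expect_error(build_report(ct[0, ], tests, cors, d1),
               class = "biophoton_validation_error")
})
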