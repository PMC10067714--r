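#' Two-tailed unpaired Student's t-test
#'
#' Classical equal-variance t statistic with df = n1 + n2 - 2 and a two-tailed
#' p-value from the t distribution; this is the test used for all group
#' comparisons in the analysis (Welch's correction available via
#' `var_equal = FALSE`). Significance is declared at p <= 0.05.
#'
#' Degenerate inputs: identical constant groups return t = 0, p = 1; constant
#' groups with different means have no valid t scale and raise an error.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param var_equal Pool variances (classical Student's test, default) or use
#'   the Welch approximation.
#' @param alpha Significance threshold (default 0.05).
#' @return An object of class `biophoton_ttest`: `statistic`, `df`,
#'   `p_value`, `mean_x`, `mean_y`, `significant`.
#' @export
#' @examples
#' students_t_test(c(1, 2, 3), c(4, 5, 6))
students_t_test <- function(x, y, var_equal = TRUE, alpha = 0.05) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop_validation("each group needs at least 2 observations")
  v1 <- stats::var(x); v2 <- stats::var(y)
  mx <- mean(x); my <- mean(y)
  if (v1 == 0 && v2 == 0) {
    if (mx == my) {
      return(new_ttest(0, n1 + n2 - 2, 1, mx, my, alpha))
    }
    stop_validation("zero variance in both groups with unequal means: t undefined")
  }
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (mx - my) / se
  p <- 2 * pt(-abs(tstat), df)
  new_ttest(tstat, df, p, mx, my, alpha)
}

new_ttest <- function(statistic, df, p, mx, my, alpha) {
  structure(list(statistic = statistic, df = df, p_value = p,
                 mean_x = mx, mean_y = my, significant = p <= alpha),
            class = "biophoton_ttest")
}

#' @export
print.biophoton_ttest <- function(x, ...) {
  cat(sprintf("<t-test: t = %.4g, df = %.4g, p = %.4g (%ssignificant); means %.4g vs %.4g>\n",
              x$statistic, x$df, x$p_value, if (x$significant) "" else "not ",
              x$mean_x, x$mean_y))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.biophoton_ttest <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         mean_x = x$mean_x, mean_y = x$mean_y, significant = x$significant)
}

#' Pearson product-moment correlation with two-tailed p-value
#'
#' Standard Pearson r; the p-value comes from t = r * sqrt((n-2)/(1-r^2))
#' on n - 2 degrees of freedom, two-tailed. Pairs with missing values are
#' dropped.
#'
#' @param x,y Paired numeric vectors (n >= 3 complete pairs, nonzero
#'   variance in both).
#' @param alpha Significance threshold (default 0.05).
#' @return An object of class `biophoton_cor`: `r`, `p_value`, `n`,
#'   `significant`.
#' @export
pearson_correlation <- function(x, y, alpha = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop_validation("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop_validation("zero variance: correlation undefined")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(min(r, 1), -1)
  if (abs(r) == 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), n - 2)
  }
  structure(list(r = r, p_value = p, n = n, significant = p <= alpha),
            class = "biophoton_cor")
}

#' @export
print.biophoton_cor <- function(x, ...) {
  cat(sprintf("<pearson: r = %.4g, p = %.4g, n = %d (%ssignificant)>\n",
              x$r, x$p_value, x$n, if (x$significant) "" else "not "))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.biophoton_cor <- function(x, ...) {
  tibble(r = x$r, p_value = x$p_value, n = x$n, significant = x$significant)
}

#' Growth-stage trend of a cohort variable
#'
#' Orders the stages, computes per-stage means, runs a Student's t-test
#' between each pair of consecutive stages, and summarizes the direction of
#' the trend as the fraction of adjacent stage transitions whose mean
#' decreases. Stages with a single sample contribute means but their adjacent
#' tests are skipped with a warning.
#'
#' @param data Cohort data frame with a `stage` column.
#' @param column Name of the numeric column to analyze (string or bare name).
#' @param alpha Significance threshold.
#' @return A list with `stage_means` (tibble stage/n/mean/sd),
#'   `adjacent_tests` (tibble with one row per consecutive-stage pair) and
#'   `frac_decreasing`.
#' @export
stage_trend <- function(data, column, alpha = 0.05) {
  col <- rlang::as_name(rlang::ensym(column))
  if (!col %in% names(data)) stop_validation(sprintf("column '%s' not found", col))
  if (!"stage" %in% names(data)) stop_validation("data needs a 'stage' column")
  stages <- sort(unique(data$stage))
  if (length(stages) < 2) stop_validation("need at least 2 stages for a trend")
  means <- data |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(n = sum(is.finite(.data[[col]])),
                     mean = mean(.data[[col]], na.rm = TRUE),
                     sd = sd(.data[[col]], na.rm = TRUE), .groups = "drop") |>
    dplyr::arrange(.data$stage)
  tests <- purrr::map_dfr(seq_len(length(stages) - 1), function(i) {
    a <- data[[col]][data$stage == stages[i]]
    b <- data[[col]][data$stage == stages[i + 1]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    delta <- mean(b) - mean(a)
    if (length(a) < 2 || length(b) < 2) {
      warn(sprintf("stage pair %s-%s: fewer than 2 samples per stage; test skipped",
                   stages[i], stages[i + 1]))
      return(tibble(stage_from = stages[i], stage_to = stages[i + 1],
                    delta = delta, statistic = NA_real_, df = NA_real_,
                    p_value = NA_real_, significant = NA))
    }
    tt <- students_t_test(a, b, alpha = alpha)
    tibble(stage_from = stages[i], stage_to = stages[i + 1], delta = delta,
           statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
           significant = tt$significant)
  })
  list(stage_means = means, adjacent_tests = tests,
       frac_decreasing = mean(tests$delta < 0))
}

#' All pairwise correlations between biophoton parameters and contents
#'
#' One Pearson correlation per (biophoton column, content column) pair over
#' the rows where both are present. No multiple-testing adjustment is
#' applied; raw p-values are reported together with the number of tests
#' performed (attribute `n_tests`), mirroring the convention of reporting
#' each correlation at face value. Pairs with fewer than 3 complete rows or
#' zero variance are reported as not computable rather than failing the run.
#'
#' @param data Cohort data frame.
#' @param biophoton_cols,content_cols Character vectors of column names.
#' @param alpha Significance threshold.
#' @return A tibble: `biophoton`, `content`, `r`, `p_value`, `n`,
#'   `significant`, `computable`.
#' @export
correlation_matrix <- function(data, biophoton_cols, content_cols, alpha = 0.05) {
  missing_cols <- setdiff(c(biophoton_cols, content_cols), names(data))
  if (length(missing_cols) > 0) {
    stop_validation(sprintf("columns not found: %s", paste(missing_cols, collapse = ", ")))
  }
  grid <- tidyr::expand_grid(biophoton = biophoton_cols, content = content_cols)
  out <- purrr::pmap_dfr(grid, function(biophoton, content) {
    x <- data[[biophoton]]; y <- data[[content]]
    res <- tryCatch(pearson_correlation(x, y, alpha = alpha), error = function(e) NULL)
    if (is.null(res)) {
      tibble(biophoton = biophoton, content = content, r = NA_real_,
             p_value = NA_real_, n = sum(is.finite(x) & is.finite(y)),
             significant = NA, computable = FALSE)
    } else {
      tibble(biophoton = biophoton, content = content, r = res$r,
             p_value = res$p_value, n = res$n, significant = res$significant,
             computable = TRUE)
    }
  })
  attr(out, "n_tests") <- sum(out$computable)
  out
}

#' Plot a biophoton-vs-content correlation matrix
#'
#' @param object Result of [correlation_matrix()].
#' @param ... Unused.
#' @return A ggplot tile map of r with significance marks.
#' @export
plot_correlation_matrix <- function(object, ...) {
  ggplot(object, aes(x = .data$content, y = .data$biophoton, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(aes(label = ifelse(is.na(.data$r), "n/a",
                                          sprintf("%.2f%s", .data$r,
                                                  ifelse(.data$significant, "*", ""))))) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "blue", high = "red") +
    labs(x = NULL, y = NULL, fill = "Pearson r")
}

#' Pharmacopoeia compliance check for marker metabolites
#'
#' Pass/fail against the minimum-content criteria for safflower markers:
#' hydroxysafflor yellow A (HSYA) >= 1% and kaempferol >= 0.05% of dry mass.
#' The boundary is inclusive. Thresholds are configurable.
#'
#' @param content_value Content in percent (vectorized).
#' @param analyte `"hsya"` or `"kaempferol"`.
#' @param thresholds Named numeric vector of minimum contents in percent.
#' @return Logical: meets the criterion.
#' @export
#' @examples
#' compliance_check(1.2, "hsya")        # TRUE
#' compliance_check(0.8, "hsya")        # FALSE
compliance_check <- function(content_value,
                             analyte = c("hsya", "kaempferol"),
                             thresholds = c(hsya = 1.0, kaempferol = 0.05)) {
  analyte <- match.arg(tolower(analyte), c("hsya", "kaempferol"))
  content_value >= thresholds[[analyte]]
}

#' Assemble a per-sample cohort table from a measurement session
#'
#' Runs the full biophoton pipeline on every sample of a session: pools the
#' background runs, computes normalized CPS, fits the Gu model to each DL
#' replicate with the measured floor (background + sample SPE rate) held
#' fixed, and averages I0 and T over converged replicates. Content and/or
#' absorbance-derived pigment columns are joined by `sample_id` when
#' supplied.
#'
#' @param session A [measurement_session()].
#' @param content_table Optional data frame with `sample_id` plus content
#'   columns, joined by `sample_id`.
#' @param ... Passed to [fit_dl_curve()] (e.g. `loss`, `discard_initial_bins`).
#' @return A tibble with one row per sample: `sample_id`, `species`, `group`,
#'   `stage`, `cps_raw`, `cps_normalized`, `I0`, `I0_sd`, `T`, `T_sd`,
#'   `n_converged`, plus joined columns.
#' @export
cohort_table <- function(session, content_table = NULL, ...) {
  stopifnot(inherits(session, "measurement_session"))
  rows <- purrr::map_dfr(session$samples, function(s) {
    bgs <- c(list(s$background_pre),
             if (!is.null(s$background_post)) list(s$background_post))
    spe <- compute_cps(s$spe_run, bgs, fresh_mass = s$fresh_mass,
                       thickness = s$thickness)
    offset <- spe$n + max(spe$cps_raw, 0)
    fits <- lapply(s$dl_runs, fit_dl_curve, offset = offset, ...)
    agg <- summarize_replicates(fits)
    tibble(sample_id = s$sample_id, species = s$species, group = s$group,
           stage = s$stage, fresh_mass = s$fresh_mass,
           cps_raw = spe$cps_raw, cps_normalized = spe$cps_normalized,
           I0 = normalize_metric(agg$I0_mean, s$fresh_mass, s$thickness),
           I0_sd = agg$I0_sd, T = agg$T_mean, T_sd = agg$T_sd,
           n_converged = agg$n_converged)
  })
  if (!is.null(content_table)) {
    rows <- dplyr::left_join(rows, as_tibble(content_table), by = "sample_id")
  }
  rows
}

#' Write the report bundle of a cohort analysis
#'
#' Writes `cohort.csv`, `tests.csv`, `correlations.csv` and a human-readable
#' `summary.txt` into `dir`. Numeric formatting is fixed (15 significant
#' digits) so repeated runs with the same inputs produce identical files.
#'
#' @param cohort Cohort tibble (e.g. from [cohort_table()]); must be
#'   non-empty.
#' @param tests Data frame of group-comparison results.
#' @param correlations Data frame from [correlation_matrix()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written, invisibly.
#' @export
build_report <- function(cohort, tests, correlations, dir) {
  if (is.null(cohort) || nrow(cohort) == 0) {
    stop_validation("empty cohort: nothing to report; run cohort_table() on a session with samples")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    df[] <- lapply(df, function(col) {
      if (is.numeric(col)) sprintf("%.15g", col) else col
    })
    df
  }
  paths <- c(cohort = file.path(dir, "cohort.csv"),
             tests = file.path(dir, "tests.csv"),
             correlations = file.path(dir, "correlations.csv"),
             summary = file.path(dir, "summary.txt"))
  write.csv(fmt(as.data.frame(cohort)), paths["cohort"], row.names = FALSE)
  write.csv(fmt(as.data.frame(tests)), paths["tests"], row.names = FALSE)
  write.csv(fmt(as.data.frame(correlations)), paths["correlations"], row.names = FALSE)
  n_sig <- if ("significant" %in% names(correlations)) {
    sum(correlations$significant, na.rm = TRUE)
  } else NA_integer_
  writeLines(c(
    sprintf("Cohort: %d samples, %d groups, %d stages", nrow(cohort),
            length(unique(cohort$group)), length(unique(cohort$stage))),
    sprintf("Group tests reported: %d", nrow(tests)),
    sprintf("Correlations reported: %d (%s significant at p <= 0.05, unadjusted)",
            nrow(correlations), n_sig),
    "Conventions: equal-variance Student's t; Pearson r; raw p-values (no multiplicity adjustment);",
    "DL offset fixed at measured background + SPE rate; normalization mode recorded per sample."
  ), paths["summary"])
  invisible(paths)
}
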