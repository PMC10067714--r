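#' Mean photon rate of a series
#'
#' Total counts divided by total duration: the average number of photons per
#' second over the run.
#'
#' @param series A [photon_series()].
#' @return Mean rate in counts/s.
#' @export
#' @examples
#' mean_rate(photon_series(c(10, 10, 10)))  # 10
mean_rate <- function(series) {
  stopifnot(inherits(series, "photon_series"))
  if (nrow(series) == 0L) stop_validation("empty series")
  sum(series$counts) / run_duration(series)
}

#' Background-corrected spontaneous photon emission rate (CPS)
#'
#' CPS = N - n, where N is the mean sample count rate during the SPE run and
#' n the mean instrument dark rate pooled over the supplied background runs
#' (duration-weighted, i.e. total background counts over total background
#' time). A negative CPS is retained — instrument noise can exceed a weak
#' signal — and flagged with a warning rather than clipped, since clipping
#' would bias group means.
#'
#' When `fresh_mass` is supplied the rate is also size-normalized via
#' [normalize_metric()]: by mass x thickness when `thickness` is given
#' (leaves), by mass alone otherwise (near-spherical flowers).
#'
#' @param spe_run SPE [photon_series()].
#' @param background_runs One background [photon_series()] or a list of 1–2
#'   (pre- and post-measurement).
#' @param fresh_mass Optional fresh mass in grams for normalization.
#' @param thickness Optional thickness in millimetres.
#' @return An object of class `spe_result` with fields `N`, `n`, `cps_raw`,
#'   and, when normalized, `cps_normalized` and `normalization_mode`.
#' @export
compute_cps <- function(spe_run, background_runs, fresh_mass = NULL, thickness = NULL) {
  if (inherits(background_runs, "photon_series")) background_runs <- list(background_runs)
  if (length(background_runs) < 1L) stop_validation("at least one background run is required")
  bw <- c(attr(spe_run, "bin_width"),
          vapply(background_runs, attr, numeric(1), "bin_width"))
  if (length(unique(bw)) != 1L) stop_validation("runs must share bin_width")
  N <- mean_rate(spe_run)
  n <- sum(vapply(background_runs, function(b) sum(b$counts), numeric(1))) /
    sum(vapply(background_runs, run_duration, numeric(1)))
  cps_raw <- N - n
  if (cps_raw < 0) {
    warn(sprintf("negative CPS (%.4g): background exceeds sample rate; retained unclipped",
                 cps_raw))
  }
  out <- list(N = N, n = n, cps_raw = cps_raw,
              cps_normalized = NULL, normalization_mode = NULL,
              n_background_runs = length(background_runs))
  if (!is.null(fresh_mass)) {
    out$cps_normalized <- normalize_metric(cps_raw, fresh_mass, thickness)
    out$normalization_mode <- if (is.null(thickness)) "mass" else "mass_thickness"
  }
  structure(out, class = "spe_result")
}

#' @export
print.spe_result <- function(x, ...) {
  cat(sprintf("<spe_result: N = %.4g, n = %.4g, CPS = %.4g counts/s%s>\n",
              x$N, x$n, x$cps_raw,
              if (is.null(x$cps_normalized)) "" else
                sprintf(", normalized = %.4g (%s)", x$cps_normalized,
                        x$normalization_mode)))
  invisible(x)
}

#' Size-normalize a biophoton metric
#'
#' Divides by fresh mass x thickness when thickness is supplied (one scalar
#' density per sample), or by fresh mass alone when it is absent.
#'
#' @param value Metric value (e.g. CPS or I0 in counts/s).
#' @param fresh_mass Fresh mass in grams (> 0).
#' @param thickness Thickness in millimetres (> 0) or `NULL`.
#' @return Normalized value.
#' @export
#' @examples
#' normalize_metric(90, 2)        # 45: mass only
#' normalize_metric(90, 2, 0.3)   # 150: mass x thickness
normalize_metric <- function(value, fresh_mass, thickness = NULL) {
  check_scalar_positive(fresh_mass, "fresh_mass")
  divisor <- fresh_mass
  if (!is.null(thickness)) {
    check_scalar_positive(thickness, "thickness")
    divisor <- fresh_mass * thickness
  }
  value / divisor
}

#' @rdname tidiers
#' @export
tidy.spe_result <- function(x, ...) {
  tibble(N = x$N, n = x$n, cps_raw = x$cps_raw,
         cps_normalized = x$cps_normalized %||% NA_real_,
         normalization_mode = x$normalization_mode %||% NA_character_,
         n_background_runs = x$n_background_runs)
}
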