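#' Construct a binned photon-count time series
#'
#' A `photon_series` is a tibble with columns `time` (bin start, seconds from
#' run start) and `counts` (non-negative integer photon counts per bin), plus
#' attributes recording the bin width, the kind of run, and — for
#' delayed-luminescence (DL) runs — the time origin relative to the end of
#' excitation.
#'
#' Measurement protocol context: a typical session records instrument
#' background for 10 min, steady-state spontaneous photon emission (SPE) for
#' 10 min, then delayed luminescence for 5 min after a 15-s white-light
#' excitation, all binned at 1 s.
#'
#' @param counts Non-negative integer counts, one per bin.
#' @param bin_width Bin width in seconds (default 1).
#' @param run_kind One of `"background"`, `"spe"`, `"dl"`.
#' @param t_origin For DL runs only: seconds between the end of excitation and
#'   the start of the first bin (default 0, i.e. counting starts immediately).
#'   Must be `NULL` for background and SPE runs.
#' @param bin_starts Optional explicit bin-start times; must form a uniform
#'   grid with spacing `bin_width`. Defaults to `0, bin_width, 2*bin_width, ...`
#'
#' @return A tibble of class `photon_series` with columns `time` and `counts`.
#' @export
#' @examples
#' photon_series(c(5, 7, 6), bin_width = 1, run_kind = "background")
photon_series <- function(counts, bin_width = 1, run_kind = c("background", "spe", "dl"),
                          t_origin = NULL, bin_starts = NULL) {
  run_kind <- match.arg(run_kind)
  if (length(counts) < 1L) stop_validation("a photon series needs at least one bin")
  check_scalar_positive(bin_width, "bin_width")
  counts <- as.numeric(counts)
  if (anyNA(counts) || any(counts < 0) || any(!is_whole(counts))) {
    stop_validation("counts must be non-negative integers")
  }
  counts <- round(counts)
  if (is.null(bin_starts)) {
    bin_starts <- (seq_along(counts) - 1) * bin_width
  } else {
    if (length(bin_starts) != length(counts)) {
      stop_validation("bin_starts and counts must have equal length")
    }
    if (length(bin_starts) > 1L) {
      steps <- diff(bin_starts)
      if (any(steps <= 0) || any(abs(steps - bin_width) > 1e-6)) {
        stop_validation("bin_starts must increase uniformly by bin_width (tolerance 1e-6 s)")
      }
    }
  }
  if (run_kind == "dl") {
    if (is.null(t_origin)) t_origin <- 0
    if (!is_scalar_number(t_origin) || t_origin < 0) {
      stop_validation("t_origin must be a single number >= 0 for dl runs")
    }
  } else if (!is.null(t_origin)) {
    stop_validation("t_origin applies only to dl runs")
  }
  out <- tibble(time = as.numeric(bin_starts), counts = counts)
  class(out) <- c("photon_series", class(out))
  attr(out, "bin_width") <- bin_width
  attr(out, "run_kind") <- run_kind
  attr(out, "t_origin") <- if (run_kind == "dl") t_origin else NULL
  out
}

#' @export
print.photon_series <- function(x, ...) {
  cat(sprintf("<photon_series: %s, %d bins x %g s, %d total counts>\n",
              attr(x, "run_kind"), nrow(x), attr(x, "bin_width"), sum(x$counts)))
  NextMethod()
}

run_duration <- function(series) nrow(series) * attr(series, "bin_width")

#' Read a photon-count time series from a delimited text file
#'
#' Accepts the two dialects photon-counter software commonly exports:
#' a single column of counts, or two columns (bin start time in seconds,
#' counts). The delimiter is auto-detected among tab and comma; lines starting
#' with `#` are comments. Headerless.
#'
#' @param path Path to the counts file.
#' @inheritParams photon_series
#' @return A [photon_series()].
#' @export
read_photon_series <- function(path, run_kind = c("background", "spe", "dl"),
                               bin_width = 1, t_origin = NULL) {
  run_kind <- match.arg(run_kind)
  if (!file.exists(path)) stop_io(sprintf("counts file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- lines[keep]
  line_no <- which(keep)
  if (length(body) == 0L) stop_parse(sprintf("no data rows in %s", path))
  delim <- if (any(grepl(",", body))) "," else "\t"
  fields <- strsplit(body, delim, fixed = TRUE)
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1L || !ncol %in% c(1L, 2L)) {
    bad <- line_no[which(lengths(fields) != lengths(fields)[1])[1]]
    stop_parse(sprintf("inconsistent column count in %s (line %d)", path, bad))
  }
  mat <- suppressWarnings(vapply(fields, function(f) as.numeric(trimws(f)), numeric(ncol)))
  mat <- matrix(mat, nrow = ncol)
  bad <- which(colSums(is.na(mat)) > 0)
  if (length(bad) > 0) {
    stop_parse(sprintf("malformed row in %s (line %d): %s",
                       path, line_no[bad[1]], body[bad[1]]))
  }
  if (ncol == 1L) {
    photon_series(mat[1, ], bin_width = bin_width, run_kind = run_kind, t_origin = t_origin)
  } else {
    photon_series(mat[2, ], bin_width = bin_width, run_kind = run_kind,
                  t_origin = t_origin, bin_starts = mat[1, ])
  }
}

#' Write a photon series to a headerless TSV file
#'
#' @param series A [photon_series()].
#' @param path Output path.
#' @param time_column Write the leading time column? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_photon_series <- function(series, path, time_column = TRUE) {
  stopifnot(inherits(series, "photon_series"))
  if (time_column) {
    lines <- sprintf("%.10g\t%d", series$time, as.integer(series$counts))
  } else {
    lines <- sprintf("%d", as.integer(series$counts))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Bundle the runs and metadata of one physical sample
#'
#' @param sample_id Unique sample identifier.
#' @param species Species label (e.g. `"motherwort"`, `"safflower"`).
#' @param group Treatment/state label (e.g. `"CG"`, `"healthy"`).
#' @param stage Positive integer growth stage.
#' @param fresh_mass Fresh mass in grams (> 0).
#' @param thickness Leaf thickness in millimetres (> 0), or `NULL` when not
#'   applicable (e.g. flowers, which are normalized by mass alone).
#' @param spe_run SPE [photon_series()].
#' @param dl_runs List of 1–3 DL [photon_series()] replicates.
#' @param background_pre,background_post Background [photon_series()];
#'   `background_post` may be `NULL`.
#' @return An object of class `sample_record`.
#' @export
sample_record <- function(sample_id, species, group, stage, fresh_mass,
                          thickness = NULL, spe_run, dl_runs,
                          background_pre, background_post = NULL) {
  check_scalar_positive(fresh_mass, "fresh_mass")
  if (!is.null(thickness)) check_scalar_positive(thickness, "thickness")
  if (!is_scalar_number(stage) || stage < 1 || !is_whole(stage)) {
    stop_validation("stage must be a positive integer")
  }
  if (inherits(dl_runs, "photon_series")) dl_runs <- list(dl_runs)
  if (length(dl_runs) < 1L) stop_validation("at least one dl run is required")
  runs <- c(list(spe_run, background_pre), dl_runs,
            if (!is.null(background_post)) list(background_post))
  for (r in runs) stopifnot(inherits(r, "photon_series"))
  bw <- vapply(runs, attr, numeric(1), "bin_width")
  if (length(unique(bw)) != 1L) {
    stop_validation(sprintf("all runs of sample '%s' must share bin_width", sample_id))
  }
  structure(
    list(sample_id = as.character(sample_id), species = species, group = group,
         stage = as.integer(stage), fresh_mass = fresh_mass, thickness = thickness,
         spe_run = spe_run, dl_runs = dl_runs,
         background_pre = background_pre, background_post = background_post),
    class = "sample_record"
  )
}

#' @export
print.sample_record <- function(x, ...) {
  cat(sprintf("<sample_record %s: %s/%s stage %d, %.3g g%s, %d DL runs>\n",
              x$sample_id, x$species, x$group, x$stage, x$fresh_mass,
              if (is.null(x$thickness)) "" else sprintf(" x %.3g mm", x$thickness),
              length(x$dl_runs)))
  invisible(x)
}

#' Construct a measurement session
#'
#' @param samples List of [sample_record()] objects with unique `sample_id`s.
#' @param session_id Session identifier.
#' @param metadata Free-form named list (instrument, protocol parameters, ...).
#' @return An object of class `measurement_session`.
#' @export
measurement_session <- function(samples, session_id = "session", metadata = list()) {
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) {
    stop_validation(sprintf("duplicate sample_id in session: %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  structure(list(session_id = session_id, samples = samples, metadata = metadata),
            class = "measurement_session")
}

#' @export
print.measurement_session <- function(x, ...) {
  cat(sprintf("<measurement_session %s: %d samples>\n", x$session_id, length(x$samples)))
  invisible(x)
}

#' Read a study manifest and all referenced count files
#'
#' The manifest is a YAML file with keys `session_id` and `samples`, each
#' sample carrying `sample_id`, `species`, `group`, `stage`, `fresh_mass_g`,
#' optional `thickness_mm`, and file paths (relative to the manifest) `spe`,
#' `dl` (list), `background_pre`, optional `background_post`. An optional
#' top-level `bin_width` (seconds, default 1) applies to all runs.
#'
#' @param path Path to the manifest file.
#' @return A [measurement_session()].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("manifest not found: %s", path))
  man <- yaml::read_yaml(path)
  base <- dirname(path)
  bw <- man$bin_width %||% 1
  resolve <- function(p, sid) {
    fp <- file.path(base, p)
    if (!file.exists(fp)) {
      stop_io(sprintf("sample '%s': referenced file not found: %s", sid, p))
    }
    fp
  }
  samples <- lapply(man$samples, function(s) {
    sid <- s$sample_id
    spe <- read_photon_series(resolve(s$spe, sid), "spe", bin_width = bw)
    dl <- lapply(s$dl, function(p) read_photon_series(resolve(p, sid), "dl", bin_width = bw))
    bg_pre <- read_photon_series(resolve(s$background_pre, sid), "background", bin_width = bw)
    bg_post <- if (!is.null(s$background_post)) {
      read_photon_series(resolve(s$background_post, sid), "background", bin_width = bw)
    }
    sample_record(sid, s$species, s$group, s$stage, s$fresh_mass_g,
                  thickness = s$thickness_mm, spe_run = spe, dl_runs = dl,
                  background_pre = bg_pre, background_post = bg_post)
  })
  measurement_session(samples, session_id = man$session_id %||% "session",
                      metadata = man$metadata %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check a session against the measurement protocol
#'
#' Advisory checks against the reference protocol (10-min SPE, 5-min DL,
#' three DL repeats, background before and after the sample). Deviations are
#' reported as findings, never as errors.
#'
#' @param session A [measurement_session()].
#' @return A tibble with columns `sample_id`, `check`, `message`; zero rows
#'   when the session is fully protocol-conforming.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "measurement_session"))
  findings <- purrr::map_dfr(session$samples, function(s) {
    f <- list()
    if (run_duration(s$spe_run) < 600) {
      f <- c(f, list(c("spe_duration",
                       sprintf("SPE run is %g s < 600 s", run_duration(s$spe_run)))))
    }
    for (d in s$dl_runs) {
      if (run_duration(d) < 300) {
        f <- c(f, list(c("dl_duration",
                         sprintf("DL run is %g s < 300 s", run_duration(d)))))
      }
    }
    if (length(s$dl_runs) < 3) {
      f <- c(f, list(c("dl_repeats",
                       sprintf("dl repeats = %d < 3", length(s$dl_runs)))))
    }
    if (is.null(s$background_post)) {
      f <- c(f, list(c("background_post", "missing post-measurement background run")))
    }
    if (length(f) == 0) return(tibble(sample_id = character(), check = character(),
                                      message = character()))
    tibble(sample_id = s$sample_id,
           check = vapply(f, `[`, character(1), 1),
           message = vapply(f, `[`, character(1), 2))
  })
  findings
}

#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_point geom_line labs
#' @export
ggplot2::autoplot

#' Plot a photon-count time series
#'
#' @param object A [photon_series()].
#' @param ... Unused.
#' @return A ggplot object: counts per bin against time.
#' @export
autoplot.photon_series <- function(object, ...) {
  ggplot(object, aes(x = .data$time, y = .data$counts)) +
    geom_step() +
    labs(x = "time (s)", y = sprintf("counts per %g s bin", attr(object, "bin_width")),
         title = sprintf("%s run", attr(object, "run_kind")))
}
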