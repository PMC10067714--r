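#' Pigment concentrations from three-wavelength absorbance
#'
#' Spectrophotometric quantification of chlorophyll a, chlorophyll b, total
#' chlorophyll and total carotenoids from absorbance readings at 665, 642 and
#' 474 nm of an alcohol/acetone leaf extract:
#'
#'   Ca  = 9.99 * A665 - 0.0872 * A642
#'   Cb  = 17.7 * A642 - 3.04  * A665
#'   Cab = Ca + Cb
#'   Cc  = 4.92 * A474 - 0.0255 * Ca - 0.225 * Cb
#'
#' all in mg/L, and per-gram content M = C * V / g (mg/g) for extract volume
#' V (litres) and sample mass g (grams). All functions are vectorized.
#'
#' @param a665,a642,a474 Absorbance readings (>= 0).
#' @return Concentration in mg/L.
#' @name pigments
NULL

#' @rdname pigments
#' @export
#' @examples
#' chlorophyll_a(1, 0)  # 9.99
chlorophyll_a <- function(a665, a642) {
  9.99 * a665 - 0.0872 * a642
}

#' @rdname pigments
#' @export
chlorophyll_b <- function(a642, a665) {
  17.7 * a642 - 3.04 * a665
}

#' @rdname pigments
#' @param ca,cb Chlorophyll a and b concentrations in mg/L.
#' @export
carotenoids <- function(a474, ca, cb) {
  4.92 * a474 - 0.0255 * ca - 0.225 * cb
}

#' Per-gram pigment content
#'
#' @param conc Concentration in mg/L.
#' @param volume_l Extract volume in litres (> 0); the reference protocol
#'   uses 15 mL.
#' @param mass_g Sample mass in grams (> 0); the reference protocol weighs
#'   0.1000 g.
#' @return Content in mg/g.
#' @export
#' @examples
#' pigment_content(10, 0.015, 0.1)  # 1.5 mg/g
pigment_content <- function(conc, volume_l, mass_g) {
  if (any(volume_l <= 0)) stop_validation("volume_l must be > 0")
  if (any(mass_g <= 0)) stop_validation("mass_g must be > 0")
  conc * volume_l / mass_g
}

#' Full pigment panel for a table of absorbance readings
#'
#' Data-frame-first: takes a table with one row per extract and columns
#' `a474`, `a642`, `a665`, `volume_l`, `mass_g` (other columns, e.g.
#' `sample_id`, pass through) and appends concentrations (`ca`, `cb`, `cab`,
#' `cc`, mg/L), contents (`m_a`, `m_b`, `m_ab`, `m_c`, mg/g) and
#' `negative_flag`. The linear formulas can produce negative concentrations
#' at extreme absorbance ratios; these are flagged, never clipped, since
#' silent clipping would distort downstream correlations.
#'
#' @param data A data frame of absorbance triplets.
#' @return A tibble: `data` plus the panel columns.
#' @export
pigment_panel <- function(data) {
  need <- c("a474", "a642", "a665", "volume_l", "mass_g")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    stop_validation(sprintf("pigment_panel needs columns: %s",
                            paste(missing_cols, collapse = ", ")))
  }
  if (any(data$a474 < 0 | data$a642 < 0 | data$a665 < 0, na.rm = TRUE)) {
    stop_validation("absorbances must be >= 0")
  }
  if (any(data$volume_l <= 0) || any(data$mass_g <= 0)) {
    stop_validation("volume_l and mass_g must be > 0")
  }
  out <- as_tibble(data)
  out <- dplyr::mutate(
    out,
    ca = chlorophyll_a(.data$a665, .data$a642),
    cb = chlorophyll_b(.data$a642, .data$a665),
    cab = .data$ca + .data$cb,
    cc = carotenoids(.data$a474, .data$ca, .data$cb),
    m_a = pigment_content(.data$ca, .data$volume_l, .data$mass_g),
    m_b = pigment_content(.data$cb, .data$volume_l, .data$mass_g),
    m_ab = pigment_content(.data$cab, .data$volume_l, .data$mass_g),
    m_c = pigment_content(.data$cc, .data$volume_l, .data$mass_g),
    negative_flag = .data$ca < 0 | .data$cb < 0 | .data$cc < 0
  )
  out
}

#' Read an absorbance table from CSV
#'
#' Expected columns: `sample_id`, `a474`, `a642`, `a665`, `volume_l`,
#' `mass_g` (case-insensitive; `A474` etc. also accepted).
#'
#' @param path CSV path.
#' @return A tibble ready for [pigment_panel()].
#' @export
read_absorbance_table <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("absorbance table not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  as_tibble(df)
}
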