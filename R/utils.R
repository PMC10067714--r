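#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom stats optim pt sd setNames rpois runif rnorm cor complete.cases
#' @importFrom utils write.csv read.csv
NULL

# Internal: stop with a classed condition so callers can distinguish
# parse / validation / io failures programmatically.
stop_parse <- function(msg) abort(msg, class = "biophoton_parse_error")
stop_validation <- function(msg) abort(msg, class = "biophoton_validation_error")
stop_io <- function(msg) abort(msg, class = "biophoton_io_error")

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_scalar_positive <- function(x, name) {
  if (!is_scalar_number(x) || x <= 0) {
    stop_validation(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}

# Near-integer check tolerant of text round-trips.
is_whole <- function(x, tol = 1e-9) {
  abs(x - round(x)) <= tol
}
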