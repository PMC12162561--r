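LAG_COLS <- paste0("lag", 0:9)

#' @noRd
stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

#' Population variance (divisor n), used so that R^2 = 1 - MSE/var(y) holds
#' exactly for in-sample fits.
#' @noRd
pop_var <- function(x) mean((x - mean(x))^2)

#' Derive independent sub-stream seeds from one global seed.
#'
#' Keeps every derived seed strictly below 2^31 so it is a valid R integer.
#' @noRd
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

#' Extract the 10-column lag matrix from a panel, in lag0..lag9 order.
#' @noRd
lag_matrix <- function(panel) {
  as.matrix(panel[, LAG_COLS, drop = FALSE])
}

#' Align an incidence series to a panel by (region_id, year).
#'
#' Returns the incidence vector in the panel's row order, or fails if the key
#' sets differ.
#' @noRd
align_incidence <- function(panel, incidence) {
  pk <- paste(panel$region_id, panel$year, sep = "\r")
  ik <- paste(incidence$region_id, incidence$year, sep = "\r")
  stop_if(anyDuplicated(pk) > 0, "duplicate (region_id, year) keys in panel")
  stop_if(anyDuplicated(ik) > 0, "duplicate (region_id, year) keys in incidence")
  stop_if(!setequal(pk, ik),
          "panel and incidence keys are misaligned: ",
          sum(!pk %in% ik) + sum(!ik %in% pk), " non-matching (region_id, year) pairs")
  incidence$incidence[match(pk, ik)]
}

#' Timestamped message to stderr; never written into reports.
#' @noRd
log_msg <- function(...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
}
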