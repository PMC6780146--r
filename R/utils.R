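#' Round half away from zero
#'
#' Report-time rounding used for all printed ratios. Unlike [base::round()],
#' which rounds half to even, exact halves move away from zero, matching the
#' convention of published summary tables (e.g. a mapping rate of 0.61585
#' prints as 0.6159).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 4).
#' @return Numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' report_round(2.36675, 4) # 2.3668
#' report_round(-0.00005, 4) # -0.0001
report_round <- function(x, digits = 4) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

is_canonical <- function(seqs) {
  !stringr::str_detect(seqs, paste0("[^", AA_CANONICAL, "]")) & nchar(seqs) > 0
}

stop_io <- function(msg) abort(msg, class = "ahtpscan_error_io")
stop_format <- function(msg) abort(msg, class = "ahtpscan_error_format")
stop_integrity <- function(msg) abort(msg, class = "ahtpscan_error_integrity")
stop_argument <- function(msg) abort(msg, class = "ahtpscan_error_argument")

# One structured log line per pipeline stage; suppress with
# options(ahtpscan.quiet = TRUE).
log_stage <- function(stage, ...) {
  if (isTRUE(getOption("ahtpscan.quiet", FALSE))) return(invisible(NULL))
  kv <- c(...)
  msg <- paste0("[ahtpscan] stage=", stage)
  if (length(kv)) {
    msg <- paste(msg, paste(names(kv), unname(kv), sep = "=", collapse = " "))
  }
  inform(msg)
}
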