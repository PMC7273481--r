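# Internal helpers shared across modules.

#' Round a percentage half-up to one decimal place
#'
#' Plain half-up rounding (0.05 always rounds away from zero), as opposed to
#' the IEEE half-even rule used by [base::round()]. All percentages the
#' package prints go through this one function so that formatting is uniform.
#'
#' @param x numeric vector of percentages (0-100 scale).
#' @return numeric vector rounded to one decimal.
#' @keywords internal
percent_1dp <- function(x) {
  # add a tiny epsilon so values such as 91.65 stored as 91.649999... still
  # round up; safe because inputs are ratios of small integer counts
  floor(x * 10 + 0.5 + 1e-9) / 10
}

#' Structured log emitter
#'
#' Pipeline stages report per-case decisions ("case_id, step, decision") and
#' recoverable anomalies through this function. Silent unless
#' `options(ihcmine.verbose = TRUE)`, so corpus-scale runs stay quiet by
#' default; tests capture the lines with [testthat::expect_message()].
#'
#' @param level one of "info", "warn".
#' @param ... message parts, pasted with spaces.
#' @param case_id optional case identifier prepended to the line.
#' @keywords internal
ihc_log <- function(level, ..., case_id = NULL) {
  if (!isTRUE(getOption("ihcmine.verbose", FALSE))) {
    return(invisible(NULL))
  }
  prefix <- if (is.null(case_id)) "" else paste0("[", case_id, "] ")
  message(sprintf("%s %s%s", toupper(level), prefix, paste(..., sep = " ")))
  invisible(NULL)
}

# stop() with a condition class so callers can discriminate error categories
ihc_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "ihcmine_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar NA-safe string check
is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
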