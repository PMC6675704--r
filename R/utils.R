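#' Round half away from zero
#'
#' Commercial-style rounding used when rendering rates as whole percent:
#' 0.5 always rounds away from zero (`round()` in R rounds half to even).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Render a proportion as whole percent
#'
#' @param p proportion in \[-1, 1\].
#' @return integer percent (half away from zero).
#' @export
percent_round <- function(p) {
  as.integer(round_half_away(100 * p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ps <- function(...) stop(sprintf(...), call. = FALSE)

warn_ps <- function(...) warning(sprintf(...), call. = FALSE)

# required-column check for the flat-file readers
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_ps("%s is missing required column(s): %s", what,
            paste(missing, collapse = ", "))
  }
  invisible(df)
}
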