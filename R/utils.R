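#' @importFrom rlang %||% abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Registry identifiers are compared after canonicalization: case and the
# punctuation registries tolerate (spaces, hyphens) never distinguish trials.
normalize_trn <- function(x) {
  toupper(stringr::str_remove_all(x, "[\\s-]"))
}

#' Round a fraction to the nearest integer percent
#'
#' Converts a proportion in `[0, 1]` to an integer percentage, rounding halves
#' away from zero (so 0.275 becomes 28, not base R's banker's 27). This is the
#' rounding used everywhere a percentage is printed or exported.
#'
#' @param p Numeric vector of fractions in `[0, 1]`.
#' @return Integer vector of percentages.
#' @examples
#' percent_round(c(0.5, 0.275, 0.45509))
#' @export
percent_round <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p < -1e-12 | p > 1 + 1e-12, na.rm = TRUE)) {
    abort("`p` must be a fraction in [0, 1].")
  }
  as.integer(sign(p) * floor(abs(100 * p) + 0.5))
}

# stop with a message naming every offending column
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(glue::glue(
      "{what} is missing required column(s): {paste(missing, collapse = ', ')}"
    ))
  }
  invisible(df)
}
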