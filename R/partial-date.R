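#' Partial calendar dates
#'
#' Registry exports mix day-resolved dates ("2015-03-12"), month-resolved
#' dates ("March 2015", "2015-03") and bare years ("2015"). `partial_date()`
#' is a vector class that keeps whatever resolution the source offered, so
#' downstream rules (e.g. the month-granular prospective-registration rule)
#' can refuse to over-interpret coarse dates instead of silently imputing.
#'
#' @param year Integer vector of calendar years.
#' @param month Optional integer vector, 1-12; `NA` for year-only dates.
#' @param day Optional integer vector, 1-31; `NA` unless the source gave a
#'   full date. A day without a month is rejected.
#' @return A `partial_date` vector.
#' @examples
#' partial_date(2015, 3)
#' granularity(partial_date(c(2015, 2015), c(3, NA), c(12, NA)))
#' @export
partial_date <- function(year = integer(), month = NA_integer_, day = NA_integer_) {
  fields <- vctrs::vec_recycle_common(
    year = vctrs::vec_cast(year, integer()),
    month = vctrs::vec_cast(month, integer()),
    day = vctrs::vec_cast(day, integer())
  )
  bad_day <- !is.na(fields$day) & is.na(fields$month)
  if (any(bad_day, na.rm = TRUE)) {
    abort("a `partial_date` with a day must also have a month")
  }
  bad_month <- !is.na(fields$month) & (fields$month < 1L | fields$month > 12L)
  if (any(bad_month, na.rm = TRUE)) {
    abort("`month` must be between 1 and 12")
  }
  full <- !is.na(fields$day)
  if (any(full)) {
    probe <- as.Date(
      sprintf("%04d-%02d-%02d", fields$year[full], fields$month[full], fields$day[full]),
      format = "%Y-%m-%d"
    )
    if (anyNA(probe)) {
      abort("`day` must form a valid Gregorian date with `year` and `month`")
    }
  }
  vctrs::new_rcrd(fields, class = "partial_date")
}

#' @export
format.partial_date <- function(x, ...) {
  y <- vctrs::field(x, "year")
  m <- vctrs::field(x, "month")
  d <- vctrs::field(x, "day")
  out <- sprintf("%04d", y)
  out[!is.na(m)] <- sprintf("%04d-%02d", y[!is.na(m)], m[!is.na(m)])
  out[!is.na(d)] <- sprintf(
    "%04d-%02d-%02d", y[!is.na(d)], m[!is.na(d)], d[!is.na(d)]
  )
  out[is.na(y)] <- NA_character_
  out
}

#' @exportS3Method vctrs::vec_ptype_abbr
vec_ptype_abbr.partial_date <- function(x, ...) "pdate"

#' Granularity of a partial date
#'
#' @param x A `partial_date` vector.
#' @return Character vector: `"year"`, `"month"` or `"day"` (`NA` for missing
#'   elements).
#' @export
granularity <- function(x) {
  stopifnot(inherits(x, "partial_date"))
  y <- vctrs::field(x, "year")
  m <- vctrs::field(x, "month")
  d <- vctrs::field(x, "day")
  dplyr::case_when(
    is.na(y) ~ NA_character_,
    !is.na(d) ~ "day",
    !is.na(m) ~ "month",
    TRUE ~ "year"
  )
}

#' @export
is.na.partial_date <- function(x) is.na(vctrs::field(x, "year"))

pd_year <- function(x) vctrs::field(x, "year")
pd_month <- function(x) vctrs::field(x, "month")
pd_day <- function(x) vctrs::field(x, "day")

pd_na <- function(n = 1L) {
  partial_date(rep(NA_integer_, n), NA_integer_, NA_integer_)
}

#' Parse free-form registry date strings
#'
#' Accepts the formats seen in ClinicalTrials.gov and DRKS flat-file exports:
#' ISO day (`"2015-03-12"`, `"2015/03/12"`), German day (`"12.03.2015"`),
#' long-form (`"March 2015"`, `"March 12, 2015"`), ISO month (`"2015-03"`)
#' and bare year (`"2015"`). The result keeps the finest granularity the
#' input expresses. Empty strings and `NA` parse to a missing date;
#' anything else is an error naming the offending string, never a silent
#' default.
#'
#' @param x Character vector of date strings (or `Date`s, passed through).
#' @return A `partial_date` vector the same length as `x`.
#' @examples
#' parse_partial_date(c("2015-03-12", "March 2015", "2015"))
#' @export
parse_partial_date <- function(x) {
  if (inherits(x, "partial_date")) {
    return(x)
  }
  if (inherits(x, "Date")) {
    lt <- as.POSIXlt(x)
    return(partial_date(lt$year + 1900L, lt$mon + 1L, lt$mday))
  }
  x <- as.character(x)
  n <- length(x)
  ys <- rep(NA_integer_, n)
  ms <- rep(NA_integer_, n)
  ds <- rep(NA_integer_, n)
  todo <- which(!(is.na(x) | !nzchar(trimws(x))))
  parsed <- purrr::map(trimws(x[todo]), parse_one_pd)
  failed <- purrr::map_lgl(parsed, is.null)
  if (any(failed)) {
    bad <- x[todo][failed]
    abort(glue::glue(
      "cannot parse date string(s): {paste(sQuote(unique(bad)), collapse = ', ')}"
    ))
  }
  for (k in seq_along(todo)) {
    ys[todo[k]] <- parsed[[k]][1]
    ms[todo[k]] <- parsed[[k]][2]
    ds[todo[k]] <- parsed[[k]][3]
  }
  partial_date(ys, ms, ds)
}

# returns c(year, month, day) with NA for absent components, NULL on failure
parse_one_pd <- function(s) {
  # day-resolved formats
  for (fmt in c("%Y-%m-%d", "%Y/%m/%d", "%d.%m.%Y", "%B %d, %Y", "%d %B %Y")) {
    d <- as.Date(s, format = fmt)
    if (!is.na(d)) {
      lt <- as.POSIXlt(d)
      return(c(lt$year + 1900L, lt$mon + 1L, lt$mday))
    }
  }
  # ISO month
  if (grepl("^\\d{4}-\\d{1,2}$", s)) {
    parts <- as.integer(strsplit(s, "-", fixed = TRUE)[[1]])
    if (parts[2] >= 1 && parts[2] <= 12) {
      return(c(parts[1], parts[2], NA_integer_))
    }
    return(NULL)
  }
  # "March 2015" (locale-independent month names)
  m <- regmatches(s, regexec("^([A-Za-z]+)\\s+(\\d{4})$", s))[[1]]
  if (length(m) == 3) {
    idx <- match(tolower(m[2]), tolower(month.name))
    if (is.na(idx)) idx <- match(tolower(m[2]), tolower(month.abb))
    if (!is.na(idx)) {
      return(c(as.integer(m[3]), idx, NA_integer_))
    }
    return(NULL)
  }
  if (grepl("^\\d{4}$", s)) {
    return(c(as.integer(s), NA_integer_, NA_integer_))
  }
  NULL
}

#' Compare two partial dates at month resolution
#'
#' The prospective-registration rule is month-granular: a trial counts as
#' prospectively registered when registered in the same or an earlier month
#' than its start. This comparison looks only at `(year, month)`; day fields
#' are ignored, and an operand without a month yields `"undetermined"`.
#'
#' @param a,b `partial_date` vectors (recycled to a common length).
#' @return Character vector with values `"before"`, `"same"`, `"after"` or
#'   `"undetermined"` (a compared to b).
#' @examples
#' compare_month(partial_date(2015, 2), partial_date(2015, 3))
#' @export
compare_month <- function(a, b) {
  stopifnot(inherits(a, "partial_date"), inherits(b, "partial_date"))
  recycled <- vctrs::vec_recycle_common(a = a, b = b)
  ka <- pd_year(recycled$a) * 12L + pd_month(recycled$a)
  kb <- pd_year(recycled$b) * 12L + pd_month(recycled$b)
  dplyr::case_when(
    is.na(ka) | is.na(kb) ~ "undetermined",
    ka < kb ~ "before",
    ka > kb ~ "after",
    TRUE ~ "same"
  )
}

#' Convert partial dates to `Date`, imputing the day
#'
#' Month-resolved dates are imputed to the first of the month; year-only
#' dates are not imputed and become `NA` (rules needing date arithmetic
#' require at least month resolution).
#'
#' @param x A `partial_date` vector.
#' @return A `Date` vector.
#' @export
pd_as_date <- function(x) {
  stopifnot(inherits(x, "partial_date"))
  y <- pd_year(x)
  m <- pd_month(x)
  d <- pd_day(x)
  d_imp <- dplyr::if_else(is.na(d), 1L, d)
  out <- rep(as.Date(NA), length(y))
  ok <- !is.na(y) & !is.na(m)
  out[ok] <- as.Date(sprintf("%04d-%02d-%02d", y[ok], m[ok], d_imp[ok]))
  out
}

# completion + N whole years at day resolution (day-imputed first-of-month
# for month-resolved inputs); lubridate handles Feb 29 rollover
pd_plus_years <- function(x, years) {
  pd_as_date(x) %m+% lubridate::years(years)
}

#' @importFrom lubridate %m+%
NULL
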