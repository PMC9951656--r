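SEX_LEVELS <- c("female", "male", "unknown")
CAUSE_LEVELS <- c("traffic", "in_care", "wild", "unknown")
HABITAT_LEVELS <- c("urban", "rural", "unclassified")

RECORD_COLUMNS <- c("id", "sex", "age_years", "death_month", "cause",
                    "latitude", "longitude", "heterozygosity", "habitat")

#' Construct a table of death records
#'
#' A death record describes one recovered animal: its sex, integer
#' age-at-death in completed years (the number of periosteal growth lines,
#' i.e. survived hibernations), the month of death, a cause-of-death
#' category, and optionally a site, an individual observed heterozygosity
#' in \eqn{[0,1]}, and an urban/rural habitat label. Unknown sex and
#' unknown cause are explicit categories, never missing values, because
#' they are reported as counts in their own right.
#'
#' @param id character identifiers.
#' @param sex one of `"female"`, `"male"`, `"unknown"` per record.
#' @param age_years non-negative integer ages in completed years.
#' @param death_month integer month 1-12 or `NA`.
#' @param cause one of `"traffic"`, `"in_care"`, `"wild"`, `"unknown"`.
#' @param latitude,longitude decimal degrees or `NA`.
#' @param heterozygosity real in \eqn{[0,1]} or `NA`.
#' @param habitat `"urban"`, `"rural"`, `"unclassified"` or `NA`.
#' @return a `data.frame` of class `death_records`.
#' @export
death_records <- function(id, sex, age_years, death_month = NA_integer_,
                          cause = "unknown", latitude = NA_real_,
                          longitude = NA_real_, heterozygosity = NA_real_,
                          habitat = NA_character_) {
  n <- length(id)
  df <- data.frame(
    id = as.character(id),
    sex = rep_len(as.character(sex), n),
    age_years = rep_len(age_years, n),
    death_month = rep_len(as.integer(death_month), n),
    cause = rep_len(as.character(cause), n),
    latitude = rep_len(as.numeric(latitude), n),
    longitude = rep_len(as.numeric(longitude), n),
    heterozygosity = rep_len(as.numeric(heterozygosity), n),
    habitat = rep_len(as.character(habitat), n),
    stringsAsFactors = FALSE
  )
  validate_death_records(df)
}

validate_death_records <- function(df) {
  bad_age <- which(is.na(df$age_years) | df$age_years < 0 |
                     df$age_years != floor(df$age_years))
  if (length(bad_age)) {
    stop("age_years must be a non-negative integer; offending row(s): ",
         paste(utils::head(bad_age, 5L), collapse = ", "), call. = FALSE)
  }
  df$age_years <- as.integer(df$age_years)
  df$sex <- coerce_enum(df$sex, SEX_LEVELS, "sex")
  df$cause <- coerce_enum(df$cause, CAUSE_LEVELS, "cause")
  bad_h <- which(!is.na(df$heterozygosity) &
                   (df$heterozygosity < 0 | df$heterozygosity > 1))
  if (length(bad_h)) {
    stop("heterozygosity must lie in [0,1]; offending row(s): ",
         paste(utils::head(bad_h, 5L), collapse = ", "), call. = FALSE)
  }
  bad_m <- which(!is.na(df$death_month) &
                   (df$death_month < 1L | df$death_month > 12L))
  if (length(bad_m)) {
    stop("death_month must be in 1..12; offending row(s): ",
         paste(utils::head(bad_m, 5L), collapse = ", "), call. = FALSE)
  }
  ok_hab <- is.na(df$habitat) | df$habitat %in% HABITAT_LEVELS
  if (!all(ok_hab)) {
    warning("unrecognised habitat label(s) set to NA", call. = FALSE)
    df$habitat[!ok_hab] <- NA_character_
  }
  class(df) <- c("death_records", "data.frame")
  df
}

# Unparseable enum values fall back to "unknown" with a warning; the
# fallback is deliberate so that messy citizen-science files still load.
coerce_enum <- function(x, levels, what) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x) | x == ""] <- "unknown"
  bad <- !(x %in% levels)
  if (any(bad)) {
    warning(sum(bad), " unparseable ", what, " value(s) set to \"unknown\" (",
            paste(utils::head(unique(x[bad]), 3L), collapse = ", "), ")",
            call. = FALSE)
    x[bad] <- "unknown"
  }
  x
}

#' Read death records from a delimited text file
#'
#' The file must have a header row and at least the columns `id`, `sex`
#' and `age_years`. The month of death may be given either directly as a
#' `death_month` integer column or as a `death_date` column holding an
#' ISO-8601 date (`YYYY-MM-DD`), from which only the month is retained —
#' all timing analyses are monthly. Missing optional columns are filled
#' with `NA` (or `"unknown"` for cause).
#'
#' @param path path to the file.
#' @param sep field separator, comma by default.
#' @return a `death_records` data frame, one row per data row of the file.
#' @export
read_records <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character", check.names = TRUE)
  for (col in c("id", "sex", "age_years")) {
    if (!col %in% names(raw)) {
      stop("mandatory column missing from ", path, ": ", col, call. = FALSE)
    }
  }
  age <- suppressWarnings(as.numeric(raw$age_years))
  bad <- which(is.na(age) | age < 0 | age != floor(age))
  if (length(bad)) {
    stop("negative or non-integer age_years at data row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  month <- if ("death_month" %in% names(raw)) {
    suppressWarnings(as.integer(raw$death_month))
  } else if ("death_date" %in% names(raw)) {
    month_from_iso(raw$death_date)
  } else {
    rep(NA_integer_, nrow(raw))
  }
  getnum <- function(col) {
    if (col %in% names(raw)) suppressWarnings(as.numeric(raw[[col]]))
    else rep(NA_real_, nrow(raw))
  }
  death_records(
    id = raw$id,
    sex = raw$sex,
    age_years = age,
    death_month = month,
    cause = if ("cause" %in% names(raw)) raw$cause else "unknown",
    latitude = getnum("latitude"),
    longitude = getnum("longitude"),
    heterozygosity = getnum("heterozygosity"),
    habitat = if ("habitat" %in% names(raw)) {
      h <- tolower(trimws(raw$habitat))
      h[h == "" | h == "na"] <- NA_character_
      h
    } else NA_character_
  )
}

month_from_iso <- function(x) {
  d <- as.Date(x, format = "%Y-%m-%d")
  out <- as.integer(format(d, "%m"))
  direct <- suppressWarnings(as.integer(x))
  out[is.na(out)] <- direct[is.na(out)]
  out
}

#' Write death records to a delimited text file
#'
#' Inverse of [read_records()]: `read_records(write_records(x, f))`
#' reproduces every field value.
#'
#' @param records a `death_records` data frame.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, sep = ",") {
  stopifnot(inherits(records, "death_records"))
  out <- as.data.frame(records)[, RECORD_COLUMNS]
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Age-at-death count table
#'
#' Holds the number of deaths observed at each completed age within one
#' stratum. Ages absent from `counts` mean zero deaths at that age;
#' survivors still pass through such ages when a life table is built.
#'
#' @param counts named non-negative integer vector; names are ages in years.
#' @param stratum label for the stratum the counts describe.
#' @return an object of class `age_counts` with elements `stratum`,
#'   `counts` and `n_total`.
#' @export
age_counts <- function(counts, stratum = "all") {
  if (length(counts) == 0) {
    out <- list(stratum = stratum, counts = integer(0), n_total = 0L)
    class(out) <- "age_counts"
    return(out)
  }
  ages <- as.integer(names(counts))
  if (anyNA(ages) || any(ages < 0)) {
    stop("count names must be non-negative integer ages", call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  cnt <- as.integer(counts)
  names(cnt) <- ages
  cnt <- cnt[order(ages)]
  out <- list(stratum = stratum, counts = cnt, n_total = sum(cnt))
  class(out) <- "age_counts"
  out
}

#' @export
print.age_counts <- function(x, ...) {
  cat("Age-at-death counts, stratum:", x$stratum,
      "(n =", paste0(x$n_total, ")\n"))
  if (length(x$counts)) print(x$counts)
  invisible(x)
}

#' Tabulate ages at death, optionally by stratum
#'
#' @param records a `death_records` data frame.
#' @param by name of a column to stratify on (e.g. `"sex"`), or `NULL`
#'   for a single stratum covering all records.
#' @return if `by` is `NULL`, a single [age_counts()] object; otherwise a
#'   named list of `age_counts`, one per observed stratum level (disjoint
#'   and exhaustive over the records).
#' @export
tabulate_ages <- function(records, by = NULL) {
  stopifnot(inherits(records, "death_records"))
  count_one <- function(ages, label) {
    if (length(ages) == 0) return(age_counts(integer(0), label))
    tab <- table(ages)
    age_counts(stats::setNames(as.integer(tab), names(tab)), label)
  }
  if (is.null(by)) return(count_one(records$age_years, "all"))
  if (!by %in% names(records)) {
    stop("unknown stratifier column: ", by, call. = FALSE)
  }
  levs <- unique(records[[by]])
  out <- lapply(levs, function(l) {
    count_one(records$age_years[records[[by]] == l], l)
  })
  stats::setNames(out, levs)
}

#' Age distribution of the Danish hedgehog study sample
#'
#' The packaged age-at-death distribution of 388 hedgehogs aged by
#' periosteal growth-line counts: per-age counts split by sex (177 males,
#' 109 females, 102 of unknown sex). Ages 7, 8, 12, 14 and 15 had no
#' observed deaths.
#'
#' @param sex `"male"`, `"female"`, `"unknown"` or `"all"`.
#' @return an [age_counts()] object for the requested stratum.
#' @export
hedgehog_agecounts <- function(sex = c("all", "male", "female", "unknown")) {
  sex <- match.arg(sex)
  ages <- c(0, 1, 2, 3, 4, 5, 6, 9, 10, 11, 13, 16)
  tab <- cbind(
    male    = c(43, 54, 23, 29, 6, 7, 8, 2, 2, 1, 1, 1),
    female  = c(39, 21, 15, 18, 9, 6, 1, 0, 0, 0, 0, 0),
    unknown = c(27, 40, 16,  6, 7, 2, 2, 0, 2, 0, 0, 0)
  )
  cnt <- if (sex == "all") rowSums(tab) else tab[, sex]
  keep <- cnt > 0
  age_counts(stats::setNames(cnt[keep], ages[keep]), sex)
}

#' Load the packaged study records (one row per animal)
#'
#' Reads the fixture file shipped with the package, which expands the
#' study's per-age, per-sex death counts into 388 individual rows.
#'
#' @return a `death_records` data frame with 388 rows.
#' @export
hedgehog_records <- function() {
  read_records(system.file("extdata", "table2_individuals.csv",
                           package = "hedgelife", mustWork = TRUE))
}
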