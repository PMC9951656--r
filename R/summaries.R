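#' Mean age-at-death with a normal-theory confidence interval
#'
#' The interval is mean \eqn{\pm z_{(1+level)/2} \cdot s/\sqrt{n}} with
#' the sample (n-1 denominator) standard deviation. With one
#' observation the mean is returned and the interval flagged undefined.
#'
#' @param ages integer ages at death, or a `death_records` data frame
#'   (its `age_years` column is used).
#' @param level confidence level in (0, 1).
#' @param stratum label carried through to the result.
#' @return an object of class `mean_age`: list with `stratum`, `n`,
#'   `mean`, `sd`, `ci_low`, `ci_high`, `level`.
#' @export
mean_age_ci <- function(ages, level = 0.95, stratum = "all") {
  if (inherits(ages, "death_records")) ages <- ages$age_years
  ages <- as.numeric(ages)
  if (length(ages) == 0) stop("no ages supplied", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0,1)", call. = FALSE)
  n <- length(ages)
  m <- mean(ages)
  if (n == 1) {
    out <- list(stratum = stratum, n = 1L, mean = m, sd = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_, level = level,
                ci_defined = FALSE)
  } else {
    s <- stats::sd(ages)
    z <- stats::qnorm((1 + level) / 2)
    half <- z * s / sqrt(n)
    out <- list(stratum = stratum, n = n, mean = m, sd = s,
                ci_low = m - half, ci_high = m + half, level = level,
                ci_defined = TRUE)
  }
  class(out) <- "mean_age"
  out
}

#' @export
print.mean_age <- function(x, ...) {
  if (x$ci_defined) {
    cat(sprintf("%s: mean age-at-death %.2f years, %d%% CI [%.2f, %.2f] (n = %d)\n",
                x$stratum, x$mean, round(100 * x$level), x$ci_low,
                x$ci_high, x$n))
  } else {
    cat(sprintf("%s: mean age-at-death %.2f years (n = 1, CI undefined)\n",
                x$stratum, x$mean))
  }
  invisible(x)
}

#' Mean age-at-death excluding the youngest age classes
#'
#' Several historical age-determination studies excluded animals under
#' one year; this applies the same filter before [mean_age_ci()].
#'
#' @param ages ages or `death_records` as in [mean_age_ci()].
#' @param min_age minimum age (inclusive) retained.
#' @param level confidence level.
#' @param stratum label for the result.
#' @return a `mean_age` object with an extra element `n_excluded`.
#' @export
mean_age_excluding <- function(ages, min_age, level = 0.95,
                               stratum = "all") {
  if (inherits(ages, "death_records")) ages <- ages$age_years
  keep <- ages >= min_age
  if (!any(keep)) {
    stop("min_age = ", min_age, " excludes every record", call. = FALSE)
  }
  out <- mean_age_ci(ages[keep], level = level,
                     stratum = paste0(stratum, " (age >= ", min_age, ")"))
  out$n_excluded <- sum(!keep)
  out
}

#' Monthly distribution of deaths by group
#'
#' @param records a `death_records` data frame with `death_month` set.
#' @param by character vector of grouping columns (e.g. `"sex"`, or
#'   `c("sex", "cause_class")` where `cause_class` means the
#'   traffic/non-traffic dichotomy, derived on the fly).
#' @return a list with `proportions` (one row per group, 12 columns
#'   summing to 1), `counts`, and `peaks` (per group, the set of modal
#'   months — ties are reported, never broken).
#' @export
monthly_distribution <- function(records, by = "sex") {
  stopifnot(inherits(records, "death_records"))
  d <- as.data.frame(records)
  d$cause_class <- ifelse(d$cause == "traffic", "traffic", "non-traffic")
  d <- d[!is.na(d$death_month), ]
  if (nrow(d) == 0) stop("no records carry a death month", call. = FALSE)
  missing_cols <- setdiff(by, names(d))
  if (length(missing_cols)) {
    stop("unknown grouping column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  key <- interaction(d[by], sep = ":", drop = TRUE)
  counts <- t(vapply(split(d$death_month, key), function(m) {
    tabulate(m, nbins = 12L)
  }, integer(12)))
  colnames(counts) <- month.abb
  props <- counts / rowSums(counts)
  peaks <- lapply(seq_len(nrow(counts)), function(i) {
    cnt <- counts[i, ]
    unname(which(cnt == max(cnt)))
  })
  names(peaks) <- rownames(counts)
  list(proportions = props, counts = counts, peaks = peaks)
}

#' Cross-tabulation with margins and percentages
#'
#' @param records a `death_records` data frame.
#' @param rows column name for the row factor.
#' @param cols column name for the column factor, or `NULL` for a
#'   one-way table.
#' @param drop_na drop records with `NA` in either factor.
#' @return an object of class `crosstab`: list with `counts` (with
#'   margins), `pct_total`, `pct_row`, `pct_col` (percentages by grand
#'   total, within row, within column).
#' @export
crosstab <- function(records, rows, cols = NULL, drop_na = TRUE) {
  stopifnot(inherits(records, "death_records"))
  d <- as.data.frame(records)
  d$cause_class <- ifelse(d$cause == "traffic", "traffic", "non-traffic")
  for (f in c(rows, cols)) {
    if (!f %in% names(d)) stop("unknown factor: ", f, call. = FALSE)
  }
  if (drop_na) {
    keep <- !is.na(d[[rows]])
    if (!is.null(cols)) keep <- keep & !is.na(d[[cols]])
    d <- d[keep, ]
  }
  tab <- if (is.null(cols)) {
    t(as.matrix(table(d[[rows]])))
  } else {
    as.matrix(table(d[[rows]], d[[cols]]))
  }
  total <- sum(tab)
  pct_total <- 100 * tab / total
  pct_row <- 100 * sweep(tab, 1, rowSums(tab), "/")
  pct_col <- 100 * sweep(tab, 2, colSums(tab), "/")
  pct_row[rowSums(tab) == 0, ] <- 0
  pct_col[, colSums(tab) == 0] <- 0
  out <- list(rows = rows, cols = cols,
              counts = stats::addmargins(as.table(tab)),
              cells = tab, n = total,
              pct_total = pct_total, pct_row = pct_row, pct_col = pct_col)
  class(out) <- "crosstab"
  out
}

#' @export
print.crosstab <- function(x, ...) {
  cat("Cross-tabulation:", x$rows,
      if (!is.null(x$cols)) paste("x", x$cols), "(n =", x$n, ")\n")
  print(x$counts)
  cat("\nPercent of total:\n")
  print(round(x$pct_total, 1))
  invisible(x)
}

#' Percent difference in life expectancy at birth between the sexes
#'
#' Computes \eqn{100 (e_0^{male}/e_0^{female} - 1)} twice: on the
#' inputs as given and on inputs rounded to one decimal (the convention
#' under which headline "x% longer life" figures are typically quoted).
#' Both are returned because the two can differ noticeably.
#'
#' @param e0_male,e0_female life expectancies at age 0 in years.
#' @return list with `full_precision` and `rounded_inputs` percent
#'   differences.
#' @export
sex_longevity_ratio <- function(e0_male, e0_female) {
  if (e0_male <= 0 || e0_female <= 0) {
    stop("life expectancies must be positive", call. = FALSE)
  }
  list(
    full_precision = 100 * (e0_male / e0_female - 1),
    rounded_inputs = 100 * (round(e0_male, 1) / round(e0_female, 1) - 1)
  )
}
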