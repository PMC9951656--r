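#' Build an empirical cohort life table from age-at-death counts
#'
#' Constructs a single-year actuarial life table for a cohort followed
#' from birth to extinction, using the standard column definitions:
#' \describe{
#'   \item{x}{exact age at the start of the interval, in years}
#'   \item{n}{interval length (1 year throughout)}
#'   \item{lx}{individuals entering the interval; the first entry is the
#'     cohort size, later entries the survivors to age x}
#'   \item{ndx}{deaths between ages x and x + n}
#'   \item{nqx}{probability of dying, ndx / lx}
#'   \item{npx}{probability of surviving, 1 - nqx}
#'   \item{nLx}{person-years lived in the interval, lx - nax * ndx}
#'   \item{Tx}{person-years lived above age x (reverse cumulation of nLx)}
#'   \item{ex}{remaining life expectancy, Tx / lx}
#'   \item{nmx}{death rate in the interval, ndx / nLx}
#'   \item{nax}{average fraction of the interval lived by those dying in
#'     it; fixed at 0.5 (deaths assumed uniform within the year),
#'     including the final interval}
#' }
#'
#' One row is produced for every integer age from 0 through the maximum
#' observed age even where no deaths occurred (survivors pass through
#' such intervals unscathed: nqx = 0, nmx = 0), plus a terminal row at
#' max age + 1 with lx = 0 whose ratio columns are undefined and stored
#' as `NA`.
#'
#' @param counts an [age_counts()] object, or a named non-negative
#'   integer vector of deaths per age (names are ages), or a plain
#'   integer vector of individual ages at death.
#' @param nax fraction of the interval lived by those dying in it;
#'   0.5 assumes deaths occur uniformly through the year.
#' @return an object of class `life_table`: a data frame with the
#'   columns above plus attributes `stratum` and `nax`.
#' @examples
#' lt <- life_table(hedgehog_agecounts("male"))
#' lt
#' summary(lt)
#' @export
life_table <- function(counts, nax = 0.5) {
  ac <- as_age_counts(counts)
  if (ac$n_total == 0) stop("no deaths: cannot build a life table",
                            call. = FALSE)
  ages <- as.integer(names(ac$counts))
  A <- max(ages)
  ndx <- integer(A + 1L)
  ndx[ages + 1L] <- ac$counts
  x <- 0:A
  lx <- rev(cumsum(rev(ndx)))           # survivors entering each age
  nqx <- ndx / lx
  npx <- 1 - nqx
  nLx <- lx - nax * ndx
  Tx <- rev(cumsum(rev(nLx)))
  ex <- Tx / lx
  nmx <- ndx / nLx
  nmx[nLx == 0] <- NA_real_
  tab <- data.frame(
    x = c(x, A + 1L), n = 1L,
    lx = c(lx, 0L), ndx = c(ndx, 0L),
    nqx = c(nqx, NA), npx = c(npx, NA),
    nLx = c(nLx, NA), Tx = c(Tx, 0), ex = c(ex, NA),
    nmx = c(nmx, NA), nax = nax
  )
  structure(tab, class = c("life_table", "data.frame"),
            stratum = ac$stratum, nax = nax)
}

as_age_counts <- function(counts) {
  if (inherits(counts, "age_counts")) return(counts)
  if (is.null(names(counts))) {
    # a vector of individual ages at death
    if (length(counts) == 0) stop("no deaths given", call. = FALSE)
    tab <- table(counts)
    return(age_counts(stats::setNames(as.integer(tab), names(tab))))
  }
  age_counts(counts)
}

#' @export
print.life_table <- function(x, digits = 3, ...) {
  cat("Empirical cohort life table",
      if (!is.null(attr(x, "stratum"))) paste0("(", attr(x, "stratum"), ")"),
      "- cohort size", x$lx[1], "\n")
  print(format_life_table(x), row.names = FALSE)
  invisible(x)
}

#' @export
summary.life_table <- function(object, ...) {
  out <- list(
    stratum = attr(object, "stratum"),
    cohort_size = object$lx[1],
    max_age = max(object$x[object$ndx > 0]),
    e0 = object$ex[1],
    classification = tryCatch(classify_survivorship(object),
                              error = function(e) NULL)
  )
  class(out) <- "summary.life_table"
  out
}

#' @export
print.summary.life_table <- function(x, ...) {
  cat("Cohort life table, stratum:", x$stratum, "\n")
  cat("  cohort size      :", x$cohort_size, "\n")
  cat("  oldest death     :", x$max_age, "years\n")
  cat("  life expectancy  :", round(x$e0, 3), "years at age 0\n")
  if (!is.null(x$classification)) {
    cat("  survivorship type:", x$classification$type,
        sprintf("(hazard-trend slope %.3f, p = %.3f)\n",
                x$classification$slope, x$classification$p_value))
  }
  invisible(x)
}

# Presentation rounding only: probabilities/rates/expectancies to 3 d.p.,
# person-years to 1 d.p.; undefined terminal ratios rendered "-".
format_life_table <- function(lt) {
  f3 <- function(v) ifelse(is.na(v), "-", sprintf("%.3f", v))
  f1 <- function(v) ifelse(is.na(v), "-", sprintf("%.1f", v))
  data.frame(
    x = lt$x, lx = lt$lx, ndx = lt$ndx,
    nqx = f3(lt$nqx), npx = f3(lt$npx),
    nLx = f1(lt$nLx), Tx = f1(lt$Tx), ex = f3(lt$ex),
    nmx = f3(lt$nmx), nax = lt$nax,
    stringsAsFactors = FALSE
  )
}

#' Export a life table as delimited text
#'
#' Writes the table with presentation rounding (3 decimals for
#' probabilities, rates and expectancies, 1 decimal for person-years)
#' and `-` for the undefined terminal ratios, in the standard column
#' order x, lx, ndx, nqx, npx, nLx, Tx, ex, nmx, nax.
#'
#' @param lt a `life_table`.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path, sep = ",") {
  stopifnot(inherits(lt, "life_table"))
  utils::write.table(format_life_table(lt), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Survivorship curve from a life table
#'
#' @param lt a `life_table`.
#' @return data frame with `age` and `survivorship` = lx / l0, starting
#'   at 1 and non-increasing to 0 at the terminal row.
#' @export
survivorship_curve <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  data.frame(age = lt$x, survivorship = lt$lx / lt$lx[1])
}

#' Hazard curve (age-specific death rate) from a life table
#'
#' Returns the interval death rate nmx = ndx / nLx per age — deaths per
#' person-year lived in the interval. The probability-scale alternative
#' nqx is included alongside for completeness.
#'
#' @param lt a `life_table`.
#' @return data frame with `age`, `nmx` and `nqx`; `NA` at rows with no
#'   person-years of exposure.
#' @export
hazard_curve <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  data.frame(age = lt$x, nmx = lt$nmx, nqx = lt$nqx)
}

#' Classify a survivorship curve as Type I, II or III
#'
#' Operationalizes the classical qualitative typology (mortality
#' concentrated late in life / constant with age / concentrated early)
#' as a log-linear hazard-trend test: interval death counts are
#' regressed on age by a quasi-Poisson GLM with offset
#' log(person-years), i.e. a discrete Gompertz model
#' \eqn{\log m_x = \beta_0 + \beta_1 x}. A slope significantly greater
#' than zero (two-sided test at `alpha`) gives Type I (risk increases
#' with age), significantly negative Type III, and otherwise Type II
#' (approximately constant risk). All rows with survivors entering
#' (lx > 0) contribute, including the final interval in which the last
#' survivors die — late-life exposure is where the trend signal lives.
#'
#' The qualitative call is a statistical operationalization of what is
#' traditionally a visual judgement, so the slope, its t statistic and
#' p-value are returned for audit.
#'
#' @param lt a `life_table`.
#' @param alpha two-sided significance threshold for the slope.
#' @return list with `type` (`"TypeI"`, `"TypeII"`, `"TypeIII"`),
#'   `slope` (log-hazard change per year of age), `t_value`, `p_value`
#'   and the underlying [fit_quasipoisson()] fit.
#' @export
classify_survivorship <- function(lt, alpha = 0.05) {
  stopifnot(inherits(lt, "life_table"))
  keep <- lt$lx > 0 & !is.na(lt$nLx) & lt$nLx > 0
  if (sum(keep) < 3) {
    stop("need at least 3 age classes with positive exposure", call. = FALSE)
  }
  d <- lt$ndx[keep]
  x <- lt$x[keep]
  L <- lt$nLx[keep]
  X <- cbind("(Intercept)" = 1, age = x)
  fit <- fit_quasipoisson(d, X, offset = log(L))
  slope <- fit$coefficients["age"]
  t <- fit$t_values["age"]
  p <- fit$p_values["age"]
  type <- if (p < alpha && slope > 0) "TypeI"
          else if (p < alpha && slope < 0) "TypeIII"
          else "TypeII"
  list(type = type, slope = unname(slope), t_value = unname(t),
       p_value = unname(p), fit = fit)
}
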