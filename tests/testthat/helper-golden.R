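# Frozen reference values and small oracles shared across the suite.

# Published single-year cohort life tables for the Danish hedgehog
# sample (printed at 3 d.p. for probabilities/rates/expectancies and
# 1 d.p. for person-years). Undefined terminal ratios are NA.
golden_male_table <- function() {
  txt <- "x lx ndx nqx npx nLx Tx ex nmx
0 177 43 0.243 0.757 155.5 460.5 2.602 0.277
1 134 54 0.403 0.597 107.0 305.0 2.276 0.505
2 80 23 0.287 0.713 68.5 198.0 2.475 0.336
3 57 29 0.509 0.491 42.5 129.5 2.272 0.682
4 28 6 0.214 0.786 25.0 87.0 3.107 0.240
5 22 7 0.318 0.682 18.5 62.0 2.818 0.378
6 15 8 0.533 0.467 11.0 43.5 2.900 0.727
7 7 0 0.000 1.000 7.0 32.5 4.643 0.000
8 7 0 0.000 1.000 7.0 25.5 3.643 0.000
9 7 2 0.286 0.714 6.0 18.5 2.643 0.333
10 5 2 0.400 0.600 4.0 12.5 2.500 0.500
11 3 1 0.333 0.667 2.5 8.5 2.833 0.400
12 2 0 0.000 1.000 2.0 6.0 3.000 0.000
13 2 1 0.500 0.500 1.5 4.0 2.000 0.667
14 1 0 0.000 1.000 1.0 2.5 2.500 0.000
15 1 0 0.000 1.000 1.0 1.5 1.500 0.000
16 1 1 1.000 0.000 0.5 0.5 0.500 2.000
17 0 0 NA NA NA 0.0 NA NA"
  read.table(text = txt, header = TRUE)
}

golden_female_table <- function() {
  txt <- "x lx ndx nqx npx nLx Tx ex nmx
0 109 39 0.358 0.642 89.5 231.5 2.124 0.436
1 70 21 0.300 0.700 59.5 142.0 2.029 0.353
2 49 15 0.306 0.694 41.5 82.5 1.684 0.361
3 34 18 0.529 0.471 25.0 41.0 1.206 0.720
4 16 9 0.562 0.438 11.5 16.0 1.000 0.783
5 7 6 0.857 0.143 4.0 4.5 0.643 1.500
6 1 1 1.000 0.000 0.5 0.5 0.500 2.000
7 0 0 NA NA NA 0.0 NA NA"
  read.table(text = txt, header = TRUE)
}

# Compare a computed column against printed values: agreement to the
# printed precision means |computed - printed| <= half a printed unit
# (plus float slack for exact rounding ties such as 23/80 = 0.2875).
expect_printed <- function(computed, printed, unit) {
  ok <- is.na(printed) | abs(computed - printed) <= unit / 2 + 1e-9
  testthat::expect_true(all(ok), label = paste(
    "cells within printed precision; worst deviation",
    max(abs(computed - printed), na.rm = TRUE)))
}

# Random age-count table for property tests
random_age_counts <- function(max_age = 12, lambda = 8) {
  repeat {
    cnt <- rpois(max_age + 1, lambda * exp(-0.2 * (0:max_age)))
    if (sum(cnt) > 0) break
  }
  keep <- cnt > 0
  age_counts(setNames(cnt[keep], (0:max_age)[keep]))
}

# Brute-force disc-offset oracle: enumerate all integer offsets within
# a generous box and keep those with center distance <= radius.
oracle_offsets <- function(radius, cellsize) {
  k <- ceiling(radius / cellsize) + 2
  g <- expand.grid(dx = -k:k, dy = -k:k)
  g[sqrt(g$dx^2 + g$dy^2) * cellsize <= radius, ]
}

# Analytic mean of the capped geometric age-at-death distribution:
# P(age = x) = q (1-q)^x for x < cap, P(age = cap) = (1-q)^cap.
geometric_mean_age <- function(q, cap) {
  x <- 0:(cap - 1)
  sum(x * q * (1 - q)^x) + cap * (1 - q)^cap
}
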