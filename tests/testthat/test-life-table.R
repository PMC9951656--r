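test_that("male life table reproduces every published cell", {
  lt <- life_table(hedgehog_agecounts("male"))
  g <- golden_male_table()
  expect_equal(lt$x, g$x)
  expect_equal(lt$lx, g$lx)
  expect_equal(lt$ndx, g$ndx)
  expect_printed(lt$nqx, g$nqx, 0.001)
  expect_printed(lt$npx, g$npx, 0.001)
  expect_printed(lt$nLx, g$nLx, 0.1)
  expect_printed(lt$Tx, g$Tx, 0.1)
  expect_printed(lt$ex, g$ex, 0.001)
  expect_printed(lt$nmx, g$nmx, 0.001)
  expect_true(all(lt$nax == 0.5))
  # undefined terminal ratios are missing, not zero
  expect_true(all(is.na(lt[nrow(lt), c("nqx", "npx", "nLx", "ex", "nmx")])))
})

test_that("female life table reproduces every published cell", {
  lt <- life_table(hedgehog_agecounts("female"))
  g <- golden_female_table()
  expect_equal(lt$lx, g$lx)
  expect_printed(lt$nqx, g$nqx, 0.001)
  expect_printed(lt$nLx, g$nLx, 0.1)
  expect_printed(lt$Tx, g$Tx, 0.1)
  expect_printed(lt$ex, g$ex, 0.001)
  expect_printed(lt$nmx, g$nmx, 0.001)
})

test_that("ages with zero deaths appear as pass-through rows", {
  lt <- life_table(hedgehog_agecounts("male"))
  r7 <- lt[lt$x == 7, ]
  expect_equal(r7$ndx, 0)
  expect_equal(r7$nqx, 0)
  expect_equal(r7$npx, 1)
  expect_equal(r7$nmx, 0)
  expect_equal(r7$lx, 7)
})

test_that("a cohort dying entirely at age 0 is forced by nax = 0.5", {
  lt <- life_table(c(`0` = 10L))
  expect_equal(lt$nqx[1], 1)
  expect_equal(lt$nLx[1], 5)
  expect_equal(lt$ex[1], 0.5)
  expect_equal(lt$nmx[1], 2)
})

test_that("degenerate and invalid inputs error", {
  expect_error(life_table(age_counts(integer(0))), "no deaths")
  expect_error(age_counts(c(`0` = -1)), "non-negative")
  expect_error(age_counts(c(`-1` = 3)), "ages")
})

test_that("life-table identities hold on random count tables", {
  set.seed(101)
  for (i in 1:200) {
    lt <- life_table(random_age_counts())
    body <- lt[-nrow(lt), ]
    expect_equal(sum(body$ndx), body$lx[1])
    expect_true(all(diff(lt$lx) <= 0))
    expect_equal(body$nqx, body$ndx / body$lx)
    expect_equal(body$npx, 1 - body$nqx)
    expect_equal(body$nLx, body$lx - 0.5 * body$ndx)
    # Tx telescoping
    expect_equal(body$Tx, rev(cumsum(rev(body$nLx))))
    expect_equal(lt$Tx[nrow(lt)], 0)
    # algebraic identity linking rate and probability
    expect_equal(body$nmx[body$nLx > 0],
                 (body$nqx / (1 - 0.5 * body$nqx))[body$nLx > 0],
                 tolerance = 1e-12)
    expect_true(all(body$ex >= 0))
  }
})

test_that("e0 matches the closed-form geometric expectation", {
  # constant per-year death probability q: expected e0 is the
  # brute-force sum over the (far-truncated) geometric law
  q <- 0.3
  horizon <- 200
  x <- 0:horizon
  ndx <- round(1e6 * q * (1 - q)^x)
  lt <- life_table(setNames(ndx[ndx > 0], x[ndx > 0]))
  l0 <- sum(ndx[ndx > 0])
  oracle <- sum((x + 0.5) * ndx) / l0
  expect_equal(lt$ex[1], oracle, tolerance = 1e-12)
})

test_that("survivorship curve is a normalized non-increasing trace", {
  lt <- life_table(hedgehog_agecounts("male"))
  sc <- survivorship_curve(lt)
  expect_equal(sc$survivorship[1], 1)
  expect_true(all(diff(sc$survivorship) <= 0))
  expect_true(all(sc$survivorship >= 0 & sc$survivorship <= 1))
  expect_equal(sc$survivorship[nrow(sc)], 0)
  # l4 / l0 from the published table
  expect_equal(sc$survivorship[sc$age == 4], 28 / 177, tolerance = 1e-12)
})

test_that("hazard curve returns the interval death rates", {
  lt <- life_table(hedgehog_agecounts("male"))
  hc <- hazard_curve(lt)
  expect_equal(hc$nmx[hc$age == 6], 8 / 11, tolerance = 1e-12)
  expect_equal(hc$nmx[hc$age == 16], 2)
  expect_equal(hc$nmx[hc$age == 7], 0)
  expect_true(is.na(hc$nmx[nrow(hc)]))
  expect_true(all(hc$nmx >= 0, na.rm = TRUE))
})

test_that("survivorship classification matches the study's calls", {
  cls_m <- classify_survivorship(life_table(hedgehog_agecounts("male")))
  expect_equal(cls_m$type, "TypeII")
  cls_f <- classify_survivorship(life_table(hedgehog_agecounts("female")))
  expect_equal(cls_f$type, "TypeI")
  expect_gt(cls_f$slope, 0)
  expect_lt(cls_f$p_value, 0.05)
})

test_that("a strictly decreasing hazard schedule is Type III", {
  # deaths front-loaded: hazard falls with age and the cohort
  # extinguishes naturally (no truncation spike at the end)
  q <- function(x) 0.9 * exp(-0.1 * x)
  l <- 10000; ndx <- integer(0); x <- 0
  while (l > 0) {
    d <- if (l <= 2) l else round(l * q(x))
    ndx <- c(ndx, d); l <- l - d; x <- x + 1
  }
  lt <- life_table(setNames(ndx[ndx > 0], (seq_along(ndx) - 1)[ndx > 0]))
  cls <- classify_survivorship(lt)
  expect_equal(cls$type, "TypeIII")
  expect_lt(cls$slope, 0)
})

test_that("classification needs at least three exposed age classes", {
  expect_error(classify_survivorship(life_table(c(`0` = 5, `1` = 5))),
               "3 age classes")
})

test_that("exported life table text mirrors the presentation rounding", {
  lt <- life_table(hedgehog_agecounts("female"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_life_table(lt, f)
  txt <- read.table(f, header = TRUE, sep = ",",
                    colClasses = "character")
  expect_equal(names(txt),
               c("x", "lx", "ndx", "nqx", "npx", "nLx", "Tx", "ex",
                 "nmx", "nax"))
  expect_equal(txt$ex[1], "2.124")
  expect_equal(txt$nLx[1], "89.5")
  expect_equal(txt$nqx[nrow(txt)], "-")
})
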