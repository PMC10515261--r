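test_that("load_panel reads long CSV into a region-by-year panel", {
  path <- write_panel_csv(list(
    list("A", "AAA", 1990, 10), list("A", "AAA", 1991, 12), list("A", "AAA", 1992, 11),
    list("B", "BBB", 1990, 20), list("B", "BBB", 1991, 25), list("B", "BBB", 1992, 22)
  ))
  p <- load_panel(path, "Deaths", units = "count")
  expect_s3_class(p, "riskcast_panel")
  expect_setequal(panel_regions(p), c("A", "B"))
  expect_equal(panel_year_range(p), c(1990L, 1992L))
  expect_equal(sum(!is.na(p$data$value)), 6)
  expect_equal(p$units, "count")
})

test_that("gaps stay explicit missing values, never zero-filled", {
  path <- write_panel_csv(list(
    list("A", "AAA", 1994, 1), list("A", "AAA", 1996, 2),
    list("B", "BBB", 1994, 3), list("B", "BBB", 1995, 4), list("B", "BBB", 1996, 5)
  ))
  p <- load_panel(path, "Deaths", units = "count")
  a95 <- p$data$value[p$data$region == "A" & p$data$year == 1995]
  expect_true(is.na(a95))
  expect_equal(sum(p$data$value == 0, na.rm = TRUE), 0)
})

test_that("schema, parse and integrity violations are reported precisely", {
  dup <- write_panel_csv(list(
    list("A", "AAA", 1990, 1), list("A", "AAA", 1990, 2), list("B", "B", 1990, 1)
  ))
  expect_error(load_panel(dup, "Deaths", units = "count"),
               class = "riskcast_integrity_error")
  expect_error(load_panel(dup, "Deaths", units = "count"), "A, 1990")

  path <- write_panel_csv(list(list("A", "AAA", 1990, 1)))
  expect_error(load_panel(path, "NoSuchColumn", units = "count"),
               class = "riskcast_schema_error")

  bad <- tempfile(fileext = ".csv")
  writeLines(c("Entity,Code,Year,Deaths", "A,AAA,1990,1", "A,AAA,1991,oops"), bad)
  err <- expect_error(load_panel(bad, "Deaths", units = "count"),
                      class = "riskcast_parse_error")
  expect_match(conditionMessage(err), "2") # offending data row index
})

test_that("per-100k inputs are converted to percent on load", {
  path <- write_panel_csv(list(list("A", "AAA", 1990, 50)))
  p <- load_panel(path, "Deaths", units = "per100k")
  expect_equal(p$data$value[!is.na(p$data$value)], 0.05)
  expect_equal(p$units, "percent")
})

test_that("normalize_to_percent divides counts by population", {
  p <- as_panel(tibble::tibble(region = c("A", "A"), year = c(1990, 1991),
                               value = c(50, 0)), units = "count")
  pops <- tibble::tibble(region = "A", year = 1990:1991, population = 1e5)
  q <- normalize_to_percent(p, pops)
  expect_equal(q$data$value, c(0.05, 0))
  expect_equal(q$units, "percent")
})

test_that("normalize_to_percent demands full population coverage", {
  p <- as_panel(tibble::tibble(region = "B", year = 2000:2001, value = c(1, 2)),
                units = "count")
  pops <- tibble::tibble(region = "B", year = 2000, population = 100)
  err <- expect_error(normalize_to_percent(p, pops),
                      class = "riskcast_coverage_error")
  expect_match(conditionMessage(err), "B, 2001")
})

test_that("normalization is homogeneous in the population scale", {
  p <- random_panel(4, 6, seed = 11)
  counts <- as_panel(dplyr::mutate(p$data, value = .data$value * 1000),
                     units = "count")
  pops <- tidyr::crossing(region = panel_regions(p), year = 2000:2005) |>
    dplyr::mutate(population = 5e4 + 1e3 * seq_len(dplyr::n()))
  q1 <- normalize_to_percent(counts, pops)
  q2 <- normalize_to_percent(counts, dplyr::mutate(pops, population = population * 3))
  expect_equal(q2$data$value, q1$data$value / 3)
})

test_that("exclude_regions drops listed regions and warns on unknowns", {
  p <- random_panel(5, 4, seed = 3)
  q <- exclude_regions(p, c("G01", "G02"))
  expect_equal(length(panel_regions(q)), 3)
  expect_equal(q$meta$n_excluded, 2)
  expect_equal(length(panel_regions(p)), 5) # original untouched

  expect_identical(exclude_regions(p, character())$data, p$data)
  expect_warning(r <- exclude_regions(p, "Atlantis"), "Atlantis")
  expect_identical(r$data, p$data)
})

test_that("excluding a union equals excluding sequentially", {
  p <- random_panel(6, 5, seed = 7)
  both <- exclude_regions(p, c("G02", "G05"))
  seq2 <- exclude_regions(exclude_regions(p, "G02"), "G05")
  expect_equal(both$data, seq2$data)
  expect_equal(both$meta$n_excluded, seq2$meta$n_excluded)
})

test_that("write -> load round-trips bit-identically", {
  path <- write_panel_csv(list(
    list("A", "AAA", 1990, 0.123), list("A", "AAA", 1992, 0.456),
    list("B", "BBB", 1990, 0.5), list("B", "BBB", 1991, 0.25)
  ))
  p1 <- load_panel(path, "Deaths", units = "percent")
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_panel(p1, f1, sidecar = FALSE)
  p2 <- load_panel(f1, "Value", units = "percent")
  write_panel(p2, f2, sidecar = FALSE)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(p2$data$value, p1$data$value)
})
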