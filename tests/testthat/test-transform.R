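test_that("scale_components divides by per-region hazard limits", {
  p <- as_panel(tibble::tibble(region = "A", year = 1990:1991,
                               value = c(0.01, 0.02)), units = "percent")
  s <- scale_components(p, 0.05)
  expect_equal(s$data$value, c(0.2, 0.4))
  expect_true(s$scaled)
  expect_equal(s$units, "scaled")

  s1 <- scale_components(tiny_panel(), 1)
  expect_equal(s1$data$value, tiny_panel()$data$value)
})

test_that("scale_components rejects missing or non-positive limits", {
  p <- tiny_panel()
  expect_error(scale_components(p, c(A = 1)), class = "riskcast_limits_error")
  err <- expect_error(scale_components(p, c(A = 1, B = 0)),
                      class = "riskcast_limits_error")
  expect_match(conditionMessage(err), "B")
})

test_that("local maxima extraction honours strict and all-values modes", {
  p <- as_panel(tibble::tibble(region = "A", year = 2001:2005,
                               value = c(1, 3, 2, 5, 4)), units = "percent")
  ev <- extract_local_maxima(p, "strict")$A
  expect_equal(ev$time, c(2002L, 2004L))
  expect_equal(ev$value, c(3, 5))

  const <- as_panel(tibble::tibble(region = "A", year = 2001:2003,
                                   value = c(2, 2, 2)), units = "percent")
  expect_equal(nrow(extract_local_maxima(const, "strict")$A), 0)

  all_ev <- extract_local_maxima(p, "all_values")$A
  expect_equal(all_ev$value, c(1, 3, 2, 5, 4))

  expect_error(local_maxima(2001:2002, c(NA_real_, NA_real_)),
               class = "riskcast_empty_error")
})

test_that("interleave merge orders disjoint events and collapses coincidences", {
  x <- tibble::tibble(time = c(1, 3), value = c(0.5, 0.8))
  y <- tibble::tibble(time = c(2, 4), value = c(0.6, 0.4))
  m <- merge_interleave(list(X = x, Y = y))
  expect_equal(m$data$time, 1:4)
  expect_equal(m$data$value, c(0.5, 0.6, 0.8, 0.4))
  expect_equal(nrow(m$data), 4)

  # simultaneous maxima collapse to the componentwise maximum, both sources kept
  x2 <- tibble::tibble(time = 3, value = 0.8)
  y2 <- tibble::tibble(time = 3, value = 0.4)
  m2 <- merge_interleave(list(X = x2, Y = y2))
  expect_equal(nrow(m2$data), 1)
  expect_equal(m2$data$value, 0.8)
  expect_equal(m2$data$sources, "X;Y")

  # an empty list among the inputs contributes nothing
  m3 <- merge_interleave(list(X = x, Y = y,
                              Z = tibble::tibble(time = integer(), value = double())))
  expect_equal(m3$data, m$data)
})

test_that("interleave merge loses no events on random inputs", {
  for (seed in 1:20) {
    set.seed(seed)
    events <- lapply(1:4, function(i) {
      times <- sort(sample(1:30, sample(3:12, 1)))
      tibble::tibble(time = times, value = round(rexp(length(times)), 3))
    })
    names(events) <- paste0("C", 1:4)
    m <- merge_interleave(events)
    expect_false(is.unsorted(m$data$time))
    # reconstruct: every input event is represented and coincidences keep the max
    all_ev <- dplyr::bind_rows(events)
    expected <- tapply(all_ev$value, all_ev$time, max)
    expect_equal(m$data$value, as.numeric(expected[as.character(m$data$time)]))
    expect_equal(nrow(m$data), length(unique(all_ev$time)))
  }
})

test_that("pointwise-max merge is the exact columnwise maximum", {
  p <- as_panel(tibble::tibble(
    region = rep(c("X", "Y"), each = 2), year = rep(1990:1991, 2),
    value = c(0.1, 0.5, 0.3, 0.2)
  ), units = "percent")
  m <- merge_pointwise_max(p)
  expect_equal(m$data$value, c(0.3, 0.5))
  expect_equal(m$data$sources, c("Y", "X"))
  expect_equal(m$events_per_year, 1)

  single <- as_panel(tibble::tibble(region = "X", year = 1990:1992,
                                    value = c(1, 2, 3)), units = "percent")
  expect_equal(merge_pointwise_max(single)$data$value, c(1, 2, 3))

  # a year observed in only one region uses that region's value
  gap <- as_panel(tibble::tibble(
    region = c("X", "Y", "Y"), year = c(1990, 1990, 1991),
    value = c(0.9, 0.1, 0.4)
  ), units = "percent")
  expect_equal(merge_pointwise_max(gap)$data$value, c(0.9, 0.4))
})

test_that("pointwise-max merge matches brute force on random sparse panels", {
  for (seed in 1:15) {
    p <- random_panel(5, 12, seed = seed, missing_frac = 0.3)
    m <- merge_pointwise_max(p)
    expect_equal(m$data$value, brute_pointwise_max(p))
    n_obs_years <- length(unique(p$data$year[!is.na(p$data$value)]))
    expect_equal(nrow(m$data), n_obs_years)
  }
})

test_that("scaling and merging commute when all limits are equal", {
  p <- random_panel(4, 8, seed = 2)
  eta <- 0.7
  a <- merge_pointwise_max(scale_components(p, eta))
  b <- merge_pointwise_max(p)
  expect_equal(a$data$value, b$data$value / eta)

  ev_scaled <- extract_local_maxima(scale_components(p, eta), "all_values")
  ev_raw <- extract_local_maxima(p, "all_values")
  expect_equal(merge_interleave(ev_scaled)$data$value,
               merge_interleave(ev_raw)$data$value / eta)
})

test_that("degenerate merge inputs raise empty-input errors", {
  empty <- as_panel(tibble::tibble(region = "A", year = 1990L, value = NA_real_),
                    units = "percent")
  expect_error(merge_pointwise_max(empty), class = "riskcast_empty_error")
  expect_error(merge_interleave(list(tibble::tibble(time = integer(), value = double()))),
               class = "riskcast_empty_error")
})
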