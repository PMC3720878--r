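test_that("peak interval of a triangular curve matches the closed form", {
  # rises 0..10 on t in [0,10], falls to 0 at t = 30; half-peak at t = 20
  tri <- activation_curve(0:30, c(0:10, 10 - (1:20) / 2))
  pk <- find_peak_interval(tri)
  expect_identical(pk$peak_time, 10)
  expect_identical(pk$peak_value, 10)
  expect_identical(pk$t_end, 20)
})

test_that("degenerate and monotone curves are handled per policy", {
  expect_error(find_peak_interval(activation_curve(0:10, rep(0, 11))),
               "degenerate")
  rising <- activation_curve(0:100, seq(0, 5, length.out = 101))
  expect_identical(find_peak_interval(rising)$t_end, 100)  # fallback
  expect_warning(s <- sample_curve(rising), "end of the curve")
  expect_identical(nrow(s), 100L)
  expect_true(all(s$section == "peak"))
})

test_that("curve samples have 100 distinct on-grid points, half in the peak", {
  cv <- reference_curve()$curve
  s <- sample_curve(cv)
  expect_identical(nrow(s), 100L)
  expect_identical(sum(s$section == "peak"), 50L)
  expect_identical(anyDuplicated(s$time_us), 0L)
  expect_true(all(s$time_us %in% cv$times))
  expect_true(all(s$percent_open == cv$values[match(s$time_us, cv$times)]))
  pk <- find_peak_interval(cv)
  expect_true(all(s$time_us[s$section == "peak"] <= pk$t_end))
  expect_true(all(s$time_us[s$section == "tail"] > pk$t_end))
  # strictly increasing within each section
  expect_true(all(diff(s$time_us[s$section == "peak"]) > 0))
  expect_true(all(diff(s$time_us[s$section == "tail"]) > 0))
  # no randomness: resampling is identical
  expect_identical(sample_curve(cv), s)
})

test_that("segment starts follow the equal-division arithmetic", {
  # construct a curve whose half-peak crossing is exactly t = 2000
  tt <- 0:10000
  v <- ifelse(tt <= 1000, tt / 100,
              pmax(0, 10 - 5 * (tt - 1000) / 1000))
  cv <- activation_curve(tt, v)
  pk <- find_peak_interval(cv)
  expect_identical(pk$t_end, 2000)
  s <- sample_curve(cv)
  expect_identical(s$time_us[s$section == "peak"], seq(0, 1960, by = 40))
  # tail: starts of 50 equal segments of (2000, 10000], advanced off t_end
  expect_identical(s$time_us[s$section == "tail"][1], 2001)
  expect_identical(s$time_us[s$section == "tail"][2], 2160)
})

test_that("very short peak intervals still yield 100 distinct points", {
  # peak collapses within a few grid steps
  tt <- 0:10000
  v <- c(0, 10, 4, rep(3, 3), seq(2.9, 0, length.out = 9995))
  cv <- activation_curve(tt, v)
  pk <- find_peak_interval(cv)
  expect_lt(pk$t_end, 50)
  s <- sample_curve(cv)
  expect_identical(nrow(s), 100L)
  expect_identical(anyDuplicated(s$time_us), 0L)
  expect_identical(sum(s$section == "peak"), 50L)
})

test_that("sampled times cover the full duration without large gaps", {
  cv <- reference_curve()$curve
  s <- sample_curve(cv)
  pk <- find_peak_interval(cv)
  gap_bound <- (max(cv$times) - pk$t_end) / 50 + diff(cv$times)[1]
  expect_lte(max(diff(sort(s$time_us))), gap_bound)
  expect_identical(min(s$time_us), 0)
})
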