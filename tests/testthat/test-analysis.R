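# a hand-built response object for the arithmetic checks
fake_response <- function(units, spikes_t, spikes_unit, window = c(0, 500),
                          w = 160, h = 160) {
  meta <- data.frame(unit = seq_len(units), cx = seq_len(units),
                     cy = seq_len(units), ring = 0L,
                     row = 0L, col = seq_len(units))
  structure(list(
    responses = list(LR = list(
      spikes = data.frame(unit = spikes_unit, t = spikes_t),
      n_units = units, units = meta, direction = "LR")),
    t_span = window, window = window, width = w, height = h),
    class = "population_response")
}

test_that("population MFR is count / (units x window)", {
  r <- fake_response(100, runif(50, 0, 500), sample(1:100, 50, TRUE))
  expect_equal(mean_firing_rate(r, "LR"), 50 / (100 * 0.5))  # 1 Hz
  empty <- fake_response(100, numeric(), integer())
  expect_equal(mean_firing_rate(empty, "LR"), 0)
  expect_error(mean_firing_rate(r, "LR", window = c(100, 100)), "window")
  expect_error(mean_firing_rate(r, "XX"), "no response")
})

test_that("instantaneous rate conserves the spike count", {
  set.seed(3)
  r <- fake_response(50, sort(runif(200, 0, 500)), sample(1:50, 200, TRUE))
  ir <- instantaneous_rate(r, "LR", bin_ms = 25)
  expect_equal(sum(ir$count), 200)
  expect_equal(sum(ir$rate_hz) * 50 * 25 / 1000, 200)
  silent <- instantaneous_rate(fake_response(50, numeric(), integer()), "LR")
  expect_true(all(silent$rate_hz == 0) && all(silent$var_hz2 == 0))
})

test_that("preferred rate dominates anti-preferred in every traversal bin", {
  resp <- run_bar("LR", 0.3)
  span <- resp$t_span
  pref <- instantaneous_rate(resp, "LR", bin_ms = 50, window = span)
  anti <- instantaneous_rate(resp, "RL", bin_ms = 50, window = span)
  active <- pref$rate_hz > 0
  expect_true(any(active))
  expect_true(all(pref$rate_hz[active] > anti$rate_hz[active]))
})

test_that("center of mass weights unit distances by MFR", {
  m <- data.frame(unit = 1:2, x = c(79.5 + 30, 79.5 - 20), y = c(79.5, 79.5),
                  ring = 1L, mfr_hz = c(1, 1))
  attr(m, "width") <- 160; attr(m, "height") <- 160
  class(m) <- c("spatial_map", "data.frame")
  expect_equal(center_of_mass(m), 25)  # two equal units at 30 and 20 px
  m$mfr_hz <- c(1, 0)
  expect_equal(center_of_mass(m), 30)  # single active unit
  expect_equal(center_of_mass(m, "euclidean"), 30)
  m$mfr_hz <- c(0, 0)
  expect_error(center_of_mass(m), "silent")
})

test_that("spatial maps place MFR at trigger centers and rasterize", {
  resp <- run_bar("LR", 0.3)
  map <- spatial_map(resp, "LR")
  expect_equal(nrow(map), resp$responses$LR$n_units)
  expect_true(all(map$mfr_hz >= 0))
  expect_true(all(map$x >= 0 & map$x <= 160 & map$y >= 0 & map$y <= 160))
  total <- sum(map$mfr_hz) * diff(resp$window) / 1000
  expect_equal(total, sum(resp$responses$LR$spikes$t >= resp$window[1] &
                            resp$responses$LR$spikes$t <= resp$window[2]))
  img <- as_image(map)
  expect_equal(dim(img), c(160, 160))
  expect_equal(sum(img), sum(map$mfr_hz))
  zero <- spatial_map(run_bar("LR", 0.3), "RL")
  expect_true(all(zero$mfr_hz == 0))
})

test_that("slow bars engage the fovea, fast bars the periphery", {
  slow <- spatial_map(run_bar("LR", 0.03), "LR")
  fast <- spatial_map(run_bar("LR", 1.0), "LR")
  d_slow <- center_of_mass(slow)
  d_fast <- center_of_mass(fast)
  expect_lt(d_slow, d_fast)
  # foveal (ring 0) units carry most of the slow response, none of the fast
  frac_fovea <- function(m) sum(m$mfr_hz[m$ring == 0]) / sum(m$mfr_hz)
  expect_gt(frac_fovea(slow), 0.3)
  expect_lt(frac_fovea(fast), 0.05)
})

test_that("eccentricity profiles track the speed-dependent activity shift", {
  flat <- data.frame(unit = 1:100, x = runif(100, 0, 160),
                     y = runif(100, 0, 160), ring = 1L, mfr_hz = 2)
  attr(flat, "width") <- 160; attr(flat, "height") <- 160
  class(flat) <- c("spatial_map", "data.frame")
  pr <- eccentricity_profile(flat, n_bins = 5)
  expect_true(all(abs(pr$mean_mfr_hz[pr$n_units > 0] - 2) < 1e-9))

  slow <- eccentricity_profile(spatial_map(run_bar("LR", 0.03), "LR"))
  fast <- eccentricity_profile(spatial_map(run_bar("LR", 1.0), "LR"))
  peak_d <- function(p) p$d_mid[which.max(p$mean_mfr_hz)]
  expect_gt(peak_d(fast), peak_d(slow))
})

test_that("longer bars recruit more units with diminishing increments", {
  tab <- bar_length_experiment(c(0, 10, 50, 100, 160), paper_scheme(),
                               paper_pops()["LR"])
  expect_equal(tab$mfr_hz[1], 0)
  expect_true(all(diff(tab$mfr_hz) > 0))
  inc <- diff(tab$mfr_hz[3:5])  # 50->100 vs 100->160
  expect_lt(inc[2], inc[1])
})
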