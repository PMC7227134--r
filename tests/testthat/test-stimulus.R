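test_that("LR bar kinematics: one ON event per pixel at t = x/v", {
  s <- moving_bar("LR", 0.5, bar_length = 160, geometry = c(160, 160))
  expect_equal(n_events(s), 160 * 160)
  expect_true(all(s$events$p == 1L))
  expect_equal(s$events$t, s$events$x / 0.5)
  # a 10-px column transit at 0.3 px/ms takes 10/0.3 = 33.33 ms
  s3 <- moving_bar("LR", 0.3, bar_length = 160)
  expect_equal(min(s3$events$t[s3$events$x == 10]), 10 / 0.3)
})

test_that("short bars are centered perpendicular to the motion", {
  s <- moving_bar("LR", 1, bar_length = 10, geometry = c(20, 20))
  expect_equal(n_events(s), 10 * 20)
  expect_equal(sort(unique(s$events$y)), 5:14)
  expect_equal(sort(unique(s$events$x)), 0:19)
})

test_that("the eight directions map onto each other under square symmetries", {
  v <- 0.4; L <- 12; g <- c(16, 16)
  key <- function(s) {
    e <- s$events
    paste(round(e$t, 9), e$x, e$y)[order(e$t, e$x, e$y)]
  }
  lr <- moving_bar("LR", v, L, g)
  # transpose: TB is LR with x and y swapped
  tb <- moving_bar("TB", v, L, g)
  sw <- event_stream(t = lr$events$t, x = lr$events$y, y = lr$events$x,
                     p = 1, width = g[1], height = g[2])
  expect_equal(key(tb), key(sw))
  # mirror: RL is LR with x -> W-1-x
  rl <- moving_bar("RL", v, L, g)
  mi <- event_stream(t = lr$events$t, x = g[1] - 1L - lr$events$x,
                     y = lr$events$y, p = 1, width = g[1], height = g[2])
  expect_equal(key(rl), key(mi))
  # 180-degree rotation maps the TL_BR diagonal onto BR_TL
  d1 <- moving_bar("TL_BR", v, L, g)
  d2 <- moving_bar("BR_TL", v, L, g)
  rot <- event_stream(t = d1$events$t, x = g[1] - 1L - d1$events$x,
                      y = g[2] - 1L - d1$events$y, p = 1,
                      width = g[1], height = g[2])
  expect_equal(key(d2), key(rot))
})

test_that("diagonal bars move at the axis speed along each axis", {
  s <- moving_bar("TL_BR", 0.5, bar_length = 160)
  e <- s$events
  expect_equal(e$t, (e$x + e$y) / 0.5)
  # fixing a row, successive columns fire 1/v apart
  row0 <- e[e$y == 0, ]
  expect_equal(diff(row0$t[order(row0$x)]), rep(2, 159))
})

test_that("background noise is Poisson at the requested rate and seeded", {
  base <- moving_bar("LR", 0.1, bar_length = 40, geometry = c(40, 40))
  expect_identical(add_noise(base, 0, seed = 1), base)
  rate <- 5  # events/px/s
  noisy <- add_noise(base, rate, seed = 42)
  added <- n_events(noisy) - n_events(base)
  lambda <- rate * 40 * 40 * max(base$events$t) / 1000
  expect_lt(abs(added - lambda), 3 * sqrt(lambda) + 1)
  expect_identical(add_noise(base, rate, seed = 42)$events, noisy$events)
  expect_false(identical(add_noise(base, rate, seed = 7)$events, noisy$events))
  # original events all preserved
  expect_true(all(paste(base$events$t, base$events$x, base$events$y) %in%
                    paste(noisy$events$t, noisy$events$x, noisy$events$y)))
  expect_error(add_noise(base, -1, seed = 1), "non-negative")
})

test_that("invalid stimulus specs are rejected", {
  expect_error(moving_bar("LR", 0), "positive")
  expect_error(moving_bar("LR", -0.1), "positive")
  expect_error(moving_bar("LR", 0.3, bar_length = 0), "bar_length")
  expect_error(moving_bar("LR", 0.3, bar_length = 200), "bar_length")
  expect_error(moving_bar("XX", 0.3))
})

test_that("timestamp quantization snaps event times to the grid", {
  s <- moving_bar("LR", 0.3, bar_length = 8, geometry = c(8, 8),
                  quantize_ms = 1)
  expect_true(all(s$events$t == round(s$events$t)))
})
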