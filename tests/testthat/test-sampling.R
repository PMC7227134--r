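test_that("rf_size follows the linear law with clamping at the fovea", {
  sp <- grid_spec()
  expect_equal(rf_size(0, sp), 10L)
  expect_equal(rf_size(sp$d_fovea / 2, sp), 5L)
  expect_equal(rf_size(sp$d_fovea, sp), 1L)  # law gives 0; clamped to 1 px
  expect_error(rf_size(-1, sp), "d_fovea")
  expect_error(rf_size(sp$d_fovea + 1, sp), "d_fovea")
})

test_that("the reference eccentric grid has 8836 RFs on a 94x94 lattice", {
  sch <- paper_scheme()
  expect_equal(nrow(sch$rfs), 8836L)
  expect_equal(sch$lattice, c(94L, 94L))
  # foveal block: 1-px RFs covering ~10% of the 160x160 layer
  fovea <- sch$rfs[sch$rfs$ring == 0L, ]
  expect_equal(nrow(fovea), 2500L)
  expect_true(all(fovea$size == 1L))
  expect_equal(nrow(fovea) / (160 * 160), 0.0977, tolerance = 0.03)
})

test_that("eccentric grids cover every pixel and sizes shrink toward the fovea", {
  for (cfg in list(c(160, 0.10, 10), c(80, 0.10, 6), c(64, 0.20, 6),
                   c(40, 0.10, 4))) {
    sch <- build_eccentric(grid_spec(c(cfg[1], cfg[1]), cfg[2], cfg[3]))
    # full coverage: every pixel belongs to at least one RF
    expect_true(all(diff(sch$pixel_ptr) >= 1))
    # ring sizes non-increasing from periphery (outermost first) inward
    expect_true(all(diff(sch$ring_sizes) <= 0))
    expect_equal(sch$ring_sizes[1], cfg[3])
    # bounding boxes inside the geometry
    expect_true(all(sch$rfs$x0 >= 0 & sch$rfs$x0 + sch$rfs$size <= cfg[1]))
    expect_true(all(sch$rfs$y0 >= 0 & sch$rfs$y0 + sch$rfs$size <= cfg[1]))
    # consecutive rings: no coverage gap, and the multi-pixel rings overlap
    a <- sch$ring_anchors; s <- sch$ring_sizes; n <- length(a)
    expect_true(all(a[-1] <= a[-n] + s[-n]))
    wide <- which(s[-n] >= 4)
    expect_true(all(a[wide + 1] < a[wide] + s[wide]))
  }
})

test_that("size-1 RFs appear exactly in the fovea and sizes match rings", {
  sch <- paper_scheme()
  expect_true(all((sch$rfs$ring == 0L) == (sch$rfs$row >= sch$n_rings &
                                             sch$rfs$row < 94 - sch$n_rings &
                                             sch$rfs$col >= sch$n_rings &
                                             sch$rfs$col < 94 - sch$n_rings)))
  per <- sch$rfs[sch$rfs$ring > 0L, ]
  expect_equal(per$size, sch$ring_sizes[sch$n_rings - per$ring + 1L])
})

test_that("uniform grids partition the array", {
  sch <- uniform_scheme()
  expect_equal(nrow(sch$rfs), 1600L)
  expect_equal(sch$lattice, c(40L, 40L))
  # partition: every pixel in exactly one RF
  expect_true(all(diff(sch$pixel_ptr) == 1))
  one <- build_uniform(c(160, 160), 160)
  expect_equal(nrow(one$rfs), 1L)
  expect_equal(one$rfs$size, 160L)
  expect_error(build_uniform(c(160, 160), 7), "divide")
})

test_that("event-driven RF integration matches closed-form expectations", {
  sch <- paper_scheme()
  fovea_id <- sch$rfs$id[sch$rfs$ring == 0L][1]
  fx <- sch$rfs$x0[fovea_id]; fy <- sch$rfs$y0[fovea_id]
  # single event into a 1-px foveal RF (R_nf = 1) -> immediate spike
  s1 <- event_stream(t = 5, x = fx, y = fy, p = 1, width = 160, height = 160)
  tr <- rf_integrate(s1, sch)
  expect_equal(rf_train(tr, fovea_id), 5)

  big <- sch$rfs[sch$rfs$size == 10L, ][1, ]  # R_nf = 0.6 * 100 = 60
  expect_equal(big$rnf, 60)
  xs <- big$x0 + (0:59) %% 10; ys <- big$y0 + (0:59) %/% 10
  # 60 simultaneous events -> exactly one spike (60 * 1/60 = threshold)
  s60 <- event_stream(t = 0, x = xs, y = ys, p = 1, width = 160, height = 160)
  n60 <- sum(rf_integrate(s60, sch)$spikes$rf == big$id)
  expect_equal(n60, 1L)
  # 59 events, then one 5000 ms later: 59/60 * e^-5 + 1/60 < 1 -> no spike
  s59 <- event_stream(t = c(rep(0, 59), 5000), x = xs[c(1:59, 60)],
                      y = ys[c(1:59, 60)], p = 1, width = 160, height = 160)
  expect_equal(sum(rf_integrate(s59, sch)$spikes$rf == big$id), 0L)
  expect_lt(59 / 60 * exp(-5) + 1 / 60, 1)

  expect_error(rf_integrate(event_stream(width = 8, height = 8), sch),
               "geometry")
})

test_that("integration matches a brute-force 0.01 ms stepped integrator", {
  set.seed(11)
  sch <- build_uniform(c(8, 8), 2, coincidence_fraction = 0.66,
                       tau_rf_ms = 50)
  n <- 1000
  s <- event_stream(t = sort(runif(n, 0, 150)),
                    x = sample(0:7, n, TRUE), y = sample(0:7, n, TRUE),
                    p = sample(0:1, n, TRUE), width = 8, height = 8)
  got <- tabulate(rf_integrate(s, sch)$spikes$rf, nbins = nrow(sch$rfs))
  want <- rf_oracle_counts(s, sch)
  expect_true(all(abs(got - want) <= 1))

  ecc <- build_eccentric(grid_spec(c(40, 40), 0.1, 4, tau_rf_ms = 50))
  n <- 800
  s2 <- event_stream(t = sort(runif(n, 0, 100)),
                     x = sample(0:39, n, TRUE), y = sample(0:39, n, TRUE),
                     p = 1, width = 40, height = 40)
  got2 <- tabulate(rf_integrate(s2, ecc)$spikes$rf, nbins = nrow(ecc$rfs))
  want2 <- rf_oracle_counts(s2, ecc)
  expect_true(all(abs(got2 - want2) <= 1))
})

test_that("the RF layer reduces the event count", {
  s <- moving_bar("LR", 0.3)
  for (sch in list(paper_scheme(), uniform_scheme())) {
    tr <- rf_integrate(s, sch)
    expect_lt(nrow(tr$spikes), n_events(s))
    expect_false(is.unsorted(tr$spikes$t))
  }
})
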