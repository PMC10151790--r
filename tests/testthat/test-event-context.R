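p_def <- ec_params()

one_ch_stream <- function(times, channel = 1, n_channels = 4) {
  ev <- data.frame(t = as.numeric(times),
                   channel = rep(as.integer(channel), length(times)),
                   threshold_id = rep(1L, length(times)),
                   neuron_id = rep(1L, length(times)))
  event_stream(ev, 16000, n_channels)
}

test_that("time surface closed form", {
  expect_identical(time_surface_value(10, 10, 16), 1)
  expect_equal(time_surface_value(26, 10, 16), exp(-1))
  expect_equal(time_surface_value(1e9, 0, 16), 0)
  expect_error(time_surface_value(5, 10, 16), ">=")
  expect_equal(ts_params(16000)$tau_v, 16)  # fs * 1e-3
})

test_that("ec_params validates", {
  expect_error(ec_params(k = 1), ">= 2")
  expect_error(ec_params(n_samples = 3), ">= k")
  expect_error(ec_params(scales = c(4, 13)), "odd")
})

test_that("1-D context: anchor cell is 1, values in [0,1], short history skips", {
  ec <- build_ec_1d(7, c(0, 1, 3, 7), p_def)
  expect_length(ec, 32)
  expect_identical(ec[32], 1)
  expect_true(all(ec >= 0 & ec <= 1))
  expect_null(build_ec_1d(3, c(0, 1, 3), p_def))  # only 3 spikes, k = 4
})

test_that("contexts are invariant to time translation and interval scaling", {
  base <- build_ec_1d(7, c(0, 1, 3, 7), p_def)
  scaled <- build_ec_1d(14, c(0, 2, 6, 14), p_def)     # intervals (1,2,4)->(2,4,8)
  shifted <- build_ec_1d(107, c(100, 101, 103, 107), p_def)
  expect_equal(scaled, base)
  expect_equal(shifted, base)
  # property over random streams
  for (seed in 1:5) {
    s <- random_stream(80, 3, 500, seed = seed)
    s_shift <- s
    s_shift$events$t <- s_shift$events$t + 977
    b <- ec_batch(s, p_def, 1)
    b_shift <- ec_batch(s_shift, p_def, 1)
    expect_equal(b$ec, b_shift$ec)
  }
})

test_that("evenly spaced spikes give a profile that decays between spikes", {
  ec <- build_ec_1d(30, c(0, 10, 20, 30), p_def)
  # spikes land on grid points 0, 31/3, 62/3, 31; between consecutive spike
  # positions the profile is non-increasing
  spike_pos <- c(0, 31 / 3, 62 / 3, 31)
  for (j in 1:3) {
    seg <- ec[(ceiling(spike_pos[j]) + 1):(floor(spike_pos[j + 1]))]
    expect_true(all(diff(seg) <= 1e-12))
  }
  # invariant to the absolute interval length
  expect_equal(build_ec_1d(3, c(0, 1, 2, 3), p_def), ec)
})

test_that("2-D context geometry: edge fill, single-channel stream, center row", {
  s <- one_ch_stream(c(0, 2, 5, 9), channel = 1, n_channels = 6)
  ec2 <- build_ec_2d(9, 1, s, 5, p_def)
  expect_equal(dim(ec2), c(5, 32))
  expect_true(all(ec2[1:2, ] == 0))  # rows below channel 1 do not exist
  expect_true(all(ec2[4:5, ] == 0))  # channels 2,3 have no spikes
  ec1 <- build_ec_1d(9, c(0, 2, 5, 9), p_def)
  expect_equal(ec2[3, ], ec1)
})

test_that("2-D rows equal 1-D construction with the shared window", {
  set.seed(42)
  s <- random_stream(400, 9, 600, seed = 17)
  ev <- s$events
  b <- ec_batch(s, p_def, 5)
  expect_gt(b$n_built, 10)
  for (r in sample(seq_len(b$n_built), 8)) {
    at <- b$anchor$t[r]; ac <- b$anchor$channel[r]
    ref <- build_ec_2d(at, ac, s, 5, p_def)
    expect_equal(matrix(b$ec[r, ], 5, 32, byrow = TRUE), ref)
    # center window from the anchor channel
    ctimes <- ev$t[ev$channel == ac & ev$t <= at]
    sel <- ctimes[(length(ctimes) - 3):length(ctimes)]
    for (row in 1:5) {
      cc <- ac - 2 + row - 1
      if (cc < 1 || cc > 9) next
      tt <- ev$t[ev$channel == cc & ev$t <= at]
      if (length(tt) < 4) next
      expect_equal(ref[row, ], build_ec_1d(at, tt, p_def, window = c(sel[1], at)))
    }
  }
})

test_that("batch equals event-by-event construction (1-D)", {
  s <- random_stream(150, 4, 400, seed = 31)
  b <- ec_batch(s, p_def, 1)
  built <- 0
  for (i in seq_len(nrow(s$events))) {
    tt <- s$events$t[s$events$channel == s$events$channel[i] &
                       s$events$t <= s$events$t[i]]
    ref <- build_ec_1d(s$events$t[i], tt, p_def)
    if (!is.null(ref)) {
      built <- built + 1
      expect_equal(b$ec[built, ], ref)
    }
  }
  expect_equal(b$n_built, built)
  expect_equal(b$n_skipped, nrow(s$events) - built)
})

test_that("batch counting rules", {
  expect_equal(ec_batch(one_ch_stream(numeric(0)), p_def, 1)$n_built, 0)
  s1 <- one_ch_stream(c(0, 3, 7, 12))  # exactly k events in one channel
  b1 <- ec_batch(s1, p_def, 1)
  expect_equal(b1$n_built, 1)
  expect_equal(b1$anchor$t, 12)
  # every event with full history builds one context
  times <- cumsum(rep(2, 20))
  b2 <- ec_batch(one_ch_stream(times), p_def, 1)
  expect_equal(b2$n_built, 20 - 3)
})

test_that("all built contexts are bounded with unit anchors (1-D)", {
  s <- random_stream(300, 5, 800, seed = 77)
  b <- ec_batch(s, p_def, 1)
  expect_true(all(b$ec >= 0 & b$ec <= 1))
  expect_true(all(b$ec[, 32] == 1))
})
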