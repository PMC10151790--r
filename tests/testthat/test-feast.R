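test_that("similarity is cosine and rejects degenerate input", {
  v <- c(0.2, 0.5, 0.1, 1)
  expect_equal(similarity(v, 3.7 * v), 1)
  expect_equal(similarity(c(1, 0, 0, 0), c(0, 0, 1, 0)), 0)
  set.seed(8)
  for (i in 1:10) {
    a <- runif(16); b <- runif(16)
    expect_equal(similarity(a, b), naive_cosine(a, b))
  }
  expect_error(similarity(rep(0, 4), v), "zero-norm")
  expect_error(similarity(v, c(1, 2)), "mismatch")
})

test_that("learn_step applies both threshold rules literally", {
  p <- feast_params(m = 3, seed = 1)
  set.seed(2)
  bank <- feast_init(p, 8)
  # rule 2: unreachable thresholds -> no winner, all drop by delta_e
  bank$Vth <- rep(1, 3)
  ec <- runif(8)
  st <- learn_step(ec, bank, p)
  expect_true(is.na(st$winner))
  expect_equal(st$bank$Vth, rep(1 - p$delta_e, 3))
  expect_equal(st$bank$W, bank$W)
  # rule 1 + weight fixed point: ec equal to a neuron's weights
  bank$Vth <- c(0.5, 0.5, 0.5)
  st2 <- learn_step(bank$W[2, ], bank, p)
  expect_equal(st2$winner, 2)
  expect_equal(st2$bank$W[2, ], bank$W[2, ])
  expect_equal(st2$bank$Vth[2], 0.5 + p$delta_i)
  expect_equal(st2$bank$Vth[c(1, 3)], bank$Vth[c(1, 3)])
})

test_that("learn_step and extraction match the brute-force reference", {
  p <- feast_params(m = 6, seed = 3)
  set.seed(33)
  for (case in 1:200) {
    W <- matrix(runif(6 * 10), 6, 10)
    Vth <- runif(6)
    ec <- runif(10)
    bank <- structure(list(W = W, Vth = Vth, params = p, scale = 1L,
                           trained = TRUE),
                      class = "feast_bank")
    st <- learn_step(ec, bank, p)
    ref <- naive_learn_step(ec, W, Vth, p$delta_i, p$delta_e, p$eta)
    expect_identical(is.na(st$winner), is.na(ref$winner))
    if (!is.na(ref$winner)) expect_equal(st$winner, ref$winner)
    expect_equal(st$bank$W, ref$W)
    expect_equal(st$bank$Vth, ref$Vth)
    expect_equal(unname(strfeast:::ec_winners(matrix(ec, 1), W)), naive_extract_winner(ec, W))
  }
})

test_that("training on a fixed batch equals iterated learn_step", {
  p <- feast_params(m = 4, epochs = 3, seed = 5, tol = 0)
  set.seed(99)
  ecs <- matrix(runif(30 * 8), 30, 8)
  got <- feast_train(ecs, p)
  ref <- feast_init(p, 8)       # reseeds exactly as feast_train does
  orders <- vapply(1:3, function(e) sample.int(30), integer(30))
  for (e in 1:3) {
    for (i in orders[, e]) {
      st <- learn_step(ecs[i, ], ref, p)
      ref <- st$bank
    }
  }
  expect_equal(got$W, ref$W)
  expect_equal(got$Vth, ref$Vth)
})

test_that("epochs = 0 returns the seeded initialisation", {
  p <- feast_params(m = 4, epochs = 0, seed = 11)
  ecs <- matrix(runif(20 * 6), 20, 6)
  b <- feast_train(ecs, p)
  expect_false(b$trained)
  expect_equal(b, feast_init(p, 6))
})

test_that("a batch of identical contexts pulls one neuron onto it", {
  # with eta = 0.001 and rate balancing, each of the 2 neurons takes ~half of
  # the 15000 presentations; (1-eta)^7500 < 1e-3 of the initialisation remains
  ec <- c(0.1, 0.4, 0.05, 0.8, 1)
  ecs <- matrix(ec, 1500, 5, byrow = TRUE)
  b <- feast_train(ecs, feast_params(m = 2, epochs = 10, seed = 7, tol = 0))
  best <- max(apply(b$W, 1, function(w) similarity(ec, w)))
  expect_gt(best, 0.999)
})

test_that("prototype recovery with jitter finds a one-to-one matching", {
  protos <- make_prototypes(4, 24, seed = 13)
  samp <- jitter_samples(protos, 300, 0.05, seed = 14)
  b <- feast_train(samp$x, feast_params(m = 4, epochs = 10, seed = 15, tol = 0))
  sim <- outer(seq_len(4), seq_len(4),
               Vectorize(function(i, j) similarity(protos[i, ], b$W[j, ])))
  # greedy one-to-one assignment
  pairs <- integer(4)
  s <- sim
  for (r in 1:4) {
    ij <- arrayInd(which.max(s), dim(s))
    pairs[ij[1]] <- ij[2]
    s[ij[1], ] <- -Inf
    s[, ij[2]] <- -Inf
  }
  expect_equal(sort(pairs), 1:4)
  expect_true(all(sim[cbind(1:4, pairs)] > 0.95))
})

test_that("adaptive thresholds balance firing rates", {
  protos <- make_prototypes(4, 24, seed = 23)
  samp <- jitter_samples(protos, 100, 0.05, seed = 24)
  b <- feast_train(samp$x, feast_params(m = 4, epochs = 10, seed = 25, tol = 0))
  wins <- b$log$wins[, ncol(b$log$wins)]
  expect_lt(max(wins) / max(1, min(wins)), 3)
})

test_that("training respects clamping and convex-hull invariants", {
  set.seed(44)
  ecs <- matrix(runif(200 * 8), 200, 8)
  p <- feast_params(m = 5, epochs = 6, seed = 45, tol = 0)
  b0 <- feast_init(p, 8)
  b <- feast_train(ecs, p)
  expect_true(all(b$Vth >= 0 & b$Vth <= 1))
  lo <- min(min(b0$W), min(ecs))
  hi <- max(max(b0$W), max(ecs))
  expect_true(all(b$W >= lo - 1e-12 & b$W <= hi + 1e-12))
  # mean |dW| settles after the first epoch (5% shuffle-noise tolerance)
  dw <- b$log$mean_dw
  expect_true(all(diff(dw[-1]) <= 0.05 * dw[2]))
})

test_that("training is deterministic in the seed and warns when m > n", {
  ecs <- matrix(runif(40 * 6), 40, 6)
  p <- feast_params(m = 4, epochs = 4, seed = 77, tol = 0)
  b1 <- feast_train(ecs, p)
  b2 <- feast_train(ecs, p)
  expect_identical(b1$W, b2$W)
  expect_identical(b1$Vth, b2$Vth)
  expect_warning(feast_train(ecs[1:3, ], p), "underdetermined")
})

test_that("extraction ignores thresholds and emits one spike per bank", {
  p_ec <- ec_params()
  s <- random_stream(200, 6, 500, seed = 55)
  batch <- ec_batch(s, p_ec, 1)
  p <- feast_params(m = 4, epochs = 2, seed = 56, tol = 0)
  bank <- feast_train(batch, p)
  fm <- feast_extract(s, bank, p_ec)[[1]]
  expect_equal(nrow(fm$events), batch$n_built)
  expect_true(all(fm$events$winner_id %in% 1:4))
  # winners equal brute force even where similarity < Vth
  for (r in sample(batch$n_built, 10)) {
    expect_equal(fm$events$winner_id[r],
                 naive_extract_winner(batch$ec[r, ], bank$W))
  }
  expect_error(feast_extract(s, feast_init(p, 32), p_ec), "untrained")
})

test_that("one valid event against several banks yields one spike per bank", {
  s <- event_stream(
    data.frame(t = c(0, 2, 5, 9), channel = 3L, threshold_id = 1L, neuron_id = 1L),
    16000, 5)
  p_ec <- ec_params(scales = c(3, 5))
  p <- feast_params(m = 2, epochs = 1, seed = 6, tol = 0)
  banks <- lapply(c(1, 3, 5), function(sc) {
    suppressWarnings(feast_train(ec_batch(s, p_ec, sc), p, scale = sc))
  })
  fms <- feast_extract(s, banks, p_ec)
  expect_length(fms, 3)
  for (fm in fms) expect_equal(nrow(fm$events), 1)
})

test_that("bank serialization round-trips exactly", {
  ecs <- matrix(runif(50 * 8), 50, 8)
  b <- feast_train(ecs, feast_params(m = 3, epochs = 2, seed = 9, tol = 0))
  path <- file.path(withr::local_tempdir(), "bank")
  write_bank(b, path)
  back <- read_bank(path)
  expect_identical(back$W, b$W)
  expect_identical(back$Vth, b$Vth)
  expect_identical(back$scale, b$scale)
  expect_true(back$trained)
})
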