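test_that("stationary Poisson counts have the prescribed mean and dispersion", {
  counts <- vapply(1:1000, function(s)
    n_spikes(generate_background(rate_model("stationary", rate = 15),
                                 n_neurons = 1, duration = 1000, seed = s)), 0)
  se <- sqrt(15 / 1000)
  expect_lt(abs(mean(counts) - 15), 3 * se)
  expect_gt(var(counts) / mean(counts), 0.8)   # Poisson dispersion
  expect_lt(var(counts) / mean(counts), 1.2)
})

test_that("the coherent rate step integrates to 15 expected spikes", {
  # 10 Hz on 900 ms plus 60 Hz on 100 ms: 0.9*10 + 0.1*60 = 15
  counts <- vapply(1:1000, function(s)
    n_spikes(generate_background(rate_model("coherent_step"),
                                 n_neurons = 1, duration = 1000, seed = s)), 0)
  expect_lt(abs(mean(counts) - 15), 3 * sqrt(15 / 1000))
  # spikes concentrate in the step: rate in [600, 700) is 6x the baseline
  st <- generate_background(rate_model("coherent_step"), 50, 1000, seed = 1)
  tt <- unlist(st$trains)
  n_step <- sum(tt >= 600 & tt < 700)
  n_base <- sum(tt < 600 | tt >= 700)
  expect_gt(n_step / 100, 3 * n_base / 900)
})

test_that("zero-duration simulations are empty", {
  st <- generate_background(rate_model("stationary", rate = 20), 5, 0, seed = 1)
  expect_equal(n_spikes(st), 0)
})

test_that("heterogeneous rates increase linearly across neurons", {
  st <- generate_background(rate_model("heterogeneous"), 100, 20000, seed = 2)
  # neuron 1 fires at 5 Hz, neuron 100 at 24.8 Hz
  n1 <- length(st$trains[[1]]); n100 <- length(st$trains[[100]])
  expect_lt(abs(n1 - 100), 3 * sqrt(100))
  expect_lt(abs(n100 - 496), 3 * sqrt(496))
})

test_that("the propagation model shows sequential group rate jumps", {
  m <- rate_model("propagation")
  expect_error(generate_background(m, 50, 1000), "n_groups")
  counts <- vapply(1:300, function(s) {
    st <- generate_background(m, 100, 1000, seed = s)
    length(st$trains[[1]])  # group-1 neuron
  }, 0)
  # baseline 14 Hz on 990 ms + 100 Hz on two 5 ms jumps = 14.86 expected
  expect_lt(abs(mean(counts) - 14.86), 3 * sqrt(14.86 / 300))
  # group 3 jumps 10 ms after group 1
  st <- generate_background(m, 100, 1000, seed = 7)
  g3 <- unlist(st$trains[11:15])
  expect_gt(sum(g3 >= 60 & g3 < 65) + sum(g3 >= 560 & g3 < 565), 0)
})

test_that("pattern injection places deterministic lagged sequences", {
  bg <- generate_background(rate_model("stationary", rate = 5), 10, 500, seed = 3)
  inj <- inject_stp(bg, z = 3, c = 1, lag = 5, onsets = 100)
  for (i in 1:3)
    expect_true((100 + (i - 1) * 5) %in% inj$trains$trains[[i]])
  expect_equal(inj$truth$lags_ms, c(0, 5, 10))
  # conservation: every ground-truth spike is present in the output
  inj2 <- inject_stp(bg, z = 6, c = 4, lag = 5, seed = 4)
  for (i in seq_along(inj2$truth$neurons)) {
    nrn <- inj2$truth$neurons[i]
    expect_true(all((inj2$truth$onsets + inj2$truth$lags_ms[i]) %in%
                      inj2$trains$trains[[nrn]]))
  }
  # a 10-spike, 5 ms-lag pattern spans 45 ms and fits a 50 ms window
  inj3 <- inject_stp(bg, z = 10, c = 2, lag = 5, seed = 5)
  expect_true(all(inj3$truth$lags_ms <= 45))
  expect_error(inject_stp(bg, z = 3, c = 2, lag = 300), "too short")
})

test_that("multiple injections draw distinct neuron sets", {
  bg <- generate_background(rate_model("stationary", rate = 10), 20, 1000,
                            seed = 6)
  specs <- list(list(z = 5, c = 10), list(z = 5, c = 10))
  res <- inject_multiple(bg, specs, seed = 7)
  expect_length(res$truths, 2L)
  expect_false(identical(sort(res$truths[[1]]$neurons),
                         sort(res$truths[[2]]$neurons)))
  # forced identical sets are rejected
  bad <- list(list(z = 3, c = 2, neurons = 1:3),
              list(z = 3, c = 2, neurons = 1:3))
  expect_error(inject_multiple(bg, bad, seed = 8), "identical")
  # overlapping but distinct sets are allowed
  ok <- list(list(z = 3, c = 2, neurons = 1:3),
             list(z = 3, c = 2, neurons = 2:4))
  expect_length(inject_multiple(bg, ok, seed = 9)$truths, 2L)
})
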