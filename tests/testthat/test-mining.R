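test_that("brute-force closure enumeration matches hand enumeration", {
  ctx <- toy_context()
  bf <- brute_force_closed(ctx, min_support = 1)
  got <- concepts_df(bf)
  want <- data.frame(z = c(1L, 2L, 2L), c = c(3L, 2L, 1L),
                     intent = c("0", "0,1", "0,2"),
                     extent = c("0,1,2", "0,1", "2"))
  expect_equal(got, want[order(want$intent), ], ignore_attr = TRUE)
  # with min_support 2 the singleton-extent concept disappears
  expect_equal(length(brute_force_closed(ctx, min_support = 2)), 2L)

  single <- spade:::context_from_incidence(list(c(0L, 2L)), 3L)
  bs <- brute_force_closed(single, min_support = 1)
  expect_equal(concepts_df(bs)$intent, "0,2")

  empty <- spade:::context_from_incidence(list(integer(0), integer(0)), 3L)
  expect_equal(length(brute_force_closed(empty, min_support = 2)), 0L)
  big <- spade:::context_from_incidence(rep(list(0L), 21L), 2L)
  expect_error(brute_force_closed(big), "20")
})

test_that("a uniquely supported attribute pair yields exactly one concept", {
  # {a,b} occurs in windows 1 and 2 and nowhere else
  ctx <- spade:::context_from_incidence(
    list(c(2L), c(0L, 1L), c(0L, 1L), c(3L)), 4L)
  m <- mine_closed_frequent(ctx, mining_config(min_support = 2, min_size = 1))
  df <- concepts_df(m)
  expect_true(any(df$intent == "0,1" & df$extent == "1,2"))
  expect_equal(sum(df$intent == "0,1"), 1L)
})

test_that("miner equals the brute-force oracle on random contexts", {
  set.seed(99)
  for (rep in 1:10) {
    ctx <- random_context(sample(2:8, 1), sample(4:12, 1))
    for (ms in 1:2) {
      a <- brute_force_closed(ctx, min_support = ms)
      b <- mine_closed_frequent(ctx, mining_config(min_support = ms, min_size = 1))
      expect_equal(concepts_df(a), concepts_df(b))
    }
  }
})

test_that("mining is monotone in support and size thresholds", {
  set.seed(123)
  for (rep in 1:5) {
    ctx <- random_context(8, 12)
    key <- function(m) paste(concepts_df(m)$intent, concepts_df(m)$extent)
    prev <- mine_closed_frequent(ctx, mining_config(1, 1, 1, 1))
    for (ms in 2:3) {
      cur <- mine_closed_frequent(ctx, mining_config(ms, 1, 1, 1))
      expect_true(all(key(cur) %in% key(prev)))
      prev <- cur
    }
    small <- mine_closed_frequent(ctx, mining_config(2, 1, 1, 1))
    large <- mine_closed_frequent(ctx, mining_config(2, 3, 1, 1))
    expect_true(all(key(large) %in% key(small)))
  }
})

test_that("single-stage mining equals mine-then-filter", {
  set.seed(321)
  for (rep in 1:5) {
    ctx <- random_context(10, 14, density = 0.4)
    two <- apply_pattern_filter(
      mine_closed_frequent(ctx, mining_config(2, 2, 3, 3)), 3, 3)
    one <- apply_pattern_filter(
      mine_closed_frequent(ctx, mining_config(3, 3, 3, 3)), 3, 3)
    expect_equal(concepts_df(two), concepts_df(one))
  }
})

test_that("every mined concept satisfies the closure invariant", {
  st <- generate_background(rate_model("stationary", rate = 60),
                            n_neurons = 6, duration = 300, seed = 5)
  ctx <- build_context(bin_spikes(st, 1), 20)
  m <- mine_closed_frequent(ctx, mining_config(2, 2))
  expect_gt(length(m), 10)
  for (i in seq_len(min(length(m), 50))) {
    cc <- concept_at(m, i)
    expect_identical(derive_intent(ctx, cc$extent), cc$intent)
    expect_identical(derive_extent(ctx, cc$intent), sort(cc$extent))
  }
})

test_that("the signature filter drops small and shifted patterns", {
  ctx <- fig1_context()
  m <- mine_closed_frequent(ctx, mining_config(1, 1))
  kept <- apply_pattern_filter(m, z_min = 3, c_min = 2)
  df <- concepts_df(kept)
  # the embedded pattern survives exactly once; its shifted copy does not
  expect_true(paste(fig1_H(), collapse = ",") %in% df$intent)
  expect_false(paste(fig1_Q(), collapse = ",") %in% df$intent)
  # boundary inclusion and sub-threshold rejection
  expect_true(all(df$z >= 3 & df$c >= 2))
  strict <- apply_pattern_filter(m, z_min = 3, c_min = 3)
  expect_false(paste(fig1_H(), collapse = ",") %in% concepts_df(strict)$intent)
})

test_that("window-edge truncated views of a chain are deduplicated", {
  # quiet background + a 5-spike chain injected 3 times: the full chain's
  # trailing-edge views (4-, 3-spike suffixes at shifted windows) must not
  # survive as separate patterns
  bg <- generate_background(rate_model("stationary", rate = 2),
                            n_neurons = 8, duration = 600, seed = 17)
  inj <- inject_stp(bg, z = 5, c = 3, lag = 5, onsets = c(100, 280, 460))
  ctx <- build_context(bin_spikes(inj$trains, 1), 30)
  fl <- apply_pattern_filter(mine_closed_frequent(ctx, mining_config(3, 3)), 3, 3)
  pats <- as_patterns(fl)
  keys <- vapply(pats, function(p) paste(p$neurons, p$lags, collapse = ";"), "")
  expect_true(paste(1:5, seq(0, 20, 5), collapse = ";") %in% keys)
  expect_false(paste(2:5, seq(0, 15, 5), collapse = ";") %in% keys)
  expect_false(paste(3:5, seq(0, 10, 5), collapse = ";") %in% keys)
})

test_that("concept ordering is deterministic", {
  set.seed(77)
  ctx <- random_context(8, 10)
  m1 <- mine_closed_frequent(ctx, mining_config(1, 1))
  m2 <- mine_closed_frequent(ctx, mining_config(1, 1))
  expect_identical(m1$intent, m2$intent)
  sc <- as.numeric(m1$z) * as.numeric(m1$c)
  expect_true(all(diff(sc) <= 0))
})
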