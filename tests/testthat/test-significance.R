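# small concept containers with prescribed signatures, for PSF unit tests
fake_concepts <- function(sig) {
  ctx <- list(K = 10L, dt = 1, n_neurons = 8L)
  intents <- lapply(seq_len(nrow(sig)), function(i)
    as.integer((seq_len(sig$z[i]) - 1L) * 10L))   # lags 0 on distinct neurons
  extents <- lapply(seq_len(nrow(sig)), function(i)
    as.integer(seq_len(sig$c[i]) * 7L))
  spade:::new_concepts(intents, extents, ctx)
}

test_that("spectrum p-values are surrogate fractions with a resolution floor", {
  sp <- spectrum_from_counts(z = c(3L, 4L), c = c(3L, 5L),
                             count = c(30L, 1L), n_surrogates = 1000L)
  expect_equal(spectrum_pvalue(sp, 3, 3), 0.03)
  expect_equal(spectrum_pvalue(sp, 4, 5), 0.001)
  expect_equal(spectrum_pvalue(sp, 9, 9), 0)   # never observed
})

test_that("cumulative spectra are non-increasing in the occurrence count", {
  st <- generate_background(rate_model("stationary", rate = 60),
                            n_neurons = 8, duration = 400, seed = 21)
  expect_warning(
    sp <- estimate_spectrum(st, K = 20, cfg = mining_config(z_min = 2, c_min = 2),
                            n_surrogates = 40, seed = 22),
    "resolution")
  expect_s3_class(sp, "pattern_spectrum")
  for (zz in names(sp$maxc)) {
    z <- as.integer(zz)
    p <- spectrum_pvalue(sp, rep(z, 8), 2:9)
    expect_true(all(diff(p) <= 0))
  }
  # deterministic given the master seed (order-invariant per-surrogate seeds)
  sp2 <- suppressWarnings(
    estimate_spectrum(st, K = 20, cfg = mining_config(z_min = 2, c_min = 2),
                      n_surrogates = 40, seed = 22))
  expect_identical(sp$maxc, sp2$maxc)
})

test_that("spectrum cache files round-trip", {
  st <- generate_background(rate_model("stationary", rate = 50),
                            n_neurons = 6, duration = 300, seed = 23)
  sp <- suppressWarnings(
    estimate_spectrum(st, K = 20, cfg = mining_config(z_min = 2, c_min = 2),
                      n_surrogates = 25, seed = 24))
  f <- withr::local_tempfile(fileext = ".json")
  write_spectrum(sp, f)
  back <- read_spectrum(f)
  expect_equal(back$maxc, sp$maxc)
  expect_equal(back$n_surrogates, sp$n_surrogates)
  expect_equal(spectrum_pvalue(back, 2, 2), spectrum_pvalue(sp, 2, 2))
})

test_that("PSF applies Benjamini-Hochberg over distinct signatures", {
  conc <- fake_concepts(data.frame(z = c(3L, 3L, 4L), c = c(3L, 4L, 3L)))
  # p-values 0.002, 0.006, 0.04 at alpha 0.01: BH keeps the two smallest
  sp <- spectrum_from_counts(z = c(3L, 3L, 4L), c = c(3L, 4L, 3L),
                             count = c(2L, 6L, 40L), n_surrogates = 1000L)
  res <- psf(conc, sp, alpha = 0.01)
  expect_equal(res$signatures$significant,
               res$signatures$p %in% c(0.002, 0.006))
  expect_equal(length(res$patterns), 2L)
  expect_equal(res$p_cut, 0.006)

  # all-zero p-values keep everything
  sp0 <- spectrum_from_counts(3L, 3L, 0L, 1000L)
  expect_equal(length(psf(conc, sp0, 0.01)$patterns), 3L)

  # single signature: BH reduces to plain alpha
  one <- fake_concepts(data.frame(z = 3L, c = 3L))
  sp1 <- spectrum_from_counts(3L, 3L, 20L, 1000L)  # p = 0.02
  expect_equal(length(psf(one, sp1, 0.01)$patterns), 0L)

  # signatures below the mined domain have no spectrum entry
  low <- fake_concepts(data.frame(z = 2L, c = 5L))
  expect_error(psf(low, sp, 0.01), "\\(2, 5\\)")
})

test_that("pattern overlap is computed by best shift alignment", {
  A <- make_stp(1:5, seq(0, 20, 5))
  expect_equal(spade:::pattern_overlap(A, make_stp(2:4, seq(0, 10, 5))), 3L)
  expect_equal(spade:::pattern_overlap(A, make_stp(6:7, c(0, 5))), 0L)
  # partial overlap: two of three spikes align at one shift
  B <- make_stp(c(2, 3, 6), c(0, 5, 10))
  expect_equal(spade:::pattern_overlap(A, B), 2L)
})

test_that("PSR retests conditional signatures exactly as prescribed", {
  sp <- spectrum_from_counts(z = c(3L, 3L), c = c(3L, 4L),
                             count = c(0L, 3L), n_surrogates = 1000L)
  p_cut <- 0.004  # signatures with spectrum p <= p_cut count as significant
  # B (z=3) contained in A (z=5): A tested at (5-3+0, c_A) = (2, .) which is
  # below the spectrum domain -> non-significant; B tested at
  # (3, c_B - c_A + 2)
  A <- make_stp(1:5, seq(0, 20, 5), occurrences = c(0L, 100L, 200L))
  B <- make_stp(1:3, seq(0, 10, 5), occurrences = c(0L, 60L, 100L, 200L))
  # c_B|A = 4 - 3 + 2 = 3, p(3,3) = 0 -> only B conditionally significant
  out <- psr(list(A, B), sp, psr_config(0, 2), p_cut = p_cut)
  expect_equal(length(out), 1L)
  expect_equal(out[[1]]$z, 3L)
  expect_match(attr(out, "notes"), "\\(2, 3\\)", all = FALSE)

  # neither significant: the larger z*c score wins (A: 15 > B: 12)
  sp2 <- spectrum_from_counts(3L, 3L, 900L, 1000L)  # p(3,3) = 0.9
  B2 <- make_stp(1:3, seq(0, 10, 5),
                 occurrences = c(0L, 60L, 100L, 200L))  # c_B|A = 3, p large
  out2 <- psr(list(A, B2), sp2, psr_config(0, 2), p_cut = 0.004)
  expect_equal(length(out2), 1L)
  expect_equal(out2[[1]]$z, 5L)

  # disjoint patterns pass through untouched
  C <- make_stp(7:9, seq(0, 10, 5))
  out3 <- psr(list(A, C), sp2, psr_config(0, 2), p_cut = 0.004)
  expect_equal(length(out3), 2L)

  # PSR never increases the pattern count
  expect_lte(length(psr(list(A, B, C), sp, psr_config(0, 2), 0.004)), 3L)
})

test_that("partial overlaps are conditioned on the aligned intersection", {
  # A and B share 2 aligned spikes; both tested at (z - 2 + h, c)
  A <- make_stp(1:4, seq(0, 15, 5), occurrences = c(0L, 50L, 100L))
  B <- make_stp(c(3, 4, 6, 7), seq(0, 15, 5), occurrences = c(10L, 60L, 110L))
  # p(2, 3) is outside the domain -> both non-significant -> tie on z*c = 12
  sp <- spectrum_from_counts(3L, 3L, 900L, 1000L)
  out <- psr(list(A, B), sp, psr_config(0, 2), p_cut = 0.004)
  expect_equal(length(out), 1L)   # tie broken deterministically
  expect_equal(out[[1]]$neurons, 1:4)  # lexicographically smaller pattern
})

test_that("the full pipeline recovers an injected pattern reproducibly", {
  bg <- generate_background(rate_model("stationary", rate = 25),
                            n_neurons = 15, duration = 800, seed = 31)
  inj <- inject_stp(bg, z = 5, c = 8, lag = 5, seed = 32)
  res <- suppressWarnings(
    spade(inj$trains, winlen = 40, method = "psf-psr", n_surrogates = 60,
          seed = 33))
  df <- as.data.frame(res)
  expect_equal(nrow(df), 1L)
  expect_equal(df$neurons, "1,2,3,4,5")
  expect_equal(df$lags_ms, "0,5,10,15,20")
  # byte-identical reports for identical seeds
  res2 <- suppressWarnings(
    spade(inj$trains, winlen = 40, method = "psf-psr", n_surrogates = 60,
          seed = 33))
  expect_identical(spade_report(res), spade_report(res2))
})

test_that("stability branch of the pipeline runs end to end", {
  bg <- generate_background(rate_model("stationary", rate = 25),
                            n_neurons = 12, duration = 600, seed = 41)
  inj <- inject_stp(bg, z = 5, c = 8, lag = 5, seed = 42)
  res <- suppressWarnings(
    spade(inj$trains, winlen = 40, method = "stab-comb", Z = 300, seed = 43))
  expect_true(res$counts$final >= 1)
  key <- vapply(res$patterns, function(p) paste(p$neurons, collapse = ","), "")
  expect_true("1,2,3,4,5" %in% key)
  f <- withr::local_tempfile(fileext = ".json")
  spade_report(res, f)
  rep <- jsonlite::fromJSON(f)
  expect_equal(rep$indexing, "0-based")
  expect_equal(rep$counts$final, res$counts$final)
})
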