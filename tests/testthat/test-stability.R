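test_that("exact stability reproduces hand-enumerated values", {
  ctx <- toy_context()
  c12 <- list(intent = c(0L, 1L), extent = c(0L, 1L))
  c123 <- list(intent = 0L, extent = c(0L, 1L, 2L))
  expect_equal(stability_exact(c12, ctx, "intensional")$value, 3 / 4)
  expect_equal(stability_exact(c123, ctx, "intensional")$value, 3 / 8)
  expect_equal(stability_exact(c12, ctx, "extensional")$value, 1 / 2)
  # singleton extent: only the singleton subset reproduces the intent
  single <- spade:::context_from_incidence(list(0L, 1L), 2L)
  expect_equal(stability_exact(list(intent = 0L, extent = 0L),
                               single, "intensional")$value, 1 / 2)
})

test_that("the all-attributes concept has stability one under any Z", {
  # every object holds every attribute: each subset reproduces the closure
  ctx <- spade:::context_from_incidence(rep(list(c(0L, 1L, 2L)), 4L), 3L)
  cc <- list(intent = c(0L, 1L, 2L), extent = 0:3)
  for (Z in c(1L, 7L, 100L))
    expect_equal(stability_approx(cc, ctx, "intensional", Z = Z, seed = 1)$value, 1)
})

test_that("small concepts are enumerated exactly by the approximation", {
  ctx <- toy_context()
  cc <- list(intent = c(0L, 1L), extent = c(0L, 1L))
  a <- stability_approx(cc, ctx, "intensional", Z = 500, seed = 5)
  e <- stability_exact(cc, ctx, "intensional")
  expect_true(a$enumerated)
  expect_identical(a$value, e$value)  # bit-for-bit, zero approximation error
})

# 14-object context engineered so sigma(A, B) = 3/4 for the top concept:
# subsets avoiding both two-attribute objects derive to {a,b,c}, not {a,b}
sampled_ctx <- function() {
  spade:::context_from_incidence(
    c(rep(list(c(0L, 1L)), 2L), rep(list(c(0L, 1L, 2L)), 12L)), 3L)
}

test_that("Monte-Carlo stability is calibrated against the exact value", {
  ctx <- sampled_ctx()
  cc <- list(intent = c(0L, 1L), extent = 0:13)
  expect_equal(stability_exact(cc, ctx, "intensional")$value, 3 / 4)
  a <- stability_approx(cc, ctx, "intensional", Z = 10000, seed = 2)
  expect_false(a$enumerated)  # 2^14 subsets exceed Z
  ci99 <- qnorm(0.995) * sqrt(0.75 * 0.25 / 10000)
  expect_lt(abs(a$value - 0.75), ci99)

  # coverage of the 99% binomial interval over repeated Z = 500 estimates
  hits <- vapply(1:200, function(s) {
    v <- stability_approx(cc, ctx, "intensional", Z = 500, seed = s)$value
    abs(v - 0.75) <= qnorm(0.995) * sqrt(0.75 * 0.25 / 500)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("intensional stability ignores intent size for fixed extent structure", {
  ctx1 <- toy_context()
  # duplicate every attribute: same extent structure, doubled intents
  ctx2 <- spade:::context_from_incidence(
    list(c(0L, 1L, 3L, 4L), c(0L, 1L, 3L, 4L), c(0L, 2L, 3L, 5L)), 6L)
  s1 <- stability_exact(list(intent = c(0L, 1L), extent = c(0L, 1L)),
                        ctx1, "intensional")$value
  s2 <- stability_exact(list(intent = c(0L, 1L, 3L, 4L), extent = c(0L, 1L)),
                        ctx2, "intensional")$value
  expect_identical(s1, s2)
})

test_that("exact stability refuses oversized base sets", {
  ctx <- spade:::context_from_incidence(rep(list(0L), 30L), 1L)
  expect_error(stability_exact(list(intent = 0L, extent = 0:29),
                               ctx, "intensional"), "approx")
})

test_that("the null quantile uses the conservative ceiling-rank convention", {
  values <- 0.1 * (1:1000)
  # corrected level 0.001: fewer than one expected exceedance -> maximum
  expect_equal(spade:::null_quantile(values, 0.001), 100.0)
  expect_equal(spade:::null_quantile(values, 0.005), 99.6)  # 5th largest
  expect_equal(spade:::null_quantile(values, 0.5), 50.1)
})

test_that("surrogate-derived thresholds warn when the null sample is thin", {
  st <- generate_background(rate_model("stationary", rate = 30),
                            n_neurons = 5, duration = 300, seed = 3)
  expect_warning(
    th <- stability_threshold(st, K = 20, kind = "intensional", alpha = 0.05,
                              cfg = mining_config(z_min = 2, c_min = 2),
                              seed = 4),
    "unreliable")
  expect_true(as.numeric(th) >= 0 && as.numeric(th) <= 1)
  expect_equal(attr(th, "correction"), "bonferroni")
})

test_that("stability filtering applies strict thresholds per mode", {
  ctx <- toy_context()
  conc <- mine_closed_frequent(ctx, mining_config(2, 1))
  conc <- compute_stability(conc, ctx, "intensional", Z = 500, seed = 1)
  conc <- compute_stability(conc, ctx, "extensional", Z = 500, seed = 2)
  # concept ({1,2},{a,b}): sigma_int 0.75, sigma_ext 0.5
  i <- which(vapply(conc$intent, function(v) identical(v, c(0L, 1L)), TRUE))
  expect_equal(conc$sigma_int[i], 0.75)
  th <- list(theta_int = 0.6, theta_ext = 0.6)
  expect_true(i %in% match(
    vapply(filter_stable(conc, th, "intensional")$intent, paste, "", collapse = ","),
    vapply(conc$intent, paste, "", collapse = ",")))
  # strictly-greater convention at the boundary
  expect_length(filter_stable(conc, list(theta_int = 0.75), "intensional"), 0)
  # combined keeps on either measure
  expect_equal(length(filter_stable(conc, list(theta_int = 0.9, theta_ext = 0.45),
                                    "combined")),
               sum(conc$sigma_ext > 0.45))
  expect_error(filter_stable(conc, list(theta_int = 0.5), "combined"), "theta_ext")
  plain <- mine_closed_frequent(ctx, mining_config(2, 1))
  expect_error(filter_stable(plain, th, "intensional"), "annotations")
})
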