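#' Conceptual stability of a formal concept
#'
#' Intensional stability of a concept `(A, B)` is the fraction of subsets
#' `C` of the extent `A` whose derived attribute set equals the intent:
#' `sigma(A, B) = |{C subset of A : C' = B}| / 2^|A|`. It measures how robust
#' the pattern is to removing occurrences: a stable intent is recovered from
#' most sub-collections of its windows. Extensional stability exchanges the
#' roles of extent and intent (`C` ranges over subsets of `B`, derived object
#' sets are compared with `A`) and measures robustness to removing spikes.
#'
#' `stability_exact()` enumerates all subsets and is limited to base sets of
#' at most 25 elements. `stability_approx()` is the Monte-Carlo version:
#' `Z` subsets are drawn uniformly from the power set (each element included
#' independently with probability 1/2) and the denominator is replaced by
#' `Z`. Whenever `2^|base| <= Z` the approximation enumerates all subsets
#' instead of sampling, so small concepts get the exact value bit-for-bit
#' (and zero approximation error) at no extra cost.
#'
#' @param concept a list with `intent` and `extent` (0-based ids), e.g. from
#'   [concept_at()].
#' @param ctx the [build_context()] the concept was mined from.
#' @param kind `"intensional"` or `"extensional"`.
#' @param Z number of Monte-Carlo subsets (default 500).
#' @param seed optional integer seed for the subset draws.
#' @return A list of class `"stability_estimate"`: `value` in `[0, 1]`,
#'   `kind`, `mode` (`"exact"` or `"approx"`), `n_samples` (`Z`, approx mode
#'   only), `enumerated` (TRUE when the approx call enumerated all subsets),
#'   `seed`.
#' @export
stability_exact <- function(concept, ctx,
                            kind = c("intensional", "extensional")) {
  kind <- match.arg(kind)
  m <- if (kind == "intensional") length(concept$extent) else length(concept$intent)
  if (m > 25L)
    stop_("base set has %d elements; exact stability enumerates 2^%d subsets — use stability_approx()", m, m)
  v <- cpp_stability_batch(ctx$incidence, ctx$tidlists,
                           list(as.integer(concept$intent)),
                           list(as.integer(concept$extent)),
                           kind == "extensional", 0L, TRUE,
                           ctx$n_attrs, ctx$n_objects)
  structure(list(value = v$sigma[1], kind = kind, mode = "exact",
                 n_samples = NULL, enumerated = TRUE, seed = NULL),
            class = "stability_estimate")
}

#' @rdname stability_exact
#' @export
stability_approx <- function(concept, ctx,
                             kind = c("intensional", "extensional"),
                             Z = 500L, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(Z >= 1)
  v <- with_seed(seed, cpp_stability_batch(
    ctx$incidence, ctx$tidlists,
    list(as.integer(concept$intent)), list(as.integer(concept$extent)),
    kind == "extensional", as.integer(Z), FALSE,
    ctx$n_attrs, ctx$n_objects))
  structure(list(value = v$sigma[1], kind = kind, mode = "approx",
                 n_samples = as.integer(Z), enumerated = v$enumerated[1] == 1L,
                 seed = seed),
            class = "stability_estimate")
}

#' @export
print.stability_estimate <- function(x, ...) {
  cat(sprintf("%s stability = %.6g (%s%s)\n", x$kind, x$value, x$mode,
              if (x$mode == "approx" && !x$enumerated)
                sprintf(", Z = %d", x$n_samples) else ""))
  invisible(x)
}

#' Annotate a concept set with Monte-Carlo stability values
#'
#' Computes approximate stability for every concept in one call (the batch
#' equivalent of [stability_approx()]) and attaches the values as a column
#' `sigma_int` or `sigma_ext`.
#'
#' @param concepts a `"spade_concepts"` object.
#' @inheritParams stability_exact
#' @inheritParams stability_approx
#' @return `concepts` with the annotation column added.
#' @export
compute_stability <- function(concepts, ctx,
                              kind = c("intensional", "extensional"),
                              Z = 500L, seed = NULL) {
  stopifnot(inherits(concepts, "spade_concepts"))
  kind <- match.arg(kind)
  v <- with_seed(seed, cpp_stability_batch(
    ctx$incidence, ctx$tidlists, concepts$intent, concepts$extent,
    kind == "extensional", as.integer(Z), FALSE,
    ctx$n_attrs, ctx$n_objects))
  col <- if (kind == "intensional") "sigma_int" else "sigma_ext"
  out <- unclass(concepts)
  out[[col]] <- v$sigma
  attr(out, "K") <- attr(concepts, "K")
  attr(out, "dt") <- attr(concepts, "dt")
  attr(out, "n_neurons") <- attr(concepts, "n_neurons")
  class(out) <- "spade_concepts"
  out
}

## Conservative empirical upper quantile: the k-th largest null value with
## k = max(1, floor(alpha_corr * n)), so that the empirical exceedance
## probability of the threshold is below alpha_corr.
null_quantile <- function(values, alpha_corr) {
  n <- length(values)
  if (!n) return(0)  # no chance patterns observed: retain anything non-trivial
  k <- max(1L, floor(alpha_corr * n))
  sort(values, decreasing = TRUE)[k]
}

#' Surrogate-derived stability threshold
#'
#' Estimates the null distribution of pattern stability under independence:
#' the input spike trains are dithered (destroying precise temporal
#' structure), patterns are mined from the surrogate and their approximate
#' stability computed. The threshold is an upper quantile of these null
#' values: with `correction = "bonferroni"` (default) the quantile level is
#' `1 - alpha / (bonferroni_factor * n_null)` where `n_null` is the number of
#' null concepts (set `bonferroni_factor = 2` when both stability kinds will
#' be tested on the same concepts); with `correction = "none"` the plain
#' `1 - alpha` quantile is used. The quantile uses a conservative
#' ceiling-rank convention (see the methods vignette). One surrogate data
#' set usually contains thousands of chance patterns and suffices; use
#' `n_surrogates > 1` to pool several.
#'
#' @param trains a [spike_trains()] object (the data to be analyzed).
#' @param K window length in bins.
#' @inheritParams stability_exact
#' @param alpha significance level in (0, 1).
#' @param dither_halfwidth surrogate dither half-width in ms.
#' @param Z Monte-Carlo subsets per stability value.
#' @param n_surrogates number of surrogate data sets to pool.
#' @param correction `"bonferroni"` or `"none"`.
#' @param bonferroni_factor extra Bonferroni divisor (2 when testing both
#'   stability kinds).
#' @param dt bin width in ms.
#' @param cfg a [mining_config()]; surrogates are mined and filtered with
#'   `z_min`/`c_min` exactly like the original data.
#' @param pad window padding flag, see [build_context()].
#' @param seed optional integer master seed.
#' @return Numeric threshold with attributes `kind`, `alpha`, `alpha_corr`,
#'   `n_null`, `correction`.
#' @export
stability_threshold <- function(trains, K,
                                kind = c("intensional", "extensional"),
                                alpha = 0.01, dither_halfwidth = 5, Z = 500L,
                                n_surrogates = 1L,
                                correction = c("bonferroni", "none"),
                                bonferroni_factor = 1L, dt = 1,
                                cfg = mining_config(), pad = TRUE,
                                seed = NULL) {
  kind <- match.arg(kind)
  nul <- stability_null(trains, K, kinds = kind, alpha = alpha,
                        dither_halfwidth = dither_halfwidth, Z = Z,
                        n_surrogates = n_surrogates, dt = dt, cfg = cfg,
                        pad = pad, seed = seed)[[kind]]
  finish_threshold(nul, kind, alpha, match.arg(correction), bonferroni_factor)
}

finish_threshold <- function(values, kind, alpha, correction, bonferroni_factor) {
  stopifnot(alpha > 0, alpha < 1)
  if (length(values) < 100L)
    warn_("only %d null stability values; the threshold quantile is unreliable",
          length(values))
  alpha_corr <- if (correction == "bonferroni")
    alpha / (bonferroni_factor * max(length(values), 1L)) else alpha
  structure(null_quantile(values, alpha_corr), kind = kind, alpha = alpha,
            alpha_corr = alpha_corr, n_null = length(values),
            correction = correction)
}

## Null stability values from dithered surrogates, for one or both kinds.
stability_null <- function(trains, K, kinds = c("intensional", "extensional"),
                           alpha = 0.01, dither_halfwidth = 5, Z = 500L,
                           n_surrogates = 1L, dt = 1, cfg = mining_config(),
                           pad = TRUE, seed = NULL) {
  seeds <- derive_seeds(seed, 3L * n_surrogates)
  out <- stats::setNames(vector("list", length(kinds)), kinds)
  for (s in seq_len(n_surrogates)) {
    surr <- dither_spikes(trains, dither_halfwidth, seed = seeds[[3L * s - 2L]])
    ctx <- build_context(bin_spikes(surr, dt), K, pad = pad)
    conc <- apply_pattern_filter(
      mine_closed_frequent(ctx, single_stage(cfg)), cfg$z_min, cfg$c_min)
    for (i in seq_along(kinds)) {
      kd <- kinds[i]
      if (length(conc)) {
        conc2 <- compute_stability(conc, ctx, kd, Z = Z,
                                   seed = seeds[[3L * s - 2L + i]])
        col <- if (kd == "intensional") "sigma_int" else "sigma_ext"
        out[[kd]] <- c(out[[kd]], conc2[[col]])
      } else out[[kd]] <- c(out[[kd]], numeric(0))
    }
  }
  out
}

## Mining config whose mining-time thresholds already include the signature
## filter (single-stage optimization; provably yields the same final set).
single_stage <- function(cfg) {
  mining_config(min_support = max(cfg$min_support, cfg$c_min),
                min_size = max(cfg$min_size, cfg$z_min),
                z_min = cfg$z_min, c_min = cfg$c_min)
}

#' Both stability thresholds from one surrogate pass
#'
#' Convenience wrapper computing `theta_int` and `theta_ext` from the same
#' surrogate(s), with the Bonferroni divisor doubled by default because each
#' concept is then tested twice (once per stability kind).
#'
#' @inheritParams stability_threshold
#' @return A list of class `"stability_thresholds"` with `theta_int`,
#'   `theta_ext`, `alpha`, `correction`, `bonferroni_factor`.
#' @export
stability_thresholds <- function(trains, K, alpha = 0.01,
                                 dither_halfwidth = 5, Z = 500L,
                                 n_surrogates = 1L,
                                 correction = c("bonferroni", "none"),
                                 bonferroni_factor = 2L, dt = 1,
                                 cfg = mining_config(), pad = TRUE,
                                 seed = NULL) {
  correction <- match.arg(correction)
  nul <- stability_null(trains, K, kinds = c("intensional", "extensional"),
                        alpha = alpha, dither_halfwidth = dither_halfwidth,
                        Z = Z, n_surrogates = n_surrogates, dt = dt,
                        cfg = cfg, pad = pad, seed = seed)
  structure(list(
    theta_int = finish_threshold(nul$intensional, "intensional", alpha,
                                 correction, bonferroni_factor),
    theta_ext = finish_threshold(nul$extensional, "extensional", alpha,
                                 correction, bonferroni_factor),
    alpha = alpha, correction = correction,
    bonferroni_factor = bonferroni_factor),
    class = "stability_thresholds")
}

#' @export
print.stability_thresholds <- function(x, ...) {
  cat(sprintf("Stability thresholds (alpha = %g, %s x %d): theta_int = %.4g, theta_ext = %.4g\n",
              x$alpha, x$correction, x$bonferroni_factor,
              as.numeric(x$theta_int), as.numeric(x$theta_ext)))
  invisible(x)
}

#' Filter concepts by stability
#'
#' Keeps concepts whose stability strictly exceeds the threshold:
#' `"intensional"`/`"extensional"` modes test the respective measure;
#' `"combined"` keeps a concept if either measure exceeds its threshold
#' (the disjunction makes rejection require failing both tests, which is why
#' the thresholds should carry a factor-2 Bonferroni correction).
#'
#' @param concepts a `"spade_concepts"` object annotated by
#'   [compute_stability()] with the column(s) the mode requires.
#' @param thresholds a [stability_thresholds()] object, or a list with
#'   numeric `theta_int` and/or `theta_ext`.
#' @param mode filtering mode.
#' @return The surviving `"spade_concepts"`.
#' @export
filter_stable <- function(concepts,
                          thresholds,
                          mode = c("intensional", "extensional", "combined")) {
  stopifnot(inherits(concepts, "spade_concepts"))
  mode <- match.arg(mode)
  need_int <- mode %in% c("intensional", "combined")
  need_ext <- mode %in% c("extensional", "combined")
  if (need_int && is.null(concepts$sigma_int))
    stop_("concepts lack intensional stability annotations; run compute_stability()")
  if (need_ext && is.null(concepts$sigma_ext))
    stop_("concepts lack extensional stability annotations; run compute_stability()")
  if (need_int && is.null(thresholds$theta_int))
    stop_("thresholds lack theta_int")
  if (need_ext && is.null(thresholds$theta_ext))
    stop_("thresholds lack theta_ext")
  keep <- switch(mode,
    intensional = concepts$sigma_int > as.numeric(thresholds$theta_int),
    extensional = concepts$sigma_ext > as.numeric(thresholds$theta_ext),
    combined = concepts$sigma_int > as.numeric(thresholds$theta_int) |
               concepts$sigma_ext > as.numeric(thresholds$theta_ext))
  concepts[keep]
}
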