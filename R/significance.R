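#' Estimate the p-value spectrum from dithered surrogates
#'
#' The p-value of a pattern signature `(z, c)` under the null hypothesis of
#' independent spiking is estimated as the fraction of surrogate data sets
#' that contain a (canonical, filtered) closed frequent pattern with that
#' signature. Each surrogate is produced by dithering the original trains,
#' mined with the same configuration as the original data, and contributes
#' one Bernoulli observation per signature, so a large number of surrogates
#' is required (at least 100; 1000 or more for stable small p-values — the
#' resolution floor is `1/n_surrogates`).
#'
#' In `"cumulative"` counting (default) a surrogate pattern with signature
#' `(z, c')` instantiates every `(z, c)` with `c <= c'`, which makes
#' `p(z, c)` non-increasing in `c`; `"exact"` counting uses the literal
#' signature only.
#'
#' @param trains a [spike_trains()] object.
#' @param K window length in bins.
#' @param cfg a [mining_config()].
#' @param n_surrogates number of surrogate data sets.
#' @param dither_halfwidth dither half-width in ms.
#' @param counting `"cumulative"` or `"exact"`.
#' @param dt bin width in ms.
#' @param pad window padding flag.
#' @param seed optional master seed; per-surrogate seeds are derived from it
#'   deterministically, so the spectrum is invariant to surrogate order.
#' @return An object of class `"pattern_spectrum"`.
#' @export
estimate_spectrum <- function(trains, K, cfg = mining_config(),
                              n_surrogates = 100L, dither_halfwidth = 5,
                              counting = c("cumulative", "exact"), dt = 1,
                              pad = TRUE, seed = NULL) {
  counting <- match.arg(counting)
  stopifnot(n_surrogates >= 1L)
  if (n_surrogates < 100L)
    warn_("n_surrogates = %d gives a coarse p-value resolution (floor %.3g)",
          n_surrogates, 1 / n_surrogates)
  seeds <- derive_seeds(seed, n_surrogates)
  maxc <- list()   # cumulative: per size z, vector of per-surrogate max counts
  exact <- list()  # exact: per "z,c" key, number of surrogates containing it
  for (s in seq_len(n_surrogates)) {
    surr <- dither_spikes(trains, dither_halfwidth, seed = seeds[[s]])
    ctx <- build_context(bin_spikes(surr, dt), K, pad = pad)
    conc <- apply_pattern_filter(
      mine_closed_frequent(ctx, single_stage(cfg)), cfg$z_min, cfg$c_min)
    if (!length(conc)) next
    if (counting == "cumulative") {
      mx <- tapply(conc$c, conc$z, max)
      for (zz in names(mx)) maxc[[zz]] <- c(maxc[[zz]], mx[[zz]])
    } else {
      for (key in unique(sprintf("%d,%d", conc$z, conc$c)))
        exact[[key]] <- (exact[[key]] %||% 0L) + 1L
    }
  }
  structure(list(counting = counting, n_surrogates = as.integer(n_surrogates),
                 z_min = cfg$z_min, c_min = cfg$c_min,
                 maxc = maxc, exact = exact, seed = seed),
            class = "pattern_spectrum")
}

#' Query a p-value spectrum
#'
#' @param spectrum a [estimate_spectrum()] result (or [spectrum_from_counts()]).
#' @param z,c integer vectors (recycled) of signature coordinates.
#' @return Numeric vector of p-values; signatures never instantiated in any
#'   surrogate have `p = 0` (true value below the `1/n_surrogates` floor).
#' @export
spectrum_pvalue <- function(spectrum, z, c) {
  stopifnot(inherits(spectrum, "pattern_spectrum"))
  n <- max(length(z), length(c))
  z <- rep_len(as.integer(z), n); c <- rep_len(as.integer(c), n)
  vapply(seq_len(n), function(i) {
    if (spectrum$counting == "cumulative") {
      v <- spectrum$maxc[[as.character(z[i])]]
      if (is.null(v)) 0 else sum(v >= c[i]) / spectrum$n_surrogates
    } else {
      (spectrum$exact[[sprintf("%d,%d", z[i], c[i])]] %||% 0L) /
        spectrum$n_surrogates
    }
  }, 0)
}

#' Construct a spectrum from known signature counts
#'
#' Test/utility constructor: builds a `"pattern_spectrum"` directly from a
#' table of signatures and the number of surrogates instantiating each
#' (interpreted in `"exact"` counting).
#'
#' @param z,c,count equal-length integer vectors.
#' @param n_surrogates total number of surrogates.
#' @param z_min,c_min domain floor of the spectrum.
#' @return A `"pattern_spectrum"`.
#' @export
spectrum_from_counts <- function(z, c, count, n_surrogates,
                                 z_min = 3L, c_min = 3L) {
  exact <- stats::setNames(as.list(as.integer(count)), sprintf("%d,%d", z, c))
  structure(list(counting = "exact", n_surrogates = as.integer(n_surrogates),
                 z_min = z_min, c_min = c_min, maxc = list(), exact = exact,
                 seed = NULL),
            class = "pattern_spectrum")
}

#' Serialize and restore a p-value spectrum
#'
#' Spectrum estimation is the expensive part of a significance analysis
#' (one mining run per surrogate); the cache file stores the per-size
#' surrogate counts, `n_surrogates` and the seed as JSON so a spectrum can
#' be reused across analyses of the same data.
#'
#' @param spectrum a `"pattern_spectrum"`.
#' @param path file path.
#' @return `read_spectrum()` returns the restored `"pattern_spectrum"`;
#'   `write_spectrum()` returns `path` invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "pattern_spectrum"))
  jsonlite::write_json(unclass(spectrum), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  x$maxc <- lapply(x$maxc, as.integer)
  x$exact <- lapply(x$exact, as.integer)
  x$n_surrogates <- as.integer(x$n_surrogates)
  x$seed <- x$seed %||% NULL
  structure(x, class = "pattern_spectrum")
}

#' @export
print.pattern_spectrum <- function(x, ...) {
  nsig <- if (x$counting == "cumulative") length(x$maxc) else length(x$exact)
  cat(sprintf("Pattern spectrum: %d surrogates, %s counting, %d %s observed\n",
              x$n_surrogates, x$counting, nsig,
              if (x$counting == "cumulative") "pattern sizes" else "signatures"))
  invisible(x)
}

#' Pattern spectrum filtering (PSF)
#'
#' Tests each distinct signature `(z, c)` present among the mined concepts
#' against the surrogate-based p-value spectrum, correcting over signatures
#' (not over patterns — the point of signature testing is to shrink the
#' multiple-testing problem) with the Benjamini-Hochberg false discovery
#' rate procedure at level `alpha`. All concepts whose signature is
#' significant are kept.
#'
#' Signatures below the mined domain (`z < z_min` or `c < c_min`) are not
#' covered by the spectrum; encountering one among the concepts is an error.
#'
#' @param concepts a `"spade_concepts"` object (canonical, filtered).
#' @param spectrum a [estimate_spectrum()] result.
#' @param alpha significance level.
#' @return A list of class `"psf_result"`: `patterns` (surviving concepts),
#'   `signatures` (data frame with `z`, `c`, `p`, `p_adj`, `significant`),
#'   `alpha`, and `p_cut` (the realized raw-p cutoff of the step-up
#'   procedure, reused by [psr()] as the significance map).
#' @export
psf <- function(concepts, spectrum, alpha = 0.01) {
  stopifnot(inherits(concepts, "spade_concepts"),
            inherits(spectrum, "pattern_spectrum"))
  if (!length(concepts)) {
    return(structure(list(patterns = concepts,
                          signatures = data.frame(z = integer(), c = integer(),
                                                  p = numeric(), p_adj = numeric(),
                                                  significant = logical()),
                          alpha = alpha, p_cut = -Inf),
                     class = "psf_result"))
  }
  bad <- concepts$z < spectrum$z_min | concepts$c < spectrum$c_min
  if (any(bad))
    stop_("no spectrum entry for signature (%d, %d)",
          concepts$z[which(bad)[1]], concepts$c[which(bad)[1]])
  sig <- unique(data.frame(z = concepts$z, c = concepts$c))
  sig <- sig[order(sig$z, sig$c), , drop = FALSE]
  sig$p <- spectrum_pvalue(spectrum, sig$z, sig$c)
  sig$p_adj <- p.adjust(sig$p, method = "BH")
  sig$significant <- sig$p_adj <= alpha
  rownames(sig) <- NULL
  p_cut <- if (any(sig$significant)) max(sig$p[sig$significant]) else -Inf
  keymap <- sprintf("%d,%d", sig$z, sig$c)
  keep <- sig$significant[match(sprintf("%d,%d", concepts$z, concepts$c), keymap)]
  structure(list(patterns = concepts[keep], signatures = sig,
                 alpha = alpha, p_cut = p_cut),
            class = "psf_result")
}

#' @export
print.psf_result <- function(x, ...) {
  cat(sprintf("PSF: %d/%d signatures significant (alpha = %g, BH); %d pattern(s) kept\n",
              sum(x$signatures$significant), nrow(x$signatures), x$alpha,
              length(x$patterns)))
  invisible(x)
}

#' PSR configuration
#'
#' The size correction `h` and count correction `k` compensate for the
#' conditional signatures being looked up in the unconditional p-value
#' spectrum; `h = 0`, `k = 2` are the validated heuristic defaults.
#'
#' @param h size-correction integer (>= 0).
#' @param k count-correction integer (>= 0).
#' @export
psr_config <- function(h = 0L, k = 2L) {
  stopifnot(h >= 0, k >= 0)
  structure(list(h = as.integer(h), k = as.integer(k)), class = "psr_config")
}

## Best shift-alignment overlap of two canonical patterns.
## Returns the maximal number of (neuron, lag) spikes of `b` that coincide
## with spikes of `a` when b is rigidly shifted in time (0 = disjoint).
pattern_overlap <- function(a, b) {
  shared <- intersect(a$neurons, b$neurons)
  if (!length(shared)) return(0L)
  ka <- paste(a$neurons, a$lags)
  shifts <- unique(as.vector(outer(a$lags[a$neurons %in% shared],
                                   b$lags[b$neurons %in% shared], "-")))
  max(vapply(shifts, function(s)
    sum(paste(b$neurons, b$lags + s) %in% ka), 0L))
}

#' Pattern set reduction (PSR)
#'
#' Re-tests the PSF survivors reciprocally for conditional significance. For
#' an overlapping pair, the larger pattern `A` is re-tested with its size
#' reduced by the conditioning pattern (`z_A - z_cond + h`, at its own count
#' `c_A`), and — when the smaller pattern `B` is contained in `A` — `B` is
#' re-tested with its count reduced by `A`'s (`c_B - c_A + k`). For partial
#' overlaps the conditioning pattern is the maximal shift-aligned
#' intersection and both patterns are size-conditioned. If both conditional
#' signatures are significant both patterns are kept; if only one is, the
#' other is discarded; if neither is, the pattern covering more spikes
#' (larger `z*c`; ties: larger `z`, then lexicographically smaller pattern)
#' is kept. Removals from all pairs are collected in one pass and applied at
#' the end. Conditional signatures outside the spectrum's domain are treated
#' as non-significant (noted in the `notes` attribute).
#'
#' @param patterns list of canonical `"stp"` patterns (see [as_patterns()]),
#'   the PSF survivors.
#' @param spectrum the [estimate_spectrum()] result used by PSF.
#' @param cfg a [psr_config()].
#' @param p_cut raw-p significance cutoff from [psf()] (its `p_cut` field) —
#'   the corrected significance map reused for the conditional tests.
#' @return The surviving patterns (same representation), with a character
#'   vector attribute `"notes"`.
#' @export
psr <- function(patterns, spectrum, cfg = psr_config(), p_cut) {
  stopifnot(inherits(spectrum, "pattern_spectrum"))
  n <- length(patterns)
  if (n <= 1L) return(structure(patterns, notes = character(0)))
  notes <- character(0)
  sig_test <- function(z, c) {
    if (z < spectrum$z_min || c < spectrum$c_min) {
      notes <<- c(notes, sprintf("signature (%d, %d) outside spectrum support: non-significant", z, c))
      return(FALSE)
    }
    spectrum_pvalue(spectrum, z, c) <= p_cut
  }
  pat_key <- vapply(patterns, function(p)
    paste(sprintf("%08d %08d", p$neurons, p$lags), collapse = ","), "")
  drop <- logical(n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pi <- patterns[[i]]; pj <- patterns[[j]]
    ov <- pattern_overlap(pi, pj)
    if (ov == 0L) next
    # orient so that A is the (weakly) larger pattern
    if (pi$z >= pj$z) { A <- pi; B <- pj; ia <- i; ib <- j }
    else { A <- pj; B <- pi; ia <- j; ib <- i }
    contained <- ov == B$z && A$z > B$z
    okA <- sig_test(A$z - (if (contained) B$z else ov) + cfg$h, A$c)
    okB <- if (contained) sig_test(B$z, B$c - A$c + cfg$k)
           else sig_test(B$z - ov + cfg$h, B$c)
    if (okA && okB) next
    if (okA && !okB) { drop[ib] <- TRUE; next }
    if (!okA && okB) { drop[ia] <- TRUE; next }
    # neither conditionally significant: keep the larger z*c score
    sa <- A$z * A$c; sb <- B$z * B$c
    loser <- if (sa > sb) ib else if (sb > sa) ia
      else if (A$z > B$z) ib else if (B$z > A$z) ia
      else if (pat_key[ia] < pat_key[ib]) ib else ia
    drop[loser] <- TRUE
  }
  structure(patterns[!drop], notes = notes)
}
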