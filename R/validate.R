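#' Score detected patterns against ground truth
#'
#' Applies the strict true-positive definition: a found pattern is a TP only
#' if it consists of all and only the spikes forming the injected pattern —
#' i.e. its (neuron, lag) composition matches a ground-truth pattern exactly
#' (with `strict_onsets = TRUE` its reported occurrences must additionally
#' cover every injected onset). Every other found pattern, including strict
#' sub- or super-patterns of the truth, is a false positive; a truth matched
#' by no found pattern is a false negative.
#'
#' @param found list of `"stp"` patterns (e.g. `spade(...)$patterns`) or a
#'   `"spade"` object.
#' @param truth a `"stp_truth"` or list thereof (see [inject_stp()]).
#' @param strict_onsets additionally require occurrence coverage of the
#'   injected onsets (default FALSE: composition-only matching).
#' @param dt bin width in ms used by the analysis (needed to map onsets to
#'   occurrence bins when `strict_onsets = TRUE`).
#' @return A list with `n_tp`, `n_fp`, `fn` (logical per truth).
#' @export
classify_outcome <- function(found, truth, strict_onsets = FALSE, dt = 1) {
  if (inherits(found, "spade")) {
    dt <- found$config$binsize
    found <- found$patterns
  }
  if (inherits(truth, "stp_truth")) truth <- list(truth)
  truth_keys <- vapply(truth, function(tr) {
    o <- order(tr$lags_ms, tr$neurons)
    paste(tr$neurons[o], tr$lags_ms[o], collapse = ";")
  }, "")
  matched <- logical(length(truth))
  n_tp <- 0L; n_fp <- 0L
  for (p in found) {
    o <- order(p$lags_ms, p$neurons)
    key <- paste(p$neurons[o], p$lags_ms[o], collapse = ";")
    hit <- which(truth_keys == key)
    if (length(hit) && strict_onsets) {
      tr <- truth[[hit[1]]]
      want <- floor(tr$onsets / dt)
      if (!all(want %in% p$occurrences)) hit <- integer(0)
    }
    if (length(hit)) { n_tp <- n_tp + 1L; matched[hit[1]] <- TRUE }
    else n_fp <- n_fp + 1L
  }
  list(n_tp = n_tp, n_fp = n_fp, fn = !matched)
}

#' False-positive / false-negative matrices over pattern signatures
#'
#' The standard validation experiment: for every injected signature
#' `(z, c)` on the grid, generate `R` realizations of the background model,
#' inject one pattern with that signature, run the full pipeline, and score
#' strictly against the ground truth. The FP cell is the fraction of
#' realizations with at least one false positive, the FN cell the fraction
#' in which the injected pattern was not recovered. With `inject = FALSE`
#' the grid collapses to a single cell measuring the FP rate on purely
#' independent data.
#'
#' Per-cell/per-realization seeds are derived from `master_seed` by a
#' counter scheme, so any cell can be recomputed independently and results
#' are order-invariant. For the stability methods a single threshold pair is
#' derived per call from an independent realization of the same background
#' (injected spikes do not measurably move the null); for the PSF methods a
#' spectrum is estimated per realization unless `share_spectrum = TRUE`, in
#' which case the first realization's spectrum (a null object that depends
#' only on the background statistics) is reused.
#'
#' @param model a [rate_model()].
#' @param z_range,c_range injected signature grid (defaults 3:10).
#' @param R realizations per cell.
#' @param method pipeline branch, as in [spade()].
#' @param n_neurons,duration background dimensions.
#' @param winlen,binsize,min_size,min_occ,n_surrogates,dither,alpha,Z,pad
#'   pipeline parameters, as in [spade()].
#' @param lag injected inter-spike lag in ms.
#' @param inject set `FALSE` for the independent-data FP experiment.
#' @param share_spectrum reuse one spectrum across realizations (PSF
#'   methods).
#' @param strict_onsets TP matching mode, see [classify_outcome()].
#' @param master_seed integer seed for the whole experiment.
#' @return An object of class `"fpfn_matrices"`: `fp` and `fn` matrices
#'   (rows = z, cols = c), `R`, `model`, `method`, `n_failed`, and
#'   `stage_counts` (mean pattern count per stage, pooled over all cells).
#' @export
fp_fn_matrices <- function(model, z_range = 3:10, c_range = 3:10, R = 10L,
                           method = "psf-psr", n_neurons = 100L,
                           duration = 1000, winlen = 50L, binsize = 1,
                           min_size = 3L, min_occ = 3L, n_surrogates = 100L,
                           dither = 5, alpha = 0.01, Z = 500L, lag = 5,
                           inject = TRUE, share_spectrum = FALSE,
                           strict_onsets = FALSE, pad = TRUE,
                           master_seed = NULL) {
  stopifnot(inherits(model, "rate_model"), R >= 1L)
  method <- match.arg(method, c("psf-psr", "psf", "stab-int", "stab-ext",
                                "stab-comb"))
  if (!inject) { z_range <- 0L; c_range <- 0L }
  n_cells <- length(z_range) * length(c_range)
  seeds <- derive_seeds(master_seed, n_cells * R * 2L + 1L)
  thresholds <- NULL
  if (startsWith(method, "stab")) {
    ind <- generate_background(model, n_neurons, duration,
                               seed = seeds[[n_cells * R * 2L + 1L]])
    thresholds <- stability_thresholds(
      ind, winlen, alpha = alpha, dither_halfwidth = dither, Z = Z,
      bonferroni_factor = if (method == "stab-comb") 2L else 1L,
      dt = binsize, cfg = mining_config(z_min = min_size, c_min = min_occ),
      pad = pad, seed = seeds[[n_cells * R * 2L + 1L]])
  }
  fp <- matrix(NA_real_, length(z_range), length(c_range),
               dimnames = list(z = z_range, c = c_range))
  fn <- fp
  n_failed <- 0L
  stage_acc <- list()
  cell <- 0L
  for (iz in seq_along(z_range)) for (ic in seq_along(c_range)) {
    cell <- cell + 1L
    fp_hits <- 0L; fn_hits <- 0L; ok_runs <- 0L
    spectrum <- NULL
    for (r in seq_len(R)) {
      s_gen <- seeds[[(cell - 1L) * R * 2L + 2L * r - 1L]]
      s_run <- seeds[[(cell - 1L) * R * 2L + 2L * r]]
      res <- tryCatch({
        bg <- generate_background(model, n_neurons, duration, seed = s_gen)
        truth <- NULL
        if (inject) {
          inj <- inject_stp(bg, z_range[iz], c_range[ic], lag = lag,
                            neurons = if (model$kind == "heterogeneous")
                              "random" else "first",
                            seed = s_gen)
          bg <- inj$trains; truth <- inj$truth
        }
        run <- spade(bg, binsize = binsize, winlen = winlen,
                     min_size = min_size, min_occ = min_occ, method = method,
                     n_surrogates = n_surrogates, dither = dither,
                     alpha = alpha, Z = Z, pad = pad, seed = s_run,
                     spectrum = spectrum, thresholds = thresholds)
        if (share_spectrum && is.null(spectrum)) spectrum <- run$spectrum
        list(run = run, truth = truth)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        n_failed <- n_failed + 1L
        warn_("realization failed at cell (z = %d, c = %d): %s",
              z_range[iz], c_range[ic], conditionMessage(res))
        next
      }
      ok_runs <- ok_runs + 1L
      stage_acc[[length(stage_acc) + 1L]] <- unlist(res$run$counts)
      if (inject) {
        sc <- classify_outcome(res$run, res$truth,
                               strict_onsets = strict_onsets)
        if (sc$n_fp > 0L) fp_hits <- fp_hits + 1L
        if (any(sc$fn)) fn_hits <- fn_hits + 1L
      } else if (length(res$run$patterns)) fp_hits <- fp_hits + 1L
    }
    fp[iz, ic] <- if (ok_runs) fp_hits / ok_runs else NA_real_
    fn[iz, ic] <- if (inject && ok_runs) fn_hits / ok_runs else NA_real_
  }
  structure(list(fp = fp, fn = fn, R = R, model = model$kind,
                 method = method, inject = inject, n_failed = n_failed,
                 stage_counts = if (length(stage_acc))
                   colMeans(do.call(rbind, stage_acc)) else NULL,
                 master_seed = master_seed),
            class = "fpfn_matrices")
}

#' @export
print.fpfn_matrices <- function(x, ...) {
  cat(sprintf("FP/FN matrices: %s background, method %s, R = %d%s\n",
              x$model, x$method, x$R,
              if (x$n_failed) sprintf(" (%d failed runs)", x$n_failed) else ""))
  cat("FP rates:\n"); print(x$fp)
  if (x$inject) { cat("FN rates:\n"); print(x$fn) }
  invisible(x)
}

#' Mean pattern counts per pipeline stage
#'
#' Aggregates the per-stage pattern counts of several [spade()] runs
#' (typically realizations of one simulated condition) into their means,
#' which expose how many candidate patterns each step of the method rejects.
#'
#' @param runs list of `"spade"` objects.
#' @return Named numeric vector of mean counts (stages as named by
#'   `spade()$counts`, e.g. `mined`, `psf`, `psr`, `final`).
#' @export
stage_counts <- function(runs) {
  stopifnot(length(runs) >= 1L,
            all(vapply(runs, inherits, TRUE, "spade")))
  colMeans(do.call(rbind, lapply(runs, function(r) unlist(r$counts))))
}
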