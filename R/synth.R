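#' Background rate models for ground-truth simulations
#'
#' Four piecewise-constant rate models for independent Poisson background
#' activity, replicating statistical features of cortical recordings that
#' are known false-positive generators for correlation analysis:
#'
#' * `"stationary"`: every neuron fires at a constant `rate` (defaults 25 Hz).
#' * `"coherent_step"`: all neurons share a rate profile with a coherent
#'   jump — `rates[i]` Hz on the interval `breaks[i]..breaks[i+1]`
#'   (defaults: 10 Hz on 0–600 ms, 60 Hz on 600–700 ms, 10 Hz on
#'   700–1000 ms; `breaks` are rescaled to the simulated duration only if
#'   they match the default 1 s grid).
#' * `"heterogeneous"`: stationary but different across neurons, increasing
#'   from `rate_min` (first neuron) in steps of `rate_step` (defaults
#'   5 Hz + 0.2 Hz steps, i.e. 5–24.8 Hz over 100 neurons).
#' * `"propagation"`: `n_groups` groups of `group_size` neurons at
#'   `baseline` Hz; at each onset the first group jumps to `peak` Hz for
#'   `jump_duration` ms, then hands the jump to the next group
#'   (defaults: 20 groups of 5, 14 to 100 Hz for 5 ms, onsets 50 and
#'   550 ms).
#'
#' @param kind model kind.
#' @param ... model parameters, see Details.
#' @return An object of class `"rate_model"`.
#' @export
rate_model <- function(kind = c("stationary", "coherent_step",
                                "heterogeneous", "propagation"), ...) {
  kind <- match.arg(kind)
  p <- list(...)
  defaults <- switch(kind,
    stationary = list(rate = 25),
    coherent_step = list(rates = c(10, 60, 10), breaks = c(0, 600, 700, 1000)),
    heterogeneous = list(rate_min = 5, rate_step = 0.2),
    propagation = list(baseline = 14, peak = 100, jump_duration = 5,
                       n_groups = 20L, group_size = 5L, onsets = c(50, 550)))
  unknown <- setdiff(names(p), names(defaults))
  if (length(unknown)) stop_("unknown parameter(s) for %s model: %s", kind,
                             paste(unknown, collapse = ", "))
  m <- utils::modifyList(defaults, p)
  if (kind == "coherent_step") {
    if (length(m$breaks) != length(m$rates) + 1L || is.unsorted(m$breaks, strictly = TRUE))
      stop_("coherent_step needs strictly increasing breaks, one more than rates")
  }
  rates <- switch(kind, stationary = m$rate, coherent_step = m$rates,
                  heterogeneous = c(m$rate_min, m$rate_step),
                  propagation = c(m$baseline, m$peak))
  if (any(rates < 0)) stop_("rates must be >= 0")
  structure(c(list(kind = kind), m), class = "rate_model")
}

## Per-neuron piecewise-constant rate profile: data.frame(start, end, rate).
rate_segments <- function(model, neuron, n_neurons, duration) {
  switch(model$kind,
    stationary = data.frame(start = 0, end = duration, rate = model$rate),
    coherent_step = {
      br <- model$breaks
      if (max(br) > duration)
        stop_("coherent_step breaks exceed the simulated duration")
      st <- br[-length(br)]; en <- br[-1]
      if (max(br) < duration) { st <- c(st, max(br)); en <- c(en, duration)
        rt <- c(model$rates, model$rates[length(model$rates)])
      } else rt <- model$rates
      data.frame(start = st, end = en, rate = rt)
    },
    heterogeneous = data.frame(start = 0, end = duration,
                               rate = model$rate_min + model$rate_step * (neuron - 1L)),
    propagation = {
      g <- (neuron - 1L) %/% model$group_size + 1L  # 1-based group of this neuron
      jumps <- model$onsets + (g - 1L) * model$jump_duration
      jumps <- jumps[jumps < duration]
      pts <- sort(unique(c(0, duration, jumps, pmin(jumps + model$jump_duration, duration))))
      st <- pts[-length(pts)]; en <- pts[-1]
      inj <- vapply(st, function(s) any(s >= jumps & s < jumps + model$jump_duration), TRUE)
      data.frame(start = st, end = en,
                 rate = ifelse(inj, model$peak, model$baseline))
    })
}

#' Generate independent Poisson background activity
#'
#' Simulates `n_neurons` mutually independent (in)homogeneous Poisson spike
#' trains over `[0, duration)` ms realizing the piecewise-constant rate
#' profile of a [rate_model()]. Sampling is exact for piecewise-constant
#' rates: per segment the spike count is Poisson with mean
#' `rate * length / 1000` and spike times are uniform on the segment.
#'
#' @param model a [rate_model()].
#' @param n_neurons number of neurons (default 100; the propagation model
#'   requires `n_groups * group_size`).
#' @param duration recording duration in ms (default 1000).
#' @param seed optional integer seed.
#' @return A [spike_trains()] object.
#' @export
generate_background <- function(model, n_neurons = 100L, duration = 1000,
                                seed = NULL) {
  stopifnot(inherits(model, "rate_model"), n_neurons >= 1L, duration >= 0)
  if (model$kind == "propagation" &&
      n_neurons != model$n_groups * model$group_size)
    stop_("propagation model needs n_neurons = n_groups * group_size = %d",
          model$n_groups * model$group_size)
  with_seed(seed, {
    trains <- lapply(seq_len(n_neurons), function(i) {
      if (duration == 0) return(numeric(0))
      seg <- rate_segments(model, i, n_neurons, duration)
      tt <- unlist(lapply(seq_len(nrow(seg)), function(s) {
        lambda <- seg$rate[s] * (seg$end[s] - seg$start[s]) / 1000
        k <- rpois(1L, lambda)
        runif(k, seg$start[s], seg$end[s])
      }))
      sort(tt)
    })
    spike_trains(trains, 0, duration)
  })
}

#' Inject a spatio-temporal pattern into background activity
#'
#' An injected pattern occurrence is a temporal sequence of `z` spikes on
#' `z` participating neurons with a constant `lag` (default 5 ms) between
#' successive spikes; `c` occurrences are placed at onsets drawn uniformly
#' in `[t_start, t_stop - (z-1)*lag)` so every occurrence fits inside the
#' recording. Injected spikes falling into an occupied bin of the same
#' neuron are later collapsed by the binning clip rule.
#'
#' @param trains background [spike_trains()].
#' @param z pattern size (>= 3 by spec of the signature filter; >= 1 here).
#' @param c number of occurrences (>= 1).
#' @param lag inter-spike lag in ms (default 5).
#' @param neurons `"first"` (neurons `1..z`), `"random"` (a random draw of
#'   `z` neurons), or an explicit integer vector of length `z`.
#' @param onsets optional fixed onset times (ms); drawn uniformly if `NULL`.
#' @param seed optional integer seed.
#' @return A list with `trains` (the enriched `spike_trains`) and `truth`
#'   (class `"stp_truth"`: `neurons`, `lags_ms`, `onsets`, `z`, `c`).
#' @export
inject_stp <- function(trains, z, c, lag = 5, neurons = "first",
                       onsets = NULL, seed = NULL) {
  stopifnot(inherits(trains, "spike_trains"), z >= 1, c >= 1, lag >= 0)
  z <- as.integer(z); c <- as.integer(c)
  span <- (z - 1) * lag
  if (trains$t_stop - span <= trains$t_start)
    stop_("recording too short to place a pattern spanning %g ms", span)
  with_seed(seed, {
    nrn <- if (identical(neurons, "first")) seq_len(z)
      else if (identical(neurons, "random")) sort(sample.int(n_neurons(trains), z))
      else as.integer(neurons)
    if (length(nrn) != z || any(nrn < 1L) || any(nrn > n_neurons(trains)) ||
        anyDuplicated(nrn))
      stop_("`neurons` must be %d distinct neuron indices in 1..%d", z,
            n_neurons(trains))
    if (is.null(onsets))
      onsets <- runif(c, trains$t_start, trains$t_stop - span)
    if (length(onsets) != c) stop_("need %d onsets", c)
    if (any(onsets < trains$t_start) || any(onsets + span >= trains$t_stop))
      stop_("onset(s) place pattern spikes outside the recording")
    lags <- (0:(z - 1)) * lag
    tr <- trains$trains
    for (i in seq_len(z))
      tr[[nrn[i]]] <- sort(c(tr[[nrn[i]]], onsets + lags[i]))
    list(trains = spike_trains(tr, trains$t_start, trains$t_stop),
         truth = structure(list(neurons = nrn, lags_ms = lags,
                                onsets = sort(onsets), z = z, c = c),
                           class = "stp_truth"))
  })
}

#' @export
print.stp_truth <- function(x, ...) {
  cat(sprintf("Injected STP (z = %d, c = %d): %s\n", x$z, x$c,
              paste(sprintf("n%d@%g", x$neurons, x$lags_ms), collapse = " ")))
  invisible(x)
}

#' Inject several distinct patterns
#'
#' Injects each spec independently (neurons drawn at random unless given),
#' enforcing that no two patterns use an identical neuron set; partially
#' overlapping neuron sets are allowed and visible in the ground truth.
#'
#' @param trains background [spike_trains()].
#' @param specs list of lists with fields `z`, `c` and optionally `lag`,
#'   `neurons`, `onsets` (at least 2 specs).
#' @param seed optional integer seed.
#' @return A list with `trains` and `truths` (list of `"stp_truth"`).
#' @export
inject_multiple <- function(trains, specs, seed = NULL) {
  stopifnot(length(specs) >= 2L)
  seeds <- derive_seeds(seed, length(specs))
  truths <- vector("list", length(specs))
  used <- character(0)
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    nrn <- sp$neurons %||% "random"
    res <- NULL
    for (try in 1:100) {
      res <- inject_stp(trains, sp$z, sp$c, lag = sp$lag %||% 5,
                        neurons = nrn, onsets = sp$onsets,
                        seed = if (is.null(seeds[[i]])) NULL
                               else (seeds[[i]] + try - 1L) %% .Machine$integer.max)
      key <- paste(sort(res$truth$neurons), collapse = ",")
      if (!key %in% used) break
      res <- NULL
      if (!identical(nrn, "random"))
        stop_("specs %d and earlier use an identical neuron set", i)
    }
    if (is.null(res))
      stop_("could not draw a distinct neuron set for spec %d", i)
    used <- c(used, paste(sort(res$truth$neurons), collapse = ","))
    trains <- res$trains
    truths[[i]] <- res$truth
  }
  list(trains = trains, truths = truths)
}
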