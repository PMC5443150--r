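# Shared fixtures, all constructed in code.

# Three-neuron recording whose window t_A (start bin 1, K = 8) holds the
# worked-example content F and whose window t_B (start bin 15) repeats the
# embedded three-spike pattern H = {(1,0), (2,6), (3,3)} (0-based offsets).
# The windows one bin earlier hold the shifted copy Q of H.
fig1_trains <- function() {
  tr <- list(c(1, 3, 8, 15, 20),     # neuron 1
             c(2, 5, 7, 21),         # neuron 2
             c(1, 4, 7, 16, 18))     # neuron 3
  spike_trains(lapply(tr, function(v) v + 0.5), 0, 30)
}

fig1_context <- function() build_context(bin_spikes(fig1_trains(), 1), K = 8)

# attribute ids of the full window content F and the pattern H, 0-based
fig1_F <- function() sort(as.integer(c(0 * 8 + c(0, 2, 7),
                                       1 * 8 + c(1, 4, 6),
                                       2 * 8 + c(0, 3, 6))))
fig1_H <- function() sort(as.integer(c(0 * 8 + 0, 1 * 8 + 6, 2 * 8 + 3)))
fig1_Q <- function() sort(as.integer(c(0 * 8 + 1, 1 * 8 + 7, 2 * 8 + 4)))

# toy context 1:{a,b}, 2:{a,b}, 3:{a,c} with a=0, b=1, c=2
toy_context <- function() {
  spade:::context_from_incidence(list(c(0L, 1L), c(0L, 1L), c(0L, 2L)), 3L)
}

# random sparse context; consumes the session RNG
random_context <- function(n_objects, n_attrs, density = 0.3) {
  inc <- lapply(seq_len(n_objects), function(i)
    which(runif(n_attrs) < density) - 1L)
  spade:::context_from_incidence(inc, n_attrs)
}

concepts_df <- function(x) {
  df <- as.data.frame(x)
  df$extent <- vapply(x$extent, paste, "", collapse = ",")
  df[order(df$intent), c("z", "c", "intent", "extent")]
}

# hand-built canonical pattern, for classifier and PSR unit tests
make_stp <- function(neurons, lags, occurrences = c(0L, 60L, 120L), dt = 1) {
  structure(list(neurons = as.integer(neurons), lags = as.integer(lags),
                 lags_ms = lags * dt, occurrences = as.integer(occurrences),
                 z = length(neurons), c = length(occurrences)),
            class = "stp")
}
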