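#' Build the sliding-window formal context of a binned recording
#'
#' Re-encodes binned parallel spike trains as a formal context `(G, M, I)`:
#' the objects `G` are window start bins (windows of `K` bins slide in steps
#' of one bin), the attributes `M` are the `N * K` spike coordinates
#' `(neuron, offset)` with offset in `0..K-1`, and window `t` carries
#' attribute `(n, o)` exactly when neuron `n` has a spike in bin `t + o`.
#' This "attribute scaling" is what lets a plain closed-itemset miner
#' enumerate spatio-temporal patterns: a pattern of spikes with fixed lags
#' becomes a plain set of attributes that repeats across windows.
#'
#' With `pad = TRUE` (default) every start bin `0..n_bins-1` is an object and
#' positions beyond the last bin read as empty, so a pattern starting in the
#' last `K-1` bins still has a window in which its first spike sits at offset
#' 0. With `pad = FALSE` only the `n_bins - K + 1` fully contained windows
#' are used.
#'
#' Attribute ids are 0-based and encode `id = (neuron - 1) * K + offset`;
#' object ids are the 0-based window start bins.
#'
#' @param binned a [bin_spikes()] result.
#' @param K window length in bins (`>= 1`, `<= n_bins`); the window duration
#'   is `K * dt` ms and bounds the maximal temporal extent of a pattern.
#' @param pad logical, see Details.
#' @return An object of class `"formal_context"`: a list with `incidence`
#'   (per-object sorted attribute-id sets), `tidlists` (per-attribute sorted
#'   object-id sets), `n_objects`, `n_attrs`, `n_neurons`, `K`, `dt`, `pad`.
#' @export
build_context <- function(binned, K, pad = TRUE) {
  stopifnot(inherits(binned, "binned_spikes"),
            is.numeric(K), length(K) == 1L, K >= 1)
  K <- as.integer(K)
  N <- nrow(binned); n_bins <- ncol(binned)
  if (K > n_bins) stop_("window length K = %d exceeds n_bins = %d", K, n_bins)
  n_objects <- if (pad) n_bins else n_bins - K + 1L
  idx <- which(binned == 1L)  # column-major over N x n_bins
  nrn0 <- (idx - 1L) %% N            # 0-based neuron
  bin0 <- (idx - 1L) %/% N           # 0-based time bin
  ns <- length(idx)
  # spike (n, b) is attribute (n, b - t) of every object t in [b-K+1, b]
  off <- rep(0:(K - 1L), times = ns)
  obj <- rep(bin0, each = K) - off
  att <- rep(nrn0 * K, each = K) + off
  keep <- obj >= 0L & obj < n_objects
  obj <- obj[keep]; att <- att[keep]
  ord <- order(obj, att)
  obj <- obj[ord]; att <- att[ord]
  incidence <- unname(split(att, factor(obj, levels = 0:(n_objects - 1L))))
  ord2 <- order(att, obj)
  tidlists <- unname(split(obj[ord2], factor(att[ord2], levels = 0:(N * K - 1L))))
  structure(list(incidence = incidence, tidlists = tidlists,
                 n_objects = n_objects, n_attrs = N * K, n_neurons = N,
                 K = K, dt = attr(binned, "dt"), pad = pad),
            class = "formal_context")
}

#' @export
print.formal_context <- function(x, ...) {
  cat(sprintf(
    "Formal context: %d windows (K = %d bins of %g ms%s) x %d attributes (%d neurons), %d incidences\n",
    x$n_objects, x$K, x$dt, if (x$pad) ", padded" else "", x$n_attrs,
    x$n_neurons, sum(lengths(x$incidence))))
  invisible(x)
}

#' FCA derivation operators
#'
#' `derive_intent()` maps a set of objects (windows) to the attributes common
#' to all of them; `derive_extent()` maps a set of attributes (spike
#' coordinates) to the objects containing all of them. The empty object set
#' derives to all of `M`, the empty attribute set to all of `G` (vacuous
#' quantification). A pair `(A, B)` with `A' = B` and `B' = A` is a formal
#' concept: a pattern that is maximal both in composition and in occurrence.
#'
#' @param ctx a [build_context()] result.
#' @param objects integer vector of 0-based object ids.
#' @param attributes integer vector of 0-based attribute ids.
#' @return Sorted integer vector of attribute (object) ids.
#' @export
derive_intent <- function(ctx, objects) {
  stopifnot(inherits(ctx, "formal_context"))
  objects <- as.integer(objects)
  if (length(objects) && (any(objects < 0L) || any(objects >= ctx$n_objects)))
    stop_("unknown object id (valid: 0..%d)", ctx$n_objects - 1L)
  if (!length(objects)) return(0:(ctx$n_attrs - 1L))
  Reduce(intersect, ctx$incidence[objects + 1L])
}

#' @rdname derive_intent
#' @export
derive_extent <- function(ctx, attributes) {
  stopifnot(inherits(ctx, "formal_context"))
  attributes <- as.integer(attributes)
  if (length(attributes) && (any(attributes < 0L) || any(attributes >= ctx$n_attrs)))
    stop_("unknown attribute id (valid: 0..%d)", ctx$n_attrs - 1L)
  if (!length(attributes)) return(0:(ctx$n_objects - 1L))
  Reduce(intersect, ctx$tidlists[attributes + 1L])
}

## Decode 0-based attribute ids into (neuron [1-based], offset [bins]).
decode_attrs <- function(intent, K) {
  list(neuron = intent %/% K + 1L, offset = intent %% K)
}

#' Canonical representative of a shift-equivalence class
#'
#' Because windows slide in steps of one bin, every repeating pattern appears
#' as up to `K` concepts whose intents are time-shifted copies of each other.
#' The class is represented by the copy whose first spike falls into the
#' first bin of the window. `canonicalize()` accepts a concept whose intent
#' has minimum offset 0 and turns it into a spatio-temporal pattern (neurons
#' plus lags in bins); any other concept is rejected as a shifted duplicate
#' and `NULL` is returned.
#'
#' @param concept a list with elements `intent` (0-based attribute ids) and
#'   `extent` (0-based window ids), e.g. one element of a
#'   [mine_closed_frequent()] result.
#' @param K window length in bins used to encode the attributes.
#' @param dt bin width in ms (annotates lags).
#' @return An object of class `"stp"` (fields `neurons` 1-based, `lags` in
#'   bins, `lags_ms`, `occurrences` = window start bins, `z`, `c`) or `NULL`
#'   if the concept is a shifted duplicate.
#' @export
canonicalize <- function(concept, K, dt = 1) {
  dec <- decode_attrs(concept$intent, K)
  if (!length(concept$intent)) return(NULL)
  if (min(dec$offset) != 0L) return(NULL)
  ord <- order(dec$offset, dec$neuron)
  structure(list(neurons = dec$neuron[ord], lags = dec$offset[ord],
                 lags_ms = dec$offset[ord] * dt,
                 occurrences = sort(concept$extent),
                 z = length(concept$intent), c = length(concept$extent)),
            class = "stp")
}

#' @export
print.stp <- function(x, ...) {
  cat(sprintf("STP (z = %d, c = %d): %s\n", x$z, x$c,
              paste(sprintf("n%d@%g", x$neurons, x$lags_ms), collapse = " ")))
  invisible(x)
}

#' Shift-equivalence class key of an intent
#'
#' Normalizes the offsets of an intent by their minimum, yielding a key that
#' is identical for all time-shifted copies of the same pattern.
#'
#' @param intent integer vector of 0-based attribute ids.
#' @param K window length in bins.
#' @return A character scalar.
#' @export
shift_class_key <- function(intent, K) {
  dec <- decode_attrs(intent, K)
  lag <- dec$offset - min(dec$offset)
  paste(sort((dec$neuron - 1L) * K + lag), collapse = ",")
}

#' Export a formal context as transaction lines
#'
#' One line per window, 0-based attribute ids space-separated — the common
#' input format of itemset miners. Empty windows become empty lines so the
#' object count is preserved.
#'
#' @param ctx a [build_context()] result.
#' @param path optional file path; if `NULL` the lines are returned.
#' @return Character vector of lines (invisibly, if written to `path`).
#' @export
write_transactions <- function(ctx, path = NULL) {
  stopifnot(inherits(ctx, "formal_context"))
  lines <- vapply(ctx$incidence, paste, "", collapse = " ")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' @rdname write_transactions
#' @param n_attrs attribute universe size of the encoded context.
#' @export
read_transactions <- function(path, n_attrs) {
  lines <- readLines(path)
  incidence <- lapply(lines, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    f <- f[nzchar(f)]
    sort(as.integer(f))
  })
  context_from_incidence(incidence, n_attrs)
}

## Assemble a formal_context from raw incidence lists (0-based attribute ids).
## Used by the transaction importer, the random-context test generators and
## the brute-force oracle; K/dt default to an attribute-per-neuron encoding.
context_from_incidence <- function(incidence, n_attrs, K = 1L, dt = 1) {
  incidence <- lapply(incidence, function(v) sort(unique(as.integer(v))))
  n_objects <- length(incidence)
  att <- unlist(incidence, use.names = FALSE)
  obj <- rep(seq_len(n_objects) - 1L, lengths(incidence))
  ord <- order(att, obj)
  tidlists <- unname(split(obj[ord], factor(att[ord], levels = 0:(n_attrs - 1L))))
  structure(list(incidence = incidence, tidlists = tidlists,
                 n_objects = n_objects, n_attrs = as.integer(n_attrs),
                 n_neurons = as.integer(ceiling(n_attrs / K)), K = as.integer(K),
                 dt = dt, pad = FALSE),
            class = "formal_context")
}
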