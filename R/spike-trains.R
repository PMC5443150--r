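#' Parallel spike train container
#'
#' Bundles per-neuron spike time sequences recorded (or simulated) over a
#' common interval `[t_start, t_stop)`. Times are in milliseconds throughout
#' the package. Spike times are sorted ascending within each neuron; neurons
#' are indexed 1..N in the R interface (serialized files use 0-based neuron
#' ids, see [write_spike_trains()]).
#'
#' @param trains list of numeric vectors, one per neuron, spike times in ms.
#' @param t_start,t_stop recording interval in ms; every spike time `t` must
#'   satisfy `t_start <= t < t_stop`.
#' @return An object of class `"spike_trains"`.
#' @examples
#' st <- spike_trains(list(c(1.2, 10.4), numeric(0), 5), t_start = 0, t_stop = 20)
#' n_neurons(st)
#' @export
spike_trains <- function(trains, t_start = 0, t_stop) {
  if (!is.list(trains)) stop_("`trains` must be a list of numeric vectors")
  stopifnot(is.numeric(t_start), is.numeric(t_stop), length(t_start) == 1L,
            length(t_stop) == 1L, t_stop >= t_start)
  trains <- lapply(seq_along(trains), function(i) {
    tt <- as.numeric(trains[[i]])
    if (length(tt) && any(!is.finite(tt)))
      stop_("non-finite spike time for neuron %d", i)
    if (length(tt) && (any(tt < t_start) || any(tt >= t_stop)))
      stop_("spike time out of [t_start, t_stop) for neuron %d", i)
    sort(tt)
  })
  structure(list(trains = trains, t_start = as.numeric(t_start),
                 t_stop = as.numeric(t_stop)),
            class = "spike_trains")
}

#' @rdname spike_trains
#' @param x a `spike_trains` object.
#' @export
n_neurons <- function(x) length(x$trains)

#' @rdname spike_trains
#' @export
n_spikes <- function(x) sum(lengths(x$trains))

#' @export
print.spike_trains <- function(x, ...) {
  dur <- x$t_stop - x$t_start
  rate <- if (dur > 0 && n_neurons(x) > 0)
    1000 * n_spikes(x) / dur / n_neurons(x) else NA_real_
  cat(sprintf("Parallel spike trains: %d neurons on [%g, %g) ms, %d spikes (mean %.2f Hz)\n",
              n_neurons(x), x$t_start, x$t_stop, n_spikes(x), rate))
  invisible(x)
}

#' Discretize spike trains into a binary bin-occupancy matrix
#'
#' Time is divided into contiguous half-open bins `[k*dt, (k+1)*dt)` relative
#' to `t_start`; a spike at time `t` falls into bin `floor((t - t_start)/dt)`.
#' Several spikes of the same neuron in one bin collapse ("clip") to a single
#' occupancy of 1; the number of clipped spikes is recorded in the
#' `"n_clipped"` attribute.
#'
#' @param x a [spike_trains()] object.
#' @param dt bin width in ms (> 0); at 1 ms (the default) cortical spike trains
#'   rarely place two spikes of one neuron in the same bin.
#' @return Integer 0/1 matrix of dimension `n_neurons x n_bins`
#'   (`n_bins = ceiling((t_stop - t_start)/dt)`), class `"binned_spikes"`,
#'   with attributes `dt`, `t_start` and `n_clipped`.
#' @examples
#' st <- spike_trains(list(c(3.1, 3.9)), t_stop = 10)
#' b <- bin_spikes(st, dt = 1)
#' sum(b)                 # 1: both spikes share bin 3
#' attr(b, "n_clipped")   # 1
#' @export
bin_spikes <- function(x, dt = 1) {
  stopifnot(inherits(x, "spike_trains"), is.numeric(dt), length(dt) == 1L, dt > 0)
  n_bins <- as.integer(ceiling((x$t_stop - x$t_start) / dt))
  N <- n_neurons(x)
  m <- matrix(0L, nrow = N, ncol = max(n_bins, 0L))
  clipped <- 0L
  for (i in seq_len(N)) {
    tt <- x$trains[[i]]
    if (!length(tt)) next
    idx <- floor((tt - x$t_start) / dt)
    idx[idx >= n_bins] <- n_bins - 1L  # t just below t_stop with fp round-up
    u <- unique(idx)
    clipped <- clipped + length(idx) - length(u)
    m[i, u + 1L] <- 1L
  }
  structure(m, dt = dt, t_start = x$t_start, n_clipped = clipped,
            class = c("binned_spikes", class(m)))
}

#' Uniform spike dithering (surrogate generation)
#'
#' Displaces every spike independently by a uniform draw in
#' `[-halfwidth, +halfwidth]` ms, destroying millisecond-precise temporal
#' structure while leaving the firing-rate profile (defined on a coarser time
#' scale) essentially unchanged. Displacements that would leave
#' `[t_start, t_stop)` are redrawn, so per-neuron spike counts are preserved
#' exactly.
#'
#' @param x a [spike_trains()] object.
#' @param halfwidth dither half-width in ms (>= 0). The default of 5 ms is a
#'   common choice for millisecond-precision pattern analysis; it must be
#'   large relative to the bin width and small relative to rate fluctuations.
#' @param seed optional integer seed; when supplied the session RNG is left
#'   untouched.
#' @return A `spike_trains` object with the same per-neuron spike counts.
#' @export
dither_spikes <- function(x, halfwidth = 5, seed = NULL) {
  stopifnot(inherits(x, "spike_trains"),
            is.numeric(halfwidth), length(halfwidth) == 1L, halfwidth >= 0)
  if (halfwidth == 0) return(x)
  with_seed(seed, {
    trains <- lapply(x$trains, function(tt) {
      if (!length(tt)) return(tt)
      out <- tt + runif(length(tt), -halfwidth, halfwidth)
      bad <- which(out < x$t_start | out >= x$t_stop)
      while (length(bad)) {  # redraw until inside the recording interval
        out[bad] <- tt[bad] + runif(length(bad), -halfwidth, halfwidth)
        bad <- bad[out[bad] < x$t_start | out[bad] >= x$t_stop]
      }
      sort(out)
    })
    spike_trains(trains, x$t_start, x$t_stop)
  })
}

#' Read and write plain-text spike train files
#'
#' Two dialects are supported: `"rows"` (one line per neuron, whitespace
#' separated spike times; an empty line is a neuron without spikes) and
#' `"pairs"` (two whitespace-separated columns `neuron_id time`, neuron ids
#' 0-based). Files carry `#`-prefixed header lines declaring the time unit
#' (ms) and the recording interval, which `read_spike_trains()` uses to
#' restore `t_start`/`t_stop`.
#'
#' @param x a [spike_trains()] object.
#' @param path file path.
#' @param dialect `"rows"` or `"pairs"`.
#' @return `read_spike_trains()` returns a `spike_trains` object;
#'   `write_spike_trains()` returns `path` invisibly. A written file read back
#'   reproduces the object to full double precision.
#' @export
write_spike_trains <- function(x, path, dialect = c("rows", "pairs")) {
  stopifnot(inherits(x, "spike_trains"))
  dialect <- match.arg(dialect)
  hdr <- c("# spade spike trains", "# units: ms",
           sprintf("# t_start: %.17g", x$t_start),
           sprintf("# t_stop: %.17g", x$t_stop),
           sprintf("# n_neurons: %d", n_neurons(x)),
           sprintf("# dialect: %s", dialect))
  body <- if (dialect == "rows") {
    vapply(x$trains, function(tt) paste(sprintf("%.17g", tt), collapse = " "), "")
  } else {
    unlist(lapply(seq_along(x$trains), function(i) {
      tt <- x$trains[[i]]
      if (!length(tt)) character(0) else sprintf("%d %.17g", i - 1L, tt)
    }))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_spike_trains
#' @param t_start,t_stop,n_neurons recording interval / neuron count, required
#'   only when the file has no header declaring them.
#' @export
read_spike_trains <- function(path, dialect = NULL, t_start = NULL,
                              t_stop = NULL, n_neurons = NULL) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  for (h in lines[is_hdr]) {
    kv <- regmatches(h, regexec("^#\\s*([a-z_]+):\\s*(\\S+)", h))[[1]]
    if (length(kv) == 3L) {
      val <- kv[3]
      switch(kv[2],
             t_start = { if (is.null(t_start)) t_start <- as.numeric(val) },
             t_stop = { if (is.null(t_stop)) t_stop <- as.numeric(val) },
             n_neurons = { if (is.null(n_neurons)) n_neurons <- as.integer(val) },
             dialect = { if (is.null(dialect)) dialect <- val })
    }
  }
  if (is.null(dialect)) stop_("dialect not given and not declared in the file header")
  dialect <- match.arg(dialect, c("rows", "pairs"))
  body <- lines[!is_hdr]
  lineno <- which(!is_hdr)
  parse_num <- function(s, ln) {
    v <- suppressWarnings(as.numeric(s))
    if (any(is.na(v))) stop_("parse error at line %d of %s", ln, path)
    v
  }
  if (dialect == "rows") {
    trains <- lapply(seq_along(body), function(i) {
      f <- strsplit(trimws(body[i]), "\\s+")[[1]]
      f <- f[nzchar(f)]
      if (!length(f)) numeric(0) else parse_num(f, lineno[i])
    })
    if (!is.null(n_neurons) && length(trains) != n_neurons)
      stop_("file declares %d neurons but has %d rows", n_neurons, length(trains))
  } else {
    keep <- nzchar(trimws(body))
    body <- body[keep]; lineno <- lineno[keep]
    parts <- strsplit(trimws(body), "\\s+")
    ok <- lengths(parts) == 2L
    if (any(!ok)) stop_("parse error at line %d of %s", lineno[which(!ok)[1]], path)
    ids <- vapply(seq_along(parts), function(i) parse_num(parts[[i]][1], lineno[i]), 0)
    tms <- vapply(seq_along(parts), function(i) parse_num(parts[[i]][2], lineno[i]), 0)
    if (any(ids != floor(ids) | ids < 0))
      stop_("invalid neuron id at line %d of %s", lineno[which(ids != floor(ids) | ids < 0)[1]], path)
    N <- max(n_neurons %||% 0L, if (length(ids)) max(ids) + 1L else 0L)
    trains <- lapply(seq_len(N) - 1L, function(id) tms[ids == id])
  }
  if (is.null(t_stop))
    stop_("t_stop not given and not declared in the file header")
  t_start <- t_start %||% 0
  if (any(vapply(trains, is.unsorted, TRUE)))
    warn_("unsorted spike times in %s; sorting", path)
  spike_trains(trains, t_start, t_stop)
}
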