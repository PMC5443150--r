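#' Mining configuration
#'
#' Bundles the mining-time thresholds (`min_support`, `min_size`) and the
#' post-mining signature filter (`z_min` spikes, `c_min` occurrences). The
#' defaults mirror the two-stage procedure: mine every closed set that
#' repeats (`min_support = 2`), then reject patterns with fewer than three
#' spikes or fewer than three occurrences — the simple filter that removes
#' the bulk of chance detections before any statistics are computed.
#'
#' @param min_support minimum occurrence count at mining time (>= 1).
#' @param min_size minimum pattern size at mining time (>= 1).
#' @param z_min,c_min signature filter applied by [apply_pattern_filter()].
#' @return A list of class `"mining_config"`.
#' @export
mining_config <- function(min_support = 2L, min_size = 2L, z_min = 3L, c_min = 3L) {
  v <- c(min_support = min_support, min_size = min_size, z_min = z_min, c_min = c_min)
  if (any(v < 1)) stop_("all mining_config fields must be >= 1")
  structure(as.list(as.integer(v)), names = names(v), class = "mining_config")
}

## Deterministic concept ordering: descending z*c, then descending z, then
## lexicographic intent.
order_concepts <- function(intents, extents) {
  z <- lengths(intents); c <- lengths(extents)
  key <- vapply(intents, function(v)
    paste(sprintf("%08d", v), collapse = " "), "")
  order(-(as.numeric(z) * as.numeric(c)), -z, key)
}

new_concepts <- function(intents, extents, ctx) {
  o <- order_concepts(intents, extents)
  structure(list(intent = intents[o], extent = extents[o],
                 z = lengths(intents)[o], c = lengths(extents)[o]),
            K = ctx$K, dt = ctx$dt, n_neurons = ctx$n_neurons,
            class = "spade_concepts")
}

#' @export
length.spade_concepts <- function(x) length(x$intent)

#' @export
`[.spade_concepts` <- function(x, i) {
  out <- lapply(unclass(x), `[`, i)
  attributes(out) <- attributes(x)
  out
}

#' Extract one concept
#' @param x a `spade_concepts` object.
#' @param i concept index.
#' @return A list with `intent`, `extent`, `z`, `c` (plus any annotation
#'   columns such as `sigma_int` at position `i`).
#' @export
concept_at <- function(x, i) {
  stopifnot(inherits(x, "spade_concepts"))
  lapply(unclass(x), `[[`, i)
}

#' @export
print.spade_concepts <- function(x, n = 6L, ...) {
  cat(sprintf("%d concept(s) [K = %d bins]\n", length(x), attr(x, "K")))
  for (i in seq_len(min(n, length(x)))) {
    cat(sprintf("  (z = %d, c = %d) intent {%s} extent {%s}\n", x$z[i], x$c[i],
                paste(x$intent[[i]], collapse = ","),
                paste(x$extent[[i]], collapse = ",")))
  }
  if (length(x) > n) cat(sprintf("  ... %d more\n", length(x) - n))
  invisible(x)
}

#' @export
as.data.frame.spade_concepts <- function(x, ...) {
  K <- attr(x, "K")
  data.frame(z = x$z, c = x$c,
             intent = vapply(x$intent, paste, "", collapse = ","),
             class_key = vapply(x$intent, shift_class_key, "", K = K),
             stringsAsFactors = FALSE)
}

#' Enumerate closed frequent concepts of a formal context
#'
#' Production miner: a native LCM-style enumerator (prefix-preserving closure
#' extension over transaction id lists) that returns exactly the closed
#' itemsets of the context with support `>= min_support` and size
#' `>= min_size`, together with their full extents. A closed itemset has no
#' proper superset with the same support; in FCA terms each result is a
#' formal concept (intent, extent). Output order is deterministic:
#' descending `z*c`, then descending `z`, then lexicographic intent.
#'
#' Correctness is pinned down by [brute_force_closed()], an independent
#' subset-enumeration oracle, on small contexts.
#'
#' @param ctx a [build_context()] result.
#' @param cfg a [mining_config()]; only `min_support` and `min_size` are used
#'   here (apply the signature filter with [apply_pattern_filter()]).
#' @return A `"spade_concepts"` object.
#' @export
mine_closed_frequent <- function(ctx, cfg = mining_config()) {
  stopifnot(inherits(ctx, "formal_context"), inherits(cfg, "mining_config"))
  if (ctx$n_objects < 1L) stop_("empty context")
  res <- cpp_mine_closed(ctx$incidence, ctx$n_attrs,
                         cfg$min_support, cfg$min_size)
  new_concepts(res$intent, res$extent, ctx)
}

#' Brute-force closed-concept oracle
#'
#' Computes the closure (`derive_intent` then `derive_extent`) of every
#' object subset, deduplicates, and keeps concepts with support
#' `>= min_support` and non-empty intent. Exponential in the number of
#' objects; refuses contexts with more than 20 objects. Exists solely as an
#' independent correctness oracle for [mine_closed_frequent()].
#'
#' @inheritParams mine_closed_frequent
#' @param min_support minimum extent size.
#' @param min_size minimum intent size (default 1: every non-empty intent).
#' @return A `"spade_concepts"` object.
#' @export
brute_force_closed <- function(ctx, min_support = 2L, min_size = 1L) {
  stopifnot(inherits(ctx, "formal_context"))
  G <- ctx$n_objects
  if (G > 20L)
    stop_("context has %d objects; brute_force_closed enumerates 2^|G| subsets and is limited to |G| <= 20 — use mine_closed_frequent()", G)
  seen <- new.env(parent = emptyenv())
  intents <- list(); extents <- list(); k <- 0L
  for (mask in 0:(2^G - 1L)) {
    S <- which(bitwAnd(bitwShiftL(1L, 0:(G - 1L)), mask) != 0L) - 1L
    B <- derive_intent(ctx, S)
    key <- paste0("k", paste(B, collapse = ","))
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    A <- derive_extent(ctx, B)
    if (length(A) >= min_support && length(B) >= min_size) {
      k <- k + 1L
      intents[[k]] <- sort(B); extents[[k]] <- sort(A)
    }
  }
  new_concepts(intents, extents, ctx)
}

#' Signature and shift-duplicate filter
#'
#' Removes shifted duplicates of each pattern's equivalence class and then
#' keeps concepts with at least `z_min` spikes and `c_min` occurrences.
#' Because windows slide in single-bin steps, one recurring spike structure
#' surfaces as several concepts: complete time-shifted copies of the intent,
#' and window-edge views in which leading spikes have slipped out of the
#' window. Complete copies and leading-edge (prefix-truncated) views are
#' rejected by the canonical-representative rule (minimum offset 0, see
#' [canonicalize()]); trailing-edge views — a concept whose extent is an
#' exact forward shift of a larger concept's extent and whose intent is that
#' concept's window-truncated restriction — are removed by extent matching.
#'
#' @param concepts a `"spade_concepts"` object.
#' @param z_min,c_min signature thresholds (defaults 3/3).
#' @return The filtered `"spade_concepts"` object.
#' @export
apply_pattern_filter <- function(concepts, z_min = 3L, c_min = 3L) {
  stopifnot(inherits(concepts, "spade_concepts"))
  K <- attr(concepts, "K")
  canonical <- vapply(concepts$intent, function(v)
    length(v) > 0L && min(v %% K) == 0L, TRUE)
  out <- concepts[canonical & concepts$z >= z_min & concepts$c >= c_min]
  drop_truncated_views(out, K)
}

## Remove canonical concepts that are trailing-edge truncated views of a
## larger canonical concept: extent(B) == extent(A) + s (s >= 1) and
## intent(B) == {(n, o - s) : (n, o) in intent(A), o >= s}.
drop_truncated_views <- function(concepts, K) {
  n <- length(concepts)
  if (n < 2L) return(concepts)
  # only concepts with identical occurrence count and shift-normalized
  # extent shape can be views of one structure
  shape <- vapply(concepts$extent, function(e)
    paste(e - e[1L], collapse = ","), "")
  drop <- logical(n)
  for (grp in split(seq_len(n), shape)) {
    if (length(grp) < 2L) next
    grp <- grp[order(-concepts$z[grp])]
    for (bi in seq_along(grp)[-1L]) {
      b <- grp[bi]
      for (ai in seq_len(bi - 1L)) {
        a <- grp[ai]
        if (drop[a] || concepts$z[a] <= concepts$z[b]) next
        s <- concepts$extent[[b]][1L] - concepts$extent[[a]][1L]
        if (s < 1L) next
        offA <- concepts$intent[[a]] %% K
        keep <- offA >= s
        trunc <- sort((concepts$intent[[a]][keep] %/% K) * K + (offA[keep] - s))
        if (identical(trunc, concepts$intent[[b]])) { drop[b] <- TRUE; break }
      }
    }
  }
  concepts[!drop]
}

#' Canonical spatio-temporal patterns of a concept set
#'
#' @param concepts a `"spade_concepts"` object (canonical concepts; shifted
#'   duplicates are skipped).
#' @return A list of [canonicalize()] `"stp"` objects, one per concept, with
#'   any annotation columns (`sigma_int`, `sigma_ext`, `pvalue`) copied over.
#' @export
as_patterns <- function(concepts) {
  stopifnot(inherits(concepts, "spade_concepts"))
  K <- attr(concepts, "K"); dt <- attr(concepts, "dt")
  extra <- setdiff(names(unclass(concepts)), c("intent", "extent", "z", "c"))
  out <- vector("list", length(concepts))
  keep <- logical(length(concepts))
  for (i in seq_len(length(concepts))) {
    p <- canonicalize(list(intent = concepts$intent[[i]],
                           extent = concepts$extent[[i]]), K, dt)
    if (is.null(p)) next
    for (e in extra) p[[e]] <- concepts[[e]][[i]]
    out[[i]] <- p; keep[i] <- TRUE
  }
  out[keep]
}
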