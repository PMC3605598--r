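#' Precluster configuration
#'
#' @param min_seed_flows Initial seed length in flows (default 8).
#' @param max_bin_size Bins larger than this are split by extending the seed
#'   (default 2000).
#' @param seed_step Flows added per seed extension (default 1).
#' @return A `precluster_config` object.
#' @export
precluster_config <- function(min_seed_flows = 8L, max_bin_size = 2000L,
                              seed_step = 1L) {
  if (min_seed_flows < 1L) stop("min_seed_flows must be >= 1")
  if (max_bin_size < 2L) stop("max_bin_size must be >= 2")
  if (seed_step < 1L) stop("seed_step must be >= 1")
  structure(list(min_seed_flows = as.integer(min_seed_flows),
                 max_bin_size = as.integer(max_bin_size),
                 seed_step = as.integer(seed_step)),
            class = "precluster_config")
}

#' Flow-sign seed key of a flowgram
#'
#' Over the first `seed_len` informative flows (after the key), each flow is
#' classified as positive (value >= 0.5, leading to at least one called
#' base) or negative (< 0.5). The key combines this sign pattern with the
#' called homopolymer length of the first positive flow, so that reads in
#' one precluster start with the same homopolymer length. Reads with fewer
#' informative flows than `seed_len` use what they have and are marked
#' short.
#'
#' @param fg A [flowgram].
#' @param seed_len Number of informative flows in the seed.
#' @return A single string key.
#' @export
seed_key <- function(fg, seed_len) {
  if (seed_len < 1L) stop("seed_len must be >= 1")
  w <- flow_window(fg)
  avail <- w[2] - w[1] + 1L
  n <- min(seed_len, avail)
  if (n < 1L) return("|empty")
  f <- fg$flow_values[w[1]:(w[1] + n - 1L)]
  signs <- ifelse(f >= 0.5, "+", "-")
  first_pos <- which(f >= 0.5)[1]
  h1 <- if (is.na(first_pos)) 0L else call_length(f[first_pos])
  key <- paste0(paste(signs, collapse = ""), "|", h1)
  if (n < seed_len) key <- paste0(key, "|S")
  key
}

#' Partition flowgrams into precluster bins
#'
#' Groups reads by their flow-sign [seed_key]; any bin exceeding
#' `max_bin_size` whose reads still have unconsumed informative flows is
#' recursively split by extending the seed by `seed_step` flows. Reads in
#' different bins are never compared downstream, so two duplicates can only
#' be found if no seed flow's sign differs between them. Oversized bins
#' whose seeds are exhausted are passed through whole with a warning.
#'
#' @param flowgrams List of [flowgram] objects.
#' @param cfg A [precluster_config].
#' @return Named list of integer index vectors into `flowgrams`, one per
#'   bin, in lexicographic key order; bins are disjoint and cover the input.
#' @export
precluster <- function(flowgrams, cfg = precluster_config()) {
  if (length(flowgrams) == 0L) return(list())
  avail <- vapply(flowgrams, function(fg) {
    w <- flow_window(fg); max(0L, w[2] - w[1] + 1L)
  }, 0L)

  split_bin <- function(idx, seed_len) {
    keys <- vapply(idx, function(i) seed_key(flowgrams[[i]], seed_len), "")
    groups <- split(idx, keys)
    out <- list()
    for (key in sort(names(groups))) {
      g <- groups[[key]]
      if (length(g) > cfg$max_bin_size && any(avail[g] > seed_len)) {
        out <- c(out, split_bin(g, seed_len + cfg$seed_step))
      } else {
        if (length(g) > cfg$max_bin_size)
          warning(sprintf(
            "precluster bin '%s' holds %d reads but its seed is exhausted",
            key, length(g)))
        out[[key]] <- g
      }
    }
    out
  }
  bins <- split_bin(seq_along(flowgrams), cfg$min_seed_flows)
  bins[order(names(bins))]
}
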