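#' Construct a flowgram record
#'
#' A flowgram is the flow-space representation of one 454 read: an ordered
#' vector of flow values (signal strengths, roughly the homopolymer length
#' incorporated in each nucleotide flow), together with the nucleotide flow
#' order, the library key sequence and the vendor quality-trim points.
#'
#' Flow values are quantized to hundredths on construction, matching the SFF
#' on-disk encoding (unsigned 16-bit hundredths). Clip points are stored in
#' 1-based base coordinates, as in SFF: `clip_left` is the first informative
#' called base, `clip_right` the last. Flows are 0-based nowhere: all indices
#' exposed by this package are 1-based.
#'
#' @param read_id Read identifier (non-empty string).
#' @param flow_values Numeric vector of non-negative flow values.
#' @param flow_order Nucleotide flow cycle, e.g. `"TACG"`; recycled to the
#'   number of flows. A full-length string of `length(flow_values)`
#'   characters is also accepted.
#' @param key_sequence Library key, typically 4 bases (`"TCAG"`).
#' @param clip_left,clip_right 1-based base coordinates of the informative
#'   (quality-trimmed) region of the called sequence. `clip_right = 0` means
#'   "use the full called length".
#' @return An object of class `flowgram`.
#' @examples
#' fg <- flowgram("r1", c(1.02, 0.05, 2.10, 0.98), flow_order = "TACG",
#'                key_sequence = "", clip_left = 1, clip_right = 0)
#' flow_to_bases(fg)
#' @export
flowgram <- function(read_id, flow_values, flow_order = "TACG",
                     key_sequence = "TCAG", clip_left = 1L, clip_right = 0L) {
  if (!is.character(read_id) || length(read_id) != 1L || !nzchar(read_id))
    stop("read_id must be a non-empty string")
  if (any(flow_values < 0))
    stop("flow values must be non-negative")
  n <- length(flow_values)
  fv <- floor(flow_values * 100 + 0.5) / 100  # half-up, matching base calling
  fo <- expand_flow_order(flow_order, n)
  fg <- structure(
    list(read_id = read_id,
         flow_values = fv,
         flow_order = fo,
         key_sequence = toupper(key_sequence),
         clip_left = as.integer(clip_left),
         clip_right = as.integer(clip_right),
         n_flows = n),
    class = "flowgram")
  ncall <- length(base_flow_index(fg))
  if (fg$clip_right == 0L) fg$clip_right <- as.integer(ncall)
  if (fg$clip_left < 1L || fg$clip_left > fg$clip_right + 1L)
    stop("clip_left must lie in [1, clip_right + 1]")
  if (fg$clip_right > ncall)
    stop(sprintf("clip_right (%d) exceeds called length (%d) for read '%s'",
                 fg$clip_right, ncall, read_id))
  fg
}

expand_flow_order <- function(flow_order, n_flows) {
  fo <- toupper(flow_order)
  if (nchar(fo) < n_flows)
    fo <- strtrim(paste(rep(fo, ceiling(n_flows / nchar(fo))), collapse = ""),
                  n_flows)
  substr(fo, 1L, n_flows)
}

#' @export
print.flowgram <- function(x, ...) {
  cat(sprintf("<flowgram> %s: %d flows (%s...), key '%s', clip [%d, %d]\n",
              x$read_id, x$n_flows, substr(x$flow_order, 1, 8),
              x$key_sequence, x$clip_left, x$clip_right))
  invisible(x)
}

#' Round a flow value to its called homopolymer length
#'
#' 454 base calling rounds half-up: a flow value of exactly 0.5 leads to one
#' called base.
#'
#' @param f Numeric vector of flow values.
#' @return Integer vector of called homopolymer lengths.
#' @export
call_length <- function(f) as.integer(floor(f + 0.5))

#' Convert a flowgram to its called nucleotide sequence
#'
#' Each flow emits `call_length(f)` copies of that flow's nucleotide; the
#' concatenation over all flows is the called sequence (key bases included,
#' untrimmed).
#'
#' @param fg A [flowgram].
#' @return A single string (possibly empty).
#' @export
flow_to_bases <- function(fg) {
  h <- call_length(fg$flow_values)
  if (sum(h) == 0L) return("")
  nt <- strsplit(fg$flow_order, "")[[1]]
  paste(rep(nt, h), collapse = "")
}

#' Encode a nucleotide sequence as integer flow values
#'
#' The inverse of [flow_to_bases] for noise-free reads: walks `seq` through
#' the flow order, emitting the homopolymer run length whenever the flow
#' nucleotide matches the next base and 0 otherwise. Used by the simulator.
#'
#' @param seq Nucleotide string.
#' @param flow_order Flow cycle, e.g. `"TACG"`.
#' @param n_flows Total flows to emit; the sequence is consumed until either
#'   it ends or `n_flows` is reached.
#' @return Integer vector of length `n_flows` of ideal flow values.
#' @export
bases_to_flows <- function(seq, flow_order = "TACG", n_flows = 800L) {
  fo <- strsplit(expand_flow_order(flow_order, n_flows), "")[[1]]
  bases <- strsplit(toupper(seq), "")[[1]]
  flows <- integer(n_flows)
  j <- 1L
  for (i in seq_len(n_flows)) {
    k <- 0L
    while (j + k <= length(bases) && bases[j + k] == fo[i]) k <- k + 1L
    flows[i] <- k
    j <- j + k
    if (j > length(bases)) break
  }
  flows
}

# Flow index incorporating each called base: flow i contributes
# call_length(f_i) consecutive bases.
base_flow_index <- function(fg) {
  h <- call_length(fg$flow_values)
  rep(seq_along(h), h)
}

# Number of flows consumed by the key sequence (the flow incorporating the
# last key base). 0 when there is no key.
key_flow_end <- function(fg) {
  k <- nchar(fg$key_sequence)
  if (k == 0L) return(0L)
  bfi <- base_flow_index(fg)
  if (length(bfi) < k)
    stop(sprintf("read '%s' does not call its full key sequence", fg$read_id))
  bfi[k]
}

#' Informative flow window of a flowgram
#'
#' Converts the base-coordinate clip points to flow coordinates by walking
#' the called sequence, and additionally excludes the flows consumed by the
#' key. Only flows inside this window take part in distance, precluster and
#' consensus computations.
#'
#' @param fg A [flowgram].
#' @return Integer vector `c(start, end)` of 1-based flow indices; `start >
#'   end` denotes an empty window.
#' @export
flow_window <- function(fg) {
  bfi <- base_flow_index(fg)
  kend <- key_flow_end(fg)
  if (fg$clip_right < fg$clip_left || fg$clip_right > length(bfi))
    return(c(kend + 1L, kend))
  start <- max(kend + 1L, bfi[fg$clip_left])
  end <- bfi[fg$clip_right]
  c(start, end)
}

# Called bases inside the trimmed region.
n_trimmed_bases <- function(fg) max(0L, fg$clip_right - fg$clip_left + 1L)
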