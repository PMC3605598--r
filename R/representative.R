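#' Select one representative read per cluster
#'
#' Three modes are supported. `"longest"` keeps the member with the most
#' called bases in its trimmed region. `"best"` keeps the member whose flow
#' values lie closest to integers, minimizing the per-flow score
#' `s = sum_i (f_i - round(f_i))^2 / n_trim` over the trimmed flows (flow
#' values near integers are the most accurately resolved). `"consensus"`
#' emits the cluster's consensus flowgram, an artificial read that need not
#' equal any member. Ties are broken by trimmed length, then input order.
#'
#' @param members Non-empty list of [flowgram] objects (one cluster).
#' @param consensus The cluster's consensus [flowgram] (required for mode
#'   `"consensus"`; defaults to computing it on the fly).
#' @param mode One of `"longest"`, `"best"`, `"consensus"`.
#' @return A [flowgram].
#' @export
select_representative <- function(members, consensus = NULL,
                                  mode = c("longest", "best", "consensus")) {
  mode <- match.arg(mode)
  if (length(members) == 0L) stop("cannot pick a representative of an empty cluster")
  if (mode == "consensus") {
    if (is.null(consensus)) consensus <- consensus_flowgram(members)
    return(consensus)
  }
  lens <- vapply(members, n_trimmed_bases, 0L)
  if (mode == "longest") {
    return(members[[which.max(lens)]])  # which.max: first max wins ties
  }
  score <- vapply(members, best_score, 0)
  best <- which(score == min(score))
  if (length(best) > 1L) best <- best[which.max(lens[best])]
  members[[best[1L]]]
}

# Squared deviation of trimmed flow values from their nearest integers,
# normalized by the number of trimmed flows.
best_score <- function(fg) {
  w <- flow_window(fg)
  if (w[2] < w[1]) return(Inf)
  f <- fg$flow_values[w[1]:w[2]]
  sum((f - call_length(f))^2) / length(f)
}

#' Representatives for every cluster of a clustering
#'
#' @param flowgrams The full read set that was clustered.
#' @param cs A `cluster_set` from [dedupe] or [agglomerate].
#' @param mode Representative mode, see [select_representative].
#' @return List of [flowgram] objects, one per cluster, in cluster order.
#' @export
representatives <- function(flowgrams, cs, mode = "longest") {
  by_id <- stats::setNames(flowgrams,
                           vapply(flowgrams, function(f) f$read_id, ""))
  lapply(names(cs$clusters), function(cid) {
    select_representative(by_id[cs$clusters[[cid]]],
                          consensus = cs$consensus[[cid]], mode = mode)
  })
}
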