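#' Consensus flowgram of a cluster
#'
#' The consensus value at flow i is the median of the member flow values at
#' i; even member counts use the midpoint of the two central values. The
#' consensus window ends at the lowest member trim point (in flow space), so
#' the consensus never extends past any member's informative region. For a
#' singleton cluster the member itself is returned.
#'
#' Duplicate clusters tend to stretch to one side of the integer at each
#' flow, so the per-flow median tracks the cluster's shared signal better
#' than rounding individual reads would.
#'
#' @param members Non-empty list of [flowgram] objects sharing flow order
#'   and key.
#' @return A [flowgram]; its trimmed window covers the flows shared by all
#'   members.
#' @export
consensus_flowgram <- function(members) {
  if (length(members) == 0L) stop("cannot build a consensus of zero flowgrams")
  if (length(members) == 1L) return(members[[1L]])
  wins <- vapply(members, flow_window, integer(2))
  start <- max(wins[1, ])
  end <- min(wins[2, ])
  n_flows <- members[[1L]]$n_flows
  vals <- vapply(members, function(fg) fg$flow_values[seq_len(end)],
                 numeric(end))
  med <- numeric(n_flows)  # flows past the shortest member trim stay 0
  med[seq_len(end)] <- if (length(members) == 2L) rowMeans(vals)
    else apply(vals, 1L, stats::median)
  key_bases <- members[[1L]]$clip_left - 1L
  cons <- flowgram(read_id = paste0("consensus:", members[[1L]]$read_id),
                   flow_values = med,
                   flow_order = members[[1L]]$flow_order,
                   key_sequence = members[[1L]]$key_sequence,
                   clip_left = key_bases + 1L,
                   clip_right = 0L)
  if (end < start) cons$clip_right <- cons$clip_left - 1L
  cons
}

new_cluster_set <- function(clusters, consensus, threshold) {
  structure(list(clusters = clusters, consensus = consensus,
                 threshold = threshold),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("<cluster_set> %d reads in %d clusters (threshold %.3f)\n",
              sum(sizes), length(sizes), x$threshold))
  if (length(sizes)) print(table(size = sizes))
  invisible(x)
}

#' Agglomerative flowgram clustering within one bin
#'
#' Starts from singleton clusters and repeatedly merges the pair of
#' clusters with the smallest consensus-to-consensus distance. After each
#' merge the new cluster's consensus flowgram is recomputed and its
#' distances to all other clusters are updated. Clustering stops as soon as
#' all pairwise distances exceed `threshold`. Ties on the minimum distance
#' are broken towards the lexicographically smallest pair of cluster
#' indices, making the procedure deterministic for a given input order.
#'
#' @param bin List of [flowgram] objects (one precluster bin).
#' @param threshold Stringency threshold: the maximum distance at which two
#'   clusters may still be merged.
#' @param cfg A [distance_config].
#' @return A `cluster_set` with one consensus per cluster.
#' @export
agglomerate <- function(bin, threshold = 0.05, cfg = distance_config()) {
  k <- length(bin)
  if (k == 0L)
    return(new_cluster_set(list(), list(), threshold))
  members <- lapply(bin, function(fg) fg$read_id)
  fgs <- lapply(bin, list)
  cons <- bin
  if (k > 1L) {
    D <- matrix(Inf, k, k)
    for (i in 1:(k - 1L)) for (j in (i + 1L):k)
      D[i, j] <- flowgram_distance(cons[[i]], cons[[j]], cfg)
    active <- rep(TRUE, k)
    repeat {
      dmin <- min(D)
      if (dmin > threshold) break
      hit <- which(D == dmin, arr.ind = TRUE)
      hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
      i <- hit[1L, 1L]; j <- hit[1L, 2L]
      members[[i]] <- c(members[[i]], members[[j]])
      fgs[[i]] <- c(fgs[[i]], fgs[[j]])
      cons[[i]] <- consensus_flowgram(fgs[[i]])
      active[j] <- FALSE
      D[j, ] <- Inf; D[, j] <- Inf
      for (m in which(active)) {
        if (m == i) next
        d <- flowgram_distance(cons[[i]], cons[[m]], cfg)
        if (m < i) D[m, i] <- d else D[i, m] <- d
      }
      if (sum(active) == 1L) break
    }
    keep <- which(active)
    members <- members[keep]
    cons <- cons[keep]
  }
  ids <- sprintf("c%d", seq_along(members))
  names(members) <- ids
  names(cons) <- ids
  new_cluster_set(members, cons, threshold)
}

#' Duplicate-read clustering of a full flowgram set
#'
#' The complete flow-space duplicate filter: preclusters reads on flow-sign
#' seeds, then runs [agglomerate] within each bin, and merges the per-bin
#' partitions. Reads in different precluster bins are never compared. Logs
#' the bin count, the cluster-size histogram and the estimated duplicate
#' rate.
#'
#' @param flowgrams List of [flowgram] objects.
#' @param threshold Stringency threshold (default 0.05, a good starting
#'   point in practice).
#' @param cfg A [distance_config].
#' @param pre_cfg A [precluster_config].
#' @param verbose Emit progress messages.
#' @return A `cluster_set` covering all reads.
#' @export
dedupe <- function(flowgrams, threshold = 0.05, cfg = distance_config(),
                   pre_cfg = precluster_config(), verbose = FALSE) {
  bins <- precluster(flowgrams, pre_cfg)
  if (verbose)
    message(sprintf("preclustered %d reads into %d bins",
                    length(flowgrams), length(bins)))
  members <- list()
  consensus <- list()
  for (b in bins) {
    cs <- agglomerate(flowgrams[b], threshold, cfg)
    members <- c(members, unname(cs$clusters))
    consensus <- c(consensus, unname(cs$consensus))
  }
  ids <- sprintf("c%d", seq_along(members))
  names(members) <- ids
  names(consensus) <- ids
  out <- new_cluster_set(members, consensus, threshold)
  if (verbose) {
    sizes <- lengths(members)
    hist <- table(sizes)
    message(sprintf("clusters: %d; size histogram: %s", length(members),
                    paste(sprintf("%sx%s", hist, names(hist)),
                          collapse = ", ")))
    if (length(flowgrams) > 0)
      message(sprintf("estimated duplicate rate: %.2f%%",
                      duplicate_rate(out, length(flowgrams))))
  }
  out
}

#' Cluster membership as a data frame
#'
#' @param cs A `cluster_set` or `truth_set`.
#' @return Data frame with columns `read_id`, `cluster_id`.
#' @export
membership <- function(cs) {
  data.frame(read_id = unlist(cs$clusters, use.names = FALSE),
             cluster_id = rep(names(cs$clusters), lengths(cs$clusters)),
             stringsAsFactors = FALSE)
}

#' Write / read a cluster membership file
#'
#' Two-column tab-separated text: `read_id TAB cluster_id`, shared between
#' the clustering output and the simulator's truth file.
#'
#' @param cs A `cluster_set` or `truth_set`.
#' @param path File path.
#' @return `write_membership`: invisibly, `path`.
#' @export
write_membership <- function(cs, path) {
  utils::write.table(membership(cs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_membership
#' @param source Partition provenance label for the returned object.
#' @return `read_membership`: a `truth_set`-like partition object.
#' @export
read_membership <- function(path, source = "file") {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("read_id", "cluster_id"),
                           colClasses = "character")
  truth_set(split(tab$read_id, tab$cluster_id), source = source)
}
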