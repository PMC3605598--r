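#' Ground-truth duplicate partition
#'
#' @param clusters List of character vectors of read ids (a partition).
#' @param source Provenance: `"alignment-derived"`, `"simulated"` or other.
#' @return A `truth_set` object.
#' @export
truth_set <- function(clusters, source = "simulated") {
  ids <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(ids))
    stop("truth clusters are not a partition: duplicated read ids")
  if (is.null(names(clusters)) || any(!nzchar(names(clusters))))
    names(clusters) <- sprintf("t%d", seq_along(clusters))
  structure(list(clusters = clusters, source = source), class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("<truth_set> (%s) %d reads in %d clusters\n", x$source,
              sum(lengths(x$clusters)), length(x$clusters)))
  invisible(x)
}

#' Ground-truth duplicate clusters from SAM alignments
#'
#' Reads mapped to a reference start at identical positions when they are
#' duplicates, so truth clusters are formed by grouping reads on (reference,
#' strand-aware alignment start, read-sequence prefix). Records are handled
#' as follows: unmapped records are dropped; alignments whose CIGAR begins
#' with a hard clip are discarded (the initial part of the read is masked,
#' so its start is not comparable); reverse-strand records are canonicalized
#' to the forward axis by using the alignment end as the strand-aware start
#' and the reverse complement of the last bases as the read prefix, which is
#' equivalent to mapping against the reverse-complemented reference and
#' keeping forward matches. Soft-clipped records are kept (and counted in a
#' message).
#'
#' @param sam_path Path to a SAM text file.
#' @param prefix_len Read-prefix length used in the grouping key (default
#'   16 bases).
#' @return A `truth_set` with `source = "alignment-derived"`.
#' @export
truth_from_sam <- function(sam_path, prefix_len = 16L) {
  lines <- readLines(sam_path)
  keys <- character(0)
  ids <- character(0)
  n_soft <- 0L
  for (ln in seq_along(lines)) {
    if (!nzchar(lines[ln]) || startsWith(lines[ln], "@")) next
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L)
      stop(sprintf("%s: unparseable SAM record at line %d", sam_path, ln))
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.integer(f[4]))
    if (is.na(flag) || is.na(pos))
      stop(sprintf("%s: unparseable SAM record at line %d", sam_path, ln))
    if (bitwAnd(flag, 4L) != 0L) next                 # unmapped
    cigar <- f[6]
    if (grepl("^[0-9]+H", cigar)) next                # masked read start
    if (grepl("^[0-9]+S", cigar)) n_soft <- n_soft + 1L
    seq <- f[10]
    if (bitwAnd(flag, 16L) == 0L) {
      start <- pos
      strand <- "+"
      prefix <- substr(seq, 1L, prefix_len)
    } else {
      start <- pos + cigar_reference_length(cigar) - 1L
      strand <- "-"
      tail_seq <- substr(seq, max(1L, nchar(seq) - prefix_len + 1L),
                         nchar(seq))
      prefix <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tail_seq)))
    }
    keys <- c(keys, paste(f[3], strand, start, prefix, sep = "\r"))
    ids <- c(ids, f[1])
  }
  if (n_soft > 0L)
    message(sprintf("kept %d soft-clipped alignment(s)", n_soft))
  truth_set(unname(split(ids, keys)), source = "alignment-derived")
}

cigar_reference_length <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[MIDNSHP=X]", "", ops))
  op <- sub("[0-9]+", "", ops)
  sum(len[op %in% c("M", "D", "N", "=", "X")])
}

#' Estimated duplicate rate of a partition
#'
#' Keeping one representative per cluster removes `n_reads - n_clusters`
#' reads; the duplicate rate is that count as a percentage of all reads.
#'
#' @param cs A `cluster_set` or `truth_set`.
#' @param n_reads Total number of clustered reads.
#' @return Percentage in [0, 100).
#' @export
duplicate_rate <- function(cs, n_reads) {
  if (n_reads <= 0L) stop("n_reads must be positive")
  if (sum(lengths(cs$clusters)) != n_reads)
    stop(sprintf("partition covers %d reads, not n_reads = %d",
                 sum(lengths(cs$clusters)), n_reads))
  100 * (n_reads - length(cs$clusters)) / n_reads
}

#' Pair counts between a truth partition and a predicted clustering
#'
#' Over all unordered read pairs: `a` pairs are clustered together in both
#' partitions (correctly identified duplicates), `b` pairs are together in
#' truth only (missed duplicates), `c` pairs are together in the prediction
#' only (spurious duplicates). Computed with cluster-size combinatorics
#' (sums of binomial coefficients over the contingency table), not by pair
#' enumeration.
#'
#' @param truth A `truth_set`.
#' @param predicted A `cluster_set` (or second `truth_set`).
#' @return Named numeric vector `c(a = , b = , c = )`.
#' @export
pair_counts <- function(truth, predicted) {
  mt <- membership(truth)
  mp <- membership(predicted)
  if (!setequal(mt$read_id, mp$read_id)) {
    only_t <- setdiff(mt$read_id, mp$read_id)
    only_p <- setdiff(mp$read_id, mt$read_id)
    stop(sprintf(
      "partitions cover different reads (%d only in truth: %s%s; %d only in prediction: %s%s)",
      length(only_t), paste(utils::head(only_t, 3), collapse = ","),
      if (length(only_t) > 3) ",..." else "",
      length(only_p), paste(utils::head(only_p, 3), collapse = ","),
      if (length(only_p) > 3) ",..." else ""))
  }
  tl <- stats::setNames(mt$cluster_id, mt$read_id)
  pl <- stats::setNames(mp$cluster_id, mp$read_id)
  tab <- table(tl, pl[names(tl)])
  choose2 <- function(n) n * (n - 1) / 2
  a <- sum(choose2(tab))
  within_truth <- sum(choose2(rowSums(tab)))
  within_pred <- sum(choose2(colSums(tab)))
  c(a = a, b = within_truth - a, c = within_pred - a)
}

#' Pair-counting Jaccard index between two partitions
#'
#' J = a / (a + b + c) over unordered read pairs (see [pair_counts]).
#' Identical partitions give 1; a prediction of all singletons against a
#' truth containing pairs gives 0. When both partitions are all singletons
#' (no pairs anywhere), J is defined as 1, the limit of identical
#' partitions.
#'
#' @inheritParams pair_counts
#' @return A value in [0, 1].
#' @export
jaccard <- function(truth, predicted) {
  pc <- pair_counts(truth, predicted)
  denom <- sum(pc)
  if (denom == 0) return(1)
  unname(pc["a"] / denom)
}

#' Stringency threshold sweep
#'
#' Reruns [dedupe] at each threshold on one fixed read set and tabulates
#' the estimated duplicate rate (and, when a truth partition is supplied,
#' the Jaccard index against it) per threshold.
#'
#' @param flowgrams List of [flowgram] objects.
#' @param thresholds Numeric vector of stringency thresholds.
#' @param truth Optional `truth_set`.
#' @param cfg,pre_cfg Passed to [dedupe].
#' @return Data frame with columns `threshold`, `duplicate_rate`,
#'   `jaccard` (NA without truth), `n_clusters`.
#' @export
threshold_sweep <- function(flowgrams, thresholds, truth = NULL,
                            cfg = distance_config(),
                            pre_cfg = precluster_config()) {
  rows <- lapply(thresholds, function(th) {
    cs <- dedupe(flowgrams, threshold = th, cfg = cfg, pre_cfg = pre_cfg)
    data.frame(threshold = th,
               duplicate_rate = duplicate_rate(cs, length(flowgrams)),
               jaccard = if (is.null(truth)) NA_real_ else jaccard(truth, cs),
               n_clusters = length(cs$clusters))
  })
  do.call(rbind, rows)
}
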