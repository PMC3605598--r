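#' Simulator configuration
#'
#' Describes a synthetic 454-like run with known duplicate structure.
#' Artificial duplicates arise from emulsion-PCR artifacts: members of a
#' duplicate cluster share the template start position exactly but are
#' sequenced independently, so they receive independent per-flow noise and
#' independent length truncation. Noise is drawn from the same parametric
#' family as [default_parametric_model]: homopolymer h >= 1 flows get
#' normal noise whose width grows with h and with the flow cycle, h = 0
#' flows get exponential noise.
#'
#' @param n_reads Total reads to simulate (default 1000).
#' @param duplicate_rate Target fraction of reads that are duplicates, i.e.
#'   removed when keeping one representative per cluster (default 0.2).
#' @param cluster_size_probs Named probabilities of duplicate-cluster sizes
#'   2, 3, 4, ...; the default (75\% pairs, 18\% triples, 5\% quadruples,
#'   2\% quintuples) follows observed duplicate-cluster size spectra.
#' @param read_length_flows `c(mean, sd)` of the trimmed read length in
#'   informative flows (default 250 +/- 50, about 140 bases).
#' @param min_length_flows Lower clamp on trimmed length (default 50).
#' @param noise List: `scale` multiplies all noise widths (0 = noise-free),
#'   plus `base_sigma`, `sigma_slope`, `degradation_rate`, `lambda0` as in
#'   [default_parametric_model].
#' @param genome_length Bases of the random template genome (default 50000).
#' @param n_flows Flows per read (default 800, Titanium chemistry).
#' @param flow_order,key_sequence Flow cycle and library key.
#' @param seed Random seed fixing all randomness.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_reads = 1000L, duplicate_rate = 0.2,
                       cluster_size_probs = c("2" = 0.75, "3" = 0.18,
                                              "4" = 0.05, "5" = 0.02),
                       read_length_flows = c(mean = 250, sd = 50),
                       min_length_flows = 50L,
                       noise = list(scale = 1, base_sigma = 0.10,
                                    sigma_slope = 0.02,
                                    degradation_rate = 0.002, lambda0 = 23),
                       genome_length = 50000L, n_flows = 800L,
                       flow_order = "TACG", key_sequence = "TCAG",
                       seed = 1L) {
  if (duplicate_rate < 0 || duplicate_rate >= 1)
    stop("duplicate_rate must lie in [0, 1)")
  if (abs(sum(cluster_size_probs) - 1) > 1e-9)
    stop("cluster_size_probs must sum to 1")
  if (any(as.integer(names(cluster_size_probs)) < 2L))
    stop("duplicate clusters have size >= 2")
  structure(list(n_reads = as.integer(n_reads),
                 duplicate_rate = duplicate_rate,
                 cluster_size_probs = cluster_size_probs,
                 read_length_flows = read_length_flows,
                 min_length_flows = as.integer(min_length_flows),
                 noise = noise, genome_length = as.integer(genome_length),
                 n_flows = as.integer(n_flows), flow_order = flow_order,
                 key_sequence = key_sequence, seed = as.integer(seed)),
            class = "sim_config")
}

# One noisy flow value per ideal homopolymer length; vectorized over flows.
noisy_flows <- function(ideal, noise) {
  n <- length(ideal)
  cycle <- ceiling(seq_len(n) / 4)
  f <- numeric(n)
  z <- ideal == 0L
  if (noise$scale == 0) return(as.numeric(ideal))
  f[z] <- noise$scale * stats::rexp(sum(z), rate = noise$lambda0)
  if (any(!z)) {
    h <- ideal[!z]
    s <- (noise$base_sigma + noise$sigma_slope * h) *
      (1 + noise$degradation_rate * cycle[!z]) * noise$scale
    f[!z] <- pmax(0, stats::rnorm(sum(!z), mean = h, sd = s))
  }
  f
}

#' Simulate a 454-like run with known duplicate clusters
#'
#' Draws a random genome, places duplicate clusters and singleton reads at
#' distinct template starts, and sequences every read independently through
#' the flow-space noise model. The realized duplicate rate equals the
#' configured target exactly (cluster sizes are capped during drawing so the
#' duplicate count comes out to `round(duplicate_rate * n_reads)`). Length
#' variation truncates at flow boundaries and sets the quality clip points
#' at the truncation point.
#'
#' @param cfg A [sim_config].
#' @return List with elements `flowgrams` (list of [flowgram]), `truth` (a
#'   `truth_set`, source `"simulated"`), and `config`.
#' @export
simulate_run <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  n_dup <- round(cfg$duplicate_rate * cfg$n_reads)
  max_multi <- cfg$n_reads - n_dup   # every cluster keeps one representative
  if (n_dup > 0L && max_multi < 1L)
    stop("infeasible config: duplicate clusters exceed the read budget")
  sizes <- integer(0)
  remaining <- n_dup
  while (remaining > 0L) {
    s <- as.integer(sample(names(cfg$cluster_size_probs), 1L,
                           prob = cfg$cluster_size_probs))
    s <- min(s, remaining + 1L)
    if (length(sizes) + 1L == max_multi) s <- remaining + 1L
    sizes <- c(sizes, s)
    remaining <- remaining - (s - 1L)
  }
  n_singletons <- cfg$n_reads - n_dup - length(sizes)
  sizes <- c(sizes, rep(1L, n_singletons))
  n_clusters <- length(sizes)

  genome <- paste(sample(c("T", "A", "C", "G"), cfg$genome_length,
                         replace = TRUE), collapse = "")
  span <- cfg$n_flows  # upper bound on template bases one read can consume
  if (cfg$genome_length - span < 2L * n_clusters)
    stop("infeasible config: genome too short for distinct template starts")
  last_key_nt <- substr(cfg$key_sequence, nchar(cfg$key_sequence),
                        nchar(cfg$key_sequence))
  cand <- sample.int(cfg$genome_length - span, min(cfg$genome_length - span,
                                                   4L * n_clusters))
  cand <- cand[substring(genome, cand, cand) != last_key_nt]  # avoid key merge
  if (length(cand) < n_clusters)
    stop("infeasible config: not enough usable template starts")
  starts <- cand[seq_len(n_clusters)]

  mlen <- cfg$read_length_flows[["mean"]]
  msd <- cfg$read_length_flows[["sd"]]
  flowgrams <- vector("list", cfg$n_reads)
  truth <- vector("list", n_clusters)
  r <- 0L
  for (k in seq_len(n_clusters)) {
    template <- substr(genome, starts[k], starts[k] + span - 1L)
    ideal <- bases_to_flows(paste0(cfg$key_sequence, template),
                            cfg$flow_order, cfg$n_flows)
    key_end <- if (nchar(cfg$key_sequence) > 0)
      which(cumsum(ideal) >= nchar(cfg$key_sequence))[1] else 0L
    ids <- character(sizes[k])
    for (m in seq_len(sizes[k])) {
      r <- r + 1L
      id <- sprintf("r%05d", r)
      ids[m] <- id
      len <- round(stats::rnorm(1L, mlen, msd))
      len <- max(cfg$min_length_flows, min(len, cfg$n_flows - key_end))
      f <- noisy_flows(ideal, cfg$noise)
      trim_flow <- key_end + len
      calls <- call_length(round(f * 100) / 100)
      clip_right <- sum(calls[seq_len(trim_flow)])
      flowgrams[[r]] <- flowgram(
        read_id = id, flow_values = f, flow_order = cfg$flow_order,
        key_sequence = cfg$key_sequence,
        clip_left = nchar(cfg$key_sequence) + 1L,
        clip_right = clip_right)
    }
    truth[[k]] <- ids
  }
  list(flowgrams = flowgrams,
       truth = truth_set(truth, source = "simulated"),
       config = cfg)
}
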