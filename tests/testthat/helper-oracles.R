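# Independent reference implementations used as oracles. These deliberately
# avoid the package's vectorized/log-space/cached code paths.

# Bare flowgram with no key and explicit clip, for hand-built examples.
bare_fg <- function(id, values, clip_right = NULL, flow_order = "TACG") {
  fg <- flowgram(id, values, flow_order = flow_order, key_sequence = "",
                 clip_left = 1L, clip_right = 0L)
  if (!is.null(clip_right)) fg$clip_right <- as.integer(clip_right)
  fg
}

# Direct evaluation of the posterior from prior and likelihood, no log-space.
oracle_posterior <- function(model, f, cycle) {
  num <- vapply(0:model$h_max,
                function(h) model$lik_fun(f, h, cycle) * model$prior[h + 1L],
                0)
  num / sum(num)
}

# Equal-homopolymer probability by explicit summation.
oracle_prob_equal <- function(model, fa, fb, cycle) {
  if (fa > model$cap_high_single || fb > model$cap_high_single) return(1)
  if (fa > model$cap_high_both && fb > model$cap_high_both) return(1)
  pa <- oracle_posterior(model, fa, cycle)
  pb <- oracle_posterior(model, fb, cycle)
  s <- 0
  for (h in 0:model$equal_sum_max) s <- s + pa[h + 1L] * pb[h + 1L]
  s
}

# Per-flow recomputation of the flowgram distance.
oracle_distance <- function(fg_a, fg_b, cfg) {
  wa <- flow_window(fg_a); wb <- flow_window(fg_b)
  start <- max(wa[1], wb[1])
  end <- min(wa[2], wb[2], start + cfg$max_flows - 1L)
  stopifnot(end >= start)
  lp <- 0
  for (i in start:end)
    lp <- lp + log(oracle_prob_equal(cfg$model, fg_a$flow_values[i],
                                     fg_b$flow_values[i], ceiling(i / 4)))
  1 - exp(lp / (end - start + 1L))
}

# Naive agglomerative clustering: at every step rebuilds every consensus
# from scratch and recomputes the full distance matrix.
oracle_agglomerate <- function(bin, threshold, cfg) {
  clusters <- lapply(seq_along(bin), function(i) i)
  consensus_of <- function(idx) {
    if (length(idx) == 1L) return(bin[[idx]])
    mem <- bin[idx]
    wins <- sapply(mem, flow_window)
    end <- min(wins[2, ])
    nf <- mem[[1]]$n_flows
    med <- numeric(nf)
    for (fl in seq_len(nf)) {
      if (fl > end) break
      med[fl] <- stats::median(vapply(mem, function(m) m$flow_values[fl], 0))
    }
    fg <- flowgram("oracle-cons", med, flow_order = mem[[1]]$flow_order,
                   key_sequence = mem[[1]]$key_sequence,
                   clip_left = mem[[1]]$clip_left, clip_right = 0L)
    fg
  }
  repeat {
    k <- length(clusters)
    if (k <= 1L) break
    cons <- lapply(clusters, consensus_of)
    best <- NULL; dmin <- Inf
    for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
      d <- flowgram_distance(cons[[i]], cons[[j]], cfg)
      if (d < dmin) { dmin <- d; best <- c(i, j) }
    }
    if (dmin > threshold) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  lapply(clusters, function(idx)
    sort(vapply(bin[idx], function(fg) fg$read_id, "")))
}

# Partition as a canonical set of sorted member vectors, for comparison.
canonical_partition <- function(clusters) {
  p <- lapply(unname(clusters), sort)
  p[order(vapply(p, `[`, "", 1L))]
}

# Brute-force pair counting by enumerating all unordered read pairs.
oracle_pair_counts <- function(truth, predicted) {
  label_of <- function(cs) {
    m <- membership(cs)
    stats::setNames(m$cluster_id, m$read_id)
  }
  tl <- label_of(truth); pl <- label_of(predicted)
  ids <- sort(names(tl))
  a <- b <- cc <- 0
  n <- length(ids)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    same_t <- tl[ids[i]] == tl[ids[j]]
    same_p <- pl[ids[i]] == pl[ids[j]]
    if (same_t && same_p) a <- a + 1
    else if (same_t) b <- b + 1
    else if (same_p) cc <- cc + 1
  }
  c(a = a, b = b, c = cc)
}

# Small simulated bin of duplicate-heavy reads for clustering tests.
sim_bin <- function(n, seed, dup_rate = 0.4, noise_scale = 1) {
  cfg <- sim_config(n_reads = n, duplicate_rate = dup_rate,
                    genome_length = 20000L, seed = seed)
  cfg$noise$scale <- noise_scale
  simulate_run(cfg)
}
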