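#' Flow-value probability models
#'
#' A flow model supplies the three distributions behind the flow-space
#' distance: the homopolymer-length prior P(h), the flow-value likelihood
#' P(f|h) (dependent on the flow cycle, since signal quality degrades
#' towards later cycles), and through Bayes' theorem the posterior P(h|f).
#' From the posteriors of two independently sequenced flow values, the
#' probability that both represent the same homopolymer length is the inner
#' product of the posteriors over h = 0..`equal_sum_max`, with two capping
#' rules for poorly resolved signals: the probability is fixed to 1 when at
#' least one value exceeds `cap_high_single` (default 5.5) or when both
#' exceed `cap_high_both` (default 2.5). Long homopolymers are thus never
#' allowed to drive reads apart, which mirrors the dominance of homopolymer
#' miscalls among 454 errors.
#'
#' Two implementations share one interface: a parametric stand-in
#' ([default_parametric_model]) and empirical lookup tables
#' ([load_lookup_model]).
#'
#' @name flow_model
NULL

new_flow_model <- function(type, h_max, prior, lik_fun, params = list(),
                           cap_high_single = 5.5, cap_high_both = 2.5,
                           equal_sum_max = 5L) {
  structure(
    list(type = type, h_max = as.integer(h_max),
         prior = prior / sum(prior), lik_fun = lik_fun, params = params,
         cap_high_single = cap_high_single, cap_high_both = cap_high_both,
         equal_sum_max = as.integer(min(equal_sum_max, h_max)),
         cache = new.env(parent = emptyenv())),
    class = "flow_model")
}

#' @export
print.flow_model <- function(x, ...) {
  cat(sprintf(
    "<flow_model> %s: h_max=%d, caps (single>%.1f, both>%.1f), sum h<=%d\n",
    x$type, x$h_max, x$cap_high_single, x$cap_high_both, x$equal_sum_max))
  invisible(x)
}

#' Parametric default flow model
#'
#' A clearly-labelled stand-in for empirically derived flow-value
#' distributions. The likelihood for h >= 1 is a normal density centred at h
#' with standard deviation `(base_sigma + sigma_slope * h) * (1 +
#' degradation_rate * cycle)`, truncated at zero; for h = 0 it is a
#' right-skewed exponential density with rate `lambda0`, concentrating mass
#' well below the 0.5 calling boundary. The prior decreases geometrically
#' with h (`prior_ratio^h`, normalized over 0..`h_max`), reflecting that
#' most flows in genomic DNA incorporate nothing or a single base.
#'
#' The default widths place the posterior argmax boundary between adjacent
#' homopolymer lengths within about 0.05 of the half-integer calling
#' boundaries over the resolved range.
#'
#' @param degradation_rate Per-cycle relative widening of the likelihood
#'   (default 0.002: ~20\% wider at cycle 100).
#' @param base_sigma Standard deviation offset at h = 0 (default 0.10).
#' @param sigma_slope Additional standard deviation per unit h (default 0.02).
#' @param lambda0 Exponential rate of the h = 0 likelihood (default 23).
#' @param h_max Largest homopolymer length modelled explicitly (default 11).
#' @param prior_ratio Geometric decay of the prior (default 0.4).
#' @return A `flow_model` object.
#' @export
default_parametric_model <- function(degradation_rate = 0.002,
                                     base_sigma = 0.10, sigma_slope = 0.02,
                                     lambda0 = 23, h_max = 11L,
                                     prior_ratio = 0.4) {
  if (base_sigma <= 0) stop("base_sigma must be > 0")
  if (sigma_slope < 0 || degradation_rate < 0 || lambda0 <= 0)
    stop("sigma_slope and degradation_rate must be >= 0, lambda0 > 0")
  params <- list(degradation_rate = degradation_rate, base_sigma = base_sigma,
                 sigma_slope = sigma_slope, lambda0 = lambda0)
  lik <- function(f, h, cycle) {
    if (h == 0L) return(stats::dexp(f, rate = lambda0))
    s <- (base_sigma + sigma_slope * h) * (1 + degradation_rate * cycle)
    stats::dnorm(f, mean = h, sd = s) / (1 - stats::pnorm(0, mean = h, sd = s))
  }
  new_flow_model("parametric", h_max, prior_ratio^(0:h_max), lik, params)
}

# Posterior matrix over h = 0..h_max for a vector of flow values at one
# cycle; rows sum to 1. Log-space to survive extreme f.
posterior_matrix <- function(model, f, cycle) {
  hs <- 0:model$h_max
  ll <- vapply(hs, function(h) log(model$lik_fun(f, h, cycle)),
               numeric(length(f)))
  if (length(f) == 1L) ll <- matrix(ll, nrow = 1L)
  ll <- sweep(ll, 2L, -log(model$prior), "-")
  m <- apply(ll, 1L, max)
  w <- exp(ll - m)
  w / rowSums(w)
}

# Posterior grids over flow values 0.00..5.50 (hundredths) are cached per
# cycle in one flat matrix: row (cycle - 1) * grid_n + f * 100 + 1 holds the
# posterior for flow value f at that cycle. Flow values are quantized to
# hundredths, so grid lookup is exact, not an approximation.
grid_rows <- function(model) round(model$cap_high_single * 100) + 1L

ensure_posterior_cycles <- function(model, cycles) {
  cache <- model$cache
  nf <- grid_rows(model)
  maxc <- max(cycles)
  if (is.null(cache$post) || nrow(cache$post) < maxc * nf) {
    post <- matrix(NA_real_, maxc * nf, model$h_max + 1L)
    built <- rep(FALSE, maxc)
    if (!is.null(cache$post)) {
      post[seq_len(nrow(cache$post)), ] <- cache$post
      built[seq_along(cache$built)] <- cache$built
    }
    cache$post <- post
    cache$built <- built
  }
  todo <- unique(cycles[!cache$built[cycles]])
  if (length(todo)) {
    f <- seq(0, model$cap_high_single, by = 0.01)
    for (cyc in todo) {
      cache$post[((cyc - 1L) * nf + 1L):(cyc * nf), ] <-
        posterior_matrix(model, f, cyc)
      cache$built[cyc] <- TRUE
    }
  }
  invisible(NULL)
}

#' Posterior distribution of homopolymer length given a flow value
#'
#' Applies Bayes' theorem: P(h|f) = P(f|h) P(h) / sum_h' P(f|h') P(h').
#'
#' @param model A `flow_model`.
#' @param f A single non-negative flow value.
#' @param cycle Flow cycle (1-based); `ceiling(flow_index / 4)` for a
#'   four-nucleotide flow order.
#' @return Numeric vector of length `h_max + 1`, named "0".."h_max",
#'   summing to 1.
#' @export
posterior_h <- function(model, f, cycle = 1L) {
  if (length(f) != 1L || is.na(f) || f < 0)
    stop("f must be a single non-negative flow value")
  p <- drop(posterior_matrix(model, f, cycle))
  names(p) <- 0:model$h_max
  p
}

#' Probability that two flow values call the same homopolymer length
#'
#' Returns exactly 1 if either value exceeds `cap_high_single` (5.5) or both
#' exceed `cap_high_both` (2.5); otherwise the inner product of the two
#' posteriors over h = 0..`equal_sum_max`, assuming the two flowgrams are
#' independent.
#'
#' @param model A `flow_model`.
#' @param f_a,f_b Non-negative flow values observed at the same flow
#'   position of two reads.
#' @param cycle Flow cycle of that position.
#' @return A probability in [0, 1].
#' @export
prob_equal <- function(model, f_a, f_b, cycle = 1L) {
  if (any(c(f_a, f_b) < 0)) stop("flow values must be non-negative")
  prob_equal_vec(model, f_a, f_b, rep_len(cycle, length(f_a)))
}

#' @rdname prob_equal
#' @param fa,fb Equal-length vectors of flow values at aligned positions.
#' @param cycles Integer vector of flow cycles, one per position.
#' @details `prob_equal_vec` is the vectorized workhorse used by
#'   [flowgram_distance]: values on the hundredth grid are served from a
#'   cached per-cycle posterior grid (exact, since flow values are
#'   quantized to hundredths); anything else falls back to direct
#'   evaluation.
#' @export
prob_equal_vec <- function(model, fa, fb, cycles) {
  n <- length(fa)
  p <- numeric(n)
  capped <- fa > model$cap_high_single | fb > model$cap_high_single |
    (fa > model$cap_high_both & fb > model$cap_high_both)
  p[capped] <- 1
  idx <- which(!capped)
  if (length(idx) == 0L) return(p)
  hsel <- 1:(model$equal_sum_max + 1L)
  ia <- round(fa[idx] * 100); ib <- round(fb[idx] * 100)
  on_grid <- abs(fa[idx] * 100 - ia) < 1e-9 & abs(fb[idx] * 100 - ib) < 1e-9
  og <- idx[on_grid]
  if (length(og)) {
    cyc <- as.integer(cycles[idx][on_grid])
    ensure_posterior_cycles(model, cyc)
    nf <- grid_rows(model)
    ra <- (cyc - 1L) * nf + as.integer(ia[on_grid]) + 1L
    rb <- (cyc - 1L) * nf + as.integer(ib[on_grid]) + 1L
    g <- model$cache$post
    p[og] <- rowSums(g[ra, hsel, drop = FALSE] * g[rb, hsel, drop = FALSE])
  }
  for (k in idx[!on_grid]) {
    pa <- posterior_matrix(model, fa[k], cycles[k])[, hsel, drop = FALSE]
    pb <- posterior_matrix(model, fb[k], cycles[k])[, hsel, drop = FALSE]
    p[k] <- sum(pa * pb)
  }
  pmin(p, 1)
}

#' Export a flow model as a binned lookup table
#'
#' Writes the prior and the likelihood densities, binned over flow values
#' and grouped by representative flow cycles, to a tab-separated file that
#' [load_lookup_model] can read back. The format mirrors published empirical
#' flow-value distributions: a `prior` section with columns `h`, `density`
#' and a `likelihood` section with columns `cycle_bin`, `h`, `f_bin_low`,
#' `f_bin_high`, `density` (piecewise-constant density per flow-value bin).
#'
#' @param model A `flow_model`.
#' @param path Output path.
#' @param cycle_bins Representative cycles at which to tabulate.
#' @param f_max Upper end of the tabulated flow-value range.
#' @param bin_width Flow-value bin width.
#' @return Invisibly, `path`.
#' @export
write_lookup_table <- function(model, path, cycle_bins = c(1L, 50L, 100L),
                               f_max = 14, bin_width = 0.02) {
  lows <- seq(0, f_max - bin_width, by = bin_width)
  rows <- list()
  for (cb in cycle_bins) {
    for (h in 0:model$h_max) {
      mids <- lows + bin_width / 2
      dens <- model$lik_fun(mids, h, cb)
      dens <- dens / sum(dens * bin_width)  # renormalize binning error away
      rows[[length(rows) + 1L]] <- data.frame(
        section = "likelihood", cycle_bin = cb, h = h, f_bin_low = lows,
        f_bin_high = lows + bin_width, density = dens)
    }
  }
  prior <- data.frame(section = "prior", cycle_bin = NA_integer_,
                      h = 0:model$h_max, f_bin_low = NA_real_,
                      f_bin_high = NA_real_, density = model$prior)
  tab <- rbind(prior, do.call(rbind, rows))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a flow model from a binned lookup table
#'
#' Reads the tab-separated format written by [write_lookup_table] (or
#' assembled from empirical flow-value distributions). The likelihood is
#' piecewise-constant per flow-value bin; flow values outside the tabulated
#' range and cycles outside the tabulated cycle bins fall back to the
#' nearest bin. If the table covers homopolymer lengths only up to some h <
#' 5, the equal-length sum is truncated there and a message is emitted.
#'
#' @param path Path to the lookup-table file.
#' @return A `flow_model` object.
#' @export
load_lookup_model <- function(path) {
  tab <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("cannot parse lookup table '%s': %s",
                                     path, conditionMessage(e))))
  need <- c("section", "cycle_bin", "h", "f_bin_low", "f_bin_high", "density")
  if (nrow(tab) == 0L || !all(need %in% names(tab)))
    stop(sprintf("lookup table '%s' is empty or lacks columns: %s",
                 path, paste(setdiff(need, names(tab)), collapse = ", ")))
  prior_rows <- tab[tab$section == "prior", ]
  lik_rows <- tab[tab$section == "likelihood", ]
  if (nrow(prior_rows) == 0L || nrow(lik_rows) == 0L)
    stop(sprintf("lookup table '%s' needs both a prior and a likelihood section",
                 path))
  h_max <- max(prior_rows$h)
  if (!setequal(prior_rows$h, 0:h_max))
    stop(sprintf("lookup table '%s': prior must cover h = 0..%d contiguously",
                 path, h_max))
  prior <- prior_rows$density[order(prior_rows$h)]
  cycle_bins <- sort(unique(lik_rows$cycle_bin))
  lik_tab <- list()
  for (cb in cycle_bins) {
    per_h <- list()
    sub_c <- lik_rows[lik_rows$cycle_bin == cb, ]
    if (!setequal(sub_c$h, 0:h_max))
      stop(sprintf(
        "lookup table '%s': cycle bin %s is missing homopolymer rows (need h = 0..%d)",
        path, cb, h_max))
    for (h in 0:h_max) {
      sub <- sub_c[sub_c$h == h, ]
      sub <- sub[order(sub$f_bin_low), ]
      mass <- sum(sub$density * (sub$f_bin_high - sub$f_bin_low))
      if (abs(mass - 1) > 1e-3)
        stop(sprintf(
          "lookup table '%s': density for cycle bin %s, h = %d integrates to %.4f, not 1",
          path, cb, h, mass))
      per_h[[h + 1L]] <- list(low = sub$f_bin_low, dens = sub$density)
    }
    lik_tab[[as.character(cb)]] <- per_h
  }
  message(sprintf(
    "lookup table covers homopolymer lengths h <= %d%s", h_max,
    if (h_max < 5L) "; equal-length sum truncated accordingly" else ""))
  lik <- function(f, h, cycle) {
    cb <- cycle_bins[which.min(abs(cycle_bins - cycle))]
    entry <- lik_tab[[as.character(cb)]][[h + 1L]]
    i <- findInterval(f, entry$low)
    i[i < 1L] <- 1L                      # nearest-bin fallback below range
    i[i > length(entry$dens)] <- length(entry$dens)  # and above
    entry$dens[i]
  }
  new_flow_model("lookup", h_max, prior, lik,
                 params = list(path = path, cycle_bins = cycle_bins),
                 equal_sum_max = min(5L, h_max))
}
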