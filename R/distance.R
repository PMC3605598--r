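#' Distance configuration
#'
#' @param model A `flow_model` used for the per-flow equal-homopolymer
#'   probabilities.
#' @param max_flows Largest number of flows compared per pair (default 400);
#'   the comparison window additionally ends at the lower of the two reads'
#'   trim points.
#' @return A `distance_config` object.
#' @export
distance_config <- function(model = default_parametric_model(),
                            max_flows = 400L) {
  if (max_flows < 1L) stop("max_flows must be >= 1")
  structure(list(model = model, max_flows = as.integer(max_flows)),
            class = "distance_config")
}

#' Flow-space distance between two flowgrams
#'
#' Compares the two reads flow by flow over their shared informative window:
#' from the first flow after the key up to `n = min(max_flows, trim end of
#' a, trim end of b)` flows. At each flow i the model gives p_i, the
#' probability that both flow values call the same homopolymer length; the
#' distance is
#'
#'   d = 1 - (prod p_i)^(1/n)
#'
#' i.e. one minus the geometric mean of the per-flow agreement
#' probabilities. This normalization keeps d in [0, 1] and comparable
#' across window lengths; d = 0 exactly when every p_i = 1 (all compared
#' values fall under the capping rules). The product is accumulated as a sum
#' of logarithms; any p_i = 0 gives d = 1.
#'
#' Duplicate reads share their template start by construction, so flows are
#' aligned by absolute flow index and no offset search is performed.
#'
#' @param fg_a,fg_b [flowgram] objects sharing a flow order.
#' @param cfg A [distance_config].
#' @return A distance in [0, 1]; symmetric in its arguments.
#' @export
flowgram_distance <- function(fg_a, fg_b, cfg = distance_config()) {
  if (substr(fg_a$flow_order, 1, 4) != substr(fg_b$flow_order, 1, 4))
    stop(sprintf("reads '%s' and '%s' have different flow orders",
                 fg_a$read_id, fg_b$read_id))
  w_a <- flow_window(fg_a)
  w_b <- flow_window(fg_b)
  start <- max(w_a[1], w_b[1])
  end <- min(w_a[2], w_b[2], start + cfg$max_flows - 1L)
  if (end < start)
    stop(sprintf("reads '%s' and '%s' share no informative flows",
                 fg_a$read_id, fg_b$read_id))
  flows <- start:end
  p <- prob_equal_vec(cfg$model, fg_a$flow_values[flows],
                      fg_b$flow_values[flows], ceiling(flows / 4))
  if (any(p == 0)) return(1)
  1 - exp(mean(log(p)))
}
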