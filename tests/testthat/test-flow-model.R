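model <- default_parametric_model()

test_that("prior normalizes and bad parameters are rejected", {
  expect_equal(sum(model$prior), 1)
  expect_true(all(diff(model$prior) < 0))  # monotonically decreasing
  expect_error(default_parametric_model(base_sigma = 0), "base_sigma")
  expect_error(default_parametric_model(degradation_rate = -1),
               "degradation_rate")
})

test_that("likelihood densities integrate to 1", {
  f <- seq(0, model$h_max + 3, by = 0.002)
  for (cyc in c(1L, 100L)) {
    for (h in 0:model$h_max) {
      dens <- model$lik_fun(f, h, cyc)
      mass <- sum((dens[-1] + dens[-length(dens)]) / 2 * diff(f))
      expect_lt(abs(mass - 1), 1e-3)
    }
  }
})

test_that("posterior normalizes everywhere and matches brute force", {
  for (f in c(0, 0.02, 0.37, 1, 2.49, 3.5, 5.5)) {
    p <- posterior_h(model, f, cycle = 7)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(unname(p), oracle_posterior(model, f, 7), tolerance = 1e-9)
  }
  expect_error(posterior_h(model, -0.1), "non-negative")
})

test_that("posterior argmax follows half-up rounding away from boundaries", {
  # crossovers between adjacent h sit within ~0.05 of the half-integers;
  # probe at least 0.1 away from every boundary
  f <- seq(0.2, 5.3, by = 0.01)
  f <- f[abs(f - (floor(f) + 0.5)) >= 0.1]
  for (x in f) {
    p <- posterior_h(model, x, cycle = 1)
    expect_identical(unname(which.max(p)) - 1L, call_length(x),
                     label = sprintf("argmax at f=%.2f", x))
  }
  expect_gt(posterior_h(model, 0.02, 1)[["0"]], 0.99)
  expect_identical(unname(which.max(posterior_h(model, 1.00, 1))) - 1L, 1L)
})

test_that("degradation_rate 0 makes the likelihood cycle-independent", {
  m0 <- default_parametric_model(degradation_rate = 0)
  f <- seq(0, 5.5, by = 0.25)
  for (x in f)
    expect_equal(posterior_h(m0, x, 1), posterior_h(m0, x, 150))
  # and with degradation the posterior does widen with cycle
  expect_false(isTRUE(all.equal(posterior_h(model, 2.6, 1),
                                posterior_h(model, 2.6, 190))))
})

test_that("prob_equal applies the capping rules exactly", {
  expect_identical(prob_equal(model, 6.2, 0.1), 1)
  expect_identical(prob_equal(model, 2.6, 2.7), 1)
  expect_lt(prob_equal(model, 2.6, 0.1), 1e-6)  # mixed case: sum applies
  expect_error(prob_equal(model, -1, 0.5), "non-negative")
})

test_that("prob_equal is symmetric and matches the brute-force sum", {
  set.seed(101)
  fa <- round(runif(40, 0, 6), 2)
  fb <- round(runif(40, 0, 6), 2)
  cyc <- sample(1:100, 40, replace = TRUE)
  for (i in seq_along(fa)) {
    p1 <- prob_equal(model, fa[i], fb[i], cyc[i])
    expect_equal(p1, prob_equal(model, fb[i], fa[i], cyc[i]))
    expect_equal(p1, oracle_prob_equal(model, fa[i], fb[i], cyc[i]),
                 tolerance = 1e-9)
    expect_true(p1 >= 0 && p1 <= 1)
  }
  # worked value: equal flow values give the sum of squared posteriors
  pa <- posterior_h(model, 1.00, 1)
  expect_equal(prob_equal(model, 1.00, 1.00, 1), sum(pa[1:6]^2),
               tolerance = 1e-12)
})

test_that("grid-backed evaluation agrees with direct evaluation", {
  direct <- default_parametric_model()  # fresh cache
  fa <- seq(0, 5.5, by = 0.13)
  fb <- rev(seq(0, 5.5, length.out = length(fa)))
  fb <- round(fb, 2)
  p_grid <- prob_equal_vec(model, fa, fb, rep(3L, length(fa)))
  p_direct <- vapply(seq_along(fa), function(i)
    oracle_prob_equal(direct, fa[i], fb[i], 3L), 0)
  expect_equal(p_grid, p_direct, tolerance = 1e-6)
})

test_that("prob_equal decreases away from agreement in the resolved range", {
  # same side of the shared integer, both below the both-cap
  f0 <- c(1.05, 2.05, 0.1)
  for (f in f0) {
    steps <- seq(0, 0.35, by = 0.05)
    p <- vapply(steps, function(s) prob_equal(model, f, f + s, 5L), 0)
    expect_true(all(diff(p) <= 1e-12))
  }
  # the best partner for f lies in f's own homopolymer basin: the inner
  # product rewards the partner whose posterior is most concentrated on
  # round(f), so the argmax sits near the integer, not exactly at f
  partners <- seq(0.5, 2.4, by = 0.01)
  p <- vapply(partners, function(x) prob_equal(model, 1.2, x, 1L), 0)
  expect_identical(call_length(partners[which.max(p)]), 1L)
  expect_gt(prob_equal(model, 1.2, 1.2, 1L), prob_equal(model, 1.2, 1.7, 1L))
  expect_gt(prob_equal(model, 1.2, 1.2, 1L), prob_equal(model, 1.2, 0.7, 1L))
})

test_that("lookup-table round trip reproduces the parametric posteriors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lookup_table(model, path, cycle_bins = c(1L, 50L, 100L))
  lm <- suppressMessages(load_lookup_model(path))
  expect_identical(lm$type, "lookup")
  # probe away from posterior crossovers, where binning error is magnified
  for (f in c(0.05, 0.97, 2.03, 3.42)) {
    expect_equal(unname(posterior_h(lm, f, 1)),
                 unname(posterior_h(model, f, 1)), tolerance = 0.05)
  }
  # nearest-bin fallback outside the tabulated range must not error
  expect_equal(sum(posterior_h(lm, 5.5, 400L)), 1, tolerance = 1e-9)
})

test_that("lookup-table validation rejects broken tables", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("", empty)
  expect_error(load_lookup_model(empty), "empty|parse")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_lookup_table(model, path, cycle_bins = 1L)
  tab <- utils::read.delim(path)
  broken <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab[!(tab$section == "likelihood" & tab$h == 3), ],
                     broken, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_lookup_model(broken), "missing homopolymer rows")

  tab2 <- tab
  tab2$density[tab2$section == "likelihood" & tab2$h == 2] <-
    tab2$density[tab2$section == "likelihood" & tab2$h == 2] * 2
  utils::write.table(tab2, broken, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(load_lookup_model(broken), "integrates")
})

test_that("a table truncated at h = 5 loads with a message", {
  m5 <- default_parametric_model(h_max = 5L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lookup_table(m5, path, cycle_bins = 1L, f_max = 9)
  expect_message(lm <- load_lookup_model(path), "h <= 5")
  expect_identical(lm$h_max, 5L)
  expect_equal(sum(posterior_h(lm, 1.1, 1)), 1, tolerance = 1e-9)
})
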