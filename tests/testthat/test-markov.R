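test_that("sliding windows honour the count formula and boundaries", {
  lab12 <- random_labels(12)
  w <- sliding_windows(lab12, window_size = 10, step = 1)
  expect_length(w, 3)
  expect_equal(vapply(w, `[[`, integer(1), "start_index"), 0:2)
  expect_identical(w[[2]]$labels, lab12[2:11])

  expect_length(sliding_windows(random_labels(10), 10), 1)
  expect_warning(none <- sliding_windows(random_labels(9), 10), "shorter")
  expect_length(none, 0)

  # closed-form count for random lengths, widths and steps
  set.seed(5)
  for (rep in 1:30) {
    L <- sample(2:80, 1); ws <- sample(2:20, 1); st <- sample(1:5, 1)
    got <- suppressWarnings(
      length(sliding_windows(random_labels(L), ws, st)))
    expect_equal(got, if (L >= ws) floor((L - ws) / st) + 1 else 0)
  }
})

test_that("the transition estimator reproduces hand-counted examples", {
  # the canonical window [A, A, A, N, A, N]: 5 adjacent pairs
  m <- estimate_transition_matrix(c("A", "A", "A", "N", "A", "N"))
  expect_equal(as.vector(m$counts), c(2L, 1L, 2L, 0L)) # AA, NA, AN, NN
  expect_equal(m$p["A", "A"], 0.5)
  expect_equal(m$p["A", "N"], 0.5)
  expect_equal(m$p["N", "A"], 1.0)
  expect_equal(m$p["N", "N"], 0.0)

  # single-state window: the other row is undefined, never imputed
  mn <- estimate_transition_matrix(c("N", "N", "N", "N"))
  expect_equal(mn$p["N", "N"], 1.0)
  expect_equal(mn$p["N", "A"], 0.0)
  expect_true(all(is.na(mn$p["A", ])))

  expect_error(estimate_transition_matrix("A"), "at least 2")
})

test_that("estimator matches the brute-force pair-counting oracle on random windows", {
  set.seed(7)
  for (rep in 1:200) {
    lab <- random_labels(sample(2:50, 1))
    got <- estimate_transition_matrix(lab)
    want <- brute_force_tm(lab)
    expect_equal(got$p, want$p)
    expect_equal(as.vector(got$counts), as.vector(want$counts))
  }
})

test_that("every defined row of every window-level matrix conserves probability", {
  set.seed(8)
  for (rep in 1:20) {
    fit <- rsa_markov(simulate_markov_rr(n_intervals = 120,
                                         seed = rep)$rr)
    row_a <- fit$window_p[, "AA"] + fit$window_p[, "AN"]
    row_n <- fit$window_p[, "NA"] + fit$window_p[, "NN"]
    expect_true(all(abs(row_a[!is.na(row_a)] - 1) <= 1e-12))
    expect_true(all(abs(row_n[!is.na(row_n)] - 1) <= 1e-12))
  }
})

test_that("the vectorised window fit agrees with per-window estimation", {
  set.seed(9)
  rr <- simulate_markov_rr(n_intervals = 200, seed = 3,
                           out_of_band_mode = "mixed")$rr
  for (st in c(1, 3)) {
    fit <- rsa_markov(rr, window_size = 10, step = st)
    wins <- sliding_windows(classify_states(rr, fit$band), 10, st)
    expect_equal(fit$n_windows, length(wins))
    for (k in seq_along(wins)) {
      ref <- estimate_transition_matrix(wins[[k]])
      expect_equal(unname(fit$window_p[k, ]),
                   c(ref$p["A", "A"], ref$p["A", "N"],
                     ref$p["N", "A"], ref$p["N", "N"]))
    }
  }
})

test_that("degenerate and forced inputs produce the predicted window probabilities", {
  band <- alpha_band(800, 1000)
  # all inside the band: N row trivial, A row undefined everywhere
  fit_in <- rsa_markov(rep(900, 30), band = band)
  expect_true(all(fit_in$window_p[, "NN"] == 1))
  expect_true(all(fit_in$window_p[, "NA"] == 0))
  expect_true(all(is.na(fit_in$window_p[, "AA"])))
  expect_length(fit_in$samples[["AA"]], 0)
  expect_length(fit_in$samples[["NN"]], fit_in$n_windows)

  # strict alternation forces both cross-transitions to 1 in every window
  fit_alt <- rsa_markov(rep(c(900, 1200), 20), band = band)
  expect_true(all(fit_alt$window_p[, "AN"] == 1))
  expect_true(all(fit_alt$window_p[, "NA"] == 1))

  # record shorter than the window: zero windows, with a warning
  expect_warning(fit0 <- rsa_markov(rep(900, 5), band = band), "window")
  expect_equal(fit0$n_windows, 0)
})

test_that("fit accessors expose the whole-sequence estimate and pooled samples", {
  sim <- simulate_markov_rr(n_intervals = 400, seed = 21)
  fit <- rsa_markov(sim$rr)
  p <- coef(fit)
  expect_equal(dim(p), c(2, 2))
  expect_equal(rowSums(p), c(A = 1, N = 1), tolerance = 1e-12)
  expect_identical(pooled_samples(list(fit), "AA"), fit$samples[["AA"]])

  s <- summary(fit)
  expect_equal(s$table$transition,
               c("A to A", "A to N", "N to A", "N to N"))
  expect_equal(s$table$n, unname(vapply(fit$samples, length, integer(1))))
})
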