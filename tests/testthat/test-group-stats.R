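test_that("pooled-sample summaries use the sample SD and flag degenerate input", {
  s <- summarize_probs(c(0, 1, 1, 1))
  expect_equal(s$mean, 0.75)
  expect_equal(s$sd, 0.5)
  expect_equal(s$n, 4L)

  expect_warning(e <- summarize_probs(numeric(0)), "empty")
  expect_true(is.na(e$mean) && is.na(e$sd))

  one <- summarize_probs(0.5)
  expect_equal(one$mean, 0.5)
  expect_true(is.na(one$sd))
})

test_that("Mann-Whitney U reproduces known exact p-values and symmetries", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u_statistic, 0)
  expect_equal(r$p_value, 0.1)
  expect_identical(r$method, "exact")

  # identical multisets: perfect symmetry, p = 1
  x <- c(0, 0, 1, 0.5, 1)
  same <- mann_whitney_u(x, x, mode = "approx")
  expect_equal(same$p_value, 1)

  set.seed(13)
  for (rep in 1:20) {
    a <- sample(c(0, 0.25, 0.5, 1), sample(3:6, 1), replace = TRUE)
    b <- sample(c(0, 0.25, 0.5, 1), sample(3:6, 1), replace = TRUE)
    r1 <- mann_whitney_u(a, b)
    # invariant under a strictly decreasing transform of both samples
    r2 <- mann_whitney_u(1 - a, 1 - b)
    expect_equal(r1$p_value, r2$p_value)
    # the two one-sided statistics partition the pair count
    expect_equal(r1$u_statistic + r1$u_other, length(a) * length(b))
  }

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact mode agrees with the pair-counting enumeration oracle, ties included", {
  set.seed(17)
  for (rep in 1:25) {
    nx <- sample(1:6, 1); ny <- sample(1:6, 1)
    vals <- c(0, 0.5, 1, 2, 3)
    x <- sample(vals, nx, replace = TRUE)
    y <- sample(vals, ny, replace = TRUE)
    expect_equal(mann_whitney_u(x, y, mode = "exact")$p_value,
                 mw_enum_oracle(x, y))
  }
})

test_that("both modes agree with stats::wilcox.test where it applies", {
  set.seed(19)
  for (rep in 1:10) {
    x <- rnorm(sample(4:8, 1)); y <- rnorm(sample(4:8, 1)) # tie-free
    expect_equal(mann_whitney_u(x, y, mode = "exact")$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value)
    xb <- rnorm(30); yb <- rnorm(35)
    expect_equal(mann_whitney_u(xb, yb, mode = "approx")$p_value,
                 wilcox.test(xb, yb, exact = FALSE, correct = TRUE)$p.value)
    # tie-heavy approximate case
    xt <- sample(0:2, 40, TRUE); yt <- sample(0:2, 45, TRUE)
    expect_equal(mann_whitney_u(xt, yt, mode = "approx")$p_value,
                 wilcox.test(xt, yt, exact = FALSE, correct = TRUE)$p.value)
  }
})

test_that("auto mode refuses infeasible enumerations gracefully", {
  x <- c(0.2, 0.4, 0.6)
  y <- runif(500)
  r <- mann_whitney_u(x, y) # min n <= 8 but choose(503, 3) is too large
  expect_identical(r$method, "normal_approximation")
  expect_error(mann_whitney_u(x, y, mode = "exact"), "limit")
})

test_that("group comparison mirrors the published table structure", {
  mkgrp <- function(seeds) {
    lapply(seeds, function(k)
      rsa_markov(simulate_markov_rr(n_intervals = 300, seed = k)$rr))
  }
  cmp <- compare_groups(mkgrp(1:3), mkgrp(11:13),
                        labels = c("with", "without"))
  tab <- cmp$table
  expect_equal(tab$transition, c("A to N", "A to A", "N to A", "N to N"))

  an <- tab[tab$transition == "A to N", ]
  aa <- tab[tab$transition == "A to A", ]
  na_ <- tab[tab$transition == "N to A", ]
  nn <- tab[tab$transition == "N to N", ]

  # complement pairs: means sum to 1, identical SDs, identical p-values
  expect_equal(an$mean_a + aa$mean_a, 1)
  expect_equal(an$mean_b + aa$mean_b, 1)
  expect_identical(an$sd_a, aa$sd_a)
  expect_identical(an$p_value, aa$p_value)
  expect_equal(na_$mean_a + nn$mean_a, 1)
  expect_identical(na_$p_value, nn$p_value)
  expect_true(all(tab$u_statistic <= tab$n_a * tab$n_b))
})

test_that("a transition undefined in one group is reported not-computable, others survive", {
  all_in <- lapply(1:2, function(k) rsa_markov(rep(900, 40 + k)))
  mixed <- lapply(3:4, function(k)
    rsa_markov(simulate_markov_rr(n_intervals = 100, seed = k)$rr))
  cmp <- compare_groups(all_in, mixed)
  tab <- cmp$table
  expect_identical(tab$method[tab$transition == "A to A"], "not_computable")
  expect_true(is.na(tab$p_value[tab$transition == "A to A"]))
  expect_identical(tab$method[tab$transition == "N to N"],
                   "normal_approximation")
  expect_false(is.na(tab$p_value[tab$transition == "N to N"]))
})
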